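// Low-level k-mer kernels: canonical k-mer counting, unitig graph
// construction, greedy seed clustering, and seed-and-extend read mapping.
// k is limited to 26 so that canonical codes are exact in a double when
// round-tripped through R.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline uint64_t rc_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; i++) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) {
    s[i] = B[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// Count canonical k-mers over all reads; windows containing non-ACGT are
// skipped, reads shorter than k contribute nothing.
static void count_canonical(const std::vector<std::string>& reads, int k,
                            std::unordered_map<uint64_t, double>& cnt) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (const std::string& s : reads) {
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t f = 0, r = 0;
    int valid = 0;
    for (int i = 0; i < n; i++) {
      int b = b2i(s[i]);
      if (b < 0) { valid = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++valid >= k) cnt[std::min(f, r)] += 1.0;
    }
  }
}

static std::vector<std::string> as_strings(const CharacterVector& x) {
  std::vector<std::string> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) out[i] = as<std::string>(x[i]);
  return out;
}

// Build the unitig graph: canonical k-mer nodes with reverse-complement
// twins are implicit; maximal non-branching chains are merged into unitigs.
// Edges connect oriented unitig ends with k-1 base overlap; both mirror
// directions are emitted.
// [[Rcpp::export]]
List cpp_unitig_graph(CharacterVector reads_, int k) {
  if (k < 4 || k > 26) stop("k must be in [4, 26]");
  std::vector<std::string> reads = as_strings(reads_);
  std::unordered_map<uint64_t, double> cnt;
  count_canonical(reads, k, cnt);

  const uint64_t mask = (1ULL << (2 * k)) - 1;
  auto canon = [&](uint64_t x) { uint64_t r = rc_code(x, k); return x < r ? x : r; };
  auto exists = [&](uint64_t x) { return cnt.find(canon(x)) != cnt.end(); };
  auto succs = [&](uint64_t x, uint64_t out[4]) {
    int m = 0;
    for (uint64_t b = 0; b < 4; b++) {
      uint64_t t = ((x << 2) | b) & mask;
      if (exists(t)) out[m++] = t;
    }
    return m;
  };
  auto preds = [&](uint64_t x, uint64_t out[4]) {
    int m = 0;
    for (uint64_t b = 0; b < 4; b++) {
      uint64_t t = (x >> 2) | (b << (2 * (k - 1)));
      if (exists(t)) out[m++] = t;
    }
    return m;
  };

  // deterministic node order
  std::vector<uint64_t> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::unordered_set<uint64_t> visited;
  visited.reserve(cnt.size() * 2);
  std::vector<std::string> useq;
  std::vector<double> ucov;
  std::vector<int> unk;
  std::vector<uint64_t> ufirst, ulast;

  auto is_start = [&](uint64_t x) {
    uint64_t p[4];
    int np = preds(x, p);
    if (np != 1) return true;
    uint64_t s2[4];
    int ns = succs(p[0], s2);
    if (ns != 1) return true;
    if (canon(p[0]) == canon(x)) return true;  // self-loop / palindrome
    return false;
  };

  auto walk = [&](uint64_t s) {
    std::string seq = decode_kmer(s, k);
    double cv = cnt[canon(s)];
    int nk = 1;
    visited.insert(canon(s));
    // oriented k-mers used in this walk: a chain may legitimately pass
    // through the twin of one of its own k-mers (even-k hairpins), but
    // never through the same oriented k-mer twice
    std::unordered_set<uint64_t> used, walk_canon;
    used.insert(s);
    walk_canon.insert(canon(s));
    uint64_t cur = s;
    while (true) {
      uint64_t sc[4];
      int ns = succs(cur, sc);
      if (ns != 1) break;
      uint64_t t = sc[0];
      uint64_t pd[4];
      int np = preds(t, pd);
      if (np != 1) break;
      if (used.count(t)) break;
      if (visited.count(canon(t)) && !walk_canon.count(canon(t))) break;
      seq.push_back("ACGT"[t & 3ULL]);
      cv += cnt[canon(t)];
      nk++;
      visited.insert(canon(t));
      used.insert(t);
      walk_canon.insert(canon(t));
      cur = t;
    }
    useq.push_back(seq);
    ucov.push_back(cv);
    unk.push_back(nk);
    ufirst.push_back(s);
    ulast.push_back(cur);
  };

  for (uint64_t c : keys) {
    if (visited.count(c)) continue;
    uint64_t r = rc_code(c, k);
    if (is_start(c)) walk(c);
    else if (is_start(r)) walk(r);
    // interior nodes are reached from their chain start; pure cycles below
  }
  for (uint64_t c : keys)
    if (!visited.count(c)) walk(c);

  // oriented start-kmer -> (unitig, orientation)
  const int NU = (int)useq.size();
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> startmap;
  for (int u = 0; u < NU; u++) {
    startmap[ufirst[u]].push_back(std::make_pair(u, 0));
    startmap[rc_code(ulast[u], k)].push_back(std::make_pair(u, 1));
  }
  std::vector<int> ef, eto, efo, etoo;
  for (int u = 0; u < NU; u++) {
    for (int o = 0; o < 2; o++) {
      uint64_t e = (o == 0) ? ulast[u] : rc_code(ufirst[u], k);
      uint64_t sc[4];
      int ns = succs(e, sc);
      for (int i = 0; i < ns; i++) {
        auto it = startmap.find(sc[i]);
        if (it == startmap.end()) continue;
        for (auto& pv : it->second) {
          ef.push_back(u + 1);
          efo.push_back(o);
          eto.push_back(pv.first + 1);
          etoo.push_back(pv.second);
        }
      }
    }
  }

  return List::create(
      _["seq"] = wrap(useq), _["cov"] = wrap(ucov), _["nk"] = wrap(unk),
      _["edge_from"] = wrap(ef), _["edge_fo"] = wrap(efo),
      _["edge_to"] = wrap(eto), _["edge_to_or"] = wrap(etoo));
}

// Reverse complement of DNA strings (A/C/G/T/N; other characters pass
// through complemented to N).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  const R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
      switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        case 'a': c = 't'; break;
        case 'c': c = 'g'; break;
        case 'g': c = 'c'; break;
        case 't': c = 'a'; break;
        case 'N': c = 'N'; break;
        default: c = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// Index of every valid k-mer window in every read, keyed by canonical code.
// pos/strand are expressed in the *oriented* read: the read as given when
// strand = 1, its reverse complement when strand = -1, such that the
// canonical spelling occurs forward at `pos` (0-based).
// [[Rcpp::export]]
DataFrame cpp_read_kmer_index(CharacterVector reads_, int k) {
  if (k < 4 || k > 26) stop("k must be in [4, 26]");
  std::vector<std::string> reads = as_strings(reads_);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<double> kk;
  std::vector<int> rd, ps, st;
  for (size_t i = 0; i < reads.size(); i++) {
    const std::string& s = reads[i];
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t f = 0, r = 0;
    int valid = 0;
    for (int j = 0; j < n; j++) {
      int b = b2i(s[j]);
      if (b < 0) { valid = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++valid >= k) {
        int wpos = j - k + 1;
        if (f <= r) {
          kk.push_back((double)f);
          rd.push_back((int)i + 1);
          ps.push_back(wpos);
          st.push_back(1);
        } else {
          kk.push_back((double)r);
          rd.push_back((int)i + 1);
          ps.push_back(n - k - wpos);
          st.push_back(-1);
        }
      }
    }
  }
  return DataFrame::create(_["kmer"] = wrap(kk), _["read"] = wrap(rd),
                           _["pos"] = wrap(ps), _["strand"] = wrap(st));
}

// Greedy seed clustering: iterate k-mers in decreasing multiplicity
// (ties broken by code); each k-mer still carried by >= min_depth
// unconsumed reads founds a cluster of all such reads. Returns per-read
// cluster id (0 = none), seed k-mer offset in the oriented read, and
// orientation, plus the seed k-mer of each cluster.
// [[Rcpp::export]]
List cpp_seed_clusters(CharacterVector reads_, int k, int min_depth) {
  if (k < 4 || k > 26) stop("k must be in [4, 26]");
  std::vector<std::string> reads = as_strings(reads_);
  const int NR = (int)reads.size();
  std::unordered_map<uint64_t, double> cnt;
  count_canonical(reads, k, cnt);

  std::vector<std::pair<double, uint64_t>> order;  // (-count, code)
  order.reserve(cnt.size());
  for (auto& kv : cnt)
    if (kv.second >= min_depth) order.push_back(std::make_pair(-kv.second, kv.first));
  std::sort(order.begin(), order.end());

  std::unordered_set<uint64_t> keep;
  keep.reserve(order.size() * 2);
  for (auto& p : order) keep.insert(p.second);

  // occurrence lists only for candidate seed k-mers
  struct Occ { int read, pos, strand; };
  std::unordered_map<uint64_t, std::vector<Occ>> occ;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int i = 0; i < NR; i++) {
    const std::string& s = reads[i];
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t f = 0, r = 0;
    int valid = 0;
    for (int j = 0; j < n; j++) {
      int b = b2i(s[j]);
      if (b < 0) { valid = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t c = std::min(f, r);
        if (!keep.count(c)) continue;
        int wpos = j - k + 1;
        Occ o;
        o.read = i;
        if (f <= r) { o.pos = wpos; o.strand = 1; }
        else { o.pos = n - k - wpos; o.strand = -1; }
        occ[c].push_back(o);
      }
    }
  }

  IntegerVector cluster(NR, 0), offset(NR, NA_INTEGER), strand(NR, NA_INTEGER);
  std::vector<bool> consumed(NR, false);
  std::vector<std::string> seed_kmers;
  int cid = 0;
  std::vector<int> members;
  for (auto& p : order) {
    uint64_t code = p.second;
    auto it = occ.find(code);
    if (it == occ.end()) continue;
    members.clear();
    std::unordered_set<int> seen;
    for (const Occ& o : it->second) {
      if (consumed[o.read] || seen.count(o.read)) continue;
      seen.insert(o.read);
      members.push_back((int)(&o - &it->second[0]));
    }
    if ((int)members.size() < min_depth) continue;
    cid++;
    seed_kmers.push_back(decode_kmer(code, k));
    for (int mi : members) {
      const Occ& o = it->second[mi];
      consumed[o.read] = true;
      cluster[o.read] = cid;
      offset[o.read] = o.pos;
      strand[o.read] = o.strand;
    }
  }
  return List::create(_["cluster"] = cluster, _["offset"] = offset,
                      _["strand"] = strand, _["n_clusters"] = cid,
                      _["seed_kmer"] = wrap(seed_kmers));
}

// Canonical code of each word (length 4..26, per-word length allowed).
// Returns NA for words containing non-ACGT. fwd indicates whether the
// canonical spelling equals the word itself.
// [[Rcpp::export]]
DataFrame cpp_canonical_code(CharacterVector words) {
  const R_xlen_t n = words.size();
  NumericVector code(n);
  LogicalVector fwd(n);
  for (R_xlen_t i = 0; i < n; i++) {
    std::string w = as<std::string>(words[i]);
    int k = (int)w.size();
    if (k < 4 || k > 26) stop("word length must be in [4, 26]");
    uint64_t f = 0;
    bool ok = true;
    for (int j = 0; j < k; j++) {
      int b = b2i(w[j]);
      if (b < 0) { ok = false; break; }
      f = (f << 2) | (uint64_t)b;
    }
    if (!ok) {
      code[i] = NA_REAL;
      fwd[i] = NA_LOGICAL;
      continue;
    }
    uint64_t r = rc_code(f, k);
    code[i] = (double)std::min(f, r);
    fwd[i] = (f <= r);
  }
  return DataFrame::create(_["code"] = code, _["fwd"] = fwd);
}

// Per-read agreement with a consensus string given alignment offsets
// (0-based column of the read's first base; may be negative or beyond the
// consensus for overhanging reads). Agreement is computed over the
// overlapping columns only.
// [[Rcpp::export]]
List cpp_agreement(CharacterVector reads_, IntegerVector offsets,
                   std::string consensus) {
  const int L = (int)consensus.size();
  const R_xlen_t n = reads_.size();
  NumericVector frac(n);
  IntegerVector overlap(n);
  for (R_xlen_t i = 0; i < n; i++) {
    std::string s = as<std::string>(reads_[i]);
    int off = offsets[i];
    int lo = std::max(0, -off);
    int hi = std::min((int)s.size(), L - off);
    int ov = std::max(0, hi - lo), match = 0;
    for (int j = lo; j < hi; j++)
      if (s[j] == consensus[j + off]) match++;
    overlap[i] = ov;
    frac[i] = ov > 0 ? (double)match / ov : 0.0;
  }
  return List::create(_["frac"] = frac, _["overlap"] = overlap);
}

// Seed-and-extend ungapped mapper. References indexed by exact seed_len-mers
// (forward strand); reads are queried forward and, if both_strands,
// reverse-complemented. Disjoint seed offsets guarantee any placement with
// <= floor(len/seed_len) - 1 mismatches is found. Best hit per read:
// fewest mismatches, ties to the lowest reference index, then + strand,
// then leftmost position.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector refs_, CharacterVector reads_,
                   int seed_len, int max_mm, bool both_strands) {
  if (seed_len < 4 || seed_len > 26) stop("seed_len must be in [4, 26]");
  std::vector<std::string> refs = as_strings(refs_);
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;

  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (size_t ri = 0; ri < refs.size(); ri++) {
    const std::string& s = refs[ri];
    const int n = (int)s.size();
    if (n < seed_len) continue;
    uint64_t f = 0;
    int valid = 0;
    for (int j = 0; j < n; j++) {
      int b = b2i(s[j]);
      if (b < 0) { valid = 0; f = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len)
        index[f].push_back(std::make_pair((int)ri, j - seed_len + 1));
    }
  }

  auto revcomp = [](const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
      switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default: c = 'N';
      }
    }
    return r;
  };

  const R_xlen_t NR = reads_.size();
  IntegerVector best_ref(NR, 0), best_mm(NR, NA_INTEGER),
      best_strand(NR, NA_INTEGER), best_pos(NR, NA_INTEGER);

  for (R_xlen_t i = 0; i < NR; i++) {
    std::string fwd = as<std::string>(reads_[i]);
    const int len = (int)fwd.size();
    if (len < seed_len) continue;
    int bmm = max_mm + 1, bref = -1, bstr = 0, bpos = -1;
    std::unordered_set<uint64_t> tried;
    for (int strand = 0; strand < (both_strands ? 2 : 1); strand++) {
      std::string q = strand == 0 ? fwd : revcomp(fwd);
      for (int o = 0; o + seed_len <= len; o += seed_len) {
        uint64_t f = 0;
        bool ok = true;
        for (int j = 0; j < seed_len; j++) {
          int b = b2i(q[o + j]);
          if (b < 0) { ok = false; break; }
          f = (f << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = index.find(f);
        if (it == index.end()) continue;
        for (auto& hit : it->second) {
          int ref = hit.first, start = hit.second - o;
          const std::string& R = refs[ref];
          if (start < 0 || start + len > (int)R.size()) continue;
          uint64_t key =
              (((uint64_t)ref << 32) | (uint64_t)(start + len)) * 2 + strand;
          if (tried.count(key)) continue;
          tried.insert(key);
          int mm = 0;
          for (int j = 0; j < len && mm <= max_mm; j++)
            if (q[j] != R[start + j]) mm++;
          if (mm > max_mm) continue;
          bool better = false;
          if (mm < bmm) better = true;
          else if (mm == bmm && bref >= 0) {
            int cs = strand == 0 ? 1 : -1;
            if (ref < bref) better = true;
            else if (ref == bref) {
              if (cs > bstr) better = true;                  // + beats -
              else if (cs == bstr && start < bpos) better = true;
            }
          }
          if (better) {
            bmm = mm;
            bref = ref;
            bstr = strand == 0 ? 1 : -1;
            bpos = start;
          }
        }
      }
    }
    if (bref >= 0) {
      best_ref[i] = bref + 1;
      best_mm[i] = bmm;
      best_strand[i] = bstr;
      best_pos[i] = bpos;
    }
  }
  return List::create(_["ref"] = best_ref, _["mm"] = best_mm,
                      _["strand"] = best_strand, _["pos"] = best_pos);
}
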