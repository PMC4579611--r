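# Discriminative motif discovery on the top-ranked ChIPtigs: exact-word
# enumeration scored by Fisher's exact test against a dinucleotide-
# shuffled background, greedy IUPAC generalisation, iterative erasure;
# plus a simplified PWM-vs-database matcher.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

check_iupac <- function(word) {
  ch <- strsplit(word, "")[[1]]
  if (!all(ch %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC symbol in word: ", word)
  }
  invisible(ch)
}

#' Convert an IUPAC word to a regular expression
#'
#' Degenerate symbols become character classes; `N` becomes `[ACGT]`
#' so that N in a scanned sequence (an erased region) never matches.
#'
#' @param word IUPAC word.
#' @return regex string.
#' @export
iupac_to_regex <- function(word) {
  ch <- check_iupac(word)
  paste0(vapply(ch, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1L) set else paste0("[", paste0(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of an IUPAC word
#' @param word IUPAC word.
#' @return IUPAC word.
#' @export
revcomp_iupac <- function(word) {
  ch <- check_iupac(word)
  paste0(rev(unname(IUPAC_COMP[ch])), collapse = "")
}

#' Dinucleotide-preserving shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide (and
#' hence mononucleotide) counts, via a random Eulerian path in the
#' dinucleotide transition multigraph (Altschul-Erickson). Sequences
#' shorter than 2 are passed through. Deterministic given the seed.
#'
#' @param sequences character vector.
#' @param seed RNG seed.
#' @return character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequences, seed = 1L) {
  with_seed(seed, vapply(sequences, shuffle_one, character(1),
                         USE.NAMES = FALSE))
}

shuffle_one <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(s)
  ch <- strsplit(s, "")[[1]]
  verts <- unique(ch)
  vi <- match(ch, verts)
  nv <- length(verts)
  # adjacency multisets: edges[[v]] = vector of target vertex indices
  edges <- split(vi[-1L], factor(vi[-n], levels = seq_len(nv)))
  last <- vi[n]
  if (nv == 1L) return(s)
  # pick a random final exit edge per vertex (except the end vertex) and
  # accept when those final edges form paths that all reach the end vertex
  for (attempt in seq_len(1000L)) {
    final <- rep(NA_integer_, nv)
    for (v in seq_len(nv)) {
      if (v == last || length(edges[[v]]) == 0L) next
      final[v] <- edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }
    ok <- TRUE
    for (v in seq_len(nv)) {
      if (v == last || length(edges[[v]]) == 0L) next
      seen <- v
      cur <- v
      repeat {
        cur <- final[cur]
        if (is.na(cur) || cur == last) break
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) return(s)  # pathological multigraph; leave unshuffled
  # permute remaining edges, appending the reserved final edge
  order_edges <- vector("list", nv)
  for (v in seq_len(nv)) {
    ev <- edges[[v]]
    if (length(ev) == 0L) { order_edges[[v]] <- integer(0); next }
    if (v == last || is.na(final[v])) {
      order_edges[[v]] <- ev[sample.int(length(ev))]
    } else {
      drop1 <- which(ev == final[v])[1]
      rest <- ev[-drop1]
      order_edges[[v]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                            final[v])
    }
  }
  # walk the Eulerian path from the original start vertex
  ptr <- rep(1L, nv)
  out <- integer(n)
  out[1L] <- vi[1L]
  cur <- vi[1L]
  for (i in 2L:n) {
    nxt <- order_edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste0(verts[out], collapse = "")
}

#' Count sequences containing an IUPAC word
#'
#' Number of sequences with at least one match of `word` on either
#' strand (a sequence counts once regardless of match count).
#'
#' @param word IUPAC word.
#' @param sequences character vector.
#' @return integer count.
#' @export
count_sequences_with_word <- function(word, sequences) {
  pat_f <- iupac_to_regex(word)
  pat_r <- iupac_to_regex(revcomp_iupac(word))
  sum(grepl(pat_f, sequences) | grepl(pat_r, sequences))
}

#' One-sided Fisher's exact test for word enrichment
#'
#' Hypergeometric tail probability of observing `a` or more
#' word-containing sequences among the positives, given the margins.
#' Stable in log space (via `phyper`) for margins up to 1e5.
#' Vectorised.
#'
#' @param a positives containing the word.
#' @param b positives lacking it.
#' @param c backgrounds containing it.
#' @param d backgrounds lacking it.
#' @return one-sided P-value(s).
#' @export
fisher_pvalue <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative contingency count")
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Build a PWM from matched sites
#'
#' Column-wise base frequencies with pseudocount 0.1 per base.
#'
#' @param word IUPAC word (defines the expected site length).
#' @param sites character vector of matched site sequences, all of the
#'   word's length.
#' @return L x 4 PWM (columns A,C,G,T; rows sum to 1).
#' @export
word_to_pwm <- function(word, sites) {
  if (length(sites) == 0L) stop("no matched sites")
  w <- nchar(word)
  if (any(nchar(sites) != w)) stop("site length differs from word length")
  m <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  for (s in sites) {
    b <- match(strsplit(s, "")[[1]], BASES)
    ok <- !is.na(b)
    m[cbind(which(ok), b[ok])] <- m[cbind(which(ok), b[ok])] + 1
  }
  sweep(m + 0.1, 1L, rowSums(m) + 0.4, "/")
}

# All word->sequence containment counts for exact words of one length,
# over both strands, via substring enumeration (counts each sequence at
# most once per word). Returns data.table(word, n).
count_words_of_length <- function(seqs, L) {
  both <- c(seqs, revcomp(seqs))
  sid <- rep(seq_along(seqs), 2L)
  n <- nchar(both)
  keep <- n >= L
  both <- both[keep]; sid <- sid[keep]; n <- n[keep]
  words <- unlist(lapply(seq_along(both), function(i) {
    substring(both[i], 1:(n[i] - L + 1L), L:n[i])
  }), use.names = FALSE)
  ids <- rep(sid, n - L + 1L)
  dt <- data.table::data.table(word = words, id = ids)
  dt <- dt[!grepl("N", dt$word, fixed = TRUE)]
  dt <- unique(dt)
  dt[, list(n = .N), by = "word"]
}

# Matched spans of an IUPAC word on both strands; erases them with N.
erase_word <- function(word, seqs) {
  pats <- unique(c(iupac_to_regex(word), iupac_to_regex(revcomp_iupac(word))))
  w <- nchar(word)
  for (pat in pats) {
    m <- gregexpr(pat, seqs)
    for (i in seq_along(seqs)) {
      starts <- m[[i]]
      if (starts[1] == -1L) next
      for (st in starts) {
        substr(seqs[i], st, st + w - 1L) <- strrep("N", w)
      }
    }
  }
  seqs
}

# Forward-oriented instances of the word's matches in the sequences.
collect_sites <- function(word, seqs) {
  w <- nchar(word)
  out <- character(0)
  m <- gregexpr(iupac_to_regex(word), seqs)
  for (i in seq_along(seqs)) {
    starts <- m[[i]]
    if (starts[1] != -1L) {
      out <- c(out, substring(seqs[i], starts, starts + w - 1L))
    }
  }
  rcpat <- iupac_to_regex(revcomp_iupac(word))
  m <- gregexpr(rcpat, seqs)
  for (i in seq_along(seqs)) {
    starts <- m[[i]]
    if (starts[1] != -1L) {
      out <- c(out, revcomp(substring(seqs[i], starts, starts + w - 1L)))
    }
  }
  out
}

# IUPAC symbols whose base set strictly contains the given symbol's set,
# in fixed order for determinism.
iupac_supersets <- function(sym) {
  set <- IUPAC_SETS[[sym]]
  names(Filter(function(s) length(s) > length(set) && all(set %in% s),
               IUPAC_SETS))
}

#' Discriminative motif discovery
#'
#' DREME-style search: the background is a seeded dinucleotide shuffle
#' of the positives. Each round (i) enumerates every exact word of
#' length `min_len..max_len` present in the positives and scores it by
#' the one-sided Fisher test of sequence-containment counts against the
#' background; (ii) generalises the best exact word greedily, trying
#' every IUPAC superset symbol at every position and keeping the single
#' change that most improves the P-value, to a fixpoint; (iii) records
#' the motif with `E = p * (number of exact words evaluated this
#' round)`; (iv) erases all matches of the motif (replaced by N) in
#' positives and background, and repeats until `n_motifs` are found or
#' the best E exceeds `e_threshold`.
#'
#' @param sequences positive set (at least 2 sequences).
#' @param max_len,min_len word length bounds (IUPAC words, <= 8).
#' @param n_motifs maximum motifs reported.
#' @param e_threshold stop when the best motif's E-value exceeds this.
#' @param seed RNG seed (background shuffle).
#' @return list of motifs ranked by discovery order: each has `word`,
#'   `table` (a, b, c, d), `p`, `e`, `pwm`, `nsites`, `rank`, `name`,
#'   `significance`.
#' @export
discover_motifs <- function(sequences, max_len = 8L, min_len = 3L,
                            n_motifs = 10L, e_threshold = 0.05, seed = 1L) {
  if (length(sequences) < 2L) stop("need at least 2 positive sequences")
  pos <- toupper(sequences)
  bg <- dinucleotide_shuffle(pos, seed)
  npos <- length(pos)
  nbg <- length(bg)
  motifs <- list()
  for (round in seq_len(n_motifs)) {
    stats_list <- lapply(min_len:max_len, function(L) {
      cp <- count_words_of_length(pos, L)
      if (nrow(cp) == 0L) return(NULL)
      cb <- count_words_of_length(bg, L)
      dt <- merge(cp, cb, by = "word", all.x = TRUE, suffixes = c("_p", "_b"))
      dt$n_b[is.na(dt$n_b)] <- 0L
      dt
    })
    stats <- data.table::rbindlist(Filter(Negate(is.null), stats_list))
    if (is.null(stats) || nrow(stats) == 0L) break
    n_words <- nrow(stats)
    stats$p <- fisher_pvalue(stats$n_p, npos - stats$n_p, stats$n_b,
                             nbg - stats$n_b)
    best_i <- order(stats$p, stats$word)[1]
    word <- stats$word[best_i]
    p_cur <- stats$p[best_i]
    # Greedy IUPAC generalisation of the best exact word. Note that the
    # E-value below (generalised p x number of exact words) is
    # anti-conservative: the generalisation repeatedly keeps the best of
    # ~80 same-data candidates, a selection the Bonferroni factor does
    # not cover. This mirrors the discriminative-word procedure as
    # specified; the vignette documents the calibration consequences.
    repeat {
      ch <- strsplit(word, "")[[1]]
      best_word <- NULL; best_p <- p_cur
      for (pos_i in seq_along(ch)) {
        for (sym in iupac_supersets(ch[pos_i])) {
          cand <- ch
          cand[pos_i] <- sym
          cw <- paste0(cand, collapse = "")
          a <- count_sequences_with_word(cw, pos)
          cc <- count_sequences_with_word(cw, bg)
          pc <- fisher_pvalue(a, npos - a, cc, nbg - cc)
          if (pc < best_p) {
            best_p <- pc
            best_word <- cw
          }
        }
      }
      if (is.null(best_word)) break
      word <- best_word
      p_cur <- best_p
    }
    a <- count_sequences_with_word(word, pos)
    cc <- count_sequences_with_word(word, bg)
    p_final <- fisher_pvalue(a, npos - a, cc, nbg - cc)
    e <- p_final * n_words
    if (e > e_threshold) break
    sites <- collect_sites(word, pos)
    pwm <- word_to_pwm(word, sites)
    rank <- length(motifs) + 1L
    motifs[[rank]] <- list(word = word,
                           table = c(a = a, b = npos - a, c = cc, d = nbg - cc),
                           p = p_final, e = e, pwm = pwm,
                           nsites = length(sites), rank = rank,
                           name = paste0("motif_", rank, "_", word),
                           significance = e)
    pos <- erase_word(word, pos)
    bg <- erase_word(word, bg)
  }
  motifs
}

# fast per-column Pearson correlation of two 4-row matrices (columns are
# motif positions); zero-variance columns contribute 0.
colwise_pearson <- function(A, B) {
  am <- colMeans(A); bm <- colMeans(B)
  Ac <- sweep(A, 2L, am); Bc <- sweep(B, 2L, bm)
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  ifelse(den > 0, num / den, 0)
}

revcomp_pwm <- function(pwm) {
  pwm[rev(seq_len(nrow(pwm))), c("T", "G", "C", "A"), drop = FALSE]
}

best_pwm_score <- function(qt, tt, min_overlap) {
  # qt, tt: 4 x L matrices (transposed PWMs)
  wq <- ncol(qt); wt <- ncol(tt)
  best <- -Inf; best_off <- NA_integer_
  for (off in (-(wq - min_overlap)):(wt - min_overlap)) {
    qs <- max(1L, 1L - off); qe <- min(wq, wt - off)
    if (qe - qs + 1L < min_overlap) next
    sc <- mean(colwise_pearson(qt[, qs:qe, drop = FALSE],
                               tt[, (qs + off):(qe + off), drop = FALSE]))
    if (sc > best) { best <- sc; best_off <- off }
  }
  list(score = best, offset = best_off)
}

#' Compare a query PWM against a motif database
#'
#' Simplified motif matcher: for every target motif and every offset
#' with at least `min_overlap` overlapping columns (query tried as-is
#' and reverse-complemented), the score is the mean per-column Pearson
#' correlation; the best offset is kept per target. An empirical
#' P-value is estimated as the fraction of column-shuffled versions of
#' the target scoring at least as well. Targets are ranked by `p_est`,
#' then score.
#'
#' @param query L x 4 PWM (columns A,C,G,T).
#' @param database a MEME minimal file path or a motif list as returned
#'   by [read_meme_motifs()] -- must be non-empty.
#' @param seed RNG seed for the shuffled null.
#' @param n_shuffle shuffled targets per motif.
#' @param min_overlap minimum overlapping columns.
#' @return data.frame of matches: `target`, `offset`, `strand`,
#'   `score`, `p_est`, sorted by rank.
#' @export
compare_to_database <- function(query, database, seed = 1L,
                                n_shuffle = 1000L, min_overlap = 4L) {
  db <- if (is.character(database)) read_meme_motifs(database) else database
  if (length(db) == 0L) stop("empty motif database")
  if (is.null(colnames(query))) colnames(query) <- BASES
  qf <- t(query)
  qr <- t(revcomp_pwm(query))
  with_seed(seed, {
    rows <- lapply(db, function(m) {
      tt <- t(m$pwm)
      sf <- best_pwm_score(qf, tt, min_overlap)
      sr <- best_pwm_score(qr, tt, min_overlap)
      if (sf$score >= sr$score) {
        obs <- sf; strand <- "+"
      } else {
        obs <- sr; strand <- "-"
      }
      wt <- ncol(tt)
      null_scores <- vapply(seq_len(n_shuffle), function(i) {
        ts <- tt[, sample.int(wt), drop = FALSE]
        max(best_pwm_score(qf, ts, min_overlap)$score,
            best_pwm_score(qr, ts, min_overlap)$score)
      }, numeric(1))
      data.frame(target = m$name, offset = obs$offset, strand = strand,
                 score = obs$score,
                 p_est = mean(null_scores >= obs$score),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_est, -out$score, out$target), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
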