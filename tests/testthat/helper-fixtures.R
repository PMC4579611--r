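# Shared fixtures and independent oracles for the test suite.
# Expensive standard-scale runs are computed once per session and cached.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Deterministic tiling reads: every position covered, alternating strands.
make_tiling_reads <- function(source, depth = 30, read_len = 36,
                              alternate = TRUE) {
  last <- nchar(source) - read_len + 1
  starts <- unique(c(round(seq(1, last, by = read_len / depth)), last))
  reads <- substring(source, starts, starts + read_len - 1)
  if (alternate && length(reads) > 1) {
    idx <- seq(2, length(reads), by = 2)
    reads[idx] <- revcomp(reads[idx])
  }
  reads
}

# Substitution noise at a fixed per-base rate (test-side twin of the
# simulator's error model, independent implementation).
mutate_reads <- function(reads, rate, seed) {
  withr::with_seed(seed, {
    nerr <- rbinom(length(reads), nchar(reads), rate)
    for (i in which(nerr > 0)) {
      s <- strsplit(reads[i], "")[[1]]
      for (p in sample(length(s), nerr[i])) {
        s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      }
      reads[i] <- paste0(s, collapse = "")
    }
    reads
  })
}

# --- independent oracles -------------------------------------------------

# Direct log-space binomial upper-tail summation.
oracle_binom_tail <- function(x1, x0, r) {
  n <- x1 + x0
  if (n == 0) return(1)
  if (x1 == 0) return(1)
  p <- r / (r + 1)
  k <- x1:n
  terms <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}

# Exhaustive hypergeometric one-sided tail.
oracle_fisher_tail <- function(a, b, c, d) {
  npos <- a + b
  white <- a + c
  total <- a + b + c + d
  ks <- a:min(white, npos)
  sum(choose(white, ks) * choose(total - white, npos - ks)) /
    choose(total, npos)
}

# Brute-force IUPAC matcher over all positions and strands.
oracle_count_word <- function(word, seqs) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  w <- strsplit(word, "")[[1]]
  matches_at <- function(s, i) {
    all(vapply(seq_along(w), function(j) {
      substr(s, i + j - 1, i + j - 1) %in% sets[[w[j]]]
    }, logical(1)))
  }
  hits_seq <- function(s) {
    for (str in c(s, revcomp(s))) {
      n <- nchar(str)
      if (n >= length(w)) {
        for (i in 1:(n - length(w) + 1)) if (matches_at(str, i)) return(TRUE)
      }
    }
    FALSE
  }
  sum(vapply(seqs, hits_seq, logical(1)))
}

dinuc_counts <- function(s) {
  n <- nchar(s)
  if (n < 2) return(table(character(0)))
  table(substring(s, 1:(n - 1), 2:n))
}

# IUPAC-compatible mismatch distance between a discovered word and a
# planted consensus: best ungapped alignment over both strands and all
# offsets; overhanging word symbols count as mismatches.
word_consensus_mismatches <- function(word, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  w <- strsplit(word, "")[[1]]
  best <- length(w)
  for (cons in c(consensus, revcomp(consensus))) {
    cc <- strsplit(cons, "")[[1]]
    for (off in (-length(w) + 1):(length(cc) - 1)) {
      mm <- 0
      for (j in seq_along(w)) {
        ci <- off + j
        if (ci < 1 || ci > length(cc)) mm <- mm + (w[j] != "N")
        else if (!(cc[ci] %in% sets[[w[j]]])) mm <- mm + 1
      }
      best <- min(best, mm)
    }
  }
  best
}

# Locate a ChIPtig on the truth genome (<= max_mm mismatches, either
# strand); returns c(start, end) 1-based or NULL.
locate_on_genome <- function(seq, genome_dna, max_mm = 2) {
  m <- Biostrings::matchPattern(seq, genome_dna, max.mismatch = max_mm)
  if (length(m) == 0) {
    m <- Biostrings::matchPattern(revcomp(seq), genome_dna,
                                  max.mismatch = max_mm)
  }
  if (length(m) == 0) return(NULL)
  c(BiocGenerics::start(m)[1], BiocGenerics::end(m)[1])
}

# --- cached standard-scale runs ------------------------------------------

.std_cache <- new.env(parent = emptyenv())

std_sim <- function(seed, enrichment_fold = 10) {
  key <- paste0("sim_", seed, "_", enrichment_fold)
  if (is.null(.std_cache[[key]])) {
    cfg <- simulation_config(seed = seed, enrichment_fold = enrichment_fold)
    .std_cache[[key]] <- simulate_experiment(cfg)
  }
  .std_cache[[key]]
}

# Full standard run: simulate, assemble (dbg), rank. Cached per seed.
std_run <- function(seed, assembler = "dbg") {
  key <- paste0("run_", assembler, "_", seed)
  if (is.null(.std_cache[[key]])) {
    sim <- std_sim(seed)
    tigs <- if (assembler == "dbg") assemble_dbg(sim$case)
            else assemble_profile(sim$case)
    enr <- enrich_chiptigs(tigs, sim$case, sim$control)
    .std_cache[[key]] <- list(sim = sim, tigs = tigs, enr = enr)
  }
  .std_cache[[key]]
}

top_sequences <- function(run) {
  run$enr$chiptigs$sequence[match(run$enr$top$chiptig_id,
                                  run$enr$chiptigs$id)]
}

planted_consensus <- function() {
  pwm <- default_site_pwm()
  paste0(c("A", "C", "G", "T")[max.col(pwm)], collapse = "")
}
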