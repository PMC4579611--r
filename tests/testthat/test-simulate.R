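test_that("generate_genome respects composition and determinism", {
  g <- generate_genome(50, gc_fraction = 1, seed = 3)
  expect_match(g, "^[GC]+$")
  expect_identical(generate_genome(200, 0.5, 9), generate_genome(200, 0.5, 9))
  expect_error(generate_genome(0), ">= 1")
  # binomial CI: observed GC within 0.5 +/- 0.01 at 100 kb
  for (s in 1:3) {
    g <- generate_genome(100000, 0.5, s)
    gc <- nchar(gsub("[AT]", "", g)) / 100000
    expect_lt(abs(gc - 0.5), 0.01)
  }
})

test_that("plant_sites places deterministic PWM bases with spacing", {
  pwm_a <- matrix(c(1, 0, 0, 0), nrow = 1,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  g <- generate_genome(2000, 0.5, 1)
  pl <- plant_sites(g, pwm_a, 3, min_spacing = 10, seed = 2)
  at <- substring(pl$genome, pl$sites$start + 1, pl$sites$start + 1)
  # deterministic single-column PWM: A on + strand, T (revcomp) on -
  expect_true(all(ifelse(pl$sites$strand == "+", at == "A", at == "T")))
  expect_equal(pl$sites$instance, rep("A", 3))

  pl0 <- plant_sites(g, pwm_a, 0, seed = 2)
  expect_identical(pl0$genome, g)
  expect_equal(nrow(pl0$sites), 0L)

  # spacing property over many seeds
  pwm <- default_site_pwm()
  for (s in 1:100) {
    pl <- plant_sites(g, pwm, 4, min_spacing = 50, seed = s)
    gaps <- diff(sort(pl$sites$start))
    expect_true(all(gaps >= 50 + nrow(pwm)))
  }
})

test_that("error-free reads are exact genome substrings", {
  cfg <- simulation_config(genome_length = 20000L, n_sites = 10L,
                           n_case_reads = 300L, n_control_reads = 300L,
                           error_rate = 0, seed = 5L)
  sim <- simulate_experiment(cfg)
  ok <- vapply(c(sim$case$sequence, sim$control$sequence), function(r) {
    grepl(r, sim$genome, fixed = TRUE) ||
      grepl(revcomp(r), sim$genome, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  # determinism
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim$case$sequence, sim2$case$sequence)
  expect_identical(sim$sites, sim2$sites)
})

test_that("strand balance is near 1/2 at n = 50,000", {
  # error-free reads match the genome exactly in their emitted orientation,
  # so the forward-match fraction estimates the strand fraction
  cfg <- simulation_config(error_rate = 0, seed = 301L)
  sim0 <- simulate_experiment(cfg)
  smp <- sim0$case$sequence
  fwd <- vapply(smp[1:5000], function(r) grepl(r, sim0$genome, fixed = TRUE),
                logical(1))
  frac <- mean(fwd)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("fold-1, error-free case and control are exchangeable", {
  cfg <- simulation_config(genome_length = 20000L, n_sites = 10L,
                           n_case_reads = 2000L, n_control_reads = 2000L,
                           enrichment_fold = 1, error_rate = 0, seed = 8L)
  sim <- simulate_experiment(cfg)
  kmer_freq <- function(seqs) {
    km <- unlist(lapply(seqs, function(s) {
      substring(s, 1:(nchar(s) - 3), 4:nchar(s))
    }))
    tabulate(factor(km, levels = unique(km)), nbins = length(unique(km)))
  }
  allr <- c(sim$case$sequence, sim$control$sequence)
  kmers4 <- function(seqs) {
    unlist(lapply(seqs, function(s) substring(s, 1:(nchar(s) - 3), 4:nchar(s))))
  }
  lv <- sort(unique(kmers4(allr[1:200])))
  stat <- function(a, b) {
    fa <- table(factor(kmers4(a), levels = lv))
    fb <- table(factor(kmers4(b), levels = lv))
    sum(abs(fa / sum(fa) - fb / sum(fb)))
  }
  obs <- stat(sim$case$sequence, sim$control$sequence)
  null <- withr::with_seed(1, vapply(1:99, function(i) {
    pm <- sample(length(allr))
    stat(allr[pm[1:2000]], allr[pm[2001:4000]])
  }, numeric(1)))
  p <- (sum(null >= obs) + 1) / 100
  expect_gt(p, 0.01)  # not rejected at alpha = 0.01
})

test_that("site coverage exceeds background by the configured fold", {
  # error-free standard-scale experiment so reads locate exactly
  cfg0 <- simulation_config(error_rate = 0, seed = 302L)
  L <- cfg0$genome_length
  rl <- cfg0$read_length
  sim0 <- simulate_experiment(cfg0)
  cov <- integer(L)
  gref <- Biostrings::DNAString(sim0$genome)
  smp <- withr::with_seed(4, sample(nrow(sim0$case), 8000))
  for (r in sim0$case$sequence[smp]) {
    m <- Biostrings::matchPattern(r, gref)
    if (length(m) == 0) m <- Biostrings::matchPattern(revcomp(r), gref)
    if (length(m) >= 1) {
      st <- BiocGenerics::start(m)[1]
      cov[st:(st + rl - 1)] <- cov[st:(st + rl - 1)] + 1L
    }
  }
  w <- nrow(cfg0$pwm)
  site_pos <- unlist(lapply(sim0$sites$start, function(s) (s + 1):(s + w)))
  near <- unlist(lapply(sim0$sites$start, function(s) {
    max(1, s - 400):min(L, s + 400)
  }))
  bg_pos <- setdiff(seq_len(L), near)
  ratio <- mean(cov[site_pos]) / mean(cov[bg_pos])
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)
})

test_that("simulate_experiment writes the documented files", {
  cfg <- simulation_config(genome_length = 5000L, n_sites = 4L,
                           n_case_reads = 100L, n_control_reads = 100L,
                           seed = 2L)
  out <- withr::local_tempdir()
  sim <- simulate_experiment(cfg, outdir = out)
  expect_true(all(file.exists(unlist(sim$paths))))
  back <- parse_reads(sim$paths$case, "case")
  expect_equal(back$sequence, sim$case$sequence)
  bed <- read.table(sim$paths$sites, sep = "\t")
  expect_equal(bed$V2, sim$sites$start)        # 0-based start
  expect_equal(bed$V3 - bed$V2, rep(8L, 4L))   # half-open width
})
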