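test_that("dinucleotide_shuffle preserves dinucleotide counts exactly", {
  expect_equal(dinucleotide_shuffle("AAAA", 1), "AAAA")
  expect_equal(dinucleotide_shuffle("A", 1), "A")
  withr::with_seed(60, {
    seqs <- vapply(1:100, function(i) random_dna(sample(20:80, 1)), character(1))
  })
  sh <- dinucleotide_shuffle(seqs, seed = 7)
  for (i in seq_along(seqs)) {
    expect_equal(dinuc_counts(sh[i]), dinuc_counts(seqs[i]))
  }
  expect_identical(dinucleotide_shuffle(seqs, 7), sh)  # determinism
  expect_false(all(sh == seqs))                        # actually shuffles
})

test_that("count_sequences_with_word matches the brute-force oracle", {
  expect_equal(count_sequences_with_word("ACGT", "TTACGTTT"), 1L)
  expect_equal(count_sequences_with_word("AAAA", "TTTT"), 1L)  # - strand
  expect_equal(count_sequences_with_word("RG", c("AG", "GG", "CG")), 2L)
  expect_error(count_sequences_with_word("AXG", "ACGT"), "IUPAC")

  withr::with_seed(61, {
    seqs <- vapply(1:30, function(i) random_dna(30), character(1))
  })
  for (w in c("ACG", "RGT", "NCGW", "TGACTCAG", "BDHV")) {
    expect_equal(count_sequences_with_word(w, seqs),
                 oracle_count_word(w, seqs), info = w)
  }
})

test_that("fisher_pvalue equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_pvalue(8, 2, 2, 8), 2126 / 184756, tolerance = 1e-12)
  expect_gt(fisher_pvalue(5, 5, 5, 5), 0.5)   # symmetric table
  expect_equal(fisher_pvalue(0, 10, 3, 7), 1, tolerance = 1e-12)
  for (npos in c(3, 8, 20)) {
    for (nbg in c(5, 20)) {
      for (a in 0:npos) {
        for (cc in c(0, 1, nbg %/% 2, nbg)) {
          expect_equal(fisher_pvalue(a, npos - a, cc, nbg - cc),
                       oracle_fisher_tail(a, npos - a, cc, nbg - cc),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("word_to_pwm applies the 0.1 pseudocount", {
  pwm <- word_to_pwm("ACGT", c("ACGT", "ACGT"))
  expect_equal(unname(pwm[1, "A"]), 2.1 / 2.4, tolerance = 1e-12)
  expect_equal(rowSums(pwm), rep(1, 4), tolerance = 1e-12)
  one <- word_to_pwm("ACG", "ACG")
  expect_equal(unname(apply(one, 1, max)), rep(1.1 / 1.4, 3), tolerance = 1e-12)
  expect_error(word_to_pwm("ACG", character(0)), "no matched")
  expect_error(word_to_pwm("ACG", "ACGT"), "length")
})

test_that("discover_motifs recovers planted words and erases them", {
  withr::with_seed(62, {
    seqs <- vapply(1:100, function(i) {
      s <- random_dna(60)
      pos <- sample(1:52, 1)
      paste0(substring(s, 1, pos - 1), "TGACTCAG", substring(s, pos + 8, 60))
    }, character(1))
  })
  mot <- discover_motifs(seqs, n_motifs = 2, seed = 3)
  expect_gte(length(mot), 1L)
  expect_lte(word_consensus_mismatches(mot[[1]]$word, "TGACTCAG"), 1L)
  # every reported motif genuinely occurs in the positives (re-scan)
  expect_gt(count_sequences_with_word(mot[[1]]$word, seqs), 0L)
  # erasure: after round 1, the motif no longer matches the worked set
  erased <- dechip:::erase_word(mot[[1]]$word, seqs)
  expect_equal(count_sequences_with_word(mot[[1]]$word, erased), 0L)

  # two planted words recovered at ranks 1 and 2
  withr::with_seed(63, {
    seqs2 <- vapply(1:120, function(i) {
      s <- random_dna(70)
      p1 <- sample(1:20, 1); p2 <- sample(35:55, 1)
      substring(s, p1, p1 + 7) <- "TGACTCAG"
      if (i <= 80) substring(s, p2, p2 + 6) <- "CCGGAAT"
      s
    }, character(1))
  })
  mot2 <- discover_motifs(seqs2, n_motifs = 3, seed = 4)
  expect_gte(length(mot2), 2L)
  expect_lte(word_consensus_mismatches(mot2[[1]]$word, "TGACTCAG"), 1L)
  expect_lte(word_consensus_mismatches(mot2[[2]]$word, "CCGGAAT"), 1L)
})

test_that("discover_motifs stays silent on unstructured input", {
  withr::with_seed(64, {
    seqs <- vapply(1:80, function(i) random_dna(60), character(1))
  })
  mot <- discover_motifs(seqs, n_motifs = 1, seed = 9)
  expect_equal(length(mot), 0L)
})

test_that("compare_to_database ranks self and revcomp matches first", {
  withr::with_seed(65, {
    mk <- function(w) {
      m <- matrix(runif(4 * w), ncol = 4)
      m <- m / rowSums(m)
      colnames(m) <- c("A", "C", "G", "T")
      m
    }
    db <- list(list(name = "target1", pwm = mk(8), nsites = 10, significance = 0),
               list(name = "target2", pwm = mk(10), nsites = 10, significance = 0),
               list(name = "target3", pwm = mk(6), nsites = 10, significance = 0))
  })
  res <- compare_to_database(db[[2]]$pwm, db, seed = 1, n_shuffle = 200)
  expect_equal(res$target[1], "target2")
  expect_equal(res$score[1], 1, tolerance = 1e-9)

  rc <- db[[2]]$pwm[nrow(db[[2]]$pwm):1, c("T", "G", "C", "A")]
  colnames(rc) <- c("A", "C", "G", "T")
  res2 <- compare_to_database(rc, db, seed = 1, n_shuffle = 200)
  expect_equal(res2$target[1], "target2")
  expect_equal(res2$score[1], 1, tolerance = 1e-9)
  expect_equal(res2$strand[1], "-")

  # uniform query scores ~0 with a large empirical p
  uni <- matrix(0.25, nrow = 8, ncol = 4, dimnames = list(NULL, c("A","C","G","T")))
  res3 <- compare_to_database(uni, db, seed = 2, n_shuffle = 200)
  expect_true(all(abs(res3$score) < 0.2))
  expect_true(all(res3$p_est >= 0.3))

  expect_error(compare_to_database(uni, list(), seed = 1), "empty")
})

test_that("MEME round trip through the motif layer", {
  withr::with_seed(66, {
    seqs <- vapply(1:60, function(i) {
      s <- random_dna(50)
      substring(s, 10, 17) <- "TGACTCAG"
      s
    }, character(1))
  })
  mot <- discover_motifs(seqs, n_motifs = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(mot, path)
  back <- read_meme_motifs(path)
  # written at 6 decimal places -> absolute agreement to 1e-6
  expect_lt(max(abs(back[[1]]$pwm - mot[[1]]$pwm)), 1e-6)
})
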