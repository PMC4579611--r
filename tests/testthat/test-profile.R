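test_that("seed_clusters groups reads sharing a k-mer", {
  reads <- rep(paste0(strrep("ACGTT", 6), "AC"), 10)  # 32 bp, identical
  cl <- seed_clusters(reads, k = 17)
  expect_equal(length(cl), 1L)
  expect_equal(length(cl[[1]]$sequence), 10L)

  # two disjoint sources share no k-mer -> two clusters
  a <- random_dna(40, seed = 41)
  b <- random_dna(40, seed = 42)
  cl2 <- seed_clusters(c(rep(a, 5), rep(b, 5)), k = 17)
  expect_equal(length(cl2), 2L)

  # below min_seed_depth founds nothing
  cl3 <- seed_clusters(rep(a, 3), k = 17, min_seed_depth = 4)
  expect_equal(length(cl3), 0L)
})

test_that("init_profile pseudocount arithmetic matches hand values", {
  reads <- rep("ACGTACGTACGTACGTACGTA", 10)
  cl <- seed_clusters(reads, k = 17)[[1]]
  m <- init_profile(cl, k = 17)
  em <- profile_emissions(m)
  expect_true(all(apply(em, 2, max) >= 0.97))
  expect_equal(max(em[, 1]), 10.1 / 10.4, tolerance = 1e-9)

  # 9 A's and 1 C in a column: emission_A = 9.1/10.4
  reads2 <- c(rep("AACGTACGTACGTACGTAC", 9), paste0("C", "ACGTACGTACGTACGTAC"))
  cl2 <- list(sequence = reads2, offset = rep(1L, 10), read = 1:10,
              seed = substr(reads2[1], 2, 18))
  m2 <- init_profile(cl2, k = 17)
  expect_equal(unname(profile_emissions(m2)["A", 1]), 9.1 / 10.4,
               tolerance = 1e-9)

  # single-read cluster: 1.1/1.4 at the read base
  m3 <- init_profile(list(sequence = "ACGTACGTACGTACGTA", offset = 0L,
                          read = 1L, seed = "ACGTACGTACGTACGTA"), k = 17)
  expect_equal(unname(profile_emissions(m3)["A", 1]), 1.1 / 1.4,
               tolerance = 1e-9)
})

test_that("column_entropy evaluates the standard values", {
  expect_equal(column_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(column_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(column_entropy(c(0.5, 0.5, 0, 0)), log(2), tolerance = 1e-12)
  expect_gt(column_entropy(c(0.5, 0.5, 0, 0)), 0.6)  # 50/50 triggers the stop
  expect_error(column_entropy(c(-0.1, 1.1, 0, 0)), "negative")
})

test_that("online_update algebra: alpha = 1 freezes, alpha = 0 replaces", {
  reads <- rep("ACGTACGTACGTACGTACGTA", 6)
  m <- init_profile(seed_clusters(reads, 17)[[1]], 17)
  g0 <- m$g
  newr <- "CCGTACGTACGTACGTACGTA"  # disagrees at column 1 only

  keep <- online_update(m, newr, 0L, online_schedule(alpha_of_r = function(r) 1))
  expect_equal(keep$model$g, g0, tolerance = 1e-12)

  repl <- online_update(m, newr, 0L, online_schedule(alpha_of_r = function(r) 0),
                        agree_min = 0.9)
  expect_equal(unname(repl$model$g["C", 1]), 1)     # replaced by the new read
  expect_equal(unname(repl$model$g["C", 2]), 1)     # (column 2 of the read is C)

  # low-agreement reads are rejected, not an error
  bad <- paste0(strrep("T", 21))
  out <- online_update(m, bad, 0L, online_schedule())
  expect_equal(out$rejected, 1L)
  expect_equal(out$model$g, g0, tolerance = 1e-12)
})

test_that("consistent reads drive the emission monotonically toward 1", {
  reads <- c(rep("ACGTACGTACGTACGTACGTA", 4),
             rep("CCGTACGTACGTACGTACGTA", 3))
  m <- init_profile(list(sequence = reads, offset = rep(0L, 7), read = 1:7,
                         seed = substr(reads[1], 1, 17)), 17)
  sched <- online_schedule()  # alpha(r) = 1 - (r+2)^-0.8, bounded away from 1
  pa <- profile_emissions(m)["A", 1]
  for (i in 1:30) {
    m <- online_update(m, "ACGTACGTACGTACGTACGTA", 0L, sched)$model
    pa_new <- profile_emissions(m)["A", 1]
    expect_gte(pa_new, pa - 1e-12)
    pa <- pa_new
  }
  expect_gt(pa, 0.9)
})

test_that("extension reconstructs a tiled source; no-overlap keeps the seed", {
  src <- random_dna(300, seed = 44)
  tigs <- assemble_profile(make_tiling_reads(src))
  expect_equal(nrow(tigs), 1L)
  expect_true(tigs$sequence[1] %in% c(src, revcomp(src)))

  # no unassigned overlapping reads: ChIPtig equals the seed consensus
  reads <- rep(substring(src, 1, 60), 5)
  tigs2 <- assemble_profile(reads, k = 17)
  expect_equal(nrow(tigs2), 1L)
  expect_true(tigs2$sequence[1] %in% c(substring(src, 1, 60),
                                       revcomp(substring(src, 1, 60))))
})

test_that("extension stops at the shared-core junction (entropy rule)", {
  withr::with_seed(45, {
    core <- random_dna(100)
    s1 <- paste0(random_dna(100), core, random_dna(100))
    s2 <- paste0(random_dna(100), core, random_dna(100))
  })
  reads <- c(make_tiling_reads(s1), make_tiling_reads(s2))
  tigs <- assemble_profile(reads)
  expect_gte(nrow(tigs), 1L)
  # the first (deepest-seeded) ChIPtig is the shared core, extended by at
  # most k bases each side
  k <- 17
  window <- paste0(substring(s1, 101 - k, 100), core,
                   substring(s1, 201, 200 + k))
  t1 <- tigs$sequence[1]
  expect_true(grepl(t1, window, fixed = TRUE) ||
                grepl(revcomp(t1), window, fixed = TRUE))
  expect_gte(nchar(t1), 100 - k)
})

test_that("finalised columns all satisfy the entropy bound", {
  withr::with_seed(46, {
    core <- random_dna(120)
    s1 <- paste0(random_dna(80), core, random_dna(80))
    s2 <- paste0(random_dna(80), core, random_dna(80))
  })
  reads <- c(make_tiling_reads(s1), make_tiling_reads(s2))
  cl <- seed_clusters(reads, 17)
  idx <- data.table::as.data.table(dechip:::cpp_read_kmer_index(reads, 17L))
  data.table::setkey(idx, kmer)
  pool <- new.env()
  pool$seqs <- reads; pool$assigned <- rep(FALSE, length(reads)); pool$idx <- idx
  pool$assigned[cl[[1]]$read] <- TRUE
  m <- init_profile(cl[[1]], 17)
  fin <- extend_and_finalize(m, pool)
  ent <- apply(fin$model$tally, 2, function(cc) column_entropy(cc / sum(cc)))
  expect_true(all(ent <= 0.6 + 1e-12))
})

test_that("profile agrees with the DBG assembler on unambiguous input", {
  src <- random_dna(260, seed = 47)
  reads <- make_tiling_reads(src)
  a <- assemble_dbg(reads)
  b <- assemble_profile(reads)
  norm <- function(s) pmin(s, revcomp(s))
  expect_equal(norm(a$sequence), norm(b$sequence))
})
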