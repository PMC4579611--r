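params17 <- assembly_params(k = 17)

test_that("build_graph merges a single linear path into one node pair", {
  # spec-level k=4 example exercised on the raw kernel (user-facing k >= 11)
  r <- dechip:::cpp_unitig_graph("ACGTACG", 4L)
  expect_equal(length(r$seq), 1L)
  expect_true(r$seq %in% c("ACGTACG", "CGTACGT"))

  # palindromic k-mer is its own twin, no duplication
  r2 <- dechip:::cpp_unitig_graph("ACGT", 4L)
  expect_equal(length(r2$seq), 1L)
  expect_equal(r2$cov, 1)

  src <- random_dna(300, seed = 21)
  g <- build_graph(make_tiling_reads(src), params17)
  expect_equal(length(g$seq), 1L)
  expect_true(g$seq[1] %in% c(src, revcomp(src)))
  validate_graph(g)
})

test_that("reads shorter than k are skipped; all-short input errors", {
  expect_message(g <- build_graph(c("ACGTACGTACGTACGTACGTA", "ACGT"), params17),
                 "1 read")
  expect_error(build_graph(c("ACGT", "AC"), params17), "empty graph")
})

test_that("remove_tips clips short low-coverage dead ends only", {
  src <- random_dna(300, seed = 22)
  main <- make_tiling_reads(src, depth = 10)
  # branch: diverges after position 100, dead-ends after 17 novel bases
  branch <- paste0(substring(src, 70, 100), random_dna(17, seed = 23))
  g <- build_graph(c(main, branch), params17)
  expect_gt(length(g$seq), 1L)
  g2 <- remove_tips(g, params17)
  expect_equal(length(g2$seq), 1L)
  expect_true(g2$seq[1] %in% c(src, revcomp(src)))
  validate_graph(g2)

  # long dead-end branch (>= 2k novel bases) is retained
  branch_long <- paste0(substring(src, 70, 100), random_dna(2 * 17 + 22, seed = 24))
  g3 <- build_graph(c(main, branch_long), params17)
  g4 <- remove_tips(g3, params17)
  expect_gt(length(g4$seq), 1L)

  # branch-free graph is unchanged (idempotence)
  g5 <- build_graph(main, params17)
  g6 <- remove_tips(g5, params17)
  expect_identical(g5$seq, g6$seq)
})

test_that("collapse_bubbles merges similar paths, keeps dissimilar ones", {
  src <- random_dna(300, seed = 25)
  hapB <- src
  substr(hapB, 150, 150) <- if (substr(src, 150, 150) == "A") "C" else "A"
  reads <- c(make_tiling_reads(src, depth = 27), make_tiling_reads(hapB, depth = 3))
  g <- build_graph(reads, params17)
  g <- remove_tips(g, params17)
  g <- collapse_bubbles(g, params17)
  validate_graph(g)
  tig <- extract_chiptigs(g, params17)
  expect_equal(nrow(tig), 1L)
  # majority base wins (27x vs 3x)
  expect_true(tig$sequence[1] %in% c(src, revcomp(src)))

  # dissimilar alternative paths (identity << 0.8) are both retained
  a <- random_dna(60, seed = 26)
  b <- random_dna(60, seed = 27)
  flank1 <- random_dna(60, seed = 28)
  flank2 <- random_dna(60, seed = 29)
  s1 <- paste0(flank1, a, flank2)
  s2 <- paste0(flank1, b, flank2)
  g2 <- build_graph(c(make_tiling_reads(s1, depth = 20),
                      make_tiling_reads(s2, depth = 20)), params17)
  n_before <- length(collapse_bubbles(g2, params17)$seq)
  expect_gte(n_before, 3L)  # both variants still present

  # bubble-free graph unchanged
  g3 <- build_graph(make_tiling_reads(src), params17)
  expect_identical(collapse_bubbles(g3, params17)$seq, g3$seq)
})

test_that("remove_low_coverage prunes below the cutoff", {
  src <- random_dna(300, seed = 30)
  other <- random_dna(120, seed = 31)
  reads <- c(make_tiling_reads(src, depth = 10), substring(other, 1, 36),
             substring(other, 37, 72))
  g <- build_graph(reads, params17)
  g2 <- remove_low_coverage(g, params17)  # default cutoff 2.0
  expect_equal(length(g2$seq), 1L)
  # cutoff 0 disables pruning
  g3 <- remove_low_coverage(g, assembly_params(k = 17, min_node_coverage = 0))
  expect_equal(length(g3$seq), length(g$seq))
})

test_that("error k-mers are cleaned from simulated reads", {
  src <- random_dna(300, seed = 33)
  reads <- mutate_reads(make_tiling_reads(src), 0.005, seed = 34)
  tigs <- assemble_dbg(reads, params17)
  expect_equal(nrow(tigs), 1L)
  loc <- locate_on_genome(tigs$sequence[1], Biostrings::DNAString(src), max_mm = 2)
  expect_false(is.null(loc))
})

test_that("extract_chiptigs applies the length boundary and ordering", {
  src49 <- random_dna(49, seed = 35)
  src80 <- random_dna(80, seed = 36)
  g <- build_graph(c(make_tiling_reads(src49, depth = 8, read_len = 30),
                     make_tiling_reads(src80, depth = 20, read_len = 30)),
                   params17)
  tigs <- extract_chiptigs(g, params17)
  expect_equal(nrow(tigs), 1L)          # 49 < 50 not reported
  expect_equal(tigs$length, 80L)
  expect_equal(tigs$id, "dbg_1")
  # canonical strand: lexicographically smaller of seq/revcomp
  expect_true(tigs$sequence <= revcomp(tigs$sequence))

  g0 <- delete_nodes <- dechip:::delete_nodes(g, seq_along(g$seq))
  expect_equal(nrow(extract_chiptigs(g0, params17)), 0L)
})

test_that("assembly is deterministic and twin-symmetric through all stages", {
  sim <- simulate_experiment(simulation_config(genome_length = 10000L,
                                               n_sites = 20L,
                                               n_case_reads = 3000L,
                                               n_control_reads = 3000L,
                                               seed = 77L))
  g <- build_graph(sim$case, params17)
  validate_graph(g)
  g <- remove_tips(g, params17); validate_graph(g)
  g <- collapse_bubbles(g, params17); validate_graph(g)
  g <- remove_low_coverage(g, params17); validate_graph(g)
  t1 <- extract_chiptigs(g, params17)
  t2 <- assemble_dbg(sim$case, params17)
  expect_identical(t1, t2)
})
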