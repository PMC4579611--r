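test_that("length_filter keeps the inclusive [50, 500] range", {
  tigs <- data.frame(id = paste0("c", 1:4), sequence = strrep("A", c(49, 50, 500, 501)),
                     length = c(49L, 50L, 500L, 501L))
  kept <- length_filter(tigs)
  expect_equal(kept$length, c(50L, 500L))
  expect_equal(nrow(length_filter(tigs[0, ])), 0L)
  allin <- tigs[2:3, ]
  expect_identical(length_filter(allin), allin)
})

test_that("map_reads is seed-and-extend with best-hit semantics", {
  tig <- data.frame(id = c("t1", "t2"),
                    sequence = c(random_dna(200, seed = 50),
                                 random_dna(200, seed = 51)))
  read <- substring(tig$sequence[1], 60, 95)
  res <- map_reads(tig, read)
  expect_equal(unname(res$counts), c(1L, 0L))

  # reverse-complement read maps only when both_strands
  rcread <- revcomp(read)
  expect_equal(unname(map_reads(tig, rcread)$counts), c(1L, 0L))
  expect_equal(unname(map_reads(tig, rcread,
                                mapping_params(both_strands = FALSE))$counts),
               c(0L, 0L))

  # max_mismatches + 1 differences -> unmapped
  r3 <- read
  for (p in c(2, 14, 26)) substr(r3, p, p) <- setdiff(c("A","C","G","T"),
                                                      substr(r3, p, p))[1]
  res3 <- map_reads(tig, r3, mapping_params(max_mismatches = 2))
  expect_equal(res3$n_mapped, 0L)
  expect_equal(res3$n_unmapped, 1L)
  # but 2 mismatches map
  r2 <- read
  for (p in c(2, 14)) substr(r2, p, p) <- setdiff(c("A","C","G","T"),
                                                  substr(r2, p, p))[1]
  expect_equal(map_reads(tig, r2)$n_mapped, 1L)

  expect_error(map_reads(tig[0, ], read), "empty")
})

test_that("binomial_pvalue matches hand-derived spot values", {
  expect_equal(binomial_pvalue(0, 7, 1), 1)
  expect_equal(binomial_pvalue(8, 2, 1), 56 / 1024, tolerance = 1e-12)
  expect_equal(binomial_pvalue(5, 0, 1), 1 / 32, tolerance = 1e-12)
  expect_error(binomial_pvalue(1, 1, 0), "positive")
  expect_message(p <- binomial_pvalue(c(0, 3), c(0, 0), 1), "no mapped reads")
  expect_equal(p[1], 1)
})

test_that("binomial_pvalue equals log-space summation and is monotone", {
  for (r in c(0.5, 1, 2)) {
    for (x1 in c(0, 1, 7, 19)) {
      for (x0 in c(0, 2, 11, 30)) {
        if (x1 + x0 == 0) next
        expect_equal(binomial_pvalue(x1, x0, r), oracle_binom_tail(x1, x0, r),
                     tolerance = 1e-10)
      }
    }
  }
  for (n in c(10, 55, 100)) {
    p <- binomial_pvalue(0:n, n:0, 1.3)
    # strictly decreasing wherever the tail is representable below 1
    # (deep upper tails saturate at 1 in double precision)
    expect_true(all(diff(p) <= 0))
    rep_ok <- p < 1 - 1e-12
    expect_true(all(diff(p[rep_ok]) < 0))
  }
})

test_that("rank_chiptigs orders by p then x1 then id and truncates", {
  rec <- data.frame(chiptig_id = c("a", "b", "c"), x1 = c(5L, 9L, 2L),
                    x0 = c(1L, 1L, 1L), p = c(0.5, 0.01, 0.2))
  rk <- rank_chiptigs(rec, top_m = 2)
  expect_equal(rk$records$chiptig_id, c("b", "c", "a"))
  expect_equal(rk$records$rank, 1:3)
  expect_equal(nrow(rk$top), 2L)

  tie <- data.frame(chiptig_id = c("a", "b"), x1 = c(10L, 100L),
                    x0 = c(5L, 5L), p = c(0.2, 0.2))
  expect_equal(rank_chiptigs(tie)$records$chiptig_id[1], "b")

  many <- data.frame(chiptig_id = paste0("c", 1:500), x1 = 1:500,
                     x0 = rep(1L, 500), p = runif(500))
  expect_equal(nrow(rank_chiptigs(many, top_m = 1000)$top), 500L)
})

test_that("null simulation is calibrated: <= 10% of ChIPtigs at p < 0.05", {
  # scaled-down null world (fold = 1); the standard-scale version runs in
  # the acceptance suite
  cfg <- simulation_config(genome_length = 30000L, n_sites = 60L,
                           n_case_reads = 15000L, n_control_reads = 15000L,
                           enrichment_fold = 1, seed = 55L)
  sim <- simulate_experiment(cfg)
  tigs <- assemble_dbg(sim$case)
  enr <- enrich_chiptigs(tigs, sim$case, sim$control)
  expect_lte(mean(enr$records$p < 0.05), 0.10)
})
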