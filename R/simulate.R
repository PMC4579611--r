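# Synthetic ChIP-seq experiment generator with known ground truth.
#
# The simulator emulates the case/control design of a TF ChIP-seq study:
# a random genome with motif sites planted from a PWM, case fragments
# drawn preferentially from site-overlapping positions (configurable
# fold enrichment of the per-bp fragment start rate), control fragments
# uniform, reads taken from the 5' end of either fragment strand (which
# produces the anti-correlated Watson/Crick read pattern around site
# centers), and uniform base-substitution sequencing error.

#' Default planted-site PWM
#'
#' A strong but non-degenerate 8-bp motif: the consensus base carries
#' `dominance` probability per column, the rest is spread evenly. The
#' default consensus is an AP-1-like word.
#'
#' @param consensus consensus string over ACGT.
#' @param dominance probability of the consensus base per column.
#' @return L x 4 PWM matrix (columns A,C,G,T).
#' @export
default_site_pwm <- function(consensus = "TGACTCAG", dominance = 0.85) {
  stopifnot(dominance > 0.25, dominance <= 1)
  b <- strsplit(consensus, "")[[1]]
  stopifnot(all(b %in% BASES))
  pwm <- matrix((1 - dominance) / 3, nrow = length(b), ncol = 4,
                dimnames = list(NULL, BASES))
  pwm[cbind(seq_along(b), match(b, BASES))] <- dominance
  pwm
}

#' Simulation configuration
#'
#' Defaults are the standard configuration used throughout the test
#' suite: a 100 kb genome at GC 0.5 with 200 planted 8-bp sites spaced
#' at least 200 bp apart, 50,000 case and 50,000 control reads of 36 bp,
#' 10x fold enrichment, fragments of 150 +/- 20 bp and 0.5% per-base
#' substitution error.
#'
#' @param genome_length genome size in bp.
#' @param gc_fraction genome GC content in `[0,1]`.
#' @param pwm planted motif PWM (L x 4).
#' @param n_sites number of planted sites.
#' @param min_site_spacing minimum gap (bp) between site starts beyond
#'   the motif length.
#' @param n_case_reads,n_control_reads library sizes.
#' @param enrichment_fold ratio of per-bp fragment start rate in site
#'   fragments vs background (>= 1).
#' @param fragment_length_mean,fragment_length_sd fragment model (bp);
#'   lengths are truncated to `[read_length, 3 * mean]`.
#' @param read_length read length (bp).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(genome_length = 100000L, gc_fraction = 0.5,
                              pwm = default_site_pwm(), n_sites = 200L,
                              min_site_spacing = 200L,
                              n_case_reads = 50000L, n_control_reads = 50000L,
                              enrichment_fold = 10, fragment_length_mean = 150,
                              fragment_length_sd = 20, read_length = 36L,
                              error_rate = 0.005, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, pwm = pwm,
              n_sites = as.integer(n_sites),
              min_site_spacing = as.integer(min_site_spacing),
              n_case_reads = as.integer(n_case_reads),
              n_control_reads = as.integer(n_control_reads),
              enrichment_fold = enrichment_fold,
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd,
              read_length = as.integer(read_length),
              error_rate = error_rate, seed = as.integer(seed))
  w <- nrow(pwm)
  if (cfg$n_sites > 0 && cfg$n_sites * (w + cfg$min_site_spacing) > cfg$genome_length) {
    stop("infeasible: n_sites * (motif length + min_site_spacing) > genome_length")
  }
  if (cfg$read_length > cfg$fragment_length_mean) {
    stop("read_length must not exceed fragment_length_mean")
  }
  if (cfg$gc_fraction < 0 || cfg$gc_fraction > 1 || cfg$error_rate < 0 ||
      cfg$error_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc_fraction/2` and
#' `P(A) = P(T) = (1 - gc_fraction)/2`; deterministic given the seed.
#'
#' @param length genome length (>= 1).
#' @param gc_fraction GC content.
#' @param seed RNG seed.
#' @return a single character string.
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = 1L) {
  if (length <= 0) stop("length must be >= 1")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  with_seed(seed, paste0(sample(BASES, length, replace = TRUE, prob = p),
                         collapse = ""))
}

#' Plant motif sites in a genome
#'
#' Draws `n_sites` non-overlapping positions whose starts are at least
#' `motif length + min_spacing` apart (uniform over all feasible
#' configurations via the gap construction), samples a site instance
#' column-wise from the PWM at each, picks a strand uniformly, and
#' writes the instance (reverse-complemented for `-`) into the genome.
#'
#' @param genome genome string.
#' @param pwm L x 4 PWM.
#' @param n_sites number of sites.
#' @param min_spacing minimum extra gap between site starts (bp).
#' @param seed RNG seed.
#' @return list with `genome` (modified string) and `sites`, a
#'   data.frame of 0-based `start`, `strand`, `instance` sorted by
#'   start.
#' @export
plant_sites <- function(genome, pwm, n_sites, min_spacing = 200L, seed = 1L) {
  L <- nchar(genome)
  w <- nrow(pwm)
  empty <- data.frame(start = integer(0), strand = character(0),
                      instance = character(0), stringsAsFactors = FALSE)
  if (n_sites == 0L) return(list(genome = genome, sites = empty))
  step <- w + min_spacing
  M <- L - w + 1L - (n_sites - 1L) * step
  if (M < n_sites) stop("infeasible site placement for this genome length")
  with_seed(seed, {
    raw <- sort(sample.int(M, n_sites))
    starts1 <- raw + (seq_len(n_sites) - 1L) * step  # 1-based
    inst <- vapply(seq_len(n_sites), function(i) {
      paste0(BASES[vapply(seq_len(w), function(j) {
        sample.int(4L, 1L, prob = pwm[j, ])
      }, integer(1))], collapse = "")
    }, character(1))
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    written <- ifelse(strand == "+", inst, revcomp(inst))
    gch <- strsplit(genome, "")[[1]]
    for (i in seq_len(n_sites)) {
      gch[starts1[i]:(starts1[i] + w - 1L)] <- strsplit(written[i], "")[[1]]
    }
    list(genome = paste0(gch, collapse = ""),
         sites = data.frame(start = starts1 - 1L, strand = strand,
                            instance = inst, stringsAsFactors = FALSE))
  })
}

# Truncated-normal fragment lengths on [read_length, 3 * mean].
sample_fragment_lengths <- function(n, mean, sd, read_length) {
  lo <- pnorm(read_length, mean, sd)
  hi <- pnorm(3 * mean, mean, sd)
  round(qnorm(lo + runif(n) * (hi - lo), mean, sd))
}

# Apply uniform substitution error in place (vectorised over reads).
apply_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), error_rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    s <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(s), nerr[i])
    for (p in pos) {
      s[p] <- sample(setdiff(BASES, s[p]), 1L)
    }
    reads[i] <- paste0(s, collapse = "")
  }
  reads
}

#' Simulate a ChIP-seq experiment
#'
#' Control fragments start uniformly on the genome. A case fragment is
#' site-derived with probability `w / (w + genome_length)` where
#' `w = enrichment_fold * n_sites * fragment_length_mean`, which makes
#' the per-bp fragment start rate inside site fragments exactly
#' `enrichment_fold` times the background rate. Site fragments are
#' placed so the fragment covers the site center (uniform offset). Every
#' read is the first `read_length` bases from the 5' end of a uniformly
#' chosen fragment strand, then subjected to substitution error.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; when given, case/control FASTQ, the
#'   genome FASTA and a BED-like TSV of 0-based half-open site intervals
#'   are written there.
#' @return list with `case`, `control` (data.frames of `id`,
#'   `sequence`, `source`), `sites` (ground truth annotations),
#'   `genome` (string with sites planted) and `config`.
#' @export
simulate_experiment <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome0 <- generate_genome(config$genome_length, config$gc_fraction,
                             derive_seed(config$seed, "genome"))
  planted <- plant_sites(genome0, config$pwm, config$n_sites,
                         config$min_site_spacing,
                         derive_seed(config$seed, "sites"))
  genome <- planted$genome
  L <- config$genome_length
  w <- nrow(config$pwm)
  rl <- config$read_length

  draw_reads <- function(n, site_prob, prefix, seed) {
    with_seed(seed, {
      flen <- sample_fragment_lengths(n, config$fragment_length_mean,
                                      config$fragment_length_sd, rl)
      from_site <- if (site_prob > 0 && config$n_sites > 0) {
        runif(n) < site_prob
      } else rep(FALSE, n)
      fstart <- integer(n)
      nbg <- sum(!from_site)
      # background: uniform fragment placement fully inside the genome
      fstart[!from_site] <- floor(runif(nbg) * pmax(L - flen[!from_site] + 1L, 1L)) + 1L
      ns <- sum(from_site)
      if (ns > 0L) {
        si <- sample.int(config$n_sites, ns, replace = TRUE)
        center <- planted$sites$start[si] + floor(w / 2) + 1L  # 1-based
        off <- floor(runif(ns) * flen[from_site])  # fragment covers center
        st <- center - off
        st <- pmax(1L, pmin(st, L - flen[from_site] + 1L))
        fstart[from_site] <- st
      }
      strand <- sample(c("+", "-"), n, replace = TRUE)
      starts <- ifelse(strand == "+", fstart, fstart + flen - rl)
      reads <- substring(genome, starts, starts + rl - 1L)
      neg <- strand == "-"
      if (any(neg)) reads[neg] <- revcomp(reads[neg])
      reads <- apply_substitutions(reads, config$error_rate)
      data.frame(id = paste0(prefix, seq_len(n)), sequence = reads,
                 source = if (prefix == "case_") "case" else "control",
                 stringsAsFactors = FALSE)
    })
  }

  ws <- config$enrichment_fold * config$n_sites * config$fragment_length_mean
  site_prob <- ws / (ws + L)
  case <- draw_reads(config$n_case_reads, site_prob, "case_",
                     derive_seed(config$seed, "case"))
  control <- draw_reads(config$n_control_reads, 0, "ctrl_",
                        derive_seed(config$seed, "control"))

  out <- list(case = case, control = control, sites = planted$sites,
              genome = genome, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fastq <- function(df, path) {
      con <- file(path, "wt")
      on.exit(close(con))
      writeLines(paste0("@", df$id, "\n", df$sequence, "\n+\n",
                        strrep("I", nchar(df$sequence))), con)
    }
    write_fastq(case, file.path(outdir, "case.fastq"))
    write_fastq(control, file.path(outdir, "control.fastq"))
    write_fasta("genome", genome, file.path(outdir, "genome.fasta"))
    sites_bed <- data.frame(chrom = "genome", start = planted$sites$start,
                            end = planted$sites$start + w,
                            strand = planted$sites$strand)
    write.table(sites_bed, file.path(outdir, "sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    out$paths <- list(case = file.path(outdir, "case.fastq"),
                      control = file.path(outdir, "control.fastq"),
                      genome = file.path(outdir, "genome.fasta"),
                      sites = file.path(outdir, "sites.tsv"))
  }
  out
}
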