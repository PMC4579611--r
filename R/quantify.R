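# Map case and control reads to ChIPtigs, filter by length, score
# enrichment with the binomial tail probability, and rank.

#' Read mapping parameters
#'
#' @param seed_length exact seed length for the seed-and-extend mapper.
#'   With disjoint seeds, any placement with up to
#'   `floor(read_length / seed_length) - 1` mismatches is guaranteed to
#'   be found.
#' @param max_mismatches maximum mismatches in the full-length ungapped
#'   verification.
#' @param both_strands map reads against both ChIPtig strands.
#' @return a `mapping_params` list.
#' @export
mapping_params <- function(seed_length = 12L, max_mismatches = 2L,
                           both_strands = TRUE) {
  p <- list(seed_length = as.integer(seed_length),
            max_mismatches = as.integer(max_mismatches),
            both_strands = isTRUE(both_strands))
  class(p) <- "mapping_params"
  p
}

#' Filter ChIPtigs by length
#'
#' Keeps ChIPtigs with `min_len <= length <= max_len` (inclusive);
#' bound regions are not expected to be much longer than 500 bp.
#'
#' @param chiptigs ChIPtig data.frame (needs a `length` column, or
#'   `sequence` from which lengths are computed).
#' @param min_len,max_len inclusive bounds (bp).
#' @return the filtered data.frame.
#' @export
length_filter <- function(chiptigs, min_len = 50L, max_len = 500L) {
  len <- if ("length" %in% names(chiptigs)) chiptigs$length
         else nchar(chiptigs$sequence)
  chiptigs[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Map reads to ChIPtigs
#'
#' Seed-and-extend: an exact `seed_length`-mer index over the ChIPtigs,
#' candidate placements verified by full-length ungapped comparison with
#' at most `max_mismatches` mismatches. Each read contributes to at most
#' one ChIPtig: the best hit by fewest mismatches, ties broken by the
#' ChIPtig earliest in the input order, then + strand, then leftmost
#' position.
#'
#' @param chiptigs ChIPtig data.frame (columns `id`, `sequence`) -- must
#'   be non-empty.
#' @param reads character vector of read sequences or data.frame with a
#'   `sequence` column.
#' @param params a [mapping_params()].
#' @return list with `counts` (named integer vector per ChIPtig id),
#'   `n_mapped`, `n_unmapped`, and `assignment` (per-read ChIPtig index,
#'   0 for unmapped).
#' @export
map_reads <- function(chiptigs, reads, params = mapping_params()) {
  if (nrow(chiptigs) == 0L) stop("empty ChIPtig set")
  seqs <- read_sequences(reads)
  res <- cpp_map_reads(chiptigs$sequence, seqs, params$seed_length,
                       params$max_mismatches, params$both_strands)
  counts <- tabulate(res$ref[res$ref > 0L], nbins = nrow(chiptigs))
  names(counts) <- chiptigs$id
  n_mapped <- sum(res$ref > 0L)
  list(counts = counts, n_mapped = n_mapped,
       n_unmapped = length(seqs) - n_mapped, assignment = res$ref)
}

#' Binomial enrichment tail probability
#'
#' Probability of observing `x1` or more successes in `x1 + x0` trials
#' with per-trial success probability `r / (r + 1)`, where `r` is the
#' case/control library ratio. Computed with the numerically stable
#' regularised incomplete beta tail (`pbinom`). Vectorised over
#' `x1`/`x0`. ChIPtigs with `x1 + x0 = 0` receive p = 1 (with a
#' message); `r <= 0` is an error.
#'
#' @param x1 case read counts.
#' @param x0 control read counts.
#' @param r positive library ratio (case / control).
#' @return tail probabilities in `[0, 1]`.
#' @export
binomial_pvalue <- function(x1, x0, r) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(x1 < 0 | x0 < 0)) stop("counts must be non-negative")
  n <- x1 + x0
  p <- rep(1, length(n))
  nz <- n > 0
  if (any(!nz)) message(sum(!nz), " ChIPtig(s) with no mapped reads; p = 1 recorded")
  p[nz] <- pbinom(x1[nz] - 1, n[nz], r / (r + 1), lower.tail = FALSE)
  p
}

#' Rank ChIPtigs by enrichment P-value
#'
#' Ascending by p; ties broken by descending `x1`, then by `chiptig_id`
#' lexicographically. Ranks are 1..N; the top `top_m` records (or all,
#' if fewer) are flagged for motif discovery.
#'
#' @param records data.frame with `chiptig_id`, `x1`, `x0`, `p` (other
#'   columns are carried through).
#' @param top_m number of top records to return in the `top` component.
#' @return list with `records` (ranked, with `rank` and BH `q` columns)
#'   and `top` (the top-m subset).
#' @export
rank_chiptigs <- function(records, top_m = 1000L) {
  ord <- order(records$p, -records$x1, records$chiptig_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  records$q <- p.adjust(records$p, method = "BH")
  rownames(records) <- NULL
  list(records = records, top = head(records, top_m))
}

#' Score and rank ChIPtigs against a control library
#'
#' Full quantification step: length-filter the ChIPtigs, map case and
#' control reads, compute the global library ratio
#' `r = mapped case / mapped control`, score every ChIPtig with
#' [binomial_pvalue()] and rank. `r` uses reads mapped to the filtered
#' ChIPtig set (internally consistent with the trials model); pass
#' `r_from_totals = TRUE` to use raw library sizes instead.
#'
#' @param chiptigs ChIPtig data.frame.
#' @param case_reads,control_reads read containers.
#' @param params a [mapping_params()].
#' @param top_m top records passed to motif discovery.
#' @param min_len,max_len length filter bounds.
#' @param r_from_totals use raw library sizes for `r`.
#' @return list with `records`, `top` (as [rank_chiptigs()]), `r`,
#'   `n_mapped_case`, `n_mapped_control`, `chiptigs` (filtered set).
#' @export
enrich_chiptigs <- function(chiptigs, case_reads, control_reads,
                            params = mapping_params(), top_m = 1000L,
                            min_len = 50L, max_len = 500L,
                            r_from_totals = FALSE) {
  flt <- length_filter(chiptigs, min_len, max_len)
  if (nrow(flt) == 0L) stop("no ChIPtig passes the length filter")
  mc <- map_reads(flt, case_reads, params)
  m0 <- map_reads(flt, control_reads, params)
  r <- if (r_from_totals) {
    length(read_sequences(case_reads)) / length(read_sequences(control_reads))
  } else {
    if (m0$n_mapped == 0L) stop("no control read maps; library ratio undefined")
    mc$n_mapped / m0$n_mapped
  }
  records <- data.frame(chiptig_id = flt$id, length = flt$length,
                        x1 = as.integer(mc$counts), x0 = as.integer(m0$counts),
                        sequence = flt$sequence, stringsAsFactors = FALSE)
  records$p <- binomial_pvalue(records$x1, records$x0, r)
  rk <- rank_chiptigs(records, top_m)
  list(records = rk$records, top = rk$top, r = r,
       n_mapped_case = mc$n_mapped, n_mapped_control = m0$n_mapped,
       chiptigs = flt)
}
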