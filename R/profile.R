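# Consensus profile assembler: seed clusters of reads sharing a k-mer,
# learn a left-to-right per-column model, extend with partially
# overlapping reads using discounted online count updates, and stop
# extension at high-entropy columns.
#
# The model is match-columns only (no insert/delete states): ChIP-seq
# reads derive from contiguous genomic DNA and the error model is
# substitution-only. Two count matrices are kept per model: `tally`
# (integer observed base counts per column, used for depth, consensus
# ties and the entropy stopping rule on *observed* frequencies) and `g`
# (the online-blended expected emission counts, used for emissions).

#' Online learning schedule
#'
#' The discount factor alpha(r) controls how much a new read (or batch)
#' can move the model after r reads have been seen: counts are updated
#' as `count <- alpha * count + (1 - alpha) * count_new`. The default
#' schedule `alpha(r) = 1 - (r + 2)^(-0.8)` rises toward 1 so that late
#' reads perturb the model less; it is injectable for experimentation.
#'
#' @param alpha_of_r function mapping read count r to alpha in `[0,1]`.
#' @param max_entropy entropy stopping threshold in nats (default 0.6,
#'   between a pure column at 0 and a 50/50 column at ln 2 = 0.693).
#' @return an `online_schedule` list.
#' @export
online_schedule <- function(alpha_of_r = function(r) 1 - (r + 2)^(-0.8),
                            max_entropy = 0.6) {
  s <- list(alpha_of_r = alpha_of_r, max_entropy = max_entropy)
  class(s) <- "online_schedule"
  s
}

#' Shannon entropy of an emission distribution
#'
#' `-sum(p * ln p)` in nats with the convention `0 * ln 0 = 0`. The
#' input is normalised if it does not sum to 1.
#'
#' @param emission non-negative numeric vector (base distribution).
#' @return entropy in nats.
#' @export
column_entropy <- function(emission) {
  if (any(emission < 0)) stop("negative emission probability")
  s <- sum(emission)
  if (s <= 0) return(0)
  p <- emission / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Seed clusters of highly similar reads
#'
#' Iterates over k-mers in decreasing multiplicity (ties by k-mer code);
#' every k-mer still carried by at least `min_seed_depth` unconsumed
#' reads founds a cluster of all such reads (either strand; minus-strand
#' members are stored reverse-complemented). Reads are consumed
#' greedily, one cluster each.
#'
#' @param reads character vector of read sequences or data.frame with a
#'   `sequence` column.
#' @param k seed k-mer length.
#' @param min_seed_depth minimum k-mer multiplicity to found a cluster.
#' @return list of clusters; each has `sequence` (oriented reads),
#'   `offset` (0-based position of the seed k-mer in the oriented read),
#'   `read` (input indices) and `seed` (the seed k-mer). The full
#'   per-read assignment is attached as attribute `assignment`.
#' @export
seed_clusters <- function(reads, k = 17L, min_seed_depth = 4L) {
  seqs <- read_sequences(reads)
  res <- cpp_seed_clusters(seqs, k, min_seed_depth)
  ncl <- res$n_clusters
  out <- vector("list", ncl)
  if (ncl > 0L) {
    for (cid in seq_len(ncl)) {
      idx <- which(res$cluster == cid)
      oriented <- ifelse(res$strand[idx] == 1L, seqs[idx], revcomp(seqs[idx]))
      out[[cid]] <- list(sequence = oriented, offset = res$offset[idx],
                         read = idx, seed = res$seed_kmer[cid])
    }
  }
  attr(out, "assignment") <- data.frame(cluster = res$cluster,
                                        offset = res$offset,
                                        strand = res$strand)
  out
}

# Tally base counts of aligned reads into a 4 x L matrix. `starts` are
# 0-based columns of each read's first base relative to column 1 = 0.
tally_reads <- function(seqs, starts, L) {
  M <- matrix(0, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  for (i in seq_along(seqs)) {
    b <- match(strsplit(seqs[i], "")[[1]], BASES)
    cols <- starts[i] + seq_along(b)
    ok <- !is.na(b) & cols >= 1L & cols <= L
    if (any(ok)) {
      M[cbind(b[ok], cols[ok])] <- M[cbind(b[ok], cols[ok])] + 1
    }
  }
  M
}

new_profile <- function(tally, g, r_seen, assigned, k) {
  L <- ncol(tally)
  m <- list(tally = tally, g = g,
            gamma = colSums(tally),
            epsilon = if (L > 1L) pmin(colSums(tally)[-L], colSums(tally)[-1L]) else numeric(0),
            a = rep(1, max(L - 1L, 0L)),
            r_seen = r_seen, assigned = assigned, k = k)
  class(m) <- "profile_model"
  m
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile model: %d column(s), %d read(s) incorporated\n",
              ncol(x$tally), x$r_seen))
  invisible(x)
}

#' Initialise a profile model from a seed cluster
#'
#' Reads are anchored by their shared k-mer offsets (ungapped multiple
#' alignment). Per column, the emission distribution is the base
#' frequency with a pseudocount of 0.1 per base.
#'
#' @param cluster one element of [seed_clusters()] output (fields
#'   `sequence`, `offset`), or a list with those fields.
#' @param k seed k-mer length used for bookkeeping.
#' @return a `profile_model`.
#' @export
init_profile <- function(cluster, k = nchar(cluster$seed %||% "")) {
  seqs <- cluster$sequence
  if (length(seqs) == 0L) stop("empty cluster")
  off <- cluster$offset
  # column 1 anchors at the leftmost read start
  starts <- max(off) - off  # 0-based
  L <- max(starts + nchar(seqs))
  tally <- tally_reads(seqs, starts, L)
  depth <- colSums(tally)
  g <- sweep(tally + 0.1, 2L, depth + 0.4, "/")
  m <- new_profile(tally, g, r_seen = length(seqs),
                   assigned = cluster$read %||% integer(0),
                   k = if (is.numeric(k) && k > 0) as.integer(k) else 17L)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-column emission matrix
#' @param model a `profile_model`.
#' @return 4 x L matrix of emission probabilities (columns sum to 1).
#' @export
profile_emissions <- function(model) {
  sweep(model$g, 2L, colSums(model$g), "/")
}

#' Consensus sequence of a profile model
#'
#' Per-column argmax emission base, ties broken in fixed order
#' A < C < G < T.
#'
#' @param model a `profile_model`.
#' @return a single character string.
#' @export
profile_consensus <- function(model) {
  paste0(BASES[max.col(t(model$g), ties.method = "first")], collapse = "")
}

# observed-frequency entropy per column (no pseudocount)
profile_entropies <- function(model) {
  apply(model$tally, 2L, column_entropy)
}

#' Discounted online count update
#'
#' Incorporates a batch of aligned reads into the model using the
#' discounted update `count <- alpha * count + (1 - alpha) * count_new`
#' on every covered column, where `count_new` is the batch's expected
#' emission distribution and `alpha = schedule$alpha_of_r(r_seen)`.
#' Reads whose agreement with the current consensus over the overlap is
#' below `agree_min` are rejected (their indices are returned), not an
#' error. Offsets may extend past either end; overhanging bases create
#' new columns initialised from the batch counts with pseudocount 0.1.
#'
#' @param model a `profile_model`.
#' @param new_reads character vector of oriented read sequences.
#' @param offsets 0-based column of each read's first base (may be
#'   negative for left extension).
#' @param schedule an [online_schedule()].
#' @param agree_min minimum consensus agreement over the overlap.
#' @return list with `model` (updated), `rejected` (indices into
#'   `new_reads`), `new_left`, `new_right` (columns created).
#' @export
online_update <- function(model, new_reads, offsets,
                          schedule = online_schedule(), agree_min = 0.9) {
  L <- ncol(model$tally)
  cons <- profile_consensus(model)
  agr <- cpp_agreement(new_reads, as.integer(offsets), cons)
  ok <- agr$overlap > 0L & agr$frac >= agree_min
  rejected <- which(!ok)
  if (!any(ok)) {
    return(list(model = model, rejected = rejected,
                new_left = 0L, new_right = 0L))
  }
  seqs <- new_reads[ok]
  off <- offsets[ok]
  new_left <- max(0L, -min(off))
  new_right <- max(0L, max(off + nchar(seqs)) - L)
  L2 <- L + new_left + new_right
  starts <- off + new_left
  M <- tally_reads(seqs, starts, L2)
  bdepth <- colSums(M)

  alpha <- schedule$alpha_of_r(model$r_seen)
  old_cols <- new_left + seq_len(L)
  tally2 <- matrix(0, nrow = 4L, ncol = L2, dimnames = list(BASES, NULL))
  g2 <- matrix(0, nrow = 4L, ncol = L2, dimnames = list(BASES, NULL))
  tally2[, old_cols] <- model$tally + M[, old_cols]
  g2[, old_cols] <- model$g
  covered <- old_cols[bdepth[old_cols] > 0]
  if (length(covered) > 0L) {
    gR <- sweep(M[, covered, drop = FALSE], 2L,
                bdepth[covered], "/")
    g2[, covered] <- alpha * g2[, covered, drop = FALSE] + (1 - alpha) * gR
  }
  new_cols <- setdiff(seq_len(L2), old_cols)
  if (length(new_cols) > 0L) {
    tally2[, new_cols] <- M[, new_cols]
    g2[, new_cols] <- sweep(M[, new_cols, drop = FALSE] + 0.1, 2L,
                            bdepth[new_cols] + 0.4, "/")
  }
  m2 <- new_profile(tally2, g2, model$r_seen + length(seqs),
                    model$assigned, model$k)
  list(model = m2, rejected = rejected,
       new_left = new_left, new_right = new_right)
}

# Look up unassigned reads containing a given k-mer in the read index.
# Returns oriented sequences and 0-based positions of the k-mer within
# the oriented read such that the k-mer reads forward.
lookup_kmer_reads <- function(idx, assigned, seqs, kmer) {
  cc <- cpp_canonical_code(kmer)
  if (is.na(cc$code)) return(NULL)
  hits <- idx[list(cc$code), nomatch = NULL]
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[!assigned[hits$read]]
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[!duplicated(hits$read)]
  n <- nchar(seqs[hits$read])
  if (cc$fwd) {
    oriented <- ifelse(hits$strand == 1L, seqs[hits$read],
                       revcomp(seqs[hits$read]))
    pos <- hits$pos
  } else {
    # the query k-mer is the reverse complement of the canonical spelling
    oriented <- ifelse(hits$strand == 1L, revcomp(seqs[hits$read]),
                       seqs[hits$read])
    pos <- n - nchar(kmer) - hits$pos
  }
  list(read = hits$read, sequence = oriented, pos = pos)
}

#' Extend a profile model and finalise a ChIPtig
#'
#' Alternately extends right and left: unassigned reads whose
#' prefix/suffix aligns to the terminal k consensus columns with at
#' least `agree_min` agreement are incorporated in batches via
#' [online_update()]; their overhanging bases create new columns. A side
#' stops when a newly created column's observed-frequency entropy
#' exceeds `schedule$max_entropy` (the side is trimmed back to its last
#' clean column) or no reads qualify. At finalisation every column with
#' entropy above the threshold is dropped and the longest contiguous
#' clean run is reported; the consensus ChIPtig is the per-column argmax
#' base with ties broken A < C < G < T.
#'
#' @param model an initialised `profile_model`.
#' @param pool environment with fields `seqs` (all read sequences),
#'   `assigned` (logical), `idx` (data.table k-mer index keyed by
#'   `kmer`), as built by [assemble_profile()]; or `NULL` for no
#'   extension.
#' @param schedule an [online_schedule()].
#' @param batch reads incorporated per online update batch.
#' @param agree_min minimum consensus agreement for extension reads.
#' @return list with `model`, `sequence` (finalised consensus),
#'   `depth` (mean column depth over the kept run).
#' @export
extend_and_finalize <- function(model, pool = NULL,
                                schedule = online_schedule(), batch = 20L,
                                agree_min = 0.9) {
  k <- model$k
  sides_open <- c(right = !is.null(pool), left = !is.null(pool))
  while (any(sides_open)) {
    for (side in names(sides_open)[sides_open]) {
      L <- ncol(model$tally)
      if (L < k) { sides_open[side] <- FALSE; next }
      cons <- profile_consensus(model)
      wseq <- if (side == "right") substring(cons, L - k + 1L, L)
              else substring(cons, 1L, k)
      cand <- lookup_kmer_reads(pool$idx, pool$assigned, pool$seqs, wseq)
      if (is.null(cand)) { sides_open[side] <- FALSE; next }
      wcol <- if (side == "right") L - k + 1L else 1L
      offsets <- (wcol - 1L) - cand$pos
      extends <- if (side == "right") {
        offsets + nchar(cand$sequence) > L
      } else offsets < 0L
      if (!any(extends)) { sides_open[side] <- FALSE; next }
      ord <- order(if (side == "right") -(offsets + nchar(cand$sequence))
                   else offsets, cand$read)
      take <- ord[extends[ord]][seq_len(min(batch, sum(extends)))]
      upd <- online_update(model, cand$sequence[take], offsets[take],
                           schedule, agree_min)
      accepted <- take[setdiff(seq_along(take), upd$rejected)]
      if (length(accepted) == 0L) { sides_open[side] <- FALSE; next }
      pool$assigned[cand$read[accepted]] <- TRUE
      model <- upd$model
      model$assigned <- c(model$assigned, cand$read[accepted])
      n_new <- if (side == "right") upd$new_right else upd$new_left
      if (n_new == 0L) { sides_open[side] <- FALSE; next }
      ent <- profile_entropies(model)
      L2 <- ncol(model$tally)
      new_cols <- if (side == "right") (L2 - n_new + 1L):L2 else seq_len(n_new)
      if (any(ent[new_cols] > schedule$max_entropy)) {
        # trim back to the last clean column on this side and stop
        bad <- new_cols[ent[new_cols] > schedule$max_entropy]
        if (side == "right") {
          keep <- seq_len(min(bad) - 1L)
        } else {
          keep <- (max(bad) + 1L):L2
        }
        model <- trim_profile(model, keep)
        sides_open[side] <- FALSE
      }
    }
  }
  # final clean-run trim on observed-frequency entropy
  ent <- profile_entropies(model)
  ok <- ent <= schedule$max_entropy
  run <- longest_run(ok)
  if (length(run) == 0L) {
    return(list(model = model, sequence = "", depth = 0))
  }
  model <- trim_profile(model, run)
  list(model = model, sequence = profile_consensus(model),
       depth = mean(colSums(model$tally)))
}

trim_profile <- function(model, keep) {
  m2 <- new_profile(model$tally[, keep, drop = FALSE],
                    model$g[, keep, drop = FALSE],
                    model$r_seen, model$assigned, model$k)
  m2
}

longest_run <- function(ok) {
  if (!any(ok)) return(integer(0))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  starts[best]:ends[best]
}

#' Assemble ChIPtigs with the consensus profile assembler
#'
#' Seeds clusters greedily by k-mer multiplicity, initialises a profile
#' per cluster (skipping clusters whose reads were meanwhile consumed),
#' extends each profile with overlapping unassigned reads, and after
#' finalisation recruits any remaining unassigned reads that align to
#' the consensus (so a uniformly covered source yields a single
#' ChIPtig).
#'
#' @param reads character vector of read sequences or data.frame with a
#'   `sequence` column (case reads only).
#' @param k seed k-mer length; by default 17 for read length < 30 and
#'   19 otherwise.
#' @param schedule an [online_schedule()].
#' @param min_seed_depth minimum k-mer multiplicity to seed a cluster.
#' @param agree_min minimum consensus agreement for extension and
#'   recruitment.
#' @param batch online-update batch size.
#' @param min_output_length minimum reported ChIPtig length.
#' @return data.frame with `id` (`prof_<n>` in discovery order),
#'   `sequence`, `length`, `mean_coverage` (mean column depth),
#'   `assembler`.
#' @export
assemble_profile <- function(reads, k = NULL, schedule = online_schedule(),
                             min_seed_depth = 4L, agree_min = 0.9,
                             batch = 20L, min_output_length = 50L) {
  seqs <- read_sequences(reads)
  if (is.null(k)) {
    rl <- stats::median(nchar(seqs))
    k <- if (rl < 30) 17L else 19L
  }
  k <- as.integer(k)
  usable <- nchar(seqs) >= k
  if (!any(usable)) stop("no read is at least k = ", k, " bases")

  clusters <- seed_clusters(seqs, k, min_seed_depth)
  idx <- data.table::as.data.table(cpp_read_kmer_index(seqs, k))
  data.table::setkey(idx, kmer)
  pool <- new.env(parent = emptyenv())
  pool$seqs <- seqs
  pool$assigned <- !usable
  pool$idx <- idx

  out_seq <- character(0); out_depth <- numeric(0)
  for (cl in clusters) {
    live <- !pool$assigned[cl$read]
    if (sum(live) < min_seed_depth) next
    cl2 <- list(sequence = cl$sequence[live], offset = cl$offset[live],
                read = cl$read[live], seed = cl$seed)
    pool$assigned[cl2$read] <- TRUE
    model <- init_profile(cl2, k)
    fin <- extend_and_finalize(model, pool, schedule, batch, agree_min)
    # recruit remaining unassigned reads that align to the consensus
    if (nchar(fin$sequence) >= k) {
      recruit_reads(fin$sequence, pool, k, agree_min)
    }
    if (nchar(fin$sequence) >= min_output_length) {
      out_seq <- c(out_seq, fin$sequence)
      out_depth <- c(out_depth, fin$depth)
    }
  }
  data.frame(id = if (length(out_seq)) paste0("prof_", seq_along(out_seq)) else character(0),
             sequence = out_seq, length = nchar(out_seq),
             mean_coverage = out_depth,
             assembler = rep("profile", length(out_seq)),
             stringsAsFactors = FALSE)
}

# Mark unassigned reads aligning to a finalised consensus as assigned.
recruit_reads <- function(consensus, pool, k, agree_min) {
  L <- nchar(consensus)
  wins <- substring(consensus, seq_len(L - k + 1L), k:L)
  cc <- cpp_canonical_code(wins)
  codes <- unique(cc$code[!is.na(cc$code)])
  if (length(codes) == 0L) return(invisible(0L))
  hits <- pool$idx[list(codes), nomatch = NULL]
  if (nrow(hits) == 0L) return(invisible(0L))
  hits <- hits[!pool$assigned[hits$read]]
  if (nrow(hits) == 0L) return(invisible(0L))
  hits <- hits[!duplicated(hits$read)]
  # align each candidate read by its matched k-mer
  n <- nchar(pool$seqs[hits$read])
  wpos <- match(hits$kmer, cc$code)  # consensus window (1-based)
  fwd <- cc$fwd[wpos]
  oriented <- ifelse(xor(hits$strand == 1L, !fwd),
                     pool$seqs[hits$read], revcomp(pool$seqs[hits$read]))
  pos <- ifelse(fwd, hits$pos, n - k - hits$pos)
  offsets <- (wpos - 1L) - pos
  agr <- cpp_agreement(oriented, as.integer(offsets), consensus)
  take <- agr$overlap >= k & agr$frac >= agree_min
  pool$assigned[hits$read[take]] <- TRUE
  invisible(sum(take))
}
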