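# Velvet-style de Bruijn graph assembler adapted for ChIP-seq.
#
# Nodes are canonical k-mers paired with their reverse complements (the
# twin is implicit in the canonical representation); maximal linear
# chains are merged into unitigs in C++, and the error-removal stages
# (tip clipping, bubble collapse, low-coverage pruning) operate on the
# small merged graph in R. Orientations: an edge (from, fo, to, to_or)
# means the path leaves `from` read in orientation `fo` ('+' = stored
# sequence, '-' = reverse complement) and enters `to` read in
# orientation `to_or`, overlapping by k-1 bases. Every adjacency is
# stored in both mirror directions.

#' Assembly parameters for the de Bruijn graph assembler
#'
#' @param k k-mer length (odd by default to avoid self-reverse-complement
#'   palindromic k-mers; even k is supported).
#' @param tip_max_length dead-end chains with cumulative sequence length
#'   strictly below this are clipped (default `2 * k`).
#' @param bubble_identity global-alignment identity at or above which
#'   parallel paths are collapsed.
#' @param min_node_coverage nodes with mean k-mer multiplicity below this
#'   are removed.
#' @param min_output_length minimum reported ChIPtig length (bp).
#' @return an `assembly_params` list.
#' @export
assembly_params <- function(k = 17L, tip_max_length = 2L * k,
                            bubble_identity = 0.8, min_node_coverage = 2.0,
                            min_output_length = 50L) {
  if (k < 11L) stop("k must be >= 11")
  p <- list(k = as.integer(k), tip_max_length = as.integer(tip_max_length),
            bubble_identity = bubble_identity,
            min_node_coverage = min_node_coverage,
            min_output_length = as.integer(min_output_length))
  class(p) <- "assembly_params"
  p
}

flip_or <- function(o) ifelse(o == "+", "-", "+")

new_dbg <- function(seq, cov, nk, edges, k, n_skipped = 0L) {
  g <- list(seq = seq, cov = cov, nk = nk, edges = edges, k = k,
            n_skipped = n_skipped)
  class(g) <- "chip_dbg"
  g
}

#' @export
print.chip_dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph (k = %d): %d node pair(s), %d oriented edge(s)\n",
              x$k, length(x$seq), nrow(x$edges)))
  invisible(x)
}

#' Build the de Bruijn graph from case reads
#'
#' Extracts canonical k-mers from the reads (reads shorter than k are
#' skipped with a message), builds the node set with reverse-complement
#' twins, and merges all linear chains into unitigs.
#'
#' @param reads character vector of read sequences or a data.frame with a
#'   `sequence` column (case reads only; assembly never sees the control).
#' @param params an [assembly_params()].
#' @return a `chip_dbg` graph.
#' @export
build_graph <- function(reads, params = assembly_params()) {
  seqs <- read_sequences(reads)
  k <- params$k
  short <- nchar(seqs) < k
  if (all(short)) stop("no read is at least k = ", k, " bases; empty graph")
  if (any(short)) {
    message(sum(short), " read(s) shorter than k skipped")
  }
  raw <- cpp_unitig_graph(seqs[!short], k)
  edges <- data.frame(from = raw$edge_from,
                      fo = ifelse(raw$edge_fo == 0L, "+", "-"),
                      to = raw$edge_to,
                      to_or = ifelse(raw$edge_to_or == 0L, "+", "-"),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  new_dbg(raw$seq, raw$cov, raw$nk, edges, k, sum(short))
}

# oriented sequences for vectors of nodes/orientations, batched revcomp
oriented_seqs <- function(g, nodes, ors) {
  s <- g$seq[nodes]
  neg <- ors == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

# number of edges leaving each oriented end; returns matrix nodes x c("+","-")
out_degrees <- function(g) {
  n <- length(g$seq)
  d <- matrix(0L, nrow = n, ncol = 2L, dimnames = list(NULL, c("+", "-")))
  if (nrow(g$edges) > 0L) {
    tab <- table(factor(g$edges$from, levels = seq_len(n)), g$edges$fo)
    d[, colnames(tab)] <- as.integer(tab)
  }
  d
}

# Drop nodes by index, removing incident edges and remapping ids.
delete_nodes <- function(g, drop) {
  if (length(drop) == 0L) return(g)
  keep <- setdiff(seq_along(g$seq), drop)
  map <- integer(length(g$seq))
  map[keep] <- seq_along(keep)
  e <- g$edges
  e <- e[!(e$from %in% drop) & !(e$to %in% drop), , drop = FALSE]
  e$from <- map[e$from]
  e$to <- map[e$to]
  new_dbg(g$seq[keep], g$cov[keep], g$nk[keep], e, g$k, g$n_skipped)
}

# Merge all linear chains: an edge u->v is a chain link when it is the
# only edge out of u's exit end and the only edge into v's entry end.
merge_linear <- function(g) {
  n <- length(g$seq)
  if (n == 0L || nrow(g$edges) == 0L) return(g)
  d <- out_degrees(g)
  e <- g$edges
  oix <- function(o) ifelse(o == "+", 1L, 2L)
  link <- d[cbind(e$from, oix(e$fo))] == 1L &
          d[cbind(e$to, oix(flip_or(e$to_or)))] == 1L &
          e$from != e$to
  if (!any(link)) return(g)
  le <- e[link, , drop = FALSE]
  okey <- function(node, o) paste0(node, o)
  succ_to <- setNames(le$to, okey(le$from, le$fo))
  succ_or <- setNames(le$to_or, okey(le$from, le$fo))
  pred_keys <- okey(le$to, le$to_or)

  visited <- rep(FALSE, n)
  chains <- list()
  heads <- le[!(okey(le$from, le$fo) %in% pred_keys), , drop = FALSE]
  walk_chain <- function(node, o) {
    ch_node <- node; ch_or <- o
    in_chain <- rep(FALSE, n); in_chain[node] <- TRUE
    repeat {
      key <- okey(node, o)
      nn <- unname(succ_to[key])
      if (is.na(nn)) break
      no <- unname(succ_or[key])
      if (visited[nn] || in_chain[nn]) break
      ch_node <- c(ch_node, nn); ch_or <- c(ch_or, no)
      in_chain[nn] <- TRUE
      node <- nn; o <- no
    }
    list(node = ch_node, o = ch_or)
  }
  if (nrow(heads) > 0L) {
    for (i in seq_len(nrow(heads))) {
      hn <- heads$from[i]; ho <- heads$fo[i]
      if (visited[hn]) next
      ch <- walk_chain(hn, ho)
      if (length(ch$node) >= 2L) {
        visited[ch$node] <- TRUE
        chains[[length(chains) + 1L]] <- ch
      }
    }
  }
  # leftover links form cycles; break each at its smallest unvisited node
  left <- le[!visited[le$from] & !visited[le$to], , drop = FALSE]
  while (nrow(left) > 0L) {
    start <- min(left$from)
    o <- left$fo[left$from == start][1]
    ch <- walk_chain(start, o)
    visited[ch$node] <- TRUE
    if (length(ch$node) >= 2L) chains[[length(chains) + 1L]] <- ch
    left <- left[!visited[left$from] & !visited[left$to], , drop = FALSE]
  }
  if (length(chains) == 0L) return(g)

  k <- g$k
  seqs <- g$seq; cov <- g$cov; nk <- g$nk

  # remove internal link edges and their mirrors before rewiring
  ekey <- paste(e$from, e$fo, e$to, e$to_or)
  internal <- unlist(lapply(chains, function(ch) {
    m <- length(ch$node)
    i <- seq_len(m - 1L)
    c(paste(ch$node[i], ch$o[i], ch$node[i + 1L], ch$o[i + 1L]),
      paste(ch$node[i + 1L], flip_or(ch$o[i + 1L]),
            ch$node[i], flip_or(ch$o[i])))
  }))
  e <- e[!(ekey %in% internal), , drop = FALSE]

  # merged sequences, one batched reverse complement over all chain parts
  all_nodes <- unlist(lapply(chains, `[[`, "node"))
  all_ors <- unlist(lapply(chains, `[[`, "o"))
  all_parts <- oriented_seqs(g, all_nodes, all_ors)
  lens <- lengths(lapply(chains, `[[`, "node"))
  part_split <- split(all_parts, rep(seq_along(chains), lens))

  firsts <- vapply(chains, function(ch) ch$node[1], integer(1))
  lasts <- vapply(chains, function(ch) ch$node[length(ch$node)], integer(1))
  o1s <- vapply(chains, function(ch) ch$o[1], character(1))
  oms <- vapply(chains, function(ch) ch$o[length(ch$o)], character(1))

  for (ci in seq_along(chains)) {
    parts <- part_split[[ci]]
    seqs[firsts[ci]] <- paste0(parts[1],
                               paste0(substring(parts[-1], k), collapse = ""))
    cov[firsts[ci]] <- sum(g$cov[chains[[ci]]$node])
    nk[firsts[ci]] <- sum(g$nk[chains[[ci]]$node])
  }

  # vectorised rewiring: tail references move to the head node
  tail_first <- integer(n); tail_first[lasts] <- firsts
  tail_om <- character(n); tail_om[lasts] <- oms
  head_flip <- rep(FALSE, n); head_flip[firsts] <- o1s == "-"
  is_last <- rep(FALSE, n); is_last[lasts] <- TRUE

  sel_f <- is_last[e$from]
  if (any(sel_f)) {
    e$fo[sel_f] <- ifelse(e$fo[sel_f] == tail_om[e$from[sel_f]], "+", "-")
    e$from[sel_f] <- tail_first[e$from[sel_f]]
  }
  sel_t <- is_last[e$to]
  if (any(sel_t)) {
    e$to_or[sel_t] <- ifelse(e$to_or[sel_t] == tail_om[e$to[sel_t]], "+", "-")
    e$to[sel_t] <- tail_first[e$to[sel_t]]
  }
  sel <- head_flip[e$from] & !sel_f
  e$fo[sel] <- flip_or(e$fo[sel])
  sel <- head_flip[e$to] & !sel_t
  e$to_or[sel] <- flip_or(e$to_or[sel])

  drop_all <- unlist(lapply(chains, function(ch) ch$node[-1L]))
  g2 <- new_dbg(seqs, cov, nk, e, k, g$n_skipped)
  g2 <- delete_nodes(g2, unique(drop_all))
  g2$edges <- unique(g2$edges)
  g2
}

#' Clip tips from the graph
#'
#' Iteratively removes short dead-end chains: after linear merging, any
#' node with exactly one free end, cumulative sequence length strictly
#' below `tip_max_length` (default 2k) and mean coverage strictly below
#' the best competing branch at its attachment point is deleted together
#' with its twin. Repeats to a fixpoint.
#'
#' @param g a `chip_dbg` graph.
#' @param params an [assembly_params()].
#' @return the simplified graph.
#' @export
remove_tips <- function(g, params = assembly_params(k = g$k)) {
  repeat {
    g <- merge_linear(g)
    n <- length(g$seq)
    if (n == 0L || nrow(g$edges) == 0L) return(g)
    d <- out_degrees(g)
    free_r <- d[, "+"] == 0L
    free_l <- d[, "-"] == 0L
    cand <- which(xor(free_l, free_r) & nchar(g$seq) < params$tip_max_length)
    if (length(cand) == 0L) return(g)
    meancov <- g$cov / pmax(g$nk, 1L)
    e <- g$edges
    # the tip's single attachment edge leaves its non-free end
    o_att <- ifelse(free_r[cand], "-", "+")
    akey <- paste(cand, o_att)
    ekey_from <- paste(e$from, e$fo)
    aidx <- match(akey, ekey_from)
    ok <- !is.na(aidx)
    cand <- cand[ok]; aidx <- aidx[ok]
    if (length(cand) == 0L) return(g)
    # competing branches entering the same oriented end of the neighbour:
    # group edges by entry endpoint and take the top two source coverages
    gkey <- paste(e$to, e$to_or)
    src_cov <- meancov[e$from]
    ord <- order(gkey, -src_cov)
    gk <- gkey[ord]
    rnk <- stats::ave(seq_along(gk), gk, FUN = seq_along)
    max1 <- src_cov[ord][rnk == 1L]
    names(max1) <- gk[rnk == 1L]
    max2 <- src_cov[ord][rnk == 2L]
    names(max2) <- gk[rnk == 2L]
    grp_size <- table(gkey)

    tip_grp <- gkey[aidx]
    size <- as.integer(grp_size[tip_grp])
    best_other <- ifelse(abs(meancov[cand] - unname(max1[tip_grp])) < 1e-12 &
                           !is.na(match(tip_grp, names(max2))),
                         unname(max2[tip_grp]), unname(max1[tip_grp]))
    # no sibling -> keep; tip must be strictly below the best competitor
    drop <- cand[size >= 2L & meancov[cand] < best_other]
    if (length(drop) == 0L) return(g)
    g <- delete_nodes(g, unique(drop))
  }
}

# Global alignment identity (percent matches over alignment length).
alignment_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::pid(al, type = "PID1") / 100
}

# Cheap identity with exact fallbacks: a length-ratio bound rules most
# pairs out; equal-length pairs are substitution bubbles and use Hamming
# identity; full global alignment only when it could still change the
# merge decision (shifted near-identical paths).
bubble_identity_of <- function(a, b, threshold) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) / max(la, lb) < threshold) return(0)
  if (la == lb) {
    h <- mean(utf8ToInt(a) == utf8ToInt(b))
    if (h >= threshold || h < 0.3) return(h)
  }
  alignment_identity(a, b)
}

#' Collapse bubbles (Tour Bus style)
#'
#' After linear merging, alternative paths between two branch points are
#' single nodes whose entry and exit ends attach to the same oriented
#' neighbours. Groups of such parallel nodes are examined in decreasing
#' coverage order; a path whose global-alignment identity with the
#' highest-coverage path in its group reaches `bubble_identity` is
#' merged into it (coverage summed, lower-coverage sequence discarded).
#' Iterates to a fixpoint, re-merging linear chains in between, which
#' also resolves nested bubbles.
#'
#' @inheritParams remove_tips
#' @return the simplified graph.
#' @export
collapse_bubbles <- function(g, params = assembly_params(k = g$k)) {
  repeat {
    g <- merge_linear(g)
    n <- length(g$seq)
    if (n == 0L || nrow(g$edges) == 0L) return(g)
    d <- out_degrees(g)
    cand <- which(d[, "+"] == 1L & d[, "-"] == 1L)
    if (length(cand) == 0L) return(g)
    e <- g$edges
    ekey_from <- paste(e$from, e$fo)
    li <- match(paste(cand, "-"), ekey_from)
    ri <- match(paste(cand, "+"), ekey_from)
    ok <- !is.na(li) & !is.na(ri) & e$to[li] != cand & e$to[ri] != cand
    cand <- cand[ok]; li <- li[ok]; ri <- ri[ok]
    if (length(cand) == 0L) return(g)
    key_f <- paste(e$to[li], flip_or(e$to_or[li]), e$to[ri], e$to_or[ri])
    key_r <- paste(e$to[ri], flip_or(e$to_or[ri]), e$to[li], e$to_or[li])
    use_f <- key_f <= key_r
    keys <- ifelse(use_f, key_f, key_r)
    kor <- ifelse(use_f, "+", "-")

    dup_keys <- unique(keys[duplicated(keys)])
    if (length(dup_keys) == 0L) return(g)
    meancov <- g$cov / pmax(g$nk, 1L)
    merged_any <- FALSE
    drop <- integer(0)
    # process bubble groups in decreasing best-coverage order
    grp_best <- vapply(dup_keys, function(kk) max(meancov[cand[keys == kk]]),
                       numeric(1))
    for (kk in dup_keys[order(-grp_best)]) {
      sel <- which(keys == kk)
      grp <- cand[sel]; gor <- kor[sel]
      oseq <- oriented_seqs(g, grp, gor)
      ord <- order(-meancov[grp], oseq)
      grp <- grp[ord]; gor <- gor[ord]; oseq <- oseq[ord]
      winner <- grp[1]
      for (j in seq_along(grp)[-1]) {
        ident <- bubble_identity_of(oseq[1], oseq[j], params$bubble_identity)
        if (ident >= params$bubble_identity) {
          g$cov[winner] <- g$cov[winner] + g$cov[grp[j]]
          drop <- c(drop, grp[j])
          merged_any <- TRUE
        }
      }
    }
    if (!merged_any) return(g)
    g <- delete_nodes(g, unique(drop))
  }
}

#' Remove low-coverage nodes
#'
#' Deletes nodes whose mean k-mer multiplicity (`cov / n_kmers`) is
#' strictly below `min_node_coverage`, together with their twins, and
#' re-merges linear chains.
#'
#' @inheritParams remove_tips
#' @return the simplified graph.
#' @export
remove_low_coverage <- function(g, params = assembly_params(k = g$k)) {
  if (length(g$seq) == 0L) return(g)
  meancov <- g$cov / pmax(g$nk, 1L)
  g <- delete_nodes(g, which(meancov < params$min_node_coverage))
  merge_linear(g)
}

#' Extract ChIPtigs from the simplified graph
#'
#' Reports one sequence per node pair (the lexicographically smaller of
#' the node sequence and its reverse complement), keeping nodes of
#' length at least `min_output_length`. Ids `dbg_<n>` are assigned in
#' decreasing mean-coverage order.
#'
#' @inheritParams remove_tips
#' @return data.frame with `id`, `sequence`, `length`, `mean_coverage`,
#'   `assembler`.
#' @export
extract_chiptigs <- function(g, params = assembly_params(k = g$k)) {
  if (length(g$seq) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      length = integer(0), mean_coverage = numeric(0),
                      assembler = character(0), stringsAsFactors = FALSE))
  }
  len <- nchar(g$seq)
  keep <- which(len >= params$min_output_length)
  seqs <- g$seq[keep]
  rc <- revcomp(seqs)
  canon <- ifelse(seqs <= rc, seqs, rc)
  mc <- g$cov[keep] / (len[keep] - g$k + 1L)
  ord <- order(-mc, canon)
  data.frame(id = paste0("dbg_", seq_along(ord)),
             sequence = canon[ord], length = len[keep][ord],
             mean_coverage = mc[ord], assembler = "dbg",
             stringsAsFactors = FALSE)
}

#' Run the full de Bruijn assembler
#'
#' Convenience wrapper: build, clip tips, collapse bubbles, prune low
#' coverage, extract ChIPtigs.
#'
#' @inheritParams build_graph
#' @return ChIPtig data.frame as from [extract_chiptigs()].
#' @export
assemble_dbg <- function(reads, params = assembly_params()) {
  g <- build_graph(reads, params)
  g <- remove_tips(g, params)
  g <- collapse_bubbles(g, params)
  g <- remove_low_coverage(g, params)
  extract_chiptigs(g, params)
}

#' Validate graph invariants
#'
#' Checks that every edge has its mirror twin and that edge overlaps are
#' consistent (the last k-1 bases of the oriented source equal the first
#' k-1 bases of the oriented target). Used by the test suite after every
#' simplification stage.
#'
#' @param g a `chip_dbg` graph.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_graph <- function(g) {
  e <- g$edges
  if (nrow(e) == 0L) return(invisible(TRUE))
  key <- paste(e$from, e$fo, e$to, e$to_or)
  mirror <- paste(e$to, flip_or(e$to_or), e$from, flip_or(e$fo))
  if (!all(mirror %in% key)) stop("twin symmetry violated")
  k <- g$k
  a <- oriented_seqs(g, e$from, e$fo)
  b <- oriented_seqs(g, e$to, e$to_or)
  bad <- substring(a, nchar(a) - k + 2L) != substring(b, 1L, k - 1L)
  if (any(bad)) stop("edge overlap violated at edge ", which(bad)[1])
  invisible(TRUE)
}
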