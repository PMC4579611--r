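# Readers and writers for the formats the pipeline touches:
# FASTQ/FASTA reads, FASTA ChIPtigs, MEME minimal motif files and the
# tab-separated ranking report.

#' Parse sequencing reads from FASTA or FASTQ
#'
#' Auto-detects FASTA vs FASTQ from the first character (`>` vs `@`) and
#' gzip compression from the magic bytes (not the file extension). The
#' file is parsed in bounded-size chunks so working memory does not grow
#' with file size when a `callback` is used; without a callback all
#' records are accumulated and returned.
#'
#' Lowercase bases are uppercased; characters outside `{A,C,G,T,N}` are
#' rejected with an error naming the record index, as are FASTQ records
#' whose quality string length differs from the sequence length. Reads
#' with more than `max_n_frac` ambiguous bases are dropped (count
#' reported via a message). FASTQ qualities are parsed (Sanger phred+33)
#' but are not used by any downstream stage.
#'
#' @param path path to a FASTA or FASTQ file, plain or gzip-compressed.
#' @param source label attached to every read, `"case"` or `"control"`.
#' @param callback optional function called with each chunk (a data.frame
#'   as below); when supplied, records are not accumulated and the return
#'   value is the total record count.
#' @param max_n_frac maximum tolerated fraction of N bases per read.
#' @param chunk_records number of records parsed per chunk.
#' @return data.frame with columns `id`, `sequence`, `quality`
#'   (phred+33 string or `NA`), `source`; or the record count in
#'   callback mode.
#' @export
parse_reads <- function(path, source = c("case", "control"), callback = NULL,
                        max_n_frac = 0.1, chunk_records = 10000L) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 2L)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- if (gz) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))

  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("empty input: ", path)
  fmt <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">")) "fasta"
         else stop("unknown read format (expected '>' or '@'): ", path)

  acc <- list()
  ids_seen <- new.env(parent = emptyenv())
  n_total <- 0L
  n_dropped <- 0L

  finish_chunk <- function(df) {
    if (nrow(df) == 0L) return(invisible(NULL))
    dup <- df$id[duplicated(df$id) | df$id %in% ls(ids_seen)]
    if (length(dup) > 0L) stop("duplicate read id in ", path, ": ", dup[1])
    for (i in df$id) assign(i, TRUE, envir = ids_seen)
    nlen <- nchar(df$sequence)
    nfrac <- (nlen - nchar(gsub("N", "", df$sequence, fixed = TRUE))) / pmax(nlen, 1L)
    drop <- nfrac > max_n_frac
    n_dropped <<- n_dropped + sum(drop)
    df <- df[!drop, , drop = FALSE]
    n_total <<- n_total + nrow(df)
    if (is.null(callback)) acc[[length(acc) + 1L]] <<- df else callback(df)
    invisible(NULL)
  }

  make_df <- function(id, sequence, quality, rec0) {
    sequence <- toupper(sequence)
    bad <- !grepl("^[ACGTN]+$", sequence)
    if (any(bad)) {
      stop("invalid characters in sequence at record ", rec0 + which(bad)[1])
    }
    data.frame(id = id, sequence = sequence, quality = quality,
               source = source, stringsAsFactors = FALSE)
  }

  if (fmt == "fastq") {
    pending <- first
    rec <- 0L
    repeat {
      lines <- c(pending, readLines(con, n = chunk_records * 4L - length(pending)))
      pending <- character(0)
      if (length(lines) == 0L) break
      nfull <- (length(lines) %/% 4L) * 4L
      if (nfull < length(lines)) {
        extra <- lines[(nfull + 1L):length(lines)]
        more <- readLines(con, n = 4L - length(extra))
        lines <- c(lines[seq_len(nfull)], extra, more)
        if ((length(extra) + length(more)) %% 4L != 0L) {
          stop("truncated FASTQ record at record ", rec + length(lines) %/% 4L + 1L)
        }
        nfull <- length(lines)
      }
      if (nfull == 0L) break
      m <- matrix(lines[seq_len(nfull)], nrow = 4L)
      hdr <- m[1L, ]; seqs <- m[2L, ]; plus <- m[3L, ]; qual <- m[4L, ]
      nrec <- ncol(m)
      if (!all(startsWith(hdr, "@"))) {
        stop("malformed FASTQ header at record ", rec + which(!startsWith(hdr, "@"))[1])
      }
      if (!all(startsWith(plus, "+"))) {
        stop("malformed FASTQ separator at record ", rec + which(!startsWith(plus, "+"))[1])
      }
      bad_len <- nchar(seqs) != nchar(qual) | nchar(seqs) == 0L
      if (any(bad_len)) {
        stop("sequence/quality length mismatch at record ", rec + which(bad_len)[1])
      }
      id <- sub("^@", "", hdr)
      id <- sub("\\s.*$", "", id)
      finish_chunk(make_df(id, seqs, qual, rec))
      rec <- rec + nrec
      if (nfull < chunk_records * 4L) {
        nxt <- readLines(con, n = 1L)
        if (length(nxt) == 0L) break
        pending <- nxt
      }
    }
  } else {
    # FASTA: stream, flushing complete records per chunk
    cur_id <- sub("\\s.*$", "", sub("^>", "", first))
    cur_seq <- character(0)
    ids <- character(0); seqs <- character(0)
    rec <- 0L
    flush_rec <- function() {
      if (length(cur_seq) == 0L || nchar(paste0(cur_seq, collapse = "")) == 0L) {
        stop("empty sequence at record ", rec + length(ids) + 1L)
      }
      ids <<- c(ids, cur_id)
      seqs <<- c(seqs, paste0(cur_seq, collapse = ""))
    }
    repeat {
      lines <- readLines(con, n = chunk_records)
      if (length(lines) == 0L) break
      for (ln in lines) {
        if (startsWith(ln, ">")) {
          flush_rec()
          cur_id <- sub("\\s.*$", "", sub("^>", "", ln))
          cur_seq <- character(0)
        } else {
          cur_seq <- c(cur_seq, ln)
        }
      }
      if (length(ids) >= chunk_records) {
        finish_chunk(make_df(ids, seqs, NA_character_, rec))
        rec <- rec + length(ids)
        ids <- character(0); seqs <- character(0)
      }
    }
    flush_rec()
    finish_chunk(make_df(ids, seqs, NA_character_, rec))
  }

  if (n_dropped > 0L) {
    message(n_dropped, " read(s) dropped for >", round(100 * max_n_frac),
            "% N content in ", basename(path))
  }
  if (is.null(callback)) {
    out <- do.call(rbind, acc)
    if (is.null(out)) {
      out <- data.frame(id = character(0), sequence = character(0),
                        quality = character(0), source = character(0))
    }
    rownames(out) <- NULL
    out
  } else {
    n_total
  }
}

#' Convert a phred+33 quality string to integer scores
#' @param quality character vector of phred+33 strings.
#' @return list of integer vectors.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (is.na(q)) return(NULL)
    utf8ToInt(q) - 33L
  })
}

#' Write sequences as FASTA
#'
#' Standard FASTA with 80-column wrapping. Round-trip through
#' [parse_reads()] preserves ids and sequences.
#'
#' @param ids character vector of unique, non-empty record ids (or a
#'   data.frame with `id` and `sequence` columns, in which case `seqs`
#'   is ignored).
#' @param seqs character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(ids, seqs = NULL, path) {
  if (is.data.frame(ids)) {
    seqs <- ids$sequence
    ids <- ids$id
  }
  if (anyDuplicated(ids)) stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  if (any(!nzchar(ids))) stop("empty FASTA id")
  if (length(ids) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Output is consumable by MEME-suite tools. Each motif is a list with
#' `name`, `pwm` (L x 4 matrix, columns A,C,G,T, rows sum to 1),
#' `nsites` and `significance` (written as the E= field). Whitespace in
#' names is replaced by underscores.
#'
#' @param motifs list of motif records.
#' @param path output path.
#' @param background length-4 background frequencies (A,C,G,T).
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.6f C %.6f G %.6f T %.6f", background[1],
                     background[2], background[3], background[4]), "")
  for (m in motifs) {
    pwm <- m$pwm
    stopifnot(is.matrix(pwm), ncol(pwm) == 4L, nrow(pwm) >= 1L)
    if (any(pwm < 0)) stop("negative PWM entry in motif ", m$name)
    if (any(abs(rowSums(pwm) - 1) > 1e-9)) {
      stop("PWM rows must sum to 1 in motif ", m$name)
    }
    name <- gsub("\\s+", "_", m$name)
    nsites <- if (is.null(m$nsites)) 20L else m$nsites
    evalue <- if (is.null(m$significance)) 0 else m$significance
    lines <- c(lines,
               paste0("MOTIF ", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %s",
                       nrow(pwm), nsites, format(evalue, digits = 6)),
               apply(pwm, 1L, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                                  r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Parses the subset of the MEME minimal format written by
#' [write_meme_motifs()] and by MEME-suite tools: `MOTIF` blocks with a
#' `letter-probability matrix:` header over the ACGT alphabet.
#'
#' @param path path to a MEME minimal file.
#' @return list of motifs, each with `name`, `pwm` (L x 4), `nsites`,
#'   `significance`.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\s+", lines)
  if (length(idx) == 0L) return(list())
  out <- vector("list", length(idx))
  bounds <- c(idx, length(lines) + 1L)
  for (i in seq_along(idx)) {
    block <- lines[idx[i]:(bounds[i + 1L] - 1L)]
    name <- strsplit(trimws(block[1L]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix:", block)
    if (length(hdr) == 0L) stop("motif ", name, " has no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr[1]]))
    nsites <- if (grepl("nsites=", block[hdr[1]])) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", block[hdr[1]]))
    } else NA_integer_
    evalue <- if (grepl("E=", block[hdr[1]])) {
      as.numeric(sub(".*E=\\s*(\\S+).*", "\\1", block[hdr[1]]))
    } else NA_real_
    rows <- block[(hdr[1] + 1L):(hdr[1] + w)]
    pwm <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    if (ncol(pwm) != 4L) stop("motif ", name, ": expected 4 columns")
    colnames(pwm) <- BASES
    out[[i]] <- list(name = name, pwm = pwm, nsites = nsites,
                     significance = evalue)
  }
  out
}

#' Write the ChIPtig enrichment ranking as TSV
#'
#' Records must already be ranked; rows are written in ascending rank
#' order regardless of input order. P-values use scientific notation
#' with six significant digits. With `qvalues = TRUE` (default) an
#' informational Benjamini-Hochberg `q_value` column is appended after
#' `rank`.
#'
#' @param records data.frame with columns `chiptig_id`, `length`, `x1`,
#'   `x0`, `p`, `rank` (and optionally `q`).
#' @param path output path.
#' @param qvalues append the BH q-value column.
#' @export
write_ranking_tsv <- function(records, path, qvalues = TRUE) {
  header <- c("chiptig_id", "length", "x1", "x0", "p_value", "rank")
  if (qvalues) header <- c(header, "q_value")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(records) > 0L) {
    records <- records[order(records$rank), , drop = FALSE]
    q <- if ("q" %in% names(records)) records$q else p.adjust(records$p, "BH")
    rows <- paste(records$chiptig_id, records$length, records$x1, records$x0,
                  formatC(records$p, format = "e", digits = 5L),
                  records$rank, sep = "\t")
    if (qvalues) rows <- paste(rows, formatC(q, format = "e", digits = 5L), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}
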