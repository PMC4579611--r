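# Shared sequence / RNG helpers. Not exported except where noted.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. Accepts A, C, G, T, N (N maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  cpp_revcomp(as.character(x))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a master seed and a stage label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 977) %% 2147483629L)
}

# Validate a DNA alphabet, rejecting anything outside ACGTN.
check_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  ok <- grepl(pat, x)
  if (!all(ok)) {
    stop("sequence contains characters outside {A,C,G,T", if (allow_n) ",N",
         "} at record ", which(!ok)[1], call. = FALSE)
  }
  invisible(TRUE)
}

# Normalise a read container (data.frame with id/sequence, or character
# vector) into a character vector of sequences.
read_sequences <- function(reads) {
  if (is.data.frame(reads)) {
    if (!"sequence" %in% names(reads)) stop("reads data.frame needs a 'sequence' column")
    as.character(reads$sequence)
  } else {
    as.character(reads)
  }
}
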