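# End-to-end orchestration: assemble (chosen assembler) -> map & rank ->
# discover motifs -> optionally match against a motif database.

#' Pipeline configuration
#'
#' @param case_path,control_path FASTA/FASTQ read files (must differ).
#' @param assembler `"dbg"` or `"profile"`.
#' @param assembly an [assembly_params()] (dbg) or a list of
#'   [assemble_profile()] arguments (profile).
#' @param mapping a [mapping_params()].
#' @param top_m ChIPtigs passed to motif discovery.
#' @param min_len,max_len ChIPtig length filter.
#' @param motif list of [discover_motifs()] arguments.
#' @param motif_db optional MEME minimal motif file for matching.
#' @param outdir output directory.
#' @param seed master seed; per-stage streams are derived from it by
#'   stage name.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(case_path, control_path, assembler = c("dbg", "profile"),
                            assembly = NULL, mapping = mapping_params(),
                            top_m = 1000L, min_len = 50L, max_len = 500L,
                            motif = list(), motif_db = NULL,
                            outdir = tempfile("dechip_run_"), seed = 1L) {
  assembler <- match.arg(assembler)
  if (identical(normalizePath(case_path, mustWork = FALSE),
                normalizePath(control_path, mustWork = FALSE))) {
    stop("case and control paths must be distinct")
  }
  cfg <- list(case_path = case_path, control_path = control_path,
              assembler = assembler, assembly = assembly, mapping = mapping,
              top_m = as.integer(top_m), min_len = as.integer(min_len),
              max_len = as.integer(max_len), motif = motif,
              motif_db = motif_db, outdir = outdir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the de novo ChIP-seq pipeline
#'
#' Parses case reads, assembles ChIPtigs (case reads only), filters by
#' length, maps case and control reads, computes binomial enrichment
#' P-values with the global library ratio, ranks and writes the ranking
#' TSV, writes the top-M ChIPtigs as FASTA, discovers motifs and writes
#' them as a MEME minimal file, and (if a motif database is configured)
#' matches the top motif against it. Every stage output is written to
#' `config$outdir`; a JSON manifest records configuration, seed, input
#' checksums, per-stage counts and wall time. A stage failure aborts
#' with the stage name; outputs of earlier stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly a list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dechip")),
    seed = config$seed,
    assembler = config$assembler,
    inputs = list(case = config$case_path, control = config$control_path),
    checksums = list(case = tools::md5sum(config$case_path)[[1]],
                     control = tryCatch(tools::md5sum(config$control_path)[[1]],
                                        error = function(e) NA_character_)),
    counts = list())

  case <- run_stage("parse_case", parse_reads(config$case_path, "case"))
  manifest$counts$case_reads <- nrow(case)

  chiptigs <- run_stage("assemble", {
    if (config$assembler == "dbg") {
      params <- config$assembly %||% assembly_params()
      assemble_dbg(case, params)
    } else {
      do.call(assemble_profile, c(list(reads = case), config$assembly))
    }
  })
  manifest$counts$chiptigs_assembled <- nrow(chiptigs)
  cov_label <- if (config$assembler == "dbg") "cov" else "depth"
  hdr_ids <- sprintf("%s len=%d %s=%.2f", chiptigs$id, chiptigs$length,
                     cov_label, chiptigs$mean_coverage)
  write_fasta(hdr_ids, chiptigs$sequence, file.path(outdir, "chiptigs.fasta"))

  control <- run_stage("parse_control", parse_reads(config$control_path, "control"))
  manifest$counts$control_reads <- nrow(control)

  enr <- run_stage("rank", enrich_chiptigs(chiptigs, case, control,
                                           config$mapping, config$top_m,
                                           config$min_len, config$max_len))
  manifest$counts$chiptigs_filtered <- nrow(enr$records)
  manifest$counts$case_mapped <- enr$n_mapped_case
  manifest$counts$control_mapped <- enr$n_mapped_control
  manifest$library_ratio <- enr$r
  write_ranking_tsv(enr$records, file.path(outdir, "ranking.tsv"))

  top_seqs <- enr$chiptigs[match(enr$top$chiptig_id, enr$chiptigs$id), ]
  write_fasta(top_seqs$id, top_seqs$sequence, file.path(outdir, "top_chiptigs.fasta"))

  motifs <- run_stage("motifs", {
    args <- c(list(sequences = top_seqs$sequence,
                   seed = derive_seed(config$seed, "motifs")), config$motif)
    do.call(discover_motifs, args)
  })
  manifest$counts$motifs_found <- length(motifs)
  write_meme_motifs(motifs, file.path(outdir, "motifs.meme"))

  if (!is.null(config$motif_db) && length(motifs) > 0L) {
    matches <- run_stage("match_db", compare_to_database(
      motifs[[1]]$pwm, config$motif_db,
      seed = derive_seed(config$seed, "match_db")))
    write.table(matches, file.path(outdir, "matches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$counts$db_matches <- nrow(matches)
  }

  manifest$wall_time_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
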