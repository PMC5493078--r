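# End-to-end orchestration: extract -> count -> normalize -> test ->
# match -> report, with a machine-readable manifest and a log. The
# package's interface is its functions; this wrapper makes a whole run
# reproducible from one configuration object.

.write_fastq <- function(reads, path) {
  # reads: data.frame with read_id and sequence
  q <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", q),
             path)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file may contain top-level entries `thresholds` (keys of
#' [sage_thresholds()]), `sim` (keys of [sim_config()]), `seed`,
#' `out_dir`, `reads` (named per-library paths), `matrix` and
#' `reference` (paths). The returned list can be passed to
#' [run_pipeline()] via `do.call()`.
#'
#' @param path YAML file.
#' @return Named list of [run_pipeline()] arguments.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$thresholds)) {
    out$thresholds <- do.call(sage_thresholds, cfg$thresholds)
  }
  if (!is.null(cfg$sim)) {
    sim_args <- cfg$sim
    if (!is.null(sim_args$library_totals)) {
      sim_args$library_totals <- unlist(sim_args$library_totals)
    }
    out$sim <- do.call(sim_config, sim_args)
  }
  for (key in c("seed", "out_dir", "matrix", "reference")) {
    if (!is.null(cfg[[key]])) out[[key]] <- cfg[[key]]
  }
  if (!is.null(cfg$reads)) out$reads <- unlist(cfg$reads)
  out
}

#' Run the SuperSAGE pipeline end to end
#'
#' Executes the analysis stages in order and writes every intermediate
#' table, a run manifest (JSON: package version, seed, thresholds,
#' input checksums, per-stage counters) and a log to `out_dir`.
#' Identical configuration and inputs give byte-identical outputs.
#'
#' Two input modes are supported. With `sim`, a synthetic experiment
#' is generated first: the reference FASTA, truth table and ditag
#' reads are written, tags are extracted from the reads (and checked
#' against the generating tags), and the analysis proceeds on the
#' multinomial count table at the configured library depths. Without
#' `sim`, supply either `reads` (named per-library FASTA/FASTQ paths,
#' names NAS/NAT/AS/AT; extraction and counting build the matrix) or
#' `matrix` (a count-matrix TSV in the [write_count_matrix()]
#' dialect), plus optionally `reference` (FASTA) for tag
#' identification.
#'
#' @param out_dir Output directory (created if missing).
#' @param sim Optional [sim_config()].
#' @param reads Optional named character vector of four read files.
#' @param matrix Optional count-matrix TSV path.
#' @param reference Optional reference FASTA path.
#' @param thresholds A [sage_thresholds()] object.
#' @param seed Integer seed for any stochastic stage (defaults to the
#'   simulation seed when `sim` is given).
#' @param n_reads Number of simulated ditag reads (sim mode).
#' @return Invisibly, a list with the calls, matches, summary,
#'   partition and the manifest path.
#' @export
run_pipeline <- function(out_dir, sim = NULL, reads = NULL, matrix = NULL,
                         reference = NULL,
                         thresholds = sage_thresholds(),
                         seed = NULL, n_reads = 5000L) {
  if (is.null(sim) && is.null(reads) && is.null(matrix)) {
    stop("supply one of sim, reads or matrix", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", "supersage", sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stages <- character(0)
  counters <- list()
  checksums <- list()

  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    if (is.null(seed)) seed <- sim$seed
    experiment <- simulate_experiment(sim)
    ref_path <- file.path(out_dir, "reference.fasta")
    write_reference(experiment$refs$sequences, ref_path)
    write_truth(experiment$truth, file.path(out_dir, "truth.tsv"))
    ditags <- generate_ditag_reads(experiment$truth, sim, n_reads = n_reads)
    reads_path <- file.path(out_dir, "reads.fastq")
    .write_fastq(ditags, reads_path)
    say("simulate: %d refs, %d truth tags, %d ditag reads",
        sim$n_refs, nrow(experiment$truth), nrow(ditags))
    stages <- c(stages, "simulate")
    counters$n_truth_tags <- nrow(experiment$truth)

    extracted <- extract_tags_flat(read_reads(reads_path))
    counters$n_reads <- nrow(ditags)
    counters$n_tags_extracted <- length(extracted)
    say("extract: %d tags from %d reads", length(extracted), nrow(ditags))
    stages <- c(stages, "extract")

    ut <- experiment$counts
    reference <- ref_path
    checksums$reads <- unname(md5sum(reads_path))
  } else if (!is.null(reads)) {
    if (!all(LIB_IDS %in% names(reads))) {
      stop("reads must be named NAS, NAT, AS, AT", call. = FALSE)
    }
    missing_files <- reads[!file.exists(reads)]
    if (length(missing_files)) {
      stop("missing read file(s): ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
    tag_lists <- lapply(reads[LIB_IDS], function(p) {
      extract_tags_flat(read_reads(p))
    })
    checksums$reads <- unname(md5sum(unname(reads[LIB_IDS])))
    counters$n_tags_extracted <- sum(lengths(tag_lists))
    say("extract: %d tags over 4 libraries", counters$n_tags_extracted)
    stages <- c(stages, "extract")
    ut <- count_unitags(tag_lists)
  } else {
    if (!file.exists(matrix)) {
      stop("missing count matrix: ", matrix, call. = FALSE)
    }
    checksums$matrix <- unname(md5sum(matrix))
    ut <- read_count_matrix(matrix)
  }
  if (is.null(seed)) seed <- 1L

  write_count_matrix(ut, file.path(out_dir, "matrix.tsv"))
  counters$n_unitags <- nrow(ut)
  say("count: %d unitags", nrow(ut))
  stages <- c(stages, "count")

  tpm <- as.data.frame(tpm_matrix(ut))
  tpm <- cbind(tag = ut$tag, round_half_up(tpm, 2L))
  write.table(tpm, file.path(out_dir, "tpm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages <- c(stages, "normalize")

  pre <- prefilter_tags(ut, thresholds)
  counters$n_prefiltered <- nrow(pre)
  calls <- call_differential_tags(ut, thresholds)
  counters$n_calls <- nrow(calls)
  counters$n_called_tags <- length(unique(calls$tag))
  say("test: %d tags pass prefilter, %d calls on %d tags",
      nrow(pre), nrow(calls), counters$n_called_tags)
  stages <- c(stages, "test")

  matches <- NULL
  if (!is.null(reference)) {
    if (!file.exists(reference)) {
      stop("missing reference: ", reference, call. = FALSE)
    }
    checksums$reference <- unname(md5sum(reference))
    matches <- match_tags(unique(calls$tag), reference)
    strand <- classify_strand(matches, unique(calls$tag))
    calls$strand <- unname(strand[calls$tag])
    write.table(matches, file.path(out_dir, "matches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counters$n_matched_tags <- length(unique(matches$tag))
    say("match: %d of %d called tags identified",
        counters$n_matched_tags, counters$n_called_tags)
    stages <- c(stages, "match")
  }
  write_calls(calls, file.path(out_dir, "calls.tsv"))

  venn <- venn_partition(ut)
  write.table(data.frame(class = names(venn), n_unitags = venn),
              file.path(out_dir, "venn.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- summarize_calls(calls, matches)
  write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_report(ut, calls, matches, file.path(out_dir, "report.txt"),
               thresholds)
  stages <- c(stages, "report")
  say("report: written to %s", out_dir)

  manifest <- list(
    package = "supersage",
    version = as.character(utils::packageVersion("supersage")),
    r_version = as.character(getRversion()),
    seed = seed,
    thresholds = unclass(thresholds),
    library_totals = as.list(attr(ut, "totals")),
    input_checksums = checksums,
    counters = counters,
    stages_completed = stages
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(unitags = ut, calls = calls, matches = matches,
                 summary = summ, venn = venn,
                 manifest = manifest_path))
}
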