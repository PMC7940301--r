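#' Run the full direct-target screen end to end
#'
#' Wires the stages together: parse the ratio table, normalize, derive or
#' accept the downregulation cut-off, scan UTRs for seed sites, classify and
#' rank candidates, and write results. Outputs are `candidates.tsv`,
#' `sites.tsv`, `screen_report.json` and `manifest.json` in `out_dir`;
#' re-running with identical inputs reproduces identical candidate TSVs.
#'
#' @param ratios Path to a ratio TSV, or a parsed records data.frame.
#' @param utrs Path to a 3'UTR FASTA, or a named character vector of
#'   sequences.
#' @param mirna Mature miRNA sequence (string) or a `mirna_seed` object.
#' @param out_dir Output directory (created if needed).
#' @param cutoff Downregulation cut-off; ignored when `control_gene` is given.
#' @param control_gene Optional positive-control gene identifier; the cut-off
#'   is then derived from its normalized ratio via [derive_cutoff()].
#' @param min_match Minimum seed-match length (6 or 7).
#' @param normalization Ratio normalization method (see [normalize_ratios()]).
#' @param column_map Column map for [parse_ratio_table()].
#' @param mirna_name Name used for the miRNA when `mirna` is a bare string.
#' @return Invisibly, a list with `candidates`, `sites`, `report`, `config`
#'   and `manifest`.
#' @export
run_full_screen <- function(ratios, utrs, mirna, out_dir,
                            cutoff = 0.8, control_gene = NULL,
                            min_match = 6L,
                            normalization = "median_log",
                            column_map = default_column_map(),
                            mirna_name = "miRNA") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_paths <- c(
    ratios = if (is.character(ratios) && length(ratios) == 1L) ratios,
    utrs = if (is.character(utrs) && length(utrs) == 1L && is.null(names(utrs)))
      utrs)

  records <- if (is.data.frame(ratios)) ratios else
    with_stage("parse", parse_ratio_table(ratios, column_map))
  utr_seqs <- if (is.character(utrs) && !is.null(names(utrs))) utrs else
    with_stage("read_utrs", read_utr_fasta(utrs))
  seed <- if (inherits(mirna, "mirna_seed")) mirna else
    with_stage("extract_seed", extract_seed(mirna, mirna_name))

  records <- with_stage("normalize", normalize_ratios(records, normalization))
  if (!is.null(control_gene)) {
    ctl <- records$ratio_hm_norm[records$gene_id == control_gene]
    if (length(ctl) != 1L || is.na(ctl))
      stop("[derive_cutoff] control gene '", control_gene,
           "' not quantified exactly once")
    cutoff <- with_stage("derive_cutoff", derive_cutoff(ctl))
  }
  config <- screen_config(cutoff = as.numeric(cutoff), min_match = min_match,
                          control_gene = control_gene,
                          normalization = normalization)

  sites <- with_stage("scan", scan_utrs(utr_seqs, seed, min_match = min_match))
  candidates <- with_stage("screen",
    screen_targets(records, sites, config, utr_genes = names(utr_seqs)))
  report <- screen_report(candidates, config)

  write_sites(sites, file.path(out_dir, "sites.tsv"))
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_screen_report(report, file.path(out_dir, "screen_report.json"))

  manifest <- run_manifest(
    subcommand = "screen",
    config = list(cutoff = unname(as.numeric(cutoff)),
                  cutoff_provenance = config$cutoff_provenance,
                  control_gene = control_gene,
                  min_match = as.integer(min_match),
                  normalization = normalization,
                  mirna = seed$mature_seq, mirna_name = seed$name),
    input_paths = input_paths)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))

  message(sprintf(
    "[screen] %d records in: %d quantified, %d downregulated (%d direct, %d indirect)",
    nrow(records), report$n_quantified, report$n_downregulated,
    report$n_direct, report$n_indirect))
  invisible(list(candidates = candidates, sites = sites, report = report,
                 config = config, manifest = manifest))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Build a run manifest
#'
#' Reproducibility metadata written next to every pipeline output: the
#' subcommand, the effective configuration snapshot, MD5 digests of file
#' inputs, RNG seed where applicable, package version and timestamp.
#'
#' @param subcommand Name of the pipeline stage or CLI subcommand.
#' @param config Named list: the effective configuration.
#' @param input_paths Named character vector of input file paths (digested
#'   with MD5).
#' @param rng_seed Optional integer seed.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(subcommand, config = list(),
                         input_paths = character(0), rng_seed = NULL) {
  digests <- if (length(input_paths))
    as.list(tools::md5sum(unlist(input_paths))) else list()
  if (length(digests)) names(digests) <- names(input_paths)
  structure(list(
    subcommand = subcommand,
    config = config,
    input_digests = digests,
    rng_seed = rng_seed,
    tool = "seedscreen",
    version = as.character(utils::packageVersion("seedscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
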