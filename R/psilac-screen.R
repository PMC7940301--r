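#' Default column map for MaxQuant-style proteinGroups tables
#'
#' @return Named list mapping record fields to table headers.
#' @export
default_column_map <- function() {
  list(protein_id = "Protein IDs",
       gene_id    = "Gene names",
       ratio      = "Ratio H/M normalized",
       intensity  = "Intensity",
       n_peptides = "Peptides")
}

#' Parse a heavy/medium protein ratio table
#'
#' Reads a tab-separated quantification table (MaxQuant proteinGroups-like).
#' Rows whose protein identifier starts with `REV__` (decoy) or `CON__`
#' (contaminant) are dropped and counted; unparseable ratio fields become
#' missing (NA); duplicate gene identifiers keep the entry with the highest
#' intensity, mirroring protein-group collapsing.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Named list naming the `protein_id`, `gene_id`, `ratio`,
#'   `intensity` and (optionally) `n_peptides` columns; see
#'   [default_column_map()].
#' @return data.frame with columns `protein_id`, `gene_id`, `ratio_hm_raw`,
#'   `intensity`, `n_peptides`, plus a `parse_report` attribute (list of
#'   dropped-row counts).
#' @export
parse_ratio_table <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("ratio table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""),
                           comment.char = "#")
  if (nrow(tab) == 0L) stop("empty ratio table: ", path)
  required <- c("protein_id", "gene_id", "ratio", "intensity")
  for (f in required) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(tab))
      stop(sprintf("mapped column '%s' (%s) not found in %s",
                   col %||% f, f, path))
  }
  pep_col <- column_map[["n_peptides"]]
  rec <- data.frame(
    protein_id = as.character(tab[[column_map$protein_id]]),
    gene_id    = as.character(tab[[column_map$gene_id]]),
    ratio_hm_raw = suppressWarnings(as.numeric(tab[[column_map$ratio]])),
    intensity  = suppressWarnings(as.numeric(tab[[column_map$intensity]])),
    n_peptides = if (!is.null(pep_col) && pep_col %in% names(tab))
      suppressWarnings(as.integer(tab[[pep_col]])) else NA_integer_,
    stringsAsFactors = FALSE
  )
  report <- list(n_rows = nrow(rec))
  is_rev <- startsWith(rec$protein_id, "REV__")
  is_con <- startsWith(rec$protein_id, "CON__")
  report$dropped_reverse <- sum(is_rev)
  report$dropped_contaminant <- sum(is_con)
  rec <- rec[!is_rev & !is_con, , drop = FALSE]
  no_gene <- is.na(rec$gene_id) | !nzchar(rec$gene_id)
  report$dropped_no_gene <- sum(no_gene)
  rec <- rec[!no_gene, , drop = FALSE]
  ## non-positive ratios are not quantifiable -> missing
  bad_ratio <- !is.na(rec$ratio_hm_raw) & rec$ratio_hm_raw <= 0
  rec$ratio_hm_raw[bad_ratio] <- NA_real_
  ## collapse duplicate genes: keep highest intensity
  ord <- order(rec$gene_id, -ifelse(is.na(rec$intensity), -Inf, rec$intensity))
  rec <- rec[ord, , drop = FALSE]
  dup <- duplicated(rec$gene_id)
  report$dropped_duplicate_gene <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  report$n_records <- nrow(rec)
  attr(rec, "parse_report") <- report
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize heavy/medium ratios
#'
#' `median_log` divides every raw ratio by the geometric-median factor
#' (exp of the median log ratio), so the median log normalized ratio is 0 —
#' the standard assumption that most proteins are unaffected by the
#' perturbation. `none` copies raw ratios through, for tables that are
#' already normalized upstream. Missing ratios stay missing and are excluded
#' from the normalization statistic.
#'
#' @param records data.frame with a `ratio_hm_raw` column (see
#'   [parse_ratio_table()]).
#' @param method `"median_log"` or `"none"`.
#' @return `records` with a `ratio_hm_norm` column added.
#' @examples
#' df <- data.frame(gene_id = c("a", "b", "c"), ratio_hm_raw = c(1, 2, 4))
#' normalize_ratios(df)$ratio_hm_norm   # 0.5 1.0 2.0
#' @export
normalize_ratios <- function(records, method = c("median_log", "none")) {
  method <- match.arg(method)
  raw <- records$ratio_hm_raw
  usable <- !is.na(raw) & raw > 0
  if (!any(usable)) stop("no usable ratios to normalize")
  if (method == "median_log") {
    factor <- exp(stats::median(log(raw[usable])))
    records$ratio_hm_norm <- raw / factor
  } else {
    records$ratio_hm_norm <- raw
  }
  attr(records, "normalization") <- method
  records
}

#' Derive the downregulation cut-off from a positive-control ratio
#'
#' A validated target of the miRNA serves as internal positive control; the
#' cut-off is the one-decimal ceiling of its normalized H/M ratio (smallest
#' multiple of 0.1 at or above it), capped at 1.0. A control ratio of 0.773
#' yields the canonical 0.8.
#'
#' @param control_ratio Normalized H/M ratio of the positive-control protein,
#'   in (0, 1): the control must be downregulated.
#' @return The cut-off (multiple of 0.1), with attribute
#'   `provenance = "derived"`.
#' @examples
#' derive_cutoff(0.773)  # 0.8
#' @export
derive_cutoff <- function(control_ratio) {
  stopifnot(is.numeric(control_ratio), length(control_ratio) == 1L)
  if (!is.finite(control_ratio) || control_ratio <= 0)
    stop("control ratio must be positive, got ", control_ratio)
  if (control_ratio >= 1)
    stop("positive control not downregulated (ratio ", control_ratio, " >= 1)")
  ## round() guards against 0.8 * 10 landing just above 8 in floating point
  cutoff <- min(1.0, ceiling(round(control_ratio * 10, 9)) / 10)
  structure(cutoff, provenance = "derived")
}

#' Screen configuration
#'
#' @param cutoff Downregulation cut-off in (0, 1]; a protein is downregulated
#'   when its normalized ratio is at or below this value. Default 0.8, the
#'   value obtained from an IRS-1-like control at 0.773 via [derive_cutoff()].
#' @param min_match Minimum seed-match length for direct classification (6
#'   or 7).
#' @param control_gene Optional gene identifier of the positive control; when
#'   given, the cut-off is derived from its normalized ratio and `cutoff`
#'   is ignored.
#' @param normalization Ratio normalization method (see [normalize_ratios()]).
#' @return A `screen_config` list.
#' @export
screen_config <- function(cutoff = 0.8, min_match = 6L, control_gene = NULL,
                          normalization = c("median_log", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(cutoff > 0, cutoff <= 1, min_match %in% c(6L, 7L))
  structure(list(cutoff = cutoff, min_match = as.integer(min_match),
                 control_gene = control_gene, normalization = normalization,
                 cutoff_provenance = if (is.null(control_gene)) "supplied"
                                     else "derived"),
            class = "screen_config")
}

#' Classify screened proteins as direct, indirect or unchanged
#'
#' A quantified protein is *downregulated* when its normalized H/M ratio is
#' at or below the cut-off (boundary inclusive). A downregulated protein with
#' a 3'UTR seed match of at least `min_match` nt is classified `direct`; a
#' downregulated protein without one is `indirect`; everything else (including
#' proteins with missing ratios, which are flagged) is `unchanged`.
#'
#' @param records data.frame with `gene_id`, `ratio_hm_norm`, `intensity`
#'   columns (see [normalize_ratios()]).
#' @param sites Seed-site data.frame from [scan_utrs()].
#' @param config A [screen_config()] object.
#' @param utr_genes Character vector of gene identifiers for which a UTR
#'   sequence was available; genes outside it get `max_match_len = 0` and are
#'   flagged `no_utr`. Defaults to assuming all genes had UTRs.
#' @return data.frame of candidates: `gene_id`, `ratio_hm_norm`, `intensity`,
#'   `n_sites_total`, `n_complete_sites`, `max_match_len`, `classification`,
#'   `rank` (direct candidates only; see [rank_candidates()]), `no_utr`,
#'   `missing_ratio`. Class counts are attached as attribute `class_counts`.
#' @export
screen_targets <- function(records, sites, config = screen_config(),
                           utr_genes = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (!"ratio_hm_norm" %in% names(records))
    stop("records must carry normalized ratios; run normalize_ratios() first")
  if (is.null(utr_genes)) utr_genes <- unique(records$gene_id)

  agg <- function(f, default) {
    v <- stats::setNames(rep(default, nrow(records)), records$gene_id)
    if (nrow(sites)) {
      s <- split(sites, sites$gene_id)
      got <- intersect(names(s), records$gene_id)
      v[got] <- vapply(s[got], f, numeric(1))
    }
    unname(v)
  }
  cand <- data.frame(
    gene_id = records$gene_id,
    ratio_hm_norm = records$ratio_hm_norm,
    intensity = records$intensity,
    n_sites_total = as.integer(agg(nrow, 0)),
    n_complete_sites = as.integer(agg(function(d) sum(d$length == 7L), 0)),
    max_match_len = as.integer(agg(function(d) max(d$length), 0)),
    stringsAsFactors = FALSE
  )
  cand$no_utr <- !cand$gene_id %in% utr_genes
  cand$max_match_len[cand$no_utr] <- 0L
  cand$missing_ratio <- is.na(cand$ratio_hm_norm)

  down <- !cand$missing_ratio & cand$ratio_hm_norm <= config$cutoff
  has_site <- cand$max_match_len >= config$min_match
  cand$classification <- rep("unchanged", nrow(cand))
  cand$classification[down & has_site] <- "direct"
  cand$classification[down & !has_site] <- "indirect"

  cand <- rank_candidates(cand)
  attr(cand, "class_counts") <- c(
    n_quantified = sum(!cand$missing_ratio),
    n_downregulated = sum(down),
    n_direct = sum(cand$classification == "direct"),
    n_indirect = sum(cand$classification == "indirect"),
    n_unchanged = sum(cand$classification == "unchanged"),
    n_missing_ratio = sum(cand$missing_ratio),
    n_no_utr = sum(cand$no_utr)
  )
  attr(cand, "config") <- config
  cand
}

#' Rank direct candidates by intensity
#'
#' Direct candidates are ranked by summed MS intensity descending (the most
#' abundantly quantified first), ties broken by normalized ratio ascending
#' (more downregulated first), then by gene identifier; rank 1 is the top
#' candidate. Non-direct rows get NA rank.
#'
#' @param candidates data.frame with `classification`, `intensity`,
#'   `ratio_hm_norm`, `gene_id` columns; or a data.frame of direct rows only.
#' @return `candidates` with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  if (!"classification" %in% names(candidates)) {
    candidates$classification <- rep("direct", nrow(candidates))
  } else if (!all(candidates$classification %in%
                  c("direct", "indirect", "unchanged"))) {
    stop("unknown classification value")
  }
  candidates$rank <- rep(NA_integer_, nrow(candidates))
  idx <- which(candidates$classification == "direct")
  if (length(idx)) {
    d <- candidates[idx, ]
    ord <- order(-d$intensity, d$ratio_hm_norm, d$gene_id)
    candidates$rank[idx[ord]] <- seq_along(idx)
  }
  candidates
}

#' Machine-readable screen summary
#'
#' @param candidates Output of [screen_targets()].
#' @param config The [screen_config()] used (defaults to the one attached to
#'   `candidates`).
#' @return A `screen_report` list of class counts plus cut-off, cut-off
#'   provenance and normalization method; serializable with
#'   [write_screen_report()] and read back bit-exactly with
#'   [read_screen_report()].
#' @export
screen_report <- function(candidates, config = attr(candidates, "config")) {
  counts <- attr(candidates, "class_counts")
  if (is.null(counts)) {
    cls <- candidates$classification
    down <- cls %in% c("direct", "indirect")
    missing <- candidates$missing_ratio %||% rep(FALSE, nrow(candidates))
    counts <- c(n_quantified = sum(!missing),
                n_downregulated = sum(down),
                n_direct = sum(cls == "direct"),
                n_indirect = sum(cls == "indirect"),
                n_unchanged = sum(cls == "unchanged"),
                n_missing_ratio = 0L, n_no_utr = 0L)
  }
  structure(c(as.list(counts),
              list(cutoff = unname(config$cutoff),
                   cutoff_provenance = config$cutoff_provenance,
                   min_match = config$min_match,
                   normalization = config$normalization)),
            class = "screen_report")
}

#' @rdname screen_report
#' @param report A `screen_report`.
#' @param path JSON file path.
#' @export
write_screen_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname screen_report
#' @export
read_screen_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  count_fields <- grep("^n_", names(x))
  x[count_fields] <- lapply(x[count_fields], as.integer)
  x$min_match <- as.integer(x$min_match)
  structure(x, class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, x[[f]]))
  invisible(x)
}
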