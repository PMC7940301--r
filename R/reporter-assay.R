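#' Normalize dual-luciferase measurements to a reference group
#'
#' Firefly activity of each well is divided by the renilla activity of the
#' same extract (controlling for transfection efficiency); the resulting
#' firefly:renilla ratio is then divided by the mean ratio of the reference
#' group (fold over control), so the reference group's mean relative activity
#' is 1 by construction.
#'
#' @param measurements data.frame with columns `well_id`, `firefly`,
#'   `renilla`, and either a `group` column or both `construct` and
#'   `condition` (combined as `"construct+condition"`).
#' @param reference_group Group label of the reference (control) wells; must
#'   be present with at least 2 wells.
#' @return `measurements` with `ratio` (firefly/renilla) and
#'   `relative_activity` columns; the reference group is recorded in the
#'   `reference_group` attribute.
#' @export
normalize_luciferase <- function(measurements, reference_group) {
  m <- measurements
  if (!"group" %in% names(m)) {
    if (!all(c("construct", "condition") %in% names(m)))
      stop("measurements need a 'group' column or 'construct' + 'condition'")
    m$group <- paste(m$construct, m$condition, sep = "+")
  }
  stopifnot(all(c("firefly", "renilla") %in% names(m)))
  if (any(!is.finite(m$renilla) | m$renilla <= 0))
    stop("renilla activity must be positive in every well")
  if (any(!is.finite(m$firefly) | m$firefly < 0))
    stop("firefly activity must be non-negative")
  ref <- m$group == reference_group
  if (!any(ref)) stop("reference group '", reference_group, "' not found")
  if (sum(ref) < 2L)
    stop("reference group needs >= 2 wells, has ", sum(ref))
  m$ratio <- m$firefly / m$renilla
  m$relative_activity <- m$ratio / mean(m$ratio[ref])
  attr(m, "reference_group") <- reference_group
  m
}

#' Two-group comparison of relative luciferase activities
#'
#' Classic unpaired two-sided Student's t test (equal variances; set
#' `welch = TRUE` for the Welch correction) on per-well relative activities,
#' reporting mean +/- SEM per group. Groups with zero pooled variance are
#' handled by an explicit guard rather than an error: the p-value is 1 when
#' the means coincide and 0 otherwise, with `degenerate_variance = TRUE`.
#'
#' @param activities data.frame from [normalize_luciferase()] (needs `group`
#'   and `relative_activity` columns).
#' @param group_a,group_b Group labels to compare; the difference reported is
#'   mean(a) - mean(b).
#' @param welch Use Welch's unequal-variance correction (default FALSE).
#' @return List: per-group `n`, `mean`, `sem`; `difference`, `t`, `df`, `p`,
#'   `degenerate_variance`.
#' @export
compare_groups <- function(activities, group_a, group_b, welch = FALSE) {
  a <- activities$relative_activity[activities$group == group_a]
  b <- activities$relative_activity[activities$group == group_b]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 wells (", group_a, ": ", length(a), ", ",
         group_b, ": ", length(b), ")")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  diff <- mean(a) - mean(b)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var < .Machine$double.eps) {
    degenerate <- TRUE
    tt <- list(statistic = if (diff == 0) 0 else sign(diff) * Inf,
               parameter = length(a) + length(b) - 2L,
               p.value = if (diff == 0) 1 else 0)
  } else {
    degenerate <- FALSE
    tt <- stats::t.test(a, b, var.equal = !welch, paired = FALSE,
                        alternative = "two.sided")
  }
  list(groups = stats::setNames(
         list(list(n = length(a), mean = mean(a), sem = sem(a)),
              list(n = length(b), mean = mean(b), sem = sem(b))),
         c(group_a, group_b)),
       difference = diff,
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = unname(tt$p.value),
       degenerate_variance = degenerate)
}

#' Read a luciferase plate TSV
#'
#' Expected columns: `well_id`, `construct`, `condition`, `firefly`,
#' `renilla` (a pre-combined `group` column is also accepted).
#'
#' @param path TSV file path.
#' @return data.frame of measurements.
#' @export
read_luciferase_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
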