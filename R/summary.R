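#' Tally heterotic patterns
#'
#' Counts pattern calls over the six labels, splits them into additive
#' (`A`) and non-additive (the rest), and computes each label's share of
#' the total and — for non-additive labels — of the non-additive subset.
#' Raw fractions are retained; integer-rounded twins are provided for
#' reporting, matching the usual "about 57%" style of published tallies.
#'
#' @param calls a `heterosis_calls` data frame (uses its `pattern`
#'   column), any data frame with a `pattern` column, or a character
#'   vector of labels among `r paste(pattern_levels(), collapse = " ")`.
#' @return An object of class `pattern_tally`: list with `counts` (named
#'   integer vector over the six labels), `total`, `additive_count`,
#'   `nonadditive_count`, `share_of_total`, `share_of_nonadditive`
#'   (percent, full precision) and their `_rounded` integer twins.
#' @examples
#' tally_patterns(c("A", "A", "+", "-", "++"))
#' @export
tally_patterns <- function(calls) {
  labels <- if (is.data.frame(calls)) {
    if (!"pattern" %in% names(calls))
      stop("data frame input must have a 'pattern' column")
    calls$pattern
  } else {
    as.character(calls)
  }
  labels <- labels[!is.na(labels)]
  bad <- setdiff(unique(labels), .pattern_levels)
  if (length(bad))
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = .pattern_levels))
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  additive <- counts[["A"]]
  nonadd <- total - additive
  share_total <- if (total > 0) 100 * counts / total else
    stats::setNames(rep(NA_real_, length(counts)), names(counts))
  nonadd_labels <- setdiff(.pattern_levels, "A")
  share_nonadd <- if (nonadd > 0) 100 * counts[nonadd_labels] / nonadd else
    stats::setNames(rep(NA_real_, length(nonadd_labels)), nonadd_labels)
  structure(list(counts = counts, total = total,
                 additive_count = additive, nonadditive_count = nonadd,
                 share_of_total = share_total,
                 share_of_nonadditive = share_nonadd,
                 share_of_total_rounded = round(share_total),
                 share_of_nonadditive_rounded = round(share_nonadd)),
            class = "pattern_tally")
}

#' @export
print.pattern_tally <- function(x, ...) {
  cat(sprintf("Pattern tally: %d spot(s); %d additive (%s%%), %d non-additive\n",
              x$total, x$additive_count,
              ifelse(is.na(x$share_of_total_rounded[["A"]]), "NA",
                     x$share_of_total_rounded[["A"]]),
              x$nonadditive_count))
  df <- data.frame(pattern = names(x$counts), count = unname(x$counts),
                   pct_of_total = unname(x$share_of_total_rounded),
                   pct_of_nonadditive =
                     unname(x$share_of_nonadditive_rounded[
                       match(names(x$counts),
                             names(x$share_of_nonadditive_rounded))]),
                   stringsAsFactors = FALSE)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.pattern_tally <- function(x, ...) {
  graphics::barplot(x$counts, xlab = "heterotic pattern",
                    ylab = "protein spots", ...)
  invisible(x)
}

#' Convert a pattern tally to a report table
#'
#' @param tally a `pattern_tally`.
#' @return Data frame with one row per pattern: count, raw and rounded
#'   shares, ready for [write_report()].
#' @export
tally_report <- function(tally) {
  stopifnot(inherits(tally, "pattern_tally"))
  nn <- names(tally$counts)
  data.frame(pattern = nn,
             count = unname(tally$counts),
             share_of_total = unname(tally$share_of_total),
             share_of_total_rounded =
               unname(tally$share_of_total_rounded),
             share_of_nonadditive =
               unname(tally$share_of_nonadditive[
                 match(nn, names(tally$share_of_nonadditive))]),
             share_of_nonadditive_rounded =
               unname(tally$share_of_nonadditive_rounded[
                 match(nn, names(tally$share_of_nonadditive_rounded))]),
             stringsAsFactors = FALSE)
}

#' Correlate a spot's stage profile with a phenotype profile
#'
#' Pearson correlation (with two-sided p-value) between per-stage mean
#' spot intensities and per-stage phenotype means (e.g. seed-setting
#' rates), over the same ordered stages.
#'
#' @param spot_series,phenotype_series equal-length numeric series
#'   (length >= 3), both with non-zero variance.
#' @return An object of class `phenotype_correlation`: list with `r`,
#'   `p_value`, `n`.
#' @export
correlate_with_phenotype <- function(spot_series, phenotype_series) {
  stopifnot(is.numeric(spot_series), is.numeric(phenotype_series))
  if (length(spot_series) != length(phenotype_series))
    stop("series must have equal length")
  if (length(spot_series) < 3L)
    stop("need at least 3 stages to correlate")
  if (anyNA(spot_series) || anyNA(phenotype_series))
    stop("series must not contain NAs")
  if (stats::var(spot_series) == 0 || stats::var(phenotype_series) == 0)
    stop("zero variance in one of the series")
  ct <- stats::cor.test(spot_series, phenotype_series, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(spot_series)),
            class = "phenotype_correlation")
}

#' @export
print.phenotype_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g)\n", x$r, x$n,
              x$p_value))
  invisible(x)
}
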