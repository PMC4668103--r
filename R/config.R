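#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline: the significance level
#' shared by all tests, the fold-change cut-offs for the inbred time-course
#' and parent/hybrid (triad) screens, the relative tolerance below which a
#' stage-to-stage change counts as flat in the replicate same-trend rule,
#' the normalization scale, and the random seed used by the synthetic
#' generators.
#'
#' @param alpha significance level for every test (ANOVA, t), in (0, 1).
#' @param fc_inbred fold-change threshold for the within-line time-course
#'   screen; a spot passes only when its maximum stage-mean fold change is
#'   strictly greater than this value.
#' @param fc_triad fold-change threshold for the parent/hybrid screen
#'   (strict inequality, as for `fc_inbred`).
#' @param trend_epsilon relative tolerance of the same-trend rule: a
#'   stage-to-stage change is "flat" when |delta| <= trend_epsilon times the
#'   mean of the two stage values.
#' @param ppm_scale normalization constant; per-gel intensities are rescaled
#'   so each gel sums to this value (parts per million by default).
#' @param rng_seed integer seed forwarded to the synthetic generators.
#' @param welch logical; use Welch (unequal-variance) t-tests in the
#'   heterotic pattern classification. The pooled-variance test is available
#'   by setting this to `FALSE`.
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$fc_triad
#' @export
analysis_config <- function(alpha = 0.05, fc_inbred = 1.5, fc_triad = 2.0,
                            trend_epsilon = 0.02, ppm_scale = 1e6,
                            rng_seed = 1L, welch = TRUE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  stopifnot(is.numeric(fc_inbred), length(fc_inbred) == 1L, fc_inbred >= 1)
  stopifnot(is.numeric(fc_triad), length(fc_triad) == 1L, fc_triad >= 1)
  stopifnot(is.numeric(trend_epsilon), length(trend_epsilon) == 1L,
            trend_epsilon >= 0)
  stopifnot(is.numeric(ppm_scale), length(ppm_scale) == 1L, ppm_scale > 0)
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L,
            rng_seed == as.integer(rng_seed))
  stopifnot(is.logical(welch), length(welch) == 1L, !is.na(welch))
  structure(list(alpha = alpha, fc_inbred = fc_inbred, fc_triad = fc_triad,
                 trend_epsilon = trend_epsilon, ppm_scale = ppm_scale,
                 rng_seed = as.integer(rng_seed), welch = welch),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  alpha:         %g\n", x$alpha))
  cat(sprintf("  fc_inbred:     %g (strict >)\n", x$fc_inbred))
  cat(sprintf("  fc_triad:      %g (strict >)\n", x$fc_triad))
  cat(sprintf("  trend_epsilon: %g\n", x$trend_epsilon))
  cat(sprintf("  ppm_scale:     %g\n", x$ppm_scale))
  cat(sprintf("  rng_seed:      %d\n", x$rng_seed))
  cat(sprintf("  welch t-tests: %s\n", x$welch))
  invisible(x)
}

#' Read or write an analysis configuration as a flat key = value file
#'
#' The file holds one `key = value` pair per line; keys are the fields of
#' [analysis_config()]. Unknown keys are an error so typos do not silently
#' fall back to defaults. Blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- c("alpha", "fc_inbred", "fc_triad", "trend_epsilon",
             "ppm_scale", "rng_seed", "welch")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    args[[keys[i]]] <- if (keys[i] == "welch") {
      as.logical(vals[i])
    } else {
      as.numeric(vals[i])
    }
  }
  do.call(analysis_config, args)
}

#' @rdname read_analysis_config
#' @param config an `analysis_config` object.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  keys <- names(unclass(config))
  vals <- vapply(unclass(config), function(v) format(v, digits = 17), "")
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

#' Declare a parent/hybrid triad
#'
#' A triad names the unit of the heterosis analysis: an F1 hybrid together
#' with its two parental inbred lines, plus the ordered developmental stages
#' at which the three genotypes are compared.
#'
#' @param f1,parent_a,parent_b genotype identifiers; must be pairwise
#'   distinct.
#' @param stages non-empty character vector of stage labels in developmental
#'   order (stage order is declared, never inferred lexically, because e.g.
#'   "D10" sorts before "D6" as a string).
#' @return An object of class `triad_design`.
#' @examples
#' triad_design("Lx9801xZong3", "Lx9801", "Zong3", c("D8", "D10", "D12"))
#' @export
triad_design <- function(f1, parent_a, parent_b, stages) {
  stopifnot(is.character(f1), length(f1) == 1L,
            is.character(parent_a), length(parent_a) == 1L,
            is.character(parent_b), length(parent_b) == 1L)
  if (anyDuplicated(c(f1, parent_a, parent_b)))
    stop("f1, parent_a and parent_b must be three distinct genotypes")
  stopifnot(is.character(stages), length(stages) >= 1L)
  if (anyDuplicated(stages)) stop("duplicated stage labels")
  structure(list(f1 = f1, parent_a = parent_a, parent_b = parent_b,
                 stages = stages),
            class = "triad_design")
}

#' @export
print.triad_design <- function(x, ...) {
  cat(sprintf("Triad: %s = %s x %s; stages: %s\n",
              x$f1, x$parent_a, x$parent_b,
              paste(x$stages, collapse = " < ")))
  invisible(x)
}
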