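#' Classical one-way fixed-effects ANOVA
#'
#' Thin wrapper around [stats::oneway.test()] with `var.equal = TRUE`,
#' returning the F statistic, its p-value from the F distribution and the
#' between/within degrees of freedom (k - 1 and N - k for k groups and N
#' observations). All replicate values enter individually; groups are
#' never collapsed to their means first.
#'
#' @param groups list of at least two numeric vectors, each of length >= 2,
#'   without missing values.
#' @return An object of class `anova_result`: list with `f_stat`,
#'   `p_value`, `df_between`, `df_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))  # F = 21
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  for (g in groups) {
    if (!is.numeric(g) || length(g) < 2L || anyNA(g))
      stop("each group must be a numeric vector of length >= 2 without NAs")
  }
  vars <- vapply(groups, stats::var, 0)
  if (all(vars == 0))
    stop("degenerate within-group variance: all groups are constant")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(f_stat = unname(fit$statistic),
                 p_value = unname(fit$p.value),
                 df_between = as.integer(unname(fit$parameter["num df"])),
                 df_within = as.integer(unname(fit$parameter["denom df"]))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Maximum fold change among group means
#'
#' The ratio of the largest to the smallest group mean; always >= 1,
#' invariant under permutation of the groups and under global rescaling.
#' Fold change is computed on group means (stage means or genotype means
#' of normalized intensities), not per replicate.
#'
#' @param group_means numeric vector of at least two strictly positive
#'   group means.
#' @return `max(group_means) / min(group_means)`.
#' @export
max_fold_change <- function(group_means) {
  stopifnot(is.numeric(group_means), length(group_means) >= 2L)
  if (anyNA(group_means) || any(group_means <= 0))
    stop("all group means must be positive")
  max(group_means) / min(group_means)
}

#' Replicate same-trend rule
#'
#' A spot in a time-course is retained only when the direction of its
#' intensity change between every pair of consecutive stages is identical
#' in all biological replicates. A change is up, down or flat; flat means
#' |delta| <= epsilon times the mean of the two stage values, so tiny
#' numeric wobble does not flip the sign.
#'
#' @param replicate_profiles matrix with one row per replicate and one
#'   ordered column per stage (a list of equal-length numeric vectors is
#'   also accepted).
#' @param epsilon non-negative relative flatness tolerance, default 0.02.
#' @return `TRUE` iff all replicates share the same up/down/flat sign for
#'   every consecutive stage pair.
#' @examples
#' same_trend(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1.5, 2, 2.5, 3)))
#' @export
same_trend <- function(replicate_profiles, epsilon = 0.02) {
  if (is.list(replicate_profiles) && !is.data.frame(replicate_profiles))
    replicate_profiles <- do.call(rbind, replicate_profiles)
  p <- as.matrix(replicate_profiles)
  stopifnot(is.numeric(p), nrow(p) >= 1L)
  if (ncol(p) < 2L)
    stop("same_trend needs at least two ordered stages")
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  d <- p[, -1L, drop = FALSE] - p[, -ncol(p), drop = FALSE]
  m <- (p[, -1L, drop = FALSE] + p[, -ncol(p), drop = FALSE]) / 2
  s <- sign(d)
  s[abs(d) <= epsilon * abs(m)] <- 0
  all(apply(s, 2L, function(col) length(unique(col)) == 1L))
}

#' Screen a time course of one inbred line for differential spots
#'
#' For every spot of `genotype` across the ordered `stages`, applies the
#' three-part inbred screen: the replicate same-trend rule, a one-way
#' ANOVA of replicate intensities across stages, and the maximum
#' stage-mean fold change. A spot passes iff the trend is consistent, the
#' ANOVA p-value is below `config$alpha` and the fold change is strictly
#' greater than `config$fc_inbred`.
#'
#' Spots with incomplete replication at any (genotype, stage) cell are
#' ineligible for testing (never imputed) and reported with
#' `eligible = FALSE`, `passed = FALSE`. A spot whose ANOVA is degenerate
#' (all replicate values identical in every stage) cannot be declared
#' significant; its p-value is `NA` and it does not pass.
#'
#' @param table a (normally ppm-normalized) `spot_table`.
#' @param genotype genotype identifier to screen.
#' @param stages ordered character vector of stage labels (>= 2).
#' @param config an [analysis_config()].
#' @return A `differential_calls` data frame with one row per spot:
#'   `spot_id`, `context`, `genotype`, `stage` (the stage span),
#'   `max_fold`, `p_value`, `trend_ok`, `eligible`, `passed`.
#' @export
select_inbred_differential <- function(table, genotype, stages,
                                       config = analysis_config()) {
  stopifnot(is.data.frame(table), inherits(config, "analysis_config"))
  stopifnot(is.character(genotype), length(genotype) == 1L)
  stopifnot(is.character(stages), length(stages) >= 2L)
  sub <- table[table$genotype == genotype & table$stage %in% stages, ,
               drop = FALSE]
  if (!nrow(sub))
    stop("no records for genotype ", genotype, " at the requested stages")
  spots <- sort(unique(sub$spot_id))
  calls <- lapply(spots, function(sp) {
    rows <- sub[sub$spot_id == sp, , drop = FALSE]
    mat <- .profile_matrix(rows, stages)
    if (is.null(mat)) {
      return(data.frame(spot_id = sp, context = "inbred",
                        genotype = genotype,
                        stage = paste(stages, collapse = ".."),
                        max_fold = NA_real_, p_value = NA_real_,
                        trend_ok = NA, eligible = FALSE, passed = FALSE,
                        stringsAsFactors = FALSE))
    }
    trend_ok <- same_trend(mat, config$trend_epsilon)
    p <- tryCatch(one_way_anova(asplit(mat, 2L))$p_value,
                  error = function(e) NA_real_)
    means <- colMeans(mat)
    fold <- if (all(means > 0)) max_fold_change(means) else NA_real_
    passed <- isTRUE(trend_ok) && !is.na(p) && p < config$alpha &&
      !is.na(fold) && fold > config$fc_inbred
    data.frame(spot_id = sp, context = "inbred", genotype = genotype,
               stage = paste(stages, collapse = ".."),
               max_fold = fold, p_value = p, trend_ok = trend_ok,
               eligible = TRUE, passed = passed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("differential_calls", "data.frame")
  out
}

#' Screen a parent/hybrid triad at one stage for differential spots
#'
#' For every spot, compares the replicate intensities of the F1 hybrid and
#' its two parents at `stage` by one-way ANOVA, together with the maximum
#' fold change among the three genotype means. A spot passes iff the
#' ANOVA p-value is below `config$alpha` and the fold change is strictly
#' greater than `config$fc_triad`. The same-trend rule applies only to the
#' inbred time-course screen, not here.
#'
#' @param table a (normally ppm-normalized) `spot_table`.
#' @param triad a [triad_design()].
#' @param stage single stage label present in the table.
#' @inheritParams select_inbred_differential
#' @return A `differential_calls` data frame with one row per spot.
#' @export
select_triad_differential <- function(table, triad, stage,
                                      config = analysis_config()) {
  stopifnot(is.data.frame(table), inherits(triad, "triad_design"),
            inherits(config, "analysis_config"))
  stopifnot(is.character(stage), length(stage) == 1L)
  genos <- c(triad$parent_a, triad$parent_b, triad$f1)
  sub <- table[table$genotype %in% genos & table$stage == stage, ,
               drop = FALSE]
  if (!nrow(sub))
    stop("no records for triad genotypes at stage ", stage)
  spots <- sort(unique(sub$spot_id))
  calls <- lapply(spots, function(sp) {
    rows <- sub[sub$spot_id == sp, , drop = FALSE]
    groups <- lapply(genos, function(g) {
      r <- rows[rows$genotype == g, , drop = FALSE]
      r$intensity[order(r$replicate)]
    })
    ns <- lengths(groups)
    if (any(ns < 2L) || length(unique(ns)) != 1L) {
      return(data.frame(spot_id = sp, context = "triad", hybrid = triad$f1,
                        stage = stage, max_fold = NA_real_,
                        p_value = NA_real_, eligible = FALSE,
                        passed = FALSE, stringsAsFactors = FALSE))
    }
    p <- tryCatch(one_way_anova(groups)$p_value,
                  error = function(e) NA_real_)
    means <- vapply(groups, mean, 0)
    fold <- if (all(means > 0)) max_fold_change(means) else NA_real_
    passed <- !is.na(p) && p < config$alpha &&
      !is.na(fold) && fold > config$fc_triad
    data.frame(spot_id = sp, context = "triad", hybrid = triad$f1,
               stage = stage, max_fold = fold, p_value = p,
               eligible = TRUE, passed = passed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("differential_calls", "data.frame")
  out
}

#' @export
print.differential_calls <- function(x, ...) {
  cat(sprintf("Differential calls (%s): %d spot(s), %d passed\n",
              paste(unique(x$context), collapse = "/"), nrow(x),
              sum(x$passed)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

# replicate x stage matrix for one spot/genotype, or NULL when replication
# is incomplete or unequal across stages
.profile_matrix <- function(rows, stages) {
  reps <- sort(unique(rows$replicate))
  if (length(reps) < 2L) return(NULL)
  mat <- matrix(NA_real_, nrow = length(reps), ncol = length(stages),
                dimnames = list(reps, stages))
  for (i in seq_len(nrow(rows))) {
    mat[as.character(rows$replicate[i]), rows$stage[i]] <- rows$intensity[i]
  }
  if (anyNA(mat)) return(NULL)
  mat
}
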