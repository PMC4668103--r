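#' Seed setting rate
#'
#' Fraction of scored spikelets bearing fully grown seeds,
#' `filled_seeds / total_spikelets`. Vectorized.
#'
#' @param filled_seeds non-negative integer(s).
#' @param total_spikelets positive integer(s); `filled_seeds` may not
#'   exceed them.
#' @return Rate(s) in `[0, 1]`.
#' @examples
#' seed_setting_rate(50, 100)
#' @export
seed_setting_rate <- function(filled_seeds, total_spikelets) {
  stopifnot(is.numeric(filled_seeds), is.numeric(total_spikelets))
  if (any(total_spikelets <= 0))
    stop("total_spikelets must be positive")
  if (any(filled_seeds < 0))
    stop("filled_seeds must be non-negative")
  if (any(filled_seeds > total_spikelets))
    stop("filled_seeds exceeds total_spikelets")
  filled_seeds / total_spikelets
}

#' Fisher LSD letter groupings
#'
#' Computes the least significant difference for each pair of groups,
#' `LSD_ij = t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j))`
#' with MSE and df from the pooled one-way ANOVA, then assigns compact
#' letters by the descending-mean sweep: start a new letter at the largest
#' mean that has none yet, extend it to every group (lettered or not)
#' whose mean lies within LSD of that anchor, and repeat. Unbalanced
#' replicate counts use the per-pair n_i, n_j. Letter assignment is
#' deterministic for a fixed input order.
#'
#' @param groups named list of k >= 2 numeric samples (each length >= 2).
#' @param alpha significance level, default 0.05.
#' @return An object of class `lsd_grouping`: list with `table` (data
#'   frame of group, n, mean, letters, in decreasing mean order), `mse`,
#'   `df_within`, `alpha`, and `lsd` (the common LSD value when the design
#'   is balanced, `NA` otherwise).
#' @examples
#' lsd_letters(list(high = c(99, 101, 100), low = c(9, 10, 11)))
#' @export
lsd_letters <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  for (g in groups) {
    if (!is.numeric(g) || length(g) < 2L || anyNA(g))
      stop("each group must be a numeric vector of length >= 2 without NAs")
  }
  k <- length(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  df_within <- sum(n) - k
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  mse <- sse / df_within
  if (mse <= 0)
    stop("degenerate variance: pooled within-group mean square is zero")
  tcrit <- stats::qt(1 - alpha / 2, df_within)
  lsd_pair <- function(i, j) tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))

  ord <- order(means, decreasing = TRUE)
  assigned <- rep(list(character(0)), k)
  lettered <- rep(FALSE, k)
  next_letter <- 0L
  while (any(!lettered)) {
    anchor <- ord[!lettered[ord]][1L]
    next_letter <- next_letter + 1L
    lab <- .cld_letter(next_letter)
    cover <- which(vapply(seq_len(k), function(j) {
      abs(means[anchor] - means[j]) <= lsd_pair(anchor, j)
    }, NA))
    for (j in cover) assigned[[j]] <- c(assigned[[j]], lab)
    lettered[cover] <- TRUE
  }

  tab <- data.frame(group = names(groups)[ord], n = unname(n[ord]),
                    mean = unname(means[ord]),
                    letters = vapply(assigned[ord], paste, "",
                                     collapse = ""),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  balanced <- length(unique(n)) == 1L
  structure(list(table = tab, mse = mse, df_within = df_within,
                 alpha = alpha,
                 lsd = if (balanced) lsd_pair(1L, 2L) else NA_real_),
            class = "lsd_grouping")
}

.cld_letter <- function(i) {
  # a..z, then aa, ab, ... for pathological k
  if (i <= 26L) letters[i]
  else paste0(letters[(i - 1L) %/% 26L], letters[(i - 1L) %% 26L + 1L])
}

#' @export
print.lsd_grouping <- function(x, ...) {
  cat(sprintf("Fisher LSD groupings (alpha = %g, MSE = %.4g, df = %d",
              x$alpha, x$mse, x$df_within))
  if (!is.na(x$lsd)) cat(sprintf(", LSD = %.4g", x$lsd))
  cat(")\n")
  print.data.frame(x$table, digits = 4, ...)
  invisible(x)
}

#' One-way ANOVA of seed-setting rates across stages
#'
#' Tests whether a genotype's replicate seed-setting rates differ among
#' sampling stages. Rates are analyzed on the raw proportion scale (no
#' arcsine transform).
#'
#' @param seedset a `seedset_table` (see [read_seedset_table()]).
#' @param genotype genotype to test; needs >= 2 stages with >= 2
#'   replicates each.
#' @return An `anova_result` (see [one_way_anova()]).
#' @export
stage_course_anova <- function(seedset, genotype) {
  stopifnot(is.data.frame(seedset))
  sub <- seedset[seedset$genotype == genotype, , drop = FALSE]
  if (!nrow(sub)) stop("no records for genotype ", genotype)
  rates <- seed_setting_rate(sub$filled_seeds, sub$total_spikelets)
  groups <- split(rates, sub$stage)
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 stages with >= 2 replicates each for genotype ",
         genotype)
  one_way_anova(groups)
}

#' Summarize a seed-setting table with LSD letters and stage ANOVA
#'
#' Produces the usual phenotype summary: per genotype and stage, the mean
#' seed-setting rate in percent (one decimal) with the Fisher LSD letter
#' of that genotype's stage comparison; alongside, the stage-course ANOVA
#' p-value per genotype and the across-genotype ANOVA p-value per stage.
#'
#' @param seedset a `seedset_table`.
#' @param stages optional ordered stage labels (default: order of
#'   appearance in the table).
#' @param alpha significance level for the LSD letters.
#' @return A `seedset_summary`: data frame with `genotype`, `stage`, `n`,
#'   `mean_percent` (1 decimal), `letters`; attributes `stage_p` (named
#'   per-genotype p-values across stages) and `genotype_p` (named
#'   per-stage p-values across genotypes, `NA` where not testable).
#' @export
summarize_seedset <- function(seedset, stages = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(seedset))
  if (is.null(stages)) stages <- unique(seedset$stage)
  genos <- unique(seedset$genotype)
  rates <- seed_setting_rate(seedset$filled_seeds, seedset$total_spikelets)

  rows <- list()
  stage_p <- stats::setNames(rep(NA_real_, length(genos)), genos)
  for (g in genos) {
    sel <- seedset$genotype == g
    by_stage <- split(rates[sel], factor(seedset$stage[sel],
                                         levels = stages))
    by_stage <- by_stage[lengths(by_stage) > 0L]
    lets <- tryCatch(lsd_letters(by_stage, alpha = alpha)$table,
                     error = function(e) NULL)
    stage_p[g] <- tryCatch(stage_course_anova(seedset, g)$p_value,
                           error = function(e) NA_real_)
    for (s in names(by_stage)) {
      lt <- if (!is.null(lets)) lets$letters[match(s, lets$group)] else ""
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, stage = s, n = length(by_stage[[s]]),
        mean_percent = round(100 * mean(by_stage[[s]]), 1),
        letters = lt, stringsAsFactors = FALSE)
    }
  }
  genotype_p <- stats::setNames(rep(NA_real_, length(stages)), stages)
  for (s in stages) {
    sel <- seedset$stage == s
    by_geno <- split(rates[sel], seedset$genotype[sel])
    by_geno <- by_geno[lengths(by_geno) >= 2L]
    if (length(by_geno) >= 2L)
      genotype_p[s] <- tryCatch(one_way_anova(by_geno)$p_value,
                                error = function(e) NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stage_p") <- stage_p
  attr(out, "genotype_p") <- genotype_p
  class(out) <- c("seedset_summary", "data.frame")
  out
}

#' @export
print.seedset_summary <- function(x, ...) {
  cat("Seed-setting summary (mean %, LSD letters within genotype)\n")
  print.data.frame(as.data.frame(x), ...)
  sp <- attr(x, "stage_p")
  if (!is.null(sp)) {
    cat("Stage-course ANOVA p by genotype:\n")
    print(signif(sp, 3))
  }
  invisible(x)
}
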