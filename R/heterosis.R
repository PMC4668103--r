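.pattern_levels <- c("A", "+", "-", "++", "--", "+-")

#' Pattern labels used by the heterotic classification
#'
#' `A` additive (F1 at the mid-parent), `+` high-parent-like, `-`
#' low-parent-like, `++` over-dominant (significantly above the high
#' parent), `--` under-dominant (significantly below the low parent),
#' `+-` partially dominant (significantly different from mid-parent and
#' both parents, strictly between them).
#'
#' @return Character vector of the six labels in their canonical order.
#' @export
pattern_levels <- function() .pattern_levels

#' Per-replicate mid-parent pseudovalues
#'
#' Pairs the two parents' replicate intensities by replicate index and
#' averages each pair, giving a replicate-level sample whose mean is the
#' mid-parent value of the parental means. The pseudovalues carry a
#' variance estimate, so the F1-versus-mid-parent comparison can be run as
#' an ordinary two-sample t-test.
#'
#' @param p1_reps,p2_reps numeric replicate vectors of equal length.
#' @return `(p1_reps + p2_reps) / 2`, element-wise.
#' @examples
#' midparent_pseudovalues(c(100, 101, 99), c(200, 201, 199))
#' @export
midparent_pseudovalues <- function(p1_reps, p2_reps) {
  stopifnot(is.numeric(p1_reps), is.numeric(p2_reps))
  if (length(p1_reps) != length(p2_reps))
    stop("parental replicate vectors differ in length; pair replicates ",
         "explicitly (one value per biological replicate, same order)")
  (p1_reps + p2_reps) / 2
}

#' Classify the heterotic accumulation pattern of one protein spot
#'
#' Given replicate intensities of the two parents and the F1 hybrid,
#' assigns exactly one of the six patterns (see [pattern_levels()]). Let
#' HP/LP denote the larger/smaller parental mean and MP their average.
#' Three two-sided t-tests (Welch by default) are run: F1 replicates
#' against the mid-parent pseudovalues (`p_mp`), against the high parent's
#' replicates (`p_hp`), and against the low parent's replicates (`p_lp`).
#' The decision precedence is:
#'
#' 1. `p_mp >= alpha` -> `A` (additive);
#' 2. else if `p_hp < alpha` and F1 mean > HP -> `++`;
#' 3. else if `p_lp < alpha` and F1 mean < LP -> `--`;
#' 4. else if `p_hp >= alpha` -> `+`;
#' 5. else if `p_lp >= alpha` -> `-`;
#' 6. else `+-` (different from MP, HP and LP; between the parents).
#'
#' Checking `++`/`--` before `+`/`-` makes beyond-parent calls
#' unambiguous when the F1 differs from both MP and a parent in the same
#' direction. When the parental means coincide exactly (HP = LP = MP),
#' "between the parents" is empty and any significant deviation is
#' classified `++` above or `--` below. Ties are broken deterministically
#' by the listed order.
#'
#' @param p1_reps,p2_reps,f1_reps replicate intensity vectors
#'   (length >= 2, non-negative); parents must have equal replicate counts.
#' @param alpha significance level for all three comparisons.
#' @param welch use Welch's unequal-variance t (default); `FALSE` gives the
#'   pooled-variance test.
#' @return An object of class `heterosis_call`: list with `pattern`,
#'   `p_mp`, `p_hp`, `p_lp`, `mp`, `hp`, `lp`, `f1_mean`.
#' @export
classify_pattern <- function(p1_reps, p2_reps, f1_reps, alpha = 0.05,
                             welch = TRUE) {
  stopifnot(is.numeric(f1_reps), length(f1_reps) >= 2L, !anyNA(f1_reps))
  stopifnot(is.numeric(p1_reps), length(p1_reps) >= 2L, !anyNA(p1_reps))
  stopifnot(is.numeric(p2_reps), length(p2_reps) >= 2L, !anyNA(p2_reps))
  if (any(c(p1_reps, p2_reps, f1_reps) < 0))
    stop("intensities must be non-negative")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)

  pseudo <- midparent_pseudovalues(p1_reps, p2_reps)
  if (stats::var(f1_reps) == 0 && stats::var(pseudo) == 0)
    stop("degenerate variance: F1 and mid-parent pseudovalues are both constant")

  m1 <- mean(p1_reps)
  m2 <- mean(p2_reps)
  hp <- max(m1, m2)
  lp <- min(m1, m2)
  mp <- (m1 + m2) / 2
  hp_reps <- if (m1 >= m2) p1_reps else p2_reps
  lp_reps <- if (m1 >= m2) p2_reps else p1_reps
  f1_mean <- mean(f1_reps)

  ttest_p <- function(x, y, label) {
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("degenerate variance in the ", label, " comparison")
    stats::t.test(x, y, var.equal = !welch)$p.value
  }
  p_mp <- ttest_p(f1_reps, pseudo, "mid-parent")
  p_hp <- ttest_p(f1_reps, hp_reps, "high-parent")
  p_lp <- ttest_p(f1_reps, lp_reps, "low-parent")

  pattern <- if (p_mp >= alpha) {
    "A"
  } else if (hp == lp) {
    # coincident parents: "between the parents" is empty
    if (f1_mean > hp) "++" else "--"
  } else if (p_hp < alpha && f1_mean > hp) {
    "++"
  } else if (p_lp < alpha && f1_mean < lp) {
    "--"
  } else if (p_hp >= alpha) {
    "+"
  } else if (p_lp >= alpha) {
    "-"
  } else {
    "+-"
  }

  structure(list(pattern = pattern, p_mp = p_mp, p_hp = p_hp, p_lp = p_lp,
                 mp = mp, hp = hp, lp = lp, f1_mean = f1_mean),
            class = "heterosis_call")
}

#' @export
print.heterosis_call <- function(x, ...) {
  cat(sprintf("Heterotic pattern: %s\n", x$pattern))
  cat(sprintf("  F1 mean %.4g; MP %.4g, HP %.4g, LP %.4g\n",
              x$f1_mean, x$mp, x$hp, x$lp))
  cat(sprintf("  p(MP) %.3g, p(HP) %.3g, p(LP) %.3g\n",
              x$p_mp, x$p_hp, x$p_lp))
  invisible(x)
}

#' Classify every spot of a triad at one stage
#'
#' Applies [classify_pattern()] to each spot of the triad at `stage` and
#' returns a report-ready table mirroring the usual published layout:
#' spot, hybrid, stage, the maximum fold change among the three genotype
#' means, a Y/N flag for whether the three-group ANOVA is significant at
#' `config$alpha`, and the pattern. The numeric fold is always reported
#' alongside the flag. Spots with incomplete replication or degenerate
#' variance receive `NA` fields.
#'
#' @inheritParams select_triad_differential
#' @param spots optional character vector restricting classification to a
#'   subset of spots (e.g. the spots passing
#'   [select_triad_differential()]).
#' @return A `heterosis_calls` data frame: `spot_id`, `hybrid`, `stage`,
#'   `fold`, `significant` ("Y"/"N"), `pattern`, `p_mp`, `p_hp`, `p_lp`,
#'   `mp`, `hp`, `lp`, `f1_mean`.
#' @export
classify_triad_patterns <- function(table, triad, stage,
                                    config = analysis_config(),
                                    spots = NULL) {
  stopifnot(is.data.frame(table), inherits(triad, "triad_design"),
            inherits(config, "analysis_config"))
  sub <- table[table$stage == stage, , drop = FALSE]
  if (is.null(spots)) spots <- sort(unique(sub$spot_id))
  rows <- lapply(spots, function(sp) {
    get_reps <- function(g) {
      r <- sub[sub$spot_id == sp & sub$genotype == g, , drop = FALSE]
      r$intensity[order(r$replicate)]
    }
    p1 <- get_reps(triad$parent_a)
    p2 <- get_reps(triad$parent_b)
    f1 <- get_reps(triad$f1)
    na_row <- data.frame(spot_id = sp, hybrid = triad$f1, stage = stage,
                         fold = NA_real_, significant = NA_character_,
                         pattern = NA_character_, p_mp = NA_real_,
                         p_hp = NA_real_, p_lp = NA_real_, mp = NA_real_,
                         hp = NA_real_, lp = NA_real_, f1_mean = NA_real_,
                         stringsAsFactors = FALSE)
    if (length(p1) < 2L || length(f1) < 2L || length(p1) != length(p2))
      return(na_row)
    call <- tryCatch(
      classify_pattern(p1, p2, f1, alpha = config$alpha,
                       welch = config$welch),
      error = function(e) NULL)
    if (is.null(call)) return(na_row)
    means <- c(mean(p1), mean(p2), mean(f1))
    fold <- if (all(means > 0)) max_fold_change(means) else NA_real_
    p_anova <- tryCatch(one_way_anova(list(p1, p2, f1))$p_value,
                        error = function(e) NA_real_)
    sig <- if (is.na(p_anova)) NA_character_ else {
      if (p_anova < config$alpha) "Y" else "N"
    }
    data.frame(spot_id = sp, hybrid = triad$f1, stage = stage,
               fold = fold, significant = sig, pattern = call$pattern,
               p_mp = call$p_mp, p_hp = call$p_hp, p_lp = call$p_lp,
               mp = call$mp, hp = call$hp, lp = call$lp,
               f1_mean = call$f1_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("heterosis_calls", "data.frame")
  out
}

#' @export
print.heterosis_calls <- function(x, ...) {
  cat(sprintf("Heterotic pattern calls: %d spot(s)\n", nrow(x)))
  tab <- table(factor(x$pattern, levels = .pattern_levels))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4, ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' Mid-parent heterosis degree
#'
#' The percent excess of the F1 mean over the mid-parent value:
#' `100 * (f1_mean - mp) / mp` with `mp = (p1_mean + p2_mean) / 2`.
#' Positive values indicate hybrid vigour above the parental average. The
#' full-precision value is stored; reports round to one decimal.
#'
#' @param f1_mean F1 trait mean.
#' @param p1_mean,p2_mean parental trait means (non-negative; their mean
#'   must be positive).
#' @return An object of class `mph_result`: list with `mph_percent`,
#'   `f1_mean`, `mp`.
#' @examples
#' mph_percent(70.4, 16.3, 100.0)  # 21.1% after rounding
#' @export
mph_percent <- function(f1_mean, p1_mean, p2_mean) {
  stopifnot(is.numeric(f1_mean), length(f1_mean) == 1L,
            is.numeric(p1_mean), length(p1_mean) == 1L,
            is.numeric(p2_mean), length(p2_mean) == 1L)
  if (p1_mean < 0 || p2_mean < 0)
    stop("parental means must be non-negative")
  mp <- (p1_mean + p2_mean) / 2
  if (mp <= 0)
    stop("mid-parent value is zero; mid-parent heterosis is undefined")
  structure(list(mph_percent = 100 * (f1_mean - mp) / mp,
                 f1_mean = f1_mean, mp = mp),
            class = "mph_result")
}

#' @export
print.mph_result <- function(x, ...) {
  cat(sprintf("Mid-parent heterosis: %.1f%% (F1 %.4g vs MP %.4g)\n",
              x$mph_percent, x$f1_mean, x$mp))
  invisible(x)
}
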