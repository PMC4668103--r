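# independent oracle: one-way ANOVA from raw sums of squares
anova_by_hand <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- lengths(groups)
  grand <- mean(y)
  ssb <- sum(n * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- length(y) - k
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  # identical groups: no between-group variation at all
  res <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)

  groups <- list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8))
  res <- one_way_anova(groups)
  oracle <- anova_by_hand(groups)
  expect_equal(res$f_stat, 21)
  expect_equal(res$f_stat, oracle$f)
  expect_equal(res$p_value, oracle$p)
  expect_identical(c(res$df_between, res$df_within), c(2L, 6L))

  set.seed(5)
  for (i in 1:20) {
    g <- replicate(sample(2:5, 1),
                   rnorm(sample(2:6, 1), mean = runif(1, 0, 10)),
                   simplify = FALSE)
    res <- one_way_anova(g)
    oracle <- anova_by_hand(g)
    expect_equal(res$f_stat, oracle$f)
    expect_equal(res$p_value, oracle$p)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(4, 10)
    b <- rnorm(5, 12)
    f <- one_way_anova(list(a, b))$f_stat
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2)
  }
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "degenerate")
})

test_that("max fold change is max/min, permutation- and scale-invariant", {
  expect_equal(max_fold_change(c(10, 10, 10)), 1)
  expect_equal(max_fold_change(c(5, 20)), 4)
  expect_error(max_fold_change(c(1, 0)), "positive")
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(2:6, 1), 0.1, 50)
    f <- max_fold_change(v)
    expect_gte(f, 1)
    expect_equal(max_fold_change(sample(v)), f)
    expect_equal(max_fold_change(v * 13.7), f)
  }
})

test_that("same-trend rule compares up/down/flat signs across replicates", {
  up <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1.5, 2, 2.5, 3))
  expect_true(same_trend(up, epsilon = 0.02))
  rev3 <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1.5, 1.4, 2.5, 3))
  expect_false(same_trend(rev3, epsilon = 0.02))
  expect_error(same_trend(cbind(c(1, 2, 3))), "two ordered stages")
})

test_that("near-constant profiles are flat in every enumerated sign pattern", {
  # oracle: enumerate the sign patterns by hand at epsilon = 0.05; any
  # profile whose consecutive changes all stay below 5% of the local mean
  # must read as all-flat and therefore trend-consistent across replicates
  base <- c(100, 101, 100.5, 100)
  set.seed(21)
  for (i in 1:20) {
    wobble <- matrix(runif(12, -0.5, 0.5), nrow = 3)
    prof <- matrix(rep(base, each = 3), nrow = 3) + wobble
    d <- prof[, -1] - prof[, -4]
    m <- (prof[, -1] + prof[, -4]) / 2
    stopifnot(all(abs(d) <= 0.05 * m))
    expect_true(same_trend(prof, epsilon = 0.05))
  }
})

test_that("inbred screen recovers planted spots at low noise and none on flat data", {
  spec <- synthetic_spec(n_spots_per_class = c("inbred-changing" = 10,
                                               "null" = 90),
                         cv = 0.05, seed = 101)
  sim <- generate_stage_course(spec)
  norm <- normalize_total_ppm(sim$table)
  calls <- select_inbred_differential(norm, "Line1", spec$inbred_stages)
  planted <- sim$truth$spot_id[sim$truth$planted_trend != "flat"]
  expect_setequal(calls$spot_id[calls$passed], planted)

  flat <- generate_stage_course(synthetic_spec(
    n_spots_per_class = c("null" = 40), cv = 0, seed = 1))
  cst <- select_inbred_differential(flat$table, "Line1",
                                    spec$inbred_stages)
  expect_identical(sum(cst$passed), 0L)
})

test_that("fold thresholds are strict: exactly 1.5x / 2x never passes", {
  # noiseless two-stage spot at exactly 1.5-fold
  df <- data.frame(spot_id = "s1", genotype = "L",
                   stage = rep(c("D6", "D8"), each = 3),
                   replicate = rep(1:3, 2),
                   intensity = rep(c(100, 150), each = 3))
  tab <- validate_spot_table(df, expected_replicates = 3)
  call <- select_inbred_differential(tab, "L", c("D6", "D8"))
  expect_equal(call$max_fold, 1.5)
  expect_false(call$passed)

  triad <- triad_table_from_reps(rep(100, 3), rep(100, 3), rep(200, 3))
  tcall <- select_triad_differential(triad, default_triad(), "D10")
  expect_equal(tcall$max_fold, 2)
  expect_false(tcall$passed)
})

test_that("triad screen: null triads pass nothing, planted elevation passes", {
  spec <- synthetic_spec(n_spots_per_class = c("null" = 60), cv = 0.05,
                         stages = "D10", seed = 31)
  sim <- generate_triads(spec)
  calls <- select_triad_differential(normalize_total_ppm(sim$table),
                                     default_triad(), "D10")
  # a null spot must also clear the strict 2-fold filter, so essentially
  # nothing should pass even before type-I error considerations
  expect_lte(sum(calls$passed), 1L)

  planted <- triad_table_from_reps(
    p1 = c(100, 104, 97), p2 = c(101, 99, 103), f1 = c(250, 256, 248))
  pcall <- select_triad_differential(planted, default_triad(), "D10")
  expect_true(pcall$passed)
})

test_that("select output is invariant to row order of the input table", {
  spec <- synthetic_spec(n_spots_per_class = c("A" = 5, "++" = 5),
                         cv = 0.05, stages = "D10", seed = 13)
  tab <- normalize_total_ppm(generate_triads(spec)$table)
  base <- select_triad_differential(tab, default_triad(), "D10")
  set.seed(2)
  shuf <- select_triad_differential(tab[sample(nrow(tab)), ],
                                    default_triad(), "D10")
  expect_equal(shuf, base)
})
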