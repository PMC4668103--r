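# independent oracle: re-derive the pattern decision from direct t.test
# calls on the same numbers, without classify_pattern()
pattern_oracle <- function(p1, p2, f1, alpha = 0.05) {
  pseudo <- (p1 + p2) / 2
  m1 <- mean(p1); m2 <- mean(p2)
  hp_reps <- if (m1 >= m2) p1 else p2
  lp_reps <- if (m1 >= m2) p2 else p1
  hp <- max(m1, m2); lp <- min(m1, m2)
  p_mp <- t.test(f1, pseudo)$p.value
  p_hp <- t.test(f1, hp_reps)$p.value
  p_lp <- t.test(f1, lp_reps)$p.value
  fm <- mean(f1)
  if (p_mp >= alpha) "A"
  else if (hp == lp) if (fm > hp) "++" else "--"
  else if (p_hp < alpha && fm > hp) "++"
  else if (p_lp < alpha && fm < lp) "--"
  else if (p_hp >= alpha) "+"
  else if (p_lp >= alpha) "-"
  else "+-"
}

test_that("mid-parent pseudovalues average parents replicate-wise", {
  expect_equal(midparent_pseudovalues(c(100, 101, 99), c(200, 201, 199)),
               c(150, 151, 149))
  expect_equal(midparent_pseudovalues(c(5, 6), c(5, 6)), c(5, 6))
  expect_error(midparent_pseudovalues(1:3, 1:4), "pair replicates")
  set.seed(4)
  for (i in 1:10) {
    a <- runif(5); b <- runif(5)
    expect_equal(mean(midparent_pseudovalues(a, b)),
                 (mean(a) + mean(b)) / 2)
  }
})

test_that("an F1 at the exact mid-parent is additive", {
  call <- classify_pattern(c(100, 101, 99), c(200, 201, 199),
                           c(150, 151, 149))
  expect_identical(call$pattern, "A")
  expect_gte(call$p_mp, 0.05)
})

test_that("seeded draws land in the planted class and agree with the t-test oracle", {
  set.seed(1234)
  p1 <- rnorm(3, 100, 2)
  p2 <- rnorm(3, 300, 2)
  f1_hp <- rnorm(3, 300, 2)    # high-parent-like
  f1_od <- rnorm(3, 500, 2)    # beyond the high parent
  f1_pd <- rnorm(3, 250, 2)    # between MP and HP
  f1_lp <- rnorm(3, 100, 2)    # low-parent-like
  f1_ud <- rnorm(3, 40, 2)     # below the low parent
  cases <- list(f1_hp, f1_od, f1_pd, f1_lp, f1_ud)
  expected <- c("+", "++", "+-", "-", "--")
  for (i in seq_along(cases)) {
    call <- classify_pattern(p1, p2, cases[[i]])
    expect_identical(call$pattern, expected[i])
    expect_identical(call$pattern, pattern_oracle(p1, p2, cases[[i]]))
  }
})

test_that("every non-degenerate triad gets exactly one of six patterns, matching the oracle", {
  set.seed(77)
  for (i in 1:200) {
    p1 <- rnorm(3, runif(1, 50, 150), runif(1, 1, 20))
    p2 <- rnorm(3, runif(1, 50, 400), runif(1, 1, 20))
    f1 <- rnorm(3, runif(1, 20, 500), runif(1, 1, 20))
    p1 <- abs(p1); p2 <- abs(p2); f1 <- abs(f1)
    call <- classify_pattern(p1, p2, f1)
    expect_true(call$pattern %in% pattern_levels())
    expect_identical(call$pattern, pattern_oracle(p1, p2, f1))
  }
})

test_that("classification is symmetric in the parent labels", {
  set.seed(15)
  for (i in 1:30) {
    p1 <- abs(rnorm(3, 100, 10))
    p2 <- abs(rnorm(3, 300, 10))
    f1 <- abs(rnorm(3, runif(1, 50, 500), 10))
    a <- classify_pattern(p1, p2, f1)
    b <- classify_pattern(p2, p1, f1)
    expect_identical(a$pattern, b$pattern)
    expect_equal(a$mp, b$mp)
    expect_equal(a$hp, b$hp)
  }
})

test_that("pattern calls are location-consistent", {
  set.seed(33)
  for (i in 1:50) {
    p1 <- abs(rnorm(3, 100, 5))
    p2 <- abs(rnorm(3, 250, 5))
    f1 <- abs(rnorm(3, runif(1, 30, 500), 5))
    call <- classify_pattern(p1, p2, f1)
    if (call$pattern == "++") expect_gt(call$f1_mean, call$hp)
    if (call$pattern == "--") expect_lt(call$f1_mean, call$lp)
    # additivity is invariant under a common shift of all three genotypes
    if (call$pattern == "A") {
      shifted <- classify_pattern(p1 + 50, p2 + 50, f1 + 50)
      expect_identical(shifted$pattern, "A")
    }
  }
})

test_that("coincident parents classify any deviation as over/under-dominant", {
  set.seed(8)
  p <- c(100, 100.4, 99.6)
  f_hi <- c(140, 141, 139)
  f_lo <- c(60, 61, 59)
  expect_identical(classify_pattern(p, p, f_hi)$pattern, "++")
  expect_identical(classify_pattern(p, p, f_lo)$pattern, "--")
})

test_that("degenerate variance is an error", {
  expect_error(classify_pattern(rep(1, 3), rep(2, 3), rep(1.5, 3)),
               "degenerate")
})

test_that("mid-parent heterosis arithmetic reproduces known degrees", {
  expect_equal(round(mph_percent(70.4, 16.3, 100.0)$mph_percent, 1), 21.1)
  expect_equal(round(mph_percent(66.9, 1.9, 100.0)$mph_percent, 1), 31.3)
  expect_equal(mph_percent(58.15, 16.3, 100.0)$mph_percent, 0)
  expect_error(mph_percent(10, 0, 0), "undefined")
  # |MPH| is symmetric in the parents
  set.seed(6)
  for (i in 1:10) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100); f <- runif(1, 1, 150)
    expect_equal(mph_percent(f, a, b)$mph_percent,
                 mph_percent(f, b, a)$mph_percent)
  }
})

test_that("classify_triad_patterns mirrors per-spot classification and flags significance", {
  spec <- synthetic_spec(n_spots_per_class = c("A" = 4, "++" = 4,
                                               "-" = 4),
                         cv = 0.05, stages = "D10", seed = 55)
  sim <- generate_triads(spec)
  calls <- classify_triad_patterns(sim$table, default_triad(), "D10")
  expect_identical(nrow(calls), 12L)
  expect_true(all(calls$pattern %in% pattern_levels()))
  expect_true(all(calls$significant %in% c("Y", "N")))
  # spot-wise agreement with classify_pattern on the same numbers
  for (sp in calls$spot_id[c(1, 5, 9)]) {
    reps <- function(g) {
      r <- sim$table[sim$table$spot_id == sp & sim$table$genotype == g, ]
      r$intensity[order(r$replicate)]
    }
    expect_identical(
      calls$pattern[calls$spot_id == sp],
      classify_pattern(reps("P1"), reps("P2"), reps("F1"))$pattern)
  }
})
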