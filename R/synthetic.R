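#' Specification for the synthetic-data generators
#'
#' Declares the generative parameters of the simulated study: how many
#' spots to plant per heterotic class (plus `null` spots with no effect
#' and `inbred-changing` spots with a monotone time-course), the two
#' parental mean intensities, the replicate coefficient of variation of
#' the multiplicative (log-normal) densitometry noise, the replicate
#' count, the stage sets of the two designs, the planted fold of the
#' inbred time course, and the random seed.
#'
#' Defaults emulate the design the pipeline assumes: three biological
#' replicates per genotype and stage, a three-fold separation between the
#' parental means, 5% replicate CV, three hybrid-comparison stages and
#' four inbred time-course stages.
#'
#' @param n_spots_per_class named integer vector; names among the six
#'   pattern labels (see [pattern_levels()]) plus `"null"` and
#'   `"inbred-changing"`.
#' @param parent_low_mean,parent_high_mean positive planted parental
#'   means, `parent_high_mean >= parent_low_mean`.
#' @param cv replicate coefficient of variation (>= 0) of the log-normal
#'   noise.
#' @param n_replicates biological replicates per genotype and stage.
#' @param stages stage labels of the triad design.
#' @param inbred_stages ordered stage labels of the inbred time course.
#' @param inbred_fold planted end-to-end fold of `inbred-changing` spots
#'   (> 1).
#' @param seed integer seed; every generator is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_spots_per_class = c("A" = 200, "+" = 200,
                                                 "-" = 200, "++" = 200,
                                                 "--" = 200, "+-" = 200,
                                                 "null" = 200,
                                                 "inbred-changing" = 100),
                           parent_low_mean = 100,
                           parent_high_mean = 300, cv = 0.05,
                           n_replicates = 3L,
                           stages = c("D8", "D10", "D12"),
                           inbred_stages = c("D6", "D8", "D10", "D12"),
                           inbred_fold = 3, seed = 1L) {
  stopifnot(is.numeric(n_spots_per_class), length(n_spots_per_class) >= 1L)
  if (is.null(names(n_spots_per_class)))
    stop("n_spots_per_class must be named")
  known <- c(.pattern_levels, "null", "inbred-changing")
  bad <- setdiff(names(n_spots_per_class), known)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (any(n_spots_per_class < 0) ||
      any(n_spots_per_class != round(n_spots_per_class)))
    stop("class counts must be non-negative integers")
  stopifnot(parent_low_mean > 0, parent_high_mean >= parent_low_mean)
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0)
  stopifnot(n_replicates >= 2L)
  stopifnot(is.character(stages), length(stages) >= 1L)
  stopifnot(is.character(inbred_stages), length(inbred_stages) >= 2L)
  stopifnot(is.numeric(inbred_fold), inbred_fold > 1)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == as.integer(seed))
  structure(list(n_spots_per_class = n_spots_per_class,
                 parent_low_mean = parent_low_mean,
                 parent_high_mean = parent_high_mean, cv = cv,
                 n_replicates = as.integer(n_replicates), stages = stages,
                 inbred_stages = inbred_stages, inbred_fold = inbred_fold,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# log-normal draws with arithmetic mean `mu` and coefficient of variation
# `cv` (sdlog = sqrt(log(1 + cv^2)), meanlog mean-corrected); cv = 0 gives
# the exact planted values
.noisy <- function(n, mu, cv) {
  if (cv == 0) return(rep(mu, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic parent/hybrid triads with truth labels
#'
#' Plants each requested heterotic class at its canonical effect
#' placement: `A` F1 at the mid-parent, `+` at the high parent, `-` at
#' the low parent, `++` at 1.6 x high parent, `--` at 0.6 x low parent,
#' `+-` midway between mid-parent and high parent; `null` spots give all
#' three genotypes the same mean. Which parent carries the high mean is
#' randomized per spot. Replicate noise is multiplicative log-normal at
#' the spec's CV; with `cv = 0` values equal the planted means exactly.
#' Genotypes are labelled `P1`, `P2` and `F1`; all spec stages are
#' emitted with the same planted means.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (a `spot_table`) and `truth` (data frame
#'   `spot_id`, `planted_pattern`, `planted_fold`, `p1_mean`, `p2_mean`,
#'   `f1_mean`), reproducible from `spec$seed`.
#' @export
generate_triads <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- spec$n_spots_per_class
  classes <- classes[names(classes) %in% c(.pattern_levels, "null")]
  classes <- classes[classes > 0]
  if (!length(classes)) stop("no triad classes requested in spec")
  set.seed(spec$seed)

  lo <- spec$parent_low_mean
  hi <- spec$parent_high_mean
  cls <- rep(names(classes), classes)
  n_spot <- length(cls)
  spot_id <- sprintf("spot%04d", seq_len(n_spot))
  # which parent carries the high mean (coin flip per spot)
  p1_high <- stats::runif(n_spot) < 0.5

  mp <- (lo + hi) / 2
  f1_of <- c("A" = mp, "+" = hi, "-" = lo, "++" = 1.6 * hi,
             "--" = 0.6 * lo, "+-" = (mp + hi) / 2)
  p1_mean <- ifelse(cls == "null", lo, ifelse(p1_high, hi, lo))
  p2_mean <- ifelse(cls == "null", lo, ifelse(p1_high, lo, hi))
  f1_mean <- ifelse(cls == "null", lo, unname(f1_of[cls]))

  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      genotype = c("P1", "P2", "F1"),
                      stage = spec$stages, spot = seq_len(n_spot),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(grid$genotype == "P1", p1_mean[grid$spot],
               ifelse(grid$genotype == "P2", p2_mean[grid$spot],
                      f1_mean[grid$spot]))
  tab <- data.frame(spot_id = spot_id[grid$spot],
                    genotype = grid$genotype, stage = grid$stage,
                    replicate = as.integer(grid$replicate),
                    intensity = .noisy(nrow(grid), mu, spec$cv),
                    stringsAsFactors = FALSE)
  tab <- validate_spot_table(tab, expected_replicates = spec$n_replicates)
  truth <- data.frame(spot_id = spot_id, planted_pattern = cls,
                      planted_fold = pmax(p1_mean, p2_mean, f1_mean) /
                        pmin(p1_mean, p2_mean, f1_mean),
                      p1_mean = p1_mean, p2_mean = p2_mean,
                      f1_mean = f1_mean, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Generate a synthetic inbred time course with truth labels
#'
#' `inbred-changing` spots follow a monotone geometric trend across the
#' spec's inbred stages with an end-to-end fold of `spec$inbred_fold`
#' (direction randomized per spot); `null` spots are flat. Noise model
#' and determinism as in [generate_triads()].
#'
#' @param spec a [synthetic_spec()].
#' @param genotype genotype label of the simulated line.
#' @return List with `table` (a `spot_table` for one genotype across
#'   `spec$inbred_stages`) and `truth` (data frame `spot_id`,
#'   `planted_trend` in up/down/flat, `planted_fold`).
#' @export
generate_stage_course <- function(spec, genotype = "Line1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- spec$n_spots_per_class
  classes <- classes[names(classes) %in% c("inbred-changing", "null")]
  classes <- classes[classes > 0]
  if (!length(classes)) stop("no inbred classes requested in spec")
  set.seed(spec$seed)

  stages <- spec$inbred_stages
  n_stage <- length(stages)
  cls <- rep(names(classes), classes)
  n_spot <- length(cls)
  spot_id <- sprintf("ispot%04d", seq_len(n_spot))
  up <- stats::runif(n_spot) < 0.5
  base <- spec$parent_low_mean
  ratio <- spec$inbred_fold^(1 / (n_stage - 1))

  means <- matrix(base, nrow = n_spot, ncol = n_stage)
  for (j in seq_len(n_stage)) {
    r <- ratio^(j - 1L)
    means[, j] <- ifelse(cls == "null", base,
                         ifelse(up, base * r, base * spec$inbred_fold / r))
  }

  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      stage = seq_len(n_stage), spot = seq_len(n_spot),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- means[cbind(grid$spot, grid$stage)]
  tab <- data.frame(spot_id = spot_id[grid$spot], genotype = genotype,
                    stage = stages[grid$stage],
                    replicate = as.integer(grid$replicate),
                    intensity = .noisy(nrow(grid), mu, spec$cv),
                    stringsAsFactors = FALSE)
  tab <- validate_spot_table(tab, expected_replicates = spec$n_replicates)
  truth <- data.frame(spot_id = spot_id,
                      planted_trend = ifelse(cls == "null", "flat",
                                             ifelse(up, "up", "down")),
                      planted_fold = ifelse(cls == "null", 1,
                                            spec$inbred_fold),
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Generate a synthetic seed-setting table
#'
#' For each (genotype, stage) with a declared true rate, draws the number
#' of filled seeds per ear from a binomial with that rate and aggregates
#' the ears of each biological replicate, emulating replications each
#' scored over several intact ears.
#'
#' @param rates data frame with columns `genotype`, `stage`, `rate` (true
#'   seed-setting probabilities in `[0, 1]`).
#' @param n_replicates biological replicates per genotype and stage.
#' @param ears_per_replicate ears pooled per replicate.
#' @param spikelets_per_ear spikelets scored per ear in the mid-base
#'   region.
#' @param seed integer seed.
#' @return A `seedset_table` (see [read_seedset_table()]).
#' @export
generate_seedset <- function(rates, n_replicates = 3L,
                             ears_per_replicate = 10L,
                             spikelets_per_ear = 150L, seed = 1L) {
  stopifnot(is.data.frame(rates),
            all(c("genotype", "stage", "rate") %in% names(rates)))
  if (any(rates$rate < 0 | rates$rate > 1))
    stop("rates must lie in [0, 1]")
  stopifnot(n_replicates >= 1L, ears_per_replicate >= 1L,
            spikelets_per_ear >= 1L)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    per_ear <- matrix(stats::rbinom(n_replicates * ears_per_replicate,
                                    spikelets_per_ear, rates$rate[i]),
                      nrow = n_replicates)
    data.frame(genotype = rates$genotype[i], stage = rates$stage[i],
               replicate = seq_len(n_replicates),
               filled_seeds = as.integer(rowSums(per_ear)),
               total_spikelets =
                 as.integer(ears_per_replicate * spikelets_per_ear),
               stringsAsFactors = FALSE)
  })
  validate_seedset_table(do.call(rbind, rows))
}
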