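# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a proportional-hazards simulated cohort
#'
#' Bundles and validates the parameters of an exponential
#' proportional-hazards data-generating process: per-group sizes, a
#' baseline hazard (events per unit time), per-group hazard ratios, a
#' target overall censoring proportion with its mechanism, a follow-up
#' horizon and a seed.
#'
#' @param group_sizes Integer vector of per-group patient counts (>= 5).
#' @param baseline_hazard Baseline event rate per unit time.
#' @param hazard_ratios Per-group hazard ratios (1 = baseline); recycled
#'   to the number of groups.
#' @param censoring_target Overall censored fraction to aim for, in
#'   \[0, 1).
#' @param censoring_mechanism One of `"uniform"`, `"exponential"`,
#'   `"administrative"`.
#' @param horizon Follow-up horizon in the same time unit (used by the
#'   non-PH generator's time scale; months in the default designs).
#' @param seed Integer seed, or `NULL` to draw from the ambient stream.
#' @return A validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group_sizes, baseline_hazard = 0.02,
                        hazard_ratios = 1, censoring_target = 0,
                        censoring_mechanism = c("uniform", "exponential",
                                                "administrative"),
                        horizon = 100, seed = NULL) {
  censoring_mechanism <- match.arg(censoring_mechanism)
  k <- length(group_sizes)
  if (k < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (any(group_sizes < 5))
    stop("all group sizes must be at least 5", call. = FALSE)
  hazard_ratios <- rep_len(hazard_ratios, k)
  stopifnot(baseline_hazard > 0, all(hazard_ratios > 0),
            censoring_target >= 0, censoring_target < 1, horizon > 0)
  structure(list(group_sizes = as.integer(group_sizes),
                 baseline_hazard = baseline_hazard,
                 hazard_ratios = hazard_ratios,
                 censoring_target = censoring_target,
                 censoring_mechanism = censoring_mechanism,
                 horizon = horizon, seed = seed),
            class = "cohort_spec")
}

#' Simulate a proportional-hazards cohort
#'
#' Event times are exponential with rate `baseline_hazard *
#' hazard_ratio[g]` in group g; censoring is applied by
#' [apply_censoring()] with the spec's mechanism, calibrated so the
#' expected censored fraction equals the target.  The same spec and seed
#' always reproduce the same dataset.
#'
#' @param spec A [cohort_spec()].
#' @return A `survival_data` data frame.
#' @examples
#' d <- simulate_ph_cohort(cohort_spec(c(100, 100), hazard_ratios = c(1, 2),
#'                                     censoring_target = 0.3, seed = 7))
#' group_summaries(d)
#' @export
simulate_ph_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    k <- length(spec$group_sizes)
    times <- unlist(lapply(seq_len(k), function(g) {
      stats::rexp(spec$group_sizes[g],
                  rate = spec$baseline_hazard * spec$hazard_ratios[g])
    }))
    d <- survival_data(
      group = rep(paste0("G", seq_len(k)), spec$group_sizes),
      time = times, event = 1L)
    apply_censoring(d, spec$censoring_target, spec$censoring_mechanism,
                    seed = NULL)
  })
}

#' Censor a cohort of latent event times
#'
#' Interprets the input rows as fully observed latent event times, draws
#' an independent censoring time per record, and returns the observed
#' dataset (`time = min(T, C)`, `event = T <= C`).  The mechanism's
#' parameter (uniform upper bound, exponential rate, or administrative
#' cutoff) is solved numerically so that the expected censored fraction
#' equals `target`; censoring is independent of group and of the latent
#' time, so it is noninformative.
#'
#' @param data A dataset accepted by [as_survival_data()]; its times are
#'   treated as latent event times.
#' @param target Desired overall censored fraction in \[0, 1); 0 returns
#'   the data unchanged.
#' @param mechanism `"uniform"` (C ~ U(0, b)), `"exponential"`
#'   (C ~ Exp(theta)) or `"administrative"` (fixed cutoff).
#' @param seed Integer seed, or `NULL` to draw from the ambient stream.
#' @return A `survival_data` data frame of the same size.
#' @export
apply_censoring <- function(data, target,
                            mechanism = c("uniform", "exponential",
                                          "administrative"),
                            seed = NULL) {
  mechanism <- match.arg(mechanism)
  data <- as_survival_data(data)
  stopifnot(target >= 0, target < 1)
  if (target == 0) return(data)
  t_lat <- data$time
  n <- length(t_lat)
  with_seed(seed, {
    if (mechanism == "administrative") {
      cutoff <- stats::quantile(t_lat, 1 - target, type = 1, names = FALSE)
      achieved <- mean(t_lat > cutoff)
      if (abs(achieved - target) > 0.05)
        stop("administrative censoring cannot reach target ", target,
             " (closest achievable: ", format(achieved), ")",
             call. = FALSE)
      cens <- rep(cutoff, n)
    } else {
      # expected censored fraction as a function of the mechanism
      # parameter, evaluated on the latent times
      f <- if (mechanism == "uniform") {
        function(b) mean(pmin(t_lat / b, 1)) - target
      } else {
        function(th) mean(1 - exp(-th * t_lat)) - target
      }
      tmax <- max(t_lat[t_lat > 0])
      bounds <- if (mechanism == "uniform") {
        c(tmax * 1e-8, tmax * 1e8)
      } else {
        c(1e-10 / tmax, 1e10 / tmax)
      }
      if (f(bounds[1]) * f(bounds[2]) > 0)
        stop("censoring calibration failed: target ", target,
             " unreachable for mechanism '", mechanism, "' (f(lo) = ",
             format(f(bounds[1]) + target), ", f(hi) = ",
             format(f(bounds[2]) + target), ")", call. = FALSE)
      par <- stats::uniroot(f, bounds, tol = 1e-10)$root
      cens <- if (mechanism == "uniform") stats::runif(n, 0, par)
              else stats::rexp(n, rate = par)
    }
    out <- data
    out$event <- as.integer(t_lat <= cens)
    out$time <- pmin(t_lat, cens)
    out
  })
}

#' Simulate a stream of null cohorts
#'
#' Generates cohorts with no true between-group differences under the
#' mixed design used by the Type I error study: half the cohorts have two
#' groups and the rest are split over three to five; per-group sizes are
#' drawn uniformly from `size_range`; every group in a cohort shares one
#' exponential event-time law; the overall censoring target is drawn
#' uniformly from `censoring_range`.
#'
#' @param n_cohorts Number of cohorts to generate.
#' @param seed Integer seed for the whole stream.
#' @param k_choices Candidate group counts beyond two (defaults 3:5).
#' @param size_range Per-group size range (inclusive).
#' @param censoring_range Range of the overall censoring target.
#' @param baseline_hazard Shared exponential event rate.
#' @param mechanism Censoring mechanism passed to [apply_censoring()].
#' @return A list of `survival_data` data frames.
#' @export
simulate_null_cohorts <- function(n_cohorts, seed = NULL,
                                  k_choices = 3:5,
                                  size_range = c(50, 1000),
                                  censoring_range = c(0.05, 0.75),
                                  baseline_hazard = 0.02,
                                  mechanism = "uniform") {
  stopifnot(n_cohorts >= 1)
  with_seed(seed, {
    lapply(seq_len(n_cohorts), function(i) {
      k <- if (stats::runif(1) < 0.5) 2L
           else k_choices[sample.int(length(k_choices), 1L)]
      sizes <- size_range[1] - 1L +
        sample.int(size_range[2] - size_range[1] + 1L, k, replace = TRUE)
      target <- stats::runif(1, censoring_range[1], censoring_range[2])
      simulate_ph_cohort(cohort_spec(
        sizes, baseline_hazard = baseline_hazard,
        hazard_ratios = 1, censoring_target = target,
        censoring_mechanism = mechanism, seed = NULL))
    })
  })
}

#' Simulate a crossing-survival-curves cohort
#'
#' A two-group design built to violate proportional hazards with crossing
#' Kaplan-Meier curves: group 1 has all its disease-related events before
#' 75 time units, group 2 all after 50; event times are uniform on those
#' windows.  Every seventh record, in generation order, has its event
#' replaced by an event of a second type, i.e. recoded as censored for
#' the event of interest.
#'
#' @param n_per_group Patients per group (>= 7).
#' @param horizon Follow-up horizon; group 2 events are uniform on
#'   (50, horizon).
#' @param seed Integer seed.
#' @return A `survival_data` data frame.
#' @export
simulate_crossing_cohort <- function(n_per_group, horizon = 100,
                                     seed = NULL) {
  stopifnot(n_per_group >= 7, horizon > 50)
  with_seed(seed, {
    t1 <- stats::runif(n_per_group, 0, 75)
    t2 <- stats::runif(n_per_group, 50, horizon)
    d <- survival_data(group = rep(c("G1", "G2"), each = n_per_group),
                       time = c(t1, t2), event = 1L)
    recode <- seq(7, nrow(d), by = 7)
    d$event[recode] <- 0L
    d
  })
}

#' Specification of a non-proportional-hazards cohort
#'
#' Extends [cohort_spec()] with a time-dependent hazard multiplier for
#' the second arm: arm A has constant hazard `baseline_hazard`, arm B has
#' hazard `baseline_hazard * exp(beta * (t / horizon - 1/2))`, which is
#' log-linear in time and crosses the baseline at mid-horizon, so the
#' hazards (and for moderate `beta` the survival curves) cross.
#' `beta = 0` degenerates to proportional hazards with ratio 1.
#'
#' @inheritParams cohort_spec
#' @param n_per_arm Patients in each of the two arms.
#' @param beta Log-linear time-interaction coefficient of arm B's hazard
#'   multiplier.
#' @return A validated list of class `c("nonph_spec", "cohort_spec")`.
#' @export
nonph_spec <- function(n_per_arm, baseline_hazard = 0.03, beta = 3,
                       censoring_target = 0,
                       censoring_mechanism = c("uniform", "exponential"),
                       horizon = 100, seed = NULL) {
  censoring_mechanism <- match.arg(censoring_mechanism)
  base <- cohort_spec(c(n_per_arm, n_per_arm),
                      baseline_hazard = baseline_hazard,
                      censoring_target = censoring_target,
                      censoring_mechanism = censoring_mechanism,
                      horizon = horizon, seed = seed)
  base$beta <- beta
  class(base) <- c("nonph_spec", "cohort_spec")
  base
}

#' Simulate a non-proportional-hazards cohort
#'
#' Arm A draws exponential event times at the baseline hazard; arm B
#' draws from the time-dependent hazard of [nonph_spec()] by inverse
#' transform on its closed-form cumulative hazard.  Censoring is then
#' applied by [apply_censoring()].
#'
#' @param spec A [nonph_spec()].
#' @return A `survival_data` data frame.
#' @export
simulate_nonph_cohort <- function(spec) {
  stopifnot(inherits(spec, "nonph_spec"))
  with_seed(spec$seed, {
    n <- spec$group_sizes[1]
    l0 <- spec$baseline_hazard
    H <- spec$horizon
    b <- spec$beta
    tA <- stats::rexp(n, rate = l0)
    u <- stats::runif(spec$group_sizes[2])
    tB <- if (b == 0) {
      -log(u) / l0
    } else {
      # Lambda_B(t) = (l0 H / b) e^{-b/2} (e^{b t / H} - 1); invert at -log u
      H / b * log(1 + (-log(u)) * b * exp(b / 2) / (l0 * H))
    }
    d <- survival_data(group = rep(c("A", "B"), spec$group_sizes),
                       time = c(tA, tB), event = 1L)
    apply_censoring(d, spec$censoring_target, spec$censoring_mechanism,
                    seed = NULL)
  })
}
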