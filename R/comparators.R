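#' Risk table at the pooled event times
#'
#' The shared substrate for the log-rank family: for every distinct pooled
#' event time, the number at risk and the number of events, per group and
#' pooled.
#'
#' @param data A dataset accepted by [as_survival_data()].
#' @return A list with `time` (ordered distinct event times), matrices
#'   `n_risk` and `n_event` (times x groups), vectors `n_pooled`,
#'   `d_pooled`, and `groups`.
#' @export
risk_table <- function(data) {
  data <- as_survival_data(data)
  groups <- sort(unique(data$group))
  tj <- sort(unique(data$time[data$event == 1L]))
  if (length(tj) == 0L) stop("no events in the dataset", call. = FALSE)
  n_risk <- vapply(groups, function(g) {
    tg <- sort(data$time[data$group == g])
    length(tg) - findInterval(tj, tg, left.open = TRUE)
  }, numeric(length(tj)))
  n_event <- vapply(groups, function(g) {
    dt <- data$time[data$group == g & data$event == 1L]
    tabulate(match(dt, tj), nbins = length(tj))
  }, numeric(length(tj)))
  n_risk <- matrix(n_risk, nrow = length(tj),
                   dimnames = list(NULL, groups))
  n_event <- matrix(n_event, nrow = length(tj),
                    dimnames = list(NULL, groups))
  list(time = tj, n_risk = n_risk, n_event = n_event,
       n_pooled = rowSums(n_risk), d_pooled = rowSums(n_event),
       groups = groups)
}

# Observed minus expected events per group and its covariance matrix,
# from the hypergeometric conditional law at each event time, with an
# optional weight per event time.
logrank_moments <- function(rt, w = NULL) {
  if (is.null(w)) w <- rep(1, length(rt$time))
  P <- rt$n_risk / rt$n_pooled                     # at-risk proportions
  OE <- colSums(w * (rt$n_event - rt$d_pooled * P))
  cj <- rt$d_pooled * (rt$n_pooled - rt$d_pooled) /
    pmax(rt$n_pooled - 1, 1)
  cj[rt$n_pooled <= 1] <- 0
  cw <- w^2 * cj
  V <- diag(colSums(cw * P), ncol(P)) - t(P) %*% (cw * P)
  dimnames(V) <- list(rt$groups, rt$groups)
  list(OE = OE, V = V)
}

# Solve u' V^{-1} u on the first k-1 coordinates, falling back to a
# pseudoinverse when the reduced covariance is singular.
quad_form_stat <- function(OE, V) {
  k <- length(OE)
  u <- OE[-k]
  Vr <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(crossprod(u, solve(Vr, u))),
                   error = function(e) NA_real_)
  if (is.na(stat)) {
    s <- svd(Vr)
    pos <- s$d > max(s$d[1], 1) * 1e-12
    stat <- drop(crossprod(u, s$v[, pos, drop = FALSE] %*%
                   ((1 / s$d[pos]) * crossprod(s$u[, pos, drop = FALSE], u))))
  }
  max(stat, 0)
}

#' k-sample log-rank test
#'
#' The standard log-rank test: observed minus expected events per group at
#' each pooled event time, with the hypergeometric covariance, compared to
#' a chi-squared distribution on k - 1 degrees of freedom.
#'
#' @inheritParams ears_test
#' @return An `"ears_htest"` object with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @export
logrank_test <- function(x, ...) UseMethod("logrank_test")

#' @rdname logrank_test
#' @export
logrank_test.formula <- function(x, data, ...) {
  out <- logrank_test.data.frame(data_from_formula(x, data), ...)
  out$data.name <- deparse(x)
  out
}

#' @rdname logrank_test
#' @export
logrank_test.data.frame <- function(x, ...) {
  dname <- deparse(substitute(x))
  data <- as_survival_data(x)
  if (length(unique(data$group)) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  rt <- risk_table(data)
  m <- logrank_moments(rt)
  k <- length(rt$groups)
  stat <- quad_form_stat(m$OE, m$V)
  out <- list(statistic = c("chi-squared" = stat),
              parameter = c(df = k - 1L),
              p.value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
              observed_minus_expected = m$OE,
              method = "Log-rank test", data.name = dname)
  class(out) <- "ears_htest"
  out
}

#' Log-rank test for trend across ordered groups
#'
#' A 1-df contrast of the log-rank observed-minus-expected vector against
#' ordered group scores, for three or more ordered groups.  With two
#' groups it reduces to the plain log-rank test.
#'
#' @inheritParams ears_test
#' @param scores Numeric scores, one per group in sorted label order;
#'   defaults to equally spaced integers `1:k`.
#' @return An `"ears_htest"` object with a 1-df chi-squared statistic.
#' @export
logrank_trend_test <- function(x, ...) UseMethod("logrank_trend_test")

#' @rdname logrank_trend_test
#' @export
logrank_trend_test.formula <- function(x, data, scores = NULL, ...) {
  out <- logrank_trend_test.data.frame(data_from_formula(x, data),
                                       scores = scores, ...)
  out$data.name <- deparse(x)
  out
}

#' @rdname logrank_trend_test
#' @export
logrank_trend_test.data.frame <- function(x, scores = NULL, ...) {
  dname <- deparse(substitute(x))
  data <- as_survival_data(x)
  k <- length(unique(data$group))
  if (k < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (is.null(scores)) scores <- seq_len(k)
  if (length(scores) != k)
    stop("scores must have one entry per group (", k, ")", call. = FALSE)
  rt <- risk_table(data)
  m <- logrank_moments(rt)
  U <- sum(scores * m$OE)
  V <- drop(crossprod(scores, m$V %*% scores))
  stat <- if (V > 0) U^2 / V else 0
  out <- list(statistic = c("chi-squared" = stat), parameter = c(df = 1L),
              p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
              scores = scores, method = "Log-rank test for trend",
              data.name = dname)
  class(out) <- "ears_htest"
  out
}

# Two-group Fleming-Harrington weighted log-rank z statistic from a risk
# table; weight S(t-)^rho (1 - S(t-))^gamma with S the pooled KM left
# limit (S(t-) = 1 at the first event time).
wlrt_z <- function(rt, rho, gamma) {
  S_left <- c(1, cumprod(1 - rt$d_pooled / rt$n_pooled))
  S_left <- S_left[seq_along(rt$time)]
  w <- S_left^rho * (1 - S_left)^gamma
  p1 <- rt$n_risk[, 1] / rt$n_pooled
  U <- sum(w * (rt$n_event[, 1] - rt$d_pooled * p1))
  vj <- p1 * (1 - p1) * rt$d_pooled * (rt$n_pooled - rt$d_pooled) /
    pmax(rt$n_pooled - 1, 1)
  vj[rt$n_pooled <= 1] <- 0
  V <- sum(w^2 * vj)
  if (V <= 0) return(0)
  U / sqrt(V)
}

#' Fleming-Harrington weighted log-rank test (two groups)
#'
#' Weights the log-rank increments by `S(t-)^rho * (1 - S(t-))^gamma`,
#' where `S` is the pooled Kaplan-Meier estimate evaluated just before
#' each event time.  `(rho, gamma) = (0, 0)` recovers the plain log-rank
#' test; `(1, 0)` stresses early differences, `(0, 1)` late differences,
#' and `(1, 1)` mid-follow-up differences.
#'
#' @inheritParams ears_test
#' @param rho,gamma Nonnegative Fleming-Harrington weight exponents.
#' @return An `"ears_htest"` object carrying the standardized statistic
#'   `z`, the 1-df chi-squared p value and the weights used.
#' @export
weighted_logrank_test <- function(x, ...) UseMethod("weighted_logrank_test")

#' @rdname weighted_logrank_test
#' @export
weighted_logrank_test.formula <- function(x, data, rho = 0, gamma = 0, ...) {
  out <- weighted_logrank_test.data.frame(data_from_formula(x, data),
                                          rho = rho, gamma = gamma, ...)
  out$data.name <- deparse(x)
  out
}

#' @rdname weighted_logrank_test
#' @export
weighted_logrank_test.data.frame <- function(x, rho = 0, gamma = 0, ...) {
  dname <- deparse(substitute(x))
  if (rho < 0 || gamma < 0)
    stop("rho and gamma must be nonnegative", call. = FALSE)
  data <- as_survival_data(x)
  if (length(unique(data$group)) != 2L)
    stop("the weighted log-rank test is implemented for exactly 2 groups",
         call. = FALSE)
  rt <- risk_table(data)
  z <- wlrt_z(rt, rho, gamma)
  out <- list(statistic = c(z = z), parameter = c(df = 1L),
              p.value = stats::pchisq(z^2, 1L, lower.tail = FALSE),
              rho = rho, gamma = gamma,
              method = sprintf(
                "Fleming-Harrington G(%g,%g) weighted log-rank test",
                rho, gamma),
              data.name = dname)
  class(out) <- "ears_htest"
  out
}

#' MaxCombo test with a permutation null distribution
#'
#' Takes the maximum of the absolute standardized Fleming-Harrington
#' statistics over a set of (rho, gamma) weights and calibrates it by
#' permuting the group labels: under the null the labels are
#' exchangeable, so the permutation distribution of the joint maximum is
#' exact up to Monte-Carlo error.  The p value uses the add-one
#' correction `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @inheritParams ears_test
#' @param weights A list of length-2 numeric vectors `c(rho, gamma)`;
#'   the default spans plain, early, mid and late weighting.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return An `"ears_htest"` object with the observed maximum `z`, the
#'   permutation p value, and the per-weight z statistics.
#' @export
maxcombo_test <- function(x, ...) UseMethod("maxcombo_test")

#' @rdname maxcombo_test
#' @export
maxcombo_test.formula <- function(x, data, ...) {
  out <- maxcombo_test.data.frame(data_from_formula(x, data), ...)
  out$data.name <- deparse(x)
  out
}

#' @rdname maxcombo_test
#' @export
maxcombo_test.data.frame <- function(x,
    weights = list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    n_perm = 1000, seed = 1, ...) {
  dname <- deparse(substitute(x))
  if (length(weights) == 0L) stop("empty weight set", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  data <- as_survival_data(x)
  if (length(unique(data$group)) != 2L)
    stop("the MaxCombo test is implemented for exactly 2 groups",
         call. = FALSE)
  max_abs_z <- function(d) {
    rt <- risk_table(d)
    vapply(weights, function(w) wlrt_z(rt, w[1], w[2]), numeric(1))
  }
  z_obs <- max_abs_z(data)
  stat <- max(abs(z_obs))
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      d <- data
      d$group <- sample(d$group)
      max(abs(max_abs_z(d)))
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= stat)) / (1 + n_perm)
  out <- list(statistic = c("max |z|" = stat), parameter = NULL,
              p.value = p, z = z_obs, weights = weights,
              n_perm = n_perm, seed = seed,
              method = "MaxCombo test (permutation null)",
              data.name = dname)
  class(out) <- "ears_htest"
  out
}

# Kaplan-Meier step function of one group: times, survival, and the
# per-event-time Greenwood increments d/(n(n-d)).
km_components <- function(time, event) {
  f <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- f$n.event > 0
  list(time = f$time[keep], surv = f$surv[keep],
       n_risk = f$n.risk[keep], n_event = f$n.event[keep])
}

# Area under a KM step curve on [0, tau] plus its Greenwood-based
# variance (the plug-in form used by standard RMST software).
rmst_one <- function(time, event, tau) {
  km <- km_components(time, event)
  idx <- km$time <= tau
  t_i <- km$time[idx]
  s_i <- km$surv[idx]
  steps <- diff(c(0, t_i, tau))
  surv_left <- c(1, s_i)                 # survival on each interval
  est <- sum(steps * surv_left)
  a <- rev(cumsum(rev(steps[-1] * surv_left[-1])))  # area from t_i to tau
  d <- km$n_event[idx]
  n <- km$n_risk[idx]
  gw <- ifelse(n - d > 0, d / (n * (n - d)), 0)
  list(rmst = est, var = sum(a^2 * gw))
}

#' Restricted mean survival time difference test (two groups)
#'
#' Estimates each group's restricted mean survival time (the area under
#' its Kaplan-Meier curve up to a truncation time tau) with a
#' Greenwood-based variance, and compares the two arms with a two-sided z
#' test on the difference.  When `tau` is not supplied it defaults to the
#' minimum across groups of the largest observed event time, so both
#' curves are supported on the whole window.
#'
#' @inheritParams ears_test
#' @param tau Truncation time; must not exceed any group's last observed
#'   time.
#' @return An object of class `c("rmst_test", "ears_htest")` with the per
#'   group estimates and variances, the difference (first group minus
#'   second, in sorted label order), `tau`, `statistic` (z) and `p.value`.
#' @export
rmst_difference_test <- function(x, ...) UseMethod("rmst_difference_test")

#' @rdname rmst_difference_test
#' @export
rmst_difference_test.formula <- function(x, data, tau = NULL, ...) {
  out <- rmst_difference_test.data.frame(data_from_formula(x, data),
                                         tau = tau, ...)
  out$data.name <- deparse(x)
  out
}

#' @rdname rmst_difference_test
#' @export
rmst_difference_test.data.frame <- function(x, tau = NULL, ...) {
  dname <- deparse(substitute(x))
  data <- as_survival_data(x)
  groups <- sort(unique(data$group))
  if (length(groups) != 2L)
    stop("the RMST difference test is implemented for exactly 2 groups",
         call. = FALSE)
  if (is.null(tau)) {
    max_event <- vapply(groups, function(g) {
      te <- data$time[data$group == g & data$event == 1L]
      if (length(te) == 0L)
        stop("group ", g, " has no events; supply tau explicitly",
             call. = FALSE)
      max(te)
    }, numeric(1))
    tau <- min(max_event)
  }
  last_obs <- vapply(groups, function(g) max(data$time[data$group == g]),
                     numeric(1))
  if (any(tau > last_obs))
    stop("tau = ", format(tau), " exceeds the last observed time of ",
         "group(s): ", paste(groups[tau > last_obs], collapse = ", "),
         call. = FALSE)
  per <- lapply(groups, function(g) {
    d <- data[data$group == g, ]
    rmst_one(d$time, d$event, tau)
  })
  est <- vapply(per, `[[`, numeric(1), "rmst")
  v <- vapply(per, `[[`, numeric(1), "var")
  diff <- est[1] - est[2]
  se <- sqrt(v[1] + v[2])
  z <- if (se > 0) diff / se else 0
  out <- list(statistic = c(z = z), parameter = NULL,
              p.value = 2 * stats::pnorm(-abs(z)),
              tau = tau,
              rmst = stats::setNames(est, groups),
              rmst_var = stats::setNames(v, groups),
              difference = diff, se = se,
              method = sprintf(
                "Restricted mean survival time difference test (tau = %g)",
                tau),
              data.name = dname)
  class(out) <- c("rmst_test", "ears_htest")
  out
}
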