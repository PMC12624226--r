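test_that("risk table counts are consistent and monotone", {
  rt <- risk_table(toy_cohort())
  expect_true(all(diff(rt$time) > 0))
  expect_true(all(apply(rt$n_risk, 2, function(x) all(diff(x) <= 0))))
  expect_true(all(rt$n_event <= rt$n_risk))
  expect_equal(rt$n_pooled, rowSums(rt$n_risk))
})

test_that("log-rank matches a hand-computed observed-minus-expected table", {
  # {1,2,3} all events in A vs {4,5,6} all events in B: at each of A's
  # event times both arms are fully at risk until A shrinks.
  # t=1: n=(3,3), d_A=1, E_A=1/2, V=1/4*(4/5)... accumulate directly:
  d <- separated_cohort()
  rt <- risk_table(d)
  OE <- 0; V <- 0
  for (j in seq_along(rt$time)) {
    n1 <- rt$n_risk[j, 1]; n <- rt$n_pooled[j]; dd <- rt$d_pooled[j]
    OE <- OE + rt$n_event[j, 1] - dd * n1 / n
    if (n > 1) V <- V + dd * (n - dd) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  lr <- logrank_test(d)
  expect_equal(unname(lr$statistic), unname(OE^2 / V), tolerance = 1e-12)
  expect_identical(unname(lr$parameter), 1L)
})

test_that("log-rank agrees with survival::survdiff on random datasets", {
  for (i in 1:30) {
    k <- sample(2:4, 1)
    set.seed(500 + i)
    n <- sample(20:60, 1)
    d <- survival_data(rep(paste0("g", 1:k), each = n),
                       rexp(k * n, rep(runif(k, 0.02, 0.08), each = n)),
                       rbinom(k * n, 1, 0.8))
    mine <- logrank_test(d)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group,
                              data = d)
    expect_equal(unname(mine$statistic), unname(ref$chisq),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is symmetric and rank-invariant", {
  d <- toy_cohort()
  same <- survival_data(rep(c("A", "B"), each = 4),
                        rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  expect_equal(unname(logrank_test(same)$statistic), 0)
  expect_equal(logrank_test(same)$p.value, 1)
  scaled <- d; scaled$time <- d$time * 1000
  expect_equal(logrank_test(scaled)$p.value, logrank_test(d)$p.value)
})

test_that("trend test reduces to log-rank for 2 groups and ignores score flips", {
  d <- random_cohort(n = 40, seed = 21, hr = 1.5, p_event = 0.8)
  expect_equal(logrank_trend_test(d, scores = c(1, 2))$p.value,
               logrank_test(d)$p.value, tolerance = 1e-10)
  set.seed(77)
  d3 <- survival_data(rep(c("a", "b", "c"), each = 30),
                      rexp(90, rep(c(0.02, 0.03, 0.05), each = 30)),
                      rbinom(90, 1, 0.8))
  up <- logrank_trend_test(d3, scores = 1:3)
  down <- logrank_trend_test(d3, scores = 3:1)
  expect_equal(up$p.value, down$p.value, tolerance = 1e-12)
  expect_error(logrank_trend_test(d3, scores = 1:2), "scores")
  # three identical groups: statistic 0
  same3 <- survival_data(rep(c("a", "b", "c"), each = 4),
                         rep(c(1, 2, 3, 4), 3), 1)
  expect_equal(unname(logrank_trend_test(same3)$statistic), 0)
})

test_that("weighted log-rank with unit weights is exactly the log-rank", {
  for (i in 1:100) {
    d <- random_cohort(n = 25, seed = 600 + i, hr = runif(1, 0.7, 1.5),
                       p_event = 0.8)
    w <- weighted_logrank_test(d, 0, 0)
    lr <- logrank_test(d)
    expect_equal(unname(w$statistic)^2, unname(lr$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Fleming-Harrington weights match a brute-force weighted sum", {
  d <- toy_cohort()
  rt <- risk_table(d)
  # pooled KM left limit, computed directly
  S <- cumprod(1 - rt$d_pooled / rt$n_pooled)
  S_left <- c(1, S[-length(S)])
  for (w in list(c(1, 0), c(1, 1), c(0, 1))) {
    wt <- S_left^w[1] * (1 - S_left)^w[2]
    U <- sum(wt * (rt$n_event[, 1] - rt$d_pooled * rt$n_risk[, 1] /
                     rt$n_pooled))
    p1 <- rt$n_risk[, 1] / rt$n_pooled
    V <- sum(wt^2 * p1 * (1 - p1) * rt$d_pooled *
               (rt$n_pooled - rt$d_pooled) / pmax(rt$n_pooled - 1, 1))
    z <- U / sqrt(V)
    got <- weighted_logrank_test(d, w[1], w[2])
    expect_equal(unname(got$statistic), z, tolerance = 1e-12)
  }
  expect_error(weighted_logrank_test(d, -1, 0), "nonnegative")
})

test_that("weighted log-rank is zero on identical groups for any weights", {
  same <- survival_data(rep(c("A", "B"), each = 5),
                        rep(c(1, 3, 5, 7, 9), 2), rep(c(1, 1, 1, 0, 1), 2))
  for (w in list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
    expect_equal(unname(weighted_logrank_test(same, w[1], w[2])$statistic),
                 0)
})

test_that("MaxCombo permutation p agrees with exhaustive relabeling on a
          6-patient cohort", {
  d <- survival_data(rep(c("A", "B"), each = 3),
                     c(1, 4, 6, 2, 3, 9), c(1, 1, 0, 1, 1, 1))
  weights <- list(c(0, 0), c(0, 1))
  obs <- max(abs(vapply(weights, function(w)
    earstest:::wlrt_z(risk_table(d), w[1], w[2]), numeric(1))))
  # enumerate all 20 assignments of 3 labels A among 6 patients
  combos <- utils::combn(6, 3)
  exact <- mean(apply(combos, 2, function(idx) {
    dd <- d
    dd$group <- ifelse(seq_len(6) %in% idx, "A", "B")
    m <- max(abs(vapply(weights, function(w)
      earstest:::wlrt_z(risk_table(dd), w[1], w[2]), numeric(1))))
    m >= obs - 1e-12
  }))
  mc <- maxcombo_test(d, weights = weights, n_perm = 2000, seed = 5)
  # permutation estimate within Monte-Carlo tolerance of the exact value
  expect_lt(abs(mc$p.value - exact), 3 * sqrt(exact * (1 - exact) / 2000) +
              2 / 2000)
})

test_that("MaxCombo is near 1 on identical groups and handles singletons", {
  same <- survival_data(rep(c("A", "B"), each = 10),
                        rep(c(1:9, 12), 2), 1)
  mc <- maxcombo_test(same, n_perm = 1000, seed = 3)
  expect_gte(mc$p.value, 0.5)
  single <- maxcombo_test(random_cohort(n = 20, seed = 9),
                          weights = list(c(0, 0)), n_perm = 500, seed = 2)
  expect_true(single$p.value > 0 && single$p.value <= 1)
  expect_error(maxcombo_test(same, weights = list()), "weight set")
})

test_that("RMST closed forms: no censoring means truncated sample means", {
  expect_equal(earstest:::rmst_one(c(1, 2, 3), c(1, 1, 1), 3)$rmst, 2)
  set.seed(12)
  t1 <- rexp(80, 0.05); t2 <- rexp(80, 0.05)
  d <- survival_data(rep(c("A", "B"), each = 80), c(t1, t2), 1)
  tau <- min(max(t1), max(t2))
  r <- rmst_difference_test(d, tau = tau)
  expect_equal(unname(r$rmst["A"]), mean(pmin(t1, tau)), tolerance = 1e-10)
  expect_equal(unname(r$rmst["B"]), mean(pmin(t2, tau)), tolerance = 1e-10)
})

test_that("the default truncation is the smaller of the groups' largest
          event times", {
  d <- survival_data(c("A", "A", "A", "B", "B", "B"),
                     c(10, 80, 95, 20, 90, 99),
                     c(1, 1, 0, 1, 1, 0))  # max event: A 80, B 90
  r <- rmst_difference_test(d)
  expect_equal(r$tau, 80)
  expect_error(rmst_difference_test(d, tau = 100), "exceeds")
})

test_that("RMST difference is 0 with p = 1 on identical groups", {
  same <- survival_data(rep(c("A", "B"), each = 5),
                        rep(c(1, 3, 5, 7, 9), 2), rep(c(1, 1, 1, 0, 1), 2))
  r <- rmst_difference_test(same)
  expect_equal(r$difference, 0)
  expect_equal(r$p.value, 1)
})

test_that("RMST variance tracks the Monte-Carlo variance of the estimate", {
  reps <- 400
  out <- earstest:::with_seed(42, {
    vapply(seq_len(reps), function(i) {
      t <- rexp(150, 0.04)
      c <- runif(150, 0, 60)
      r <- earstest:::rmst_one(pmin(t, c), as.numeric(t <= c), 25)
      c(r$rmst, r$var)
    }, numeric(2))
  })
  empirical <- var(out[1, ])
  expect_equal(mean(out[2, ]), empirical, tolerance = 0.2)
})

test_that("log-rank family is invariant under monotone time transforms;
          RMST is not", {
  d <- random_cohort(n = 50, seed = 55, hr = 1.4, p_event = 0.7)
  cubed <- d; cubed$time <- d$time^3
  expect_equal(logrank_test(cubed)$p.value, logrank_test(d)$p.value)
  expect_equal(weighted_logrank_test(cubed, 1, 1)$p.value,
               weighted_logrank_test(d, 1, 1)$p.value)
  r1 <- rmst_difference_test(d); r2 <- rmst_difference_test(cubed)
  expect_false(isTRUE(all.equal(r1$p.value, r2$p.value)))
  # the event-proportion divisor acts on the original time scale, so the
  # adjusted-rank test shares scale invariance (tested elsewhere) but not
  # invariance under nonlinear monotone transforms
  expect_false(isTRUE(all.equal(ears_test(cubed)$p.value,
                                ears_test(d)$p.value)))
})
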