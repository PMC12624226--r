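test_that("adjusted times divide event times by the group event proportion", {
  ast <- adjusted_survival_times(toy_cohort())
  # group A: proportion 0.5 so times 1,2 become 2,4; B: proportion 1
  expect_equal(ast$ast[ast$group == "A"], c(2, 4))
  expect_equal(ast$ast[ast$group == "B"], c(2, 4, 6, 8))
  # censored records have no entry
  expect_identical(nrow(ast), 6L)
  # mid-ranks over the pooled entries sum to M(M+1)/2
  expect_equal(sum(ast$rank), 6 * 7 / 2)
})

test_that("a group with zero events is a hard error naming the group", {
  d <- survival_data(c("A", "A", "B", "B"), c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_error(adjusted_survival_times(d), "A")
  expect_error(ears_test(d), "zero events")
})

test_that("within-group AST order equals within-group event-time order", {
  set.seed(11)
  for (i in 1:20) {
    d <- random_cohort(n = 30, seed = i, p_event = 0.6)
    ast <- adjusted_survival_times(d)
    for (g in unique(ast$group)) {
      sub <- ast[ast$group == g, ]
      expect_identical(order(sub$ast), order(sub$time))
    }
  }
})

test_that("rank statistic matches a frozen hand-computed case and the stock
          Kruskal-Wallis on random data", {
  # {1,2,3} vs {4,5,6}: rank sums 6 and 15, H = 12/(6*7)*(36/3+225/3)-3*7
  kw <- ast_kruskal_wallis(separated_cohort())
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_identical(kw$df, 1L)
  expect_equal(kw$p.value, 0.04953461, tolerance = 1e-6)

  for (i in 1:25) {
    d <- random_cohort(n = 25, seed = 100 + i, p_event = 0.7)
    ast <- adjusted_survival_times(d)
    ref <- stats::kruskal.test(ast$ast, factor(ast$group))
    kw <- ast_kruskal_wallis(ast)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("identical AST multisets give H = 0 and three groups give df 2", {
  d <- survival_data(rep(c("A", "B"), each = 3), rep(c(1, 2, 3), 2), 1)
  kw <- ast_kruskal_wallis(adjusted_survival_times(d))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)

  d3 <- survival_data(rep(c("A", "B", "C"), each = 4), rexp(12) + 1, 1)
  expect_identical(ast_kruskal_wallis(adjusted_survival_times(d3))$df, 2L)
})

test_that("censoring adjustment follows the divisor rule with a cap at 1", {
  expect_equal(censoring_adjustment(0.10, 0.5), 0.20)
  expect_equal(censoring_adjustment(0.37, 0), 0.37)
  expect_equal(censoring_adjustment(0.60, 0.5), 1.0)
  expect_error(censoring_adjustment(0.5, 1), "censor_proportion")
  # monotone nondecreasing in the censored fraction
  cs <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(censoring_adjustment(0.04, cs)) >= 0))
})

test_that("EARS p is the penalized Kruskal-Wallis p, never smaller", {
  for (i in 1:20) {
    d <- random_cohort(n = 40, seed = 200 + i, p_event = 0.7)
    e <- suppressWarnings(ears_test(d))
    expect_gte(e$p.value, e$p.kruskal_wallis)
    expect_equal(e$p.value,
                 min(1, e$p.kruskal_wallis / (1 - e$censor_proportion)))
  }
  # no censoring: penalty is the identity
  d0 <- random_cohort(n = 40, seed = 3, p_event = 1)
  e0 <- ears_test(d0)
  expect_identical(e0$censor_proportion, 0)
  expect_identical(e0$p.value, e0$p.kruskal_wallis)
})

test_that("EARS warns on fewer than five events per group and needs 2 groups", {
  d <- survival_data(rep(c("A", "B"), each = 10),
                     time = 1:20,
                     event = c(rep(1, 3), rep(0, 7), rep(1, 10)))
  expect_warning(ears_test(d), "fewer than 5")
  one <- survival_data(rep("A", 10), 1:10, 1)
  expect_error(ears_test(one), "2 groups")
})

test_that("relabeling groups and rescaling time leave the test unchanged", {
  d <- random_cohort(n = 50, seed = 31, hr = 1.6, p_event = 0.7)
  e1 <- ears_test(d)

  relabeled <- d
  relabeled$group <- ifelse(d$group == "A", "zebra", "aardvark")
  e2 <- ears_test(relabeled)
  expect_equal(unname(e2$statistic), unname(e1$statistic))
  expect_equal(e2$p.value, e1$p.value)

  scaled <- d
  scaled$time <- d$time * 12  # months to years does not change ranks
  e3 <- ears_test(scaled)
  expect_equal(unname(e3$statistic), unname(e1$statistic))
  expect_equal(e3$p.value, e1$p.value)
})

test_that("duplicating every record preserves event proportions and ASTs", {
  d <- random_cohort(n = 25, seed = 17, p_event = 0.7)
  doubled <- as_survival_data(rbind(as.data.frame(d), as.data.frame(d)))
  expect_equal(group_summaries(doubled)$event_proportion,
               group_summaries(d)$event_proportion)
  expect_equal(sort(unique(adjusted_survival_times(doubled)$ast)),
               sort(unique(adjusted_survival_times(d)$ast)))
})

test_that("for two groups H equals the squared standardized rank-sum statistic", {
  for (i in 1:100) {
    set.seed(400 + i)
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    d <- survival_data(rep(c("A", "B"), c(n1, n2)),
                       round(rexp(n1 + n2), 2) + 0.01, 1)
    ast <- adjusted_survival_times(d)
    kw <- ast_kruskal_wallis(ast)
    # standardized two-sample rank-sum with mid-ranks and ties correction
    r <- rank(ast$ast)
    M <- length(r)
    R1 <- sum(r[ast$group == "A"])
    m <- n1 * (M + 1) / 2
    ties <- table(ast$ast)
    v <- n1 * n2 / 12 * (M + 1 - sum(ties^3 - ties) / (M * (M - 1)))
    z2 <- (R1 - m)^2 / v
    expect_equal(kw$statistic, z2, tolerance = 1e-8)
  }
})

test_that("formula interface agrees with the data-frame interface", {
  d <- random_cohort(n = 40, seed = 8, p_event = 0.8)
  e1 <- ears_test(d)
  e2 <- ears_test(survival::Surv(time, event) ~ group, data = d)
  expect_equal(e2$p.value, e1$p.value)
  expect_equal(unname(e2$statistic), unname(e1$statistic))
})

test_that("EARS p values are uniform under the null without censoring", {
  # no censoring: divisor 1, so the penalty is inert and p should be ~U(0,1)
  p <- earstest:::with_seed(99, {
    vapply(1:2000, function(i) {
      d <- survival_data(rep(c("A", "B"), each = 100), rexp(200, 0.02), 1)
      ears_test(d)$p.value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))  # 1% critical value
})

test_that("zero follow-up with an event yields AST 0 and a finite test", {
  d <- survival_data(rep(c("A", "B"), each = 6),
                     c(0, 1:5, 2:7), 1)
  ast <- adjusted_survival_times(d)
  expect_equal(min(ast$ast), 0)
  expect_true(is.finite(ears_test(d)$p.value))
})
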