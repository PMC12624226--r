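#' Adjusted survival times
#'
#' Computes the event-adjusted survival time for every record that
#' experienced the event of interest: the observed time divided by the
#' event proportion of the record's group.  Censored records receive no
#' adjusted time — they contribute only through the group event
#' proportion.  Because the divisor is constant within a group, the
#' ordering of adjusted times within a group equals the ordering of the
#' original event times; across groups the adjustment shifts a
#' low-incidence group's events towards larger values, so that incidence
#' and timing are compared jointly when all adjusted times are pooled and
#' ranked.
#'
#' @param data A dataset accepted by [as_survival_data()].
#' @return An object of class `"ast_table"`: a data frame with one row per
#'   event record and columns `group`, `time`, `ast` (adjusted time) and
#'   `rank` (mid-rank of `ast` in the pooled table), with the per-group
#'   event counts in attribute `"group_sizes"`.
#' @examples
#' d <- survival_data(rep(c("A", "B"), each = 4),
#'                    time = c(1, 2, 3, 4, 2, 4, 6, 8),
#'                    event = c(1, 1, 0, 0, 1, 1, 1, 1))
#' adjusted_survival_times(d)  # group A divisor 0.5, group B divisor 1
#' @export
adjusted_survival_times <- function(data) {
  data <- as_survival_data(data)
  gs <- group_summaries(data)
  zero <- gs$group[gs$n_events == 0L]
  if (length(zero))
    stop("group(s) with zero events: ", paste(zero, collapse = ", "),
         "; adjusted survival times require at least one event per group",
         call. = FALSE)
  ev <- data[data$event == 1L, , drop = FALSE]
  prop <- gs$event_proportion[match(ev$group, gs$group)]
  out <- data.frame(group = ev$group, time = ev$time,
                    ast = ev$time / prop, stringsAsFactors = FALSE)
  out$rank <- rank(out$ast)  # mid-ranks for ties
  attr(out, "group_sizes") <- stats::setNames(gs$n_events, gs$group)
  class(out) <- c("ast_table", "data.frame")
  out
}

#' Kruskal-Wallis rank statistic on adjusted survival times
#'
#' The k-sample rank statistic at the heart of the EARS test: pooled
#' mid-ranks of the adjusted times, rank sums per group, the H statistic
#' with the standard ties correction, and an upper-tail chi-squared p
#' value on k - 1 degrees of freedom.
#'
#' @param ast An `"ast_table"` from [adjusted_survival_times()], or a
#'   dataset accepted by [as_survival_data()] (converted first).
#' @return A list of class `"kw_result"` with elements `statistic` (H),
#'   `df`, and `p.value`.
#' @export
ast_kruskal_wallis <- function(ast) {
  if (!inherits(ast, "ast_table")) ast <- adjusted_survival_times(ast)
  groups <- unique(ast$group)
  k <- length(groups)
  if (k < 2L)
    stop("at least 2 groups are required for a between-group test",
         call. = FALSE)
  M <- nrow(ast)
  r <- rank(ast$ast)
  Rsum <- vapply(groups, function(g) sum(r[ast$group == g]), numeric(1))
  nj <- vapply(groups, function(g) sum(ast$group == g), numeric(1))
  H <- 12 / (M * (M + 1)) * sum(Rsum^2 / nj) - 3 * (M + 1)
  ties <- table(ast$ast)
  corr <- 1 - sum(ties^3 - ties) / (M^3 - M)
  H <- if (corr > 0) H / corr else 0  # all values tied: no discrimination
  out <- list(statistic = H, df = k - 1L,
              p.value = stats::pchisq(H, k - 1L, lower.tail = FALSE))
  class(out) <- "kw_result"
  out
}

#' Censoring penalty on a rank-test p value
#'
#' Divides a p value by one minus the overall censored fraction, capping
#' the result at 1.  With no censoring the p value is unchanged; with 50%
#' censoring it doubles.  The penalty makes the test conservative on
#' heavily censored data, where the ranked events carry less of the
#' cohort's information.
#'
#' @param p A p value in \[0, 1\].
#' @param censor_proportion Overall censored fraction, in \[0, 1).
#' @return The penalized p value, `min(1, p / (1 - censor_proportion))`.
#' @examples
#' censoring_adjustment(0.10, 0.5)  # 0.20
#' @export
censoring_adjustment <- function(p, censor_proportion) {
  stopifnot(is.numeric(p), p >= 0, p <= 1, is.numeric(censor_proportion))
  if (any(censor_proportion < 0) || any(censor_proportion >= 1))
    stop("censor_proportion must lie in [0, 1): a fully censored dataset ",
         "has no events to rank", call. = FALSE)
  pmin(1, p / (1 - censor_proportion))
}

#' Event-adjusted rank sum (EARS) test
#'
#' A nonparametric k-sample test of survival distributions that does not
#' require proportional hazards.  Each event time is divided by the event
#' proportion of its group; the adjusted times are pooled, ranked, and
#' compared with the Kruskal-Wallis H statistic (chi-squared on k - 1
#' degrees of freedom); the resulting p value is divided by one minus the
#' overall censored fraction (capped at 1).  A low-incidence group with
#' late events is thereby separated from a high-incidence group with the
#' same event times, and heavy censoring pushes the test towards
#' conservatism rather than anticonservatism.
#'
#' Every group must contain at least one event; with fewer than five
#' events in a group the chi-squared approximation is doubtful and a
#' warning is issued.
#'
#' @param x A dataset accepted by [as_survival_data()], or a model formula
#'   `survival::Surv(time, event) ~ group`.
#' @param data For the formula method, the data frame in which to evaluate
#'   the formula.
#' @param ... Unused.
#' @return An object of class `c("ears_test", "ears_htest")` with elements
#'   `statistic` (the H statistic), `parameter` (df), `p.value` (the
#'   censoring-penalized EARS p), `p.kruskal_wallis` (the unpenalized p),
#'   `censor_proportion`, `summaries` (per-group counts), `ast` (the
#'   adjusted-time table), `method` and `data.name`.
#' @examples
#' set.seed(1)
#' d <- survival_data(rep(c("A", "B"), each = 60),
#'                    time = c(rexp(60, 0.05), rexp(60, 0.02)),
#'                    event = rbinom(120, 1, 0.8))
#' ears_test(d)
#' ears_test(survival::Surv(time, event) ~ group, data = d)
#' @export
ears_test <- function(x, ...) UseMethod("ears_test")

#' @rdname ears_test
#' @export
ears_test.formula <- function(x, data, ...) {
  d <- data_from_formula(x, data)
  out <- ears_test.data.frame(d, ...)
  out$data.name <- deparse(x)
  out
}

#' @rdname ears_test
#' @export
ears_test.data.frame <- function(x, ...) {
  dname <- deparse(substitute(x))
  data <- as_survival_data(x)
  gs <- group_summaries(data)
  if (nrow(gs) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  zero <- gs$group[gs$n_events == 0L]
  if (length(zero))
    stop("group(s) with zero events: ", paste(zero, collapse = ", "),
         "; the EARS test cannot be applied", call. = FALSE)
  few <- gs$group[gs$n_events < 5L]
  if (length(few))
    warning("fewer than 5 events in group(s): ",
            paste(few, collapse = ", "),
            "; the chi-squared approximation may be unreliable",
            call. = FALSE)
  ast <- adjusted_survival_times(data)
  kw <- ast_kruskal_wallis(ast)
  cens <- censor_proportion(data)
  out <- list(
    statistic = c(H = kw$statistic),
    parameter = c(df = kw$df),
    p.value = censoring_adjustment(kw$p.value, cens),
    p.kruskal_wallis = kw$p.value,
    censor_proportion = cens,
    summaries = gs,
    ast = ast,
    method = "Event-adjusted rank sum (EARS) test",
    data.name = dname
  )
  class(out) <- c("ears_test", "ears_htest")
  out
}

# Extract a survival_data frame from Surv(time, event) ~ group.
data_from_formula <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  resp <- mf[[1L]]
  if (!inherits(resp, "Surv"))
    stop("the left-hand side must be a survival::Surv(time, event) object",
         call. = FALSE)
  if (ncol(mf) < 2L)
    stop("the right-hand side must name the grouping variable",
         call. = FALSE)
  survival_data(group = interaction(mf[-1L], drop = TRUE),
                time = resp[, "time"], event = resp[, "status"])
}

#' @export
print.ears_test <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("data:  ", x$data.name, "\n", sep = "")
  cat(sprintf("H = %s, df = %d, Kruskal-Wallis p = %s\n",
              format(unname(x$statistic), digits = digits),
              unname(x$parameter),
              format(x$p.kruskal_wallis, digits = digits)))
  cat(sprintf("overall censoring = %.1f%%, EARS p = %s\n",
              100 * x$censor_proportion,
              format(x$p.value, digits = digits)))
  invisible(x)
}

#' @export
print.ears_htest <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("data:  ", x$data.name, "\n", sep = "")
  stat <- unname(x$statistic)
  lab <- if (!is.null(names(x$statistic))) names(x$statistic) else "statistic"
  cat(sprintf("%s = %s", lab, format(stat, digits = digits)))
  if (!is.null(x$parameter))
    cat(sprintf(", df = %s", format(unname(x$parameter))))
  cat(sprintf(", p = %s\n", format(x$p.value, digits = digits)))
  invisible(x)
}

#' @export
summary.ears_test <- function(object, ...) {
  print(object, ...)
  cat("\nPer-group summary:\n")
  print(object$summaries, row.names = FALSE)
  invisible(object)
}
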