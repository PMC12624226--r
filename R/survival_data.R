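#' Coerce a table to the three-column survival layout
#'
#' The package works on tabular time-to-event data with three semantic
#' columns: a group label, a nonnegative follow-up time, and a binary event
#' indicator (1 = event of interest, 0 = censored).  `as_survival_data()`
#' normalizes a data frame to this layout: column names are matched
#' case-insensitively and in any order against `Group`, `Time` and `Event`,
#' values are validated, and the result is returned with the canonical
#' lower-case names `group`, `time`, `event`.
#'
#' @param x A data frame (or object coercible to one) containing group,
#'   time and event columns under any capitalization.
#' @return A `data.frame` with columns `group` (character), `time`
#'   (numeric) and `event` (integer 0/1), classed `"survival_data"`.
#' @examples
#' d <- data.frame(Group = c("A", "A", "B"), Time = c(5, 3, 8),
#'                 Event = c(1, 0, 1))
#' as_survival_data(d)
#' @export
as_survival_data <- function(x) {
  if (inherits(x, "survival_data")) return(x)
  x <- as.data.frame(x)
  nm <- tolower(names(x))
  idx <- match(c("group", "time", "event"), nm)
  if (anyNA(idx)) {
    missing <- c("Group", "Time", "Event")[is.na(idx)]
    stop("input is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    group = as.character(x[[idx[1]]]),
    time  = x[[idx[2]]],
    event = x[[idx[3]]],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) stop("empty dataset", call. = FALSE)
  if (!is.numeric(out$time)) {
    tm <- suppressWarnings(as.numeric(out$time))
    bad <- which(is.na(tm) & !is.na(out$time))
    if (length(bad))
      stop("non-numeric Time value in row ", bad[1], call. = FALSE)
    out$time <- tm
  }
  bad <- which(!is.finite(out$time) | out$time < 0)
  if (length(bad))
    stop("negative, missing or non-finite Time value in row ", bad[1],
         call. = FALSE)
  ev <- suppressWarnings(as.numeric(out$event))
  bad <- which(is.na(ev) | !(ev %in% c(0, 1)))
  if (length(bad))
    stop("Event value outside {0, 1} in row ", bad[1], call. = FALSE)
  out$event <- as.integer(ev)
  class(out) <- c("survival_data", "data.frame")
  out
}

#' Build a survival dataset from vectors
#'
#' @param group Vector of group labels.
#' @param time Numeric vector of nonnegative follow-up times.
#' @param event Binary vector, 1 = event of interest, 0 = censored.
#' @return A `survival_data` data frame; see [as_survival_data()].
#' @export
survival_data <- function(group, time, event) {
  as_survival_data(data.frame(Group = group, Time = time, Event = event))
}

#' Per-group patient and event counts
#'
#' Summarizes a survival dataset by group: number of patients, number of
#' events of interest, and the event proportion.  All patients — including
#' censored ones — enter the denominator: the event proportion is the
#' divisor that converts an observed event time into an adjusted survival
#' time, and it is defined over the whole group.
#'
#' @param data A dataset accepted by [as_survival_data()].
#' @return A data frame with one row per group and columns `group`, `n`,
#'   `n_events`, `event_proportion`.
#' @examples
#' d <- survival_data(rep(c("A", "B"), each = 10),
#'                    time = rexp(20), event = rbinom(20, 1, 0.7))
#' group_summaries(d)
#' @export
group_summaries <- function(data) {
  data <- as_survival_data(data)
  g <- sort(unique(data$group))
  n <- vapply(g, function(l) sum(data$group == l), integer(1))
  ne <- vapply(g, function(l) sum(data$event[data$group == l]), integer(1))
  data.frame(group = g, n = n, n_events = ne,
             event_proportion = ne / n, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Overall censored fraction of a dataset (pooled across groups).
censor_proportion <- function(data) {
  data <- as_survival_data(data)
  mean(data$event == 0L)
}
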