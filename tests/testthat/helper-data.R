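# Small in-code fixtures shared across test files.

# Two groups, half the records censored in A, none in B.
toy_cohort <- function() {
  survival_data(group = rep(c("A", "B"), each = 4),
                time = c(1, 2, 3, 4, 2, 4, 6, 8),
                event = c(1, 1, 0, 0, 1, 1, 1, 1))
}

# Two clearly separated groups, all events.
separated_cohort <- function() {
  survival_data(group = rep(c("A", "B"), each = 3),
                time = c(1, 2, 3, 4, 5, 6), event = 1)
}

# A moderately sized random two-group cohort with censoring.
random_cohort <- function(n = 60, seed = 1, hr = 1, p_event = 0.8) {
  set.seed(seed)
  survival_data(group = rep(c("A", "B"), each = n),
                time = c(rexp(n, 0.05), rexp(n, 0.05 * hr)),
                event = rbinom(2 * n, 1, p_event))
}

write_cohort_csv <- function(data, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(Group = data$group, Time = data$time,
                              Event = data$event),
                   path, row.names = FALSE)
  path
}
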