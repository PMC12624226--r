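Package: earstest
Title: Event-Adjusted Rank Sum Test for Survival Analysis Without
    Proportional Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the event-adjusted rank sum (EARS) test, a
    nonparametric k-sample test for time-to-event data that does not rely
    on the proportional-hazards assumption. Event times are normalized by
    the event proportion of their group, compared with a Kruskal-Wallis
    rank statistic, and the resulting p value is penalized by the overall
    censoring proportion. Also provides the comparator tests commonly
    used under non-proportional hazards (log-rank, log-rank trend,
    Fleming-Harrington weighted log-rank, permutation MaxCombo, and the
    restricted mean survival time difference test), seeded survival-cohort
    simulators with calibrated censoring mechanisms, and Monte-Carlo study
    harnesses for Type I error, power, decision agreement, and chi-squared
    asymptotics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
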