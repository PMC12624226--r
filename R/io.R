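#' Read a three-column survival table
#'
#' Reads Group/Time/Event tabular data from CSV, TSV, or a spreadsheet
#' (first sheet; requires the readxl package).  Column names are matched
#' case-insensitively and in any order; a missing column, an Event value
#' outside \{0, 1\}, or a nonnumeric or negative Time fails loudly with
#' the offending column or row.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by file extension), `"csv"`, `"tsv"`, or
#'   `"spreadsheet"`.
#' @return A `survival_data` data frame.
#' @export
read_survival_table <- function(path,
                                dialect = c("auto", "csv", "tsv",
                                            "spreadsheet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
                      csv = "csv", tsv = "tsv", txt = "tsv",
                      xlsx = "spreadsheet", xls = "spreadsheet",
                      stop("cannot infer dialect from extension '.", ext,
                           "'; pass dialect explicitly", call. = FALSE))
  }
  raw <- switch(dialect,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    spreadsheet = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading spreadsheets requires the 'readxl' package",
             call. = FALSE)
      as.data.frame(readxl::read_excel(path, sheet = 1))
    })
  as_survival_data(raw)
}

#' Bundle test results into a serializable document
#'
#' Collects one or more test objects together with a fingerprint of the
#' input data (size, groups, events, censoring) and run metadata, in a
#' form that round-trips losslessly through JSON.
#'
#' @param tests A single `"ears_htest"` object or a list of them.
#' @param data The dataset the tests were run on.
#' @param seed Optional seed to record.
#' @return A list of class `"results_document"`.
#' @export
results_document <- function(tests, data, seed = NULL) {
  if (inherits(tests, "ears_htest")) tests <- list(tests)
  data <- as_survival_data(data)
  gs <- group_summaries(data)
  methods <- lapply(tests, function(t) {
    out <- list(method = t$method,
                statistic = unname(t$statistic),
                df = if (!is.null(t$parameter)) unname(t$parameter),
                p = t$p.value)
    if (!is.null(t$p.kruskal_wallis)) {
      out$p_unadjusted <- t$p.kruskal_wallis
      out$censor_proportion <- t$censor_proportion
    }
    if (!is.null(t$tau)) out$tau <- t$tau
    out[!vapply(out, is.null, logical(1))]
  })
  structure(list(
    methods = methods,
    input = list(n = nrow(data), groups = nrow(gs),
                 events = sum(data$event),
                 censor_proportion = censor_proportion(data)),
    run = list(seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
               version = as.character(utils::packageVersion("earstest")))),
    class = "results_document")
}

#' Write a results document
#'
#' JSON output reads back into an equivalent document with
#' [read_results()]; TSV output is a flat table with one row per method.
#' p values are written at full floating precision — presentation such as
#' "< 0.0001" is left to the caller.
#'
#' @param doc A [results_document()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(doc, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(doc, "results_document"))
  if (format == "json") {
    jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    rows <- do.call(rbind, lapply(doc$methods, function(m) {
      data.frame(method = m$method, statistic = m$statistic,
                 df = if (is.null(m$df)) NA else m$df, p = m$p,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON results document
#'
#' @param path Path written by [write_results()] with `format = "json"`.
#' @return A `"results_document"` list.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$methods <- lapply(doc$methods, function(m) {
    m[c("statistic", "df", "p", "p_unadjusted", "censor_proportion",
        "tau")] <- lapply(
      m[c("statistic", "df", "p", "p_unadjusted", "censor_proportion",
          "tau")], function(v) if (is.null(v)) NULL else as.numeric(v))
    m[!vapply(m, is.null, logical(1))]
  })
  structure(doc, class = "results_document")
}
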