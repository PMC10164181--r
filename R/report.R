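# Benchmark report serialisation: JSON (canonical, full precision) plus a
# flat TSV summary for spreadsheet use.

#' Write a benchmark report
#'
#' Writes `path` (JSON, the canonical machine-readable form, numbers at full
#' double precision) and a sibling `.tsv` with the flat metric table, values
#' rounded to `tsv_digits`.
#'
#' @param report A [run_benchmark()] report.
#' @param path Output JSON path.
#' @param tsv_digits Decimal digits in the TSV rendering (default 4).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path, tsv_digits = 4L) {
  stopifnot(inherits(report, "benchmark_report"))
  payload <- list(metrics = report$metrics, comparisons = report$comparisons,
                  adp = report$adp, failures = report$failures,
                  provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  tsv_path <- sub("\\.json$", "", path)
  tsv_path <- paste0(tsv_path, ".tsv")
  flat <- report$metrics
  if (nrow(flat)) flat$value <- round(flat$value, tsv_digits)
  utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a benchmark report back from JSON
#'
#' Inverse of [write_report()]: reconstructs the `benchmark_report` object
#' (data frames and provenance) from the canonical JSON rendering.
#'
#' @param path JSON path written by [write_report()].
#' @return A `benchmark_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x, template) {
    if (is.data.frame(x) && nrow(x)) return(x)
    template
  }
  structure(
    list(
      metrics = as_df(raw$metrics, data.frame(
        seed = integer(), model = character(), stratum = character(),
        metric = character(), value = numeric())),
      comparisons = as_df(raw$comparisons, data.frame(
        seed = integer(), metric = character(), model = character(),
        baseline = character(), sidedness = character(),
        statistic = numeric(), p_value = numeric(), stars = character(),
        p_holm = numeric())),
      adp = as_df(raw$adp, data.frame(
        seed = integer(), model = character(), adp = numeric(),
        ci_low = numeric(), ci_high = numeric(),
        range_warnings = character())),
      failures = as_df(raw$failures, data.frame(
        seed = integer(), model = character(), error = character())),
      provenance = raw$provenance
    ),
    class = "benchmark_report"
  )
}
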