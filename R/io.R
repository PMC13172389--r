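#' Write a cohort to plain-text CSV files
#'
#' Writes `static.csv`, `timeseries.csv` (long format: `patient_id`,
#' `variable`, `t_start_h`, `t_end_h`, `value`) and, when present,
#' `truth.csv` into `dir`.
#'
#' @param cohort A `pkip_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$static, file.path(dir, "static.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$timeseries, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `static.csv` and `timeseries.csv`.
#' @return A `pkip_cohort` list.
#' @export
read_cohort <- function(dir) {
  static <- as_tibble(utils::read.csv(file.path(dir, "static.csv")))
  timeseries <- as_tibble(utils::read.csv(file.path(dir, "timeseries.csv")))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    as_tibble(utils::read.csv(truth_path))
  } else {
    NULL
  }
  structure(list(static = static, timeseries = timeseries, truth = truth),
            class = "pkip_cohort")
}
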