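#' Construct a single patient record
#'
#' One subject's static fields plus all time-stamped series, with the clock
#' zeroed at presentation. This is the unit the adjudicator and the episode
#' injectors operate on; cohort-level functions work on the tabular cohort
#' form (see [simulate_cohort()]) and convert internally.
#'
#' @param static A one-row data frame with at least `patient_id`, `age`,
#'   `weight`, `end_time` (hours to death or discharge) and `death` (logical);
#'   optionally `paraquat`, `pesticide_category`, `sex`, comorbidity flags and
#'   other static covariates.
#' @param scr Data frame of creatinine measurements: columns `time_h`,
#'   `value` (mg/dL).
#' @param uo Data frame of urine-output intervals: columns `start_h`, `end_h`,
#'   `volume_ml`; intervals must be non-overlapping with `start_h < end_h`.
#' @param dialysis Data frame of dialysis events: columns `start_h`,
#'   `maintenance` (logical; non-maintenance rows are toxin-removal sessions
#'   and never stage AKI).
#' @param measurements Data frame of other time-stamped observations:
#'   columns `variable`, `time_h`, `value`.
#'
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(static,
                           scr = NULL,
                           uo = NULL,
                           dialysis = NULL,
                           measurements = NULL) {
  static <- as_tibble(static)
  stopifnot(nrow(static) == 1L)
  empty <- function(df, proto) {
    if (is.null(df) || nrow(df) == 0L) proto else as_tibble(df)
  }
  scr <- empty(scr, tibble(time_h = numeric(), value = numeric()))
  uo <- empty(uo, tibble(start_h = numeric(), end_h = numeric(),
                         volume_ml = numeric()))
  dialysis <- empty(dialysis, tibble(start_h = numeric(),
                                     maintenance = logical()))
  measurements <- empty(measurements,
                        tibble(variable = character(), time_h = numeric(),
                               value = numeric()))
  scr <- arrange(scr, .data$time_h)
  uo <- arrange(uo, .data$start_h)
  end_time <- static$end_time
  if (nrow(scr) && (any(scr$value <= 0) || any(scr$time_h < 0))) {
    abort("creatinine values must be positive at non-negative times",
          class = "pkipr_record_error")
  }
  if (nrow(uo)) {
    if (any(uo$start_h >= uo$end_h) || any(uo$volume_ml < 0) ||
        any(uo$start_h < 0)) {
      abort("urine-output intervals need start < end and volume >= 0",
            class = "pkipr_record_error")
    }
    if (nrow(uo) > 1L && any(uo$start_h[-1L] < uo$end_h[-nrow(uo)] - 1e-9)) {
      abort("urine-output intervals must not overlap",
            class = "pkipr_record_error")
    }
  }
  if (!is.null(static$weight) && !is.na(static$weight) && static$weight <= 0) {
    abort("weight must be positive", class = "pkipr_record_error")
  }
  structure(list(static = static, scr = scr, uo = uo, dialysis = dialysis,
                 measurements = measurements,
                 patient_id = static$patient_id,
                 weight = static$weight %||% NA_real_,
                 end_time = end_time),
            class = "patient_record")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record %s: %d sCr, %d UO intervals, %d dialysis, end %.1f h>\n",
    x$patient_id, nrow(x$scr), nrow(x$uo), nrow(x$dialysis), x$end_time))
  invisible(x)
}

#' Split a tabular cohort into patient records
#'
#' @param cohort A `pkip_cohort` (list with `static` and `timeseries`
#'   tibbles, as produced by [simulate_cohort()] or [read_cohort()]).
#' @return A named list of [patient_record()] objects, one per row of
#'   `static`.
#' @export
as_patient_records <- function(cohort) {
  ts_split <- split(cohort$timeseries, cohort$timeseries$patient_id)
  lapply(seq_len(nrow(cohort$static)), function(i) {
    st <- cohort$static[i, ]
    ts <- ts_split[[as.character(st$patient_id)]]
    if (is.null(ts)) {
      ts <- cohort$timeseries[0, ]
    }
    scr <- filter(ts, .data$variable == "creatinine")
    uo <- filter(ts, .data$variable == "urine_output")
    dia <- filter(ts, .data$variable == "dialysis")
    meas <- filter(ts, !.data$variable %in%
                     c("creatinine", "urine_output", "dialysis"))
    patient_record(
      static = st,
      scr = tibble(time_h = scr$t_start_h, value = scr$value),
      uo = tibble(start_h = uo$t_start_h, end_h = uo$t_end_h,
                  volume_ml = uo$value),
      dialysis = tibble(start_h = dia$t_start_h,
                        maintenance = dia$value > 0.5),
      measurements = tibble(variable = meas$variable,
                            time_h = meas$t_start_h, value = meas$value)
    )
  }) |> setNames(cohort$static$patient_id)
}

# long-format timeseries rows for one record (inverse of as_patient_records)
record_to_timeseries <- function(record) {
  pid <- record$patient_id
  bind_rows(
    tibble(patient_id = pid, variable = "creatinine",
           t_start_h = record$scr$time_h, t_end_h = NA_real_,
           value = record$scr$value),
    tibble(patient_id = pid, variable = "urine_output",
           t_start_h = record$uo$start_h, t_end_h = record$uo$end_h,
           value = record$uo$volume_ml),
    tibble(patient_id = pid, variable = "dialysis",
           t_start_h = record$dialysis$start_h, t_end_h = NA_real_,
           value = as.numeric(record$dialysis$maintenance)),
    tibble(patient_id = pid, variable = record$measurements$variable,
           t_start_h = record$measurements$time_h, t_end_h = NA_real_,
           value = record$measurements$value)
  )
}
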