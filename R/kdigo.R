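#' Dynamic rolling-minimum baseline creatinine
#'
#' The baseline against which a measurement at time `t` is judged is the
#' minimum creatinine in the half-open window `[t - lookback, t)`: strictly
#' earlier values only, so a measurement never serves as its own baseline,
#' with the left edge included. When no earlier value falls in the window the
#' minimum over the first `substitute_baseline_window` hours of presentation
#' substitutes (in strict mode, the first measured value in that window
#' instead of the minimum — see [flag_ambiguous()]).
#'
#' @param scr Data frame of creatinine measurements with columns `time_h`
#'   and `value`, time-sorted.
#' @param t Index time (hours).
#' @param lookback Lookback horizon (hours).
#' @param thresholds A [kdigo_thresholds()] object (supplies the substitute
#'   window).
#' @param strict Logical; strict baseline mode. A transient dip inside the
#'   presentation window may otherwise serve as baseline twice over — as the
#'   substitute and, for later measurements, inside the rolling window
#'   itself. Strict mode therefore replaces every value in the presentation
#'   window by the first measured value before any baseline is computed.
#'
#' @return A one-row tibble with `value` (mg/dL; `NA` when no baseline can be
#'   defined), `source` (`"rolling_min"`, `"substitute_first2h"` or
#'   `"none"`), and `window_h`.
#' @export
#' @examples
#' scr <- tibble::tibble(time_h = c(0, 10, 60), value = c(1.0, 0.7, 1.4))
#' rolling_baseline(scr, t = 60, lookback = 48)
rolling_baseline <- function(scr, t, lookback,
                             thresholds = kdigo_thresholds(),
                             strict = FALSE) {
  sw <- thresholds$substitute_baseline_window
  if (strict) {
    scr <- strict_series(scr, sw)
  }
  in_window <- scr$time_h >= t - lookback & scr$time_h < t
  if (any(in_window)) {
    return(tibble(value = min(scr$value[in_window]),
                  source = "rolling_min", window_h = lookback))
  }
  sub <- scr$time_h >= 0 & scr$time_h <= sw
  if (any(sub)) {
    return(tibble(value = min(scr$value[sub]),
                  source = "substitute_first2h", window_h = sw))
  }
  tibble(value = NA_real_, source = "none", window_h = NA_real_)
}

# strict baseline mode: presentation-window values are all replaced by the
# first measured value, so an early transient dip can never act as baseline
strict_series <- function(scr, sw) {
  early <- scr$time_h >= 0 & scr$time_h <= sw
  if (any(early)) {
    scr$value[early] <- scr$value[early][which.min(scr$time_h[early])]
  }
  scr
}

# vectorised baselines for every measurement of one series; errors when the
# substitute set is empty (no creatinine within the presentation window)
baselines_for_series <- function(scr, lookback, thresholds, strict) {
  sw <- thresholds$substitute_baseline_window
  if (strict) {
    scr <- strict_series(scr, sw)
  }
  tm <- scr$time_h
  v <- scr$value
  sub <- tm >= 0 & tm <= sw
  sub_val <- if (!any(sub)) NA_real_ else min(v[sub])
  vapply(seq_along(tm), function(i) {
    inw <- tm >= tm[i] - lookback & tm < tm[i]
    if (any(inw)) {
      min(v[inw])
    } else if (!is.na(sub_val)) {
      sub_val
    } else {
      abort("no definable baseline creatinine", class = "pkipr_no_baseline")
    }
  }, numeric(1))
}

#' Creatinine-criterion staging events
#'
#' Evaluates every measurement against its dynamic baseline. The ratio
#' criterion uses the `ratio_lookback` (168 h) rolling minimum and the bands
#' `[1.5, 2.0)`, `[2.0, 3.0)`, `>= 3.0` (lower edges inclusive) for stages
#' 1-3. Independently, an absolute rise of at least `abs_increment`
#' (0.3 mg/dL) over the `abs_lookback` (48 h) rolling minimum flags stage 1
#' even when the ratio stays below the first band. Events are capped at
#' `obs_horizon`.
#'
#' @inheritParams rolling_baseline
#' @return A tibble with `time_h`, `stage` (1-3) and `criterion`
#'   (`"scr_ratio"` or `"scr_abs"`), one row per staging measurement.
#' @export
scr_stage_events <- function(scr, thresholds = kdigo_thresholds(),
                             strict = FALSE) {
  out <- tibble(time_h = numeric(), stage = integer(), criterion = character())
  if (nrow(scr) == 0L) {
    return(out)
  }
  scr <- arrange(scr, .data$time_h)
  keep <- scr$time_h <= thresholds$obs_horizon
  scr_c <- scr[keep, ]
  if (nrow(scr_c) == 0L) {
    return(out)
  }
  b_ratio <- baselines_for_series(scr, thresholds$ratio_lookback,
                                  thresholds, strict)[keep]
  b_abs <- baselines_for_series(scr, thresholds$abs_lookback,
                                thresholds, strict)[keep]
  r <- scr_c$value / b_ratio
  bands <- thresholds$ratio_bands
  ratio_stage <- (r >= bands[1] - .EPS) + (r >= bands[2] - .EPS) +
    (r >= bands[3] - .EPS)
  abs_hit <- (scr_c$value - b_abs) >= thresholds$abs_increment - .EPS
  stage <- pmax(ratio_stage, as.integer(abs_hit))
  hit <- stage >= 1L
  tibble(
    time_h = scr_c$time_h[hit],
    stage = as.integer(stage[hit]),
    criterion = as.character(
      ifelse(ratio_stage[hit] >= 1L, "scr_ratio", "scr_abs"))
  )
}

# piecewise-linear cumulative function over intervals: volume (or covered
# time) accumulated from 0 to each query time; flat across recording gaps
interval_cumulative <- function(start, end, amount, xout) {
  if (length(start) == 0L) {
    return(rep(0, length(xout)))
  }
  knots_x <- c(0, as.vector(rbind(start, end)))
  knots_y <- c(0, as.vector(rbind(cumsum(amount) - amount, cumsum(amount))))
  ord <- order(knots_x, knots_y)
  approx(knots_x[ord], knots_y[ord], xout = xout, rule = 2, ties = max)$y
}

#' Urine-output criterion staging events
#'
#' A moving-window scan of weight-normalised urine output. Candidate windows
#' of width 6, 12 and 24 h end at each recorded interval boundary (an hourly
#' grid for hourly records); a window triggers stage 1 when the mean rate
#' over 6 h is strictly below 0.5 mL/kg/h, stage 2 below 0.5 over 12 h, and
#' stage 3 below 0.3 over 24 h or for zero output sustained over
#' `anuria_duration` (12 h). The event time is the window end. Windows that
#' would extend before presentation, end beyond `obs_horizon`, or whose
#' recorded coverage falls below `uo_coverage` are skipped. Partial interval
#' overlap is prorated linearly.
#'
#' @param uo Data frame of intervals: `start_h`, `end_h`, `volume_ml`,
#'   non-overlapping.
#' @param weight Body weight in kg (positive).
#' @param thresholds A [kdigo_thresholds()] object.
#' @return A tibble with `time_h`, `stage`, `criterion = "uo"`.
#' @export
#' @examples
#' uo <- tibble::tibble(start_h = 0:5, end_h = 1:6, volume_ml = rep(20, 6))
#' uo_stage_events(uo, weight = 50)
uo_stage_events <- function(uo, weight, thresholds = kdigo_thresholds()) {
  if (is.null(weight) || is.na(weight) || weight <= 0) {
    abort("weight must be a positive number", class = "pkipr_record_error")
  }
  out <- tibble(time_h = numeric(), stage = integer(), criterion = character())
  if (nrow(uo) == 0L) {
    return(out)
  }
  uo <- arrange(uo, .data$start_h)
  ends <- sort(unique(c(uo$start_h, uo$end_h)))
  ends <- ends[ends <= thresholds$obs_horizon + .EPS]
  specs <- list(
    list(w = thresholds$uo_window_stage1, rate = thresholds$uo_rate_stage1,
         stage = 1L, anuria = FALSE),
    list(w = thresholds$uo_window_stage2, rate = thresholds$uo_rate_stage2,
         stage = 2L, anuria = FALSE),
    list(w = thresholds$uo_window_stage3, rate = thresholds$uo_rate_stage3,
         stage = 3L, anuria = FALSE),
    list(w = thresholds$anuria_duration, rate = NA_real_,
         stage = 3L, anuria = TRUE)
  )
  res <- lapply(specs, function(sp) {
    e <- ends[ends >= sp$w - .EPS]
    if (length(e) == 0L) {
      return(out)
    }
    vol <- interval_cumulative(uo$start_h, uo$end_h, uo$volume_ml, e) -
      interval_cumulative(uo$start_h, uo$end_h, uo$volume_ml, e - sp$w)
    cov <- interval_cumulative(uo$start_h, uo$end_h,
                               uo$end_h - uo$start_h, e) -
      interval_cumulative(uo$start_h, uo$end_h,
                          uo$end_h - uo$start_h, e - sp$w)
    ok_cov <- cov >= thresholds$uo_coverage * sp$w - .EPS
    hit <- if (sp$anuria) {
      ok_cov & vol <= .EPS
    } else {
      ok_cov & (vol / (weight * sp$w)) < sp$rate - .EPS
    }
    tibble(time_h = e[hit], stage = sp$stage,
           criterion = rep("uo", sum(hit)))
  })
  bind_rows(res) %>% arrange(.data$time_h, .data$stage)
}

#' Dialysis-criterion staging events
#'
#' Initiation of maintenance dialysis is stage 3 at the start time. Sessions
#' that are not maintenance renal replacement (toxin-removal extracorporeal
#' treatment) emit nothing.
#'
#' @param dialysis Data frame with `start_h` and `maintenance` (logical).
#' @param thresholds A [kdigo_thresholds()] object.
#' @return A tibble with `time_h`, `stage = 3L`, `criterion = "dialysis"`.
#' @export
dialysis_stage_events <- function(dialysis,
                                  thresholds = kdigo_thresholds()) {
  if (nrow(dialysis) == 0L) {
    return(tibble(time_h = numeric(), stage = integer(),
                  criterion = character()))
  }
  keep <- dialysis$maintenance & dialysis$start_h <= thresholds$obs_horizon
  tibble(time_h = dialysis$start_h[keep], stage = 3L,
         criterion = rep("dialysis", sum(keep)))
}

#' Adjudicate AKI for one patient
#'
#' Merges the creatinine, urine-output and dialysis event lists, truncated at
#' `min(obs_horizon, end_time)`. The final stage is the highest stage across
#' all events and the onset the earliest event time of any stage; the
#' triggering criterion is that of the earliest event (ties at one time are
#' broken by higher stage, then scr_ratio > scr_abs > uo > dialysis). A
#' patient with no event — including one who dies before any criterion is
#' met — is labelled stage 0, non-AKI. The ambiguity flag marks labels that
#' exist only because a transient first-2-hours creatinine dip was accepted
#' as baseline (see [flag_ambiguous()]).
#'
#' @param record A [patient_record()].
#' @param thresholds A [kdigo_thresholds()] object.
#' @param strict Logical; use the strict (first measured value) substitute
#'   baseline rather than the first-2-hours minimum.
#' @return A one-row tibble: `patient_id`, `has_aki`, `stage`, `onset_h`,
#'   `criterion`, `ambiguous`.
#' @export
adjudicate <- function(record, thresholds = kdigo_thresholds(),
                       strict = FALSE) {
  cap <- min(thresholds$obs_horizon, record$end_time)
  scr_ev <- scr_stage_events(record$scr, thresholds, strict = strict)
  other_ev <- bind_rows(
    uo_stage_events(record$uo, record$weight, thresholds),
    dialysis_stage_events(record$dialysis, thresholds)
  )
  events <- filter(bind_rows(scr_ev, other_ev),
                   .data$time_h <= cap + .EPS)
  if (nrow(events) == 0L) {
    return(tibble(patient_id = record$patient_id, has_aki = FALSE,
                  stage = 0L, onset_h = NA_real_,
                  criterion = NA_character_, ambiguous = FALSE))
  }
  crit_rank <- c(scr_ratio = 1L, scr_abs = 2L, uo = 3L, dialysis = 4L)
  first <- events %>%
    arrange(.data$time_h, dplyr::desc(.data$stage),
            crit_rank[.data$criterion]) %>%
    slice(1L)
  # ambiguity: the strict substitute baseline only changes creatinine
  # events, so a UO or dialysis event within the cap settles it directly
  amb <- if (strict) {
    FALSE
  } else if (any(other_ev$time_h <= cap + .EPS)) {
    FALSE
  } else {
    strict_ev <- scr_stage_events(record$scr, thresholds, strict = TRUE)
    !any(strict_ev$time_h <= cap + .EPS)
  }
  tibble(patient_id = record$patient_id, has_aki = TRUE,
         stage = max(events$stage), onset_h = first$time_h,
         criterion = first$criterion, ambiguous = amb)
}

#' Flag ambiguous AKI labels
#'
#' A label is ambiguous when the patient is adjudicated AKI-positive under
#' the default substitute baseline (minimum creatinine over the first 2 h,
#' so a transient early dip can serve as baseline) but AKI-negative when the
#' substitute is the first measured creatinine instead (strict mode). Such
#' patterns may reflect recovery from pre-admission injury or resuscitation
#' dilution rather than new injury.
#'
#' @inheritParams adjudicate
#' @return Logical flag.
#' @export
flag_ambiguous <- function(record, thresholds = kdigo_thresholds()) {
  adjudicate(record, thresholds, strict = FALSE)$ambiguous
}

#' Adjudicate every patient of a cohort
#'
#' @param cohort A `pkip_cohort` (list with `static` and `timeseries`),
#'   e.g. from [simulate_cohort()] or [read_cohort()].
#' @inheritParams adjudicate
#' @return A tibble with one adjudication row per patient (see
#'   [adjudicate()]).
#' @export
adjudicate_cohort <- function(cohort, thresholds = kdigo_thresholds(),
                              strict = FALSE) {
  records <- as_patient_records(cohort)
  purrr::map_dfr(records, adjudicate, thresholds = thresholds,
                 strict = strict)
}

#' Apply the cohort inclusion filters
#'
#' Exclusion reasons are evaluated in a fixed order and the first match is
#' recorded: (1) age below the adult cutoff; (2) paraquat poisoning; (3) no
#' definable baseline creatinine (no measurement within the presentation
#' window); (4) baseline creatinine strictly above `baseline_exclusion`
#' (2.5 mg/dL; exactly 2.5 is admitted); (5) AKI onset, death or discharge
#' within the first `presentation_window` hours (boundary inclusive).
#'
#' @param cohort A `pkip_cohort` or a list of [patient_record()] objects.
#' @param thresholds A [kdigo_thresholds()] object.
#' @return A tibble: `patient_id`, `included`, `reason` (one of
#'   `adult_only`, `paraquat`, `no_baseline`, `baseline_gt_cutoff`,
#'   `event_within_2h`, `none`).
#' @export
apply_cohort_filters <- function(cohort, thresholds = kdigo_thresholds()) {
  records <- if (inherits(cohort, "pkip_cohort")) {
    as_patient_records(cohort)
  } else {
    cohort
  }
  purrr::map_dfr(records, function(rec) {
    decide <- function(reason) {
      tibble(patient_id = rec$patient_id, included = reason == "none",
             reason = reason)
    }
    get_field <- function(nm) {
      if (nm %in% names(rec$static)) rec$static[[nm]] else NA
    }
    age <- get_field("age")
    if (!is.na(age) && age < thresholds$adult_age) {
      return(decide("adult_only"))
    }
    pq <- isTRUE(get_field("paraquat"))
    if (pq) {
      return(decide("paraquat"))
    }
    sw <- thresholds$presentation_window
    sub <- rec$scr$time_h >= 0 & rec$scr$time_h <= sw
    if (!any(sub)) {
      return(decide("no_baseline"))
    }
    if (min(rec$scr$value[sub]) > thresholds$baseline_exclusion + .EPS) {
      return(decide("baseline_gt_cutoff"))
    }
    lab <- adjudicate(rec, thresholds)
    early_event <- (!is.na(lab$onset_h) && lab$onset_h <= sw + .EPS) ||
      rec$end_time <= sw + .EPS
    if (early_event) {
      return(decide("event_within_2h"))
    }
    decide("none")
  })
}
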