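#' Operational KDIGO staging thresholds
#'
#' Bundles every constant of the operational KDIGO definition used by the
#' adjudicator: creatinine ratio bands, the absolute-increment criterion and
#' its lookback, the ratio-criterion lookback, the first-2-hours substitute
#' baseline window, weight-normalised urine-output rate thresholds and window
#' widths, the anuria duration, the observation cap, and the cohort-filter
#' constants (adult age, baseline-creatinine exclusion cutoff, minimum event
#' time).
#'
#' Baseline creatinine is dynamic: the minimum value in the half-open lookback
#' window strictly before the index measurement; when that set is empty the
#' minimum over the first `presentation_window` hours substitutes.
#'
#' @param ratio_bands Ascending creatinine ratio cut points for stages 1/2/3
#'   (times baseline). A ratio at or above band k (lower edge inclusive)
#'   reaches stage k.
#' @param abs_increment Absolute serum-creatinine rise (mg/dL) over the
#'   `abs_lookback` minimum that flags AKI (stage 1) even below the first
#'   ratio band.
#' @param abs_lookback,ratio_lookback Lookback horizons (hours) for the
#'   rolling-minimum baseline used by the absolute and ratio criteria.
#' @param substitute_baseline_window Hours after presentation whose minimum
#'   creatinine substitutes for an empty rolling window.
#' @param uo_rate_stage1,uo_rate_stage2,uo_rate_stage3 Urine-output rate
#'   thresholds (mL/kg/h); output strictly below the threshold sustained over
#'   the matching window triggers the stage.
#' @param uo_window_stage1,uo_window_stage2,uo_window_stage3 Window widths
#'   (hours) for the three urine-output criteria.
#' @param anuria_duration Hours of zero urine output that qualify as stage 3.
#' @param uo_coverage Minimum fraction of a candidate window that must be
#'   covered by recorded intervals for the window to be evaluated.
#' @param obs_horizon Observation cap (hours); events beyond it are ignored.
#' @param baseline_exclusion Baseline creatinine (mg/dL) above which (strictly)
#'   a patient is excluded from the cohort.
#' @param presentation_window Hours defining "at presentation" for the
#'   substitute baseline, the no-baseline exclusion and the early-event
#'   exclusion.
#' @param adult_age Minimum age (years) for inclusion.
#'
#' @return A list of class `kdigo_thresholds`.
#' @export
#' @examples
#' th <- kdigo_thresholds()
#' th$ratio_bands
kdigo_thresholds <- function(ratio_bands = c(1.5, 2.0, 3.0),
                             abs_increment = 0.3,
                             abs_lookback = 48,
                             ratio_lookback = 168,
                             substitute_baseline_window = 2,
                             uo_rate_stage1 = 0.5,
                             uo_rate_stage2 = 0.5,
                             uo_rate_stage3 = 0.3,
                             uo_window_stage1 = 6,
                             uo_window_stage2 = 12,
                             uo_window_stage3 = 24,
                             anuria_duration = 12,
                             uo_coverage = 0.8,
                             obs_horizon = 168,
                             baseline_exclusion = 2.5,
                             presentation_window = 2,
                             adult_age = 19) {
  th <- list(
    ratio_bands = ratio_bands,
    abs_increment = abs_increment,
    abs_lookback = abs_lookback,
    ratio_lookback = ratio_lookback,
    substitute_baseline_window = substitute_baseline_window,
    uo_rate_stage1 = uo_rate_stage1,
    uo_rate_stage2 = uo_rate_stage2,
    uo_rate_stage3 = uo_rate_stage3,
    uo_window_stage1 = uo_window_stage1,
    uo_window_stage2 = uo_window_stage2,
    uo_window_stage3 = uo_window_stage3,
    anuria_duration = anuria_duration,
    uo_coverage = uo_coverage,
    obs_horizon = obs_horizon,
    baseline_exclusion = baseline_exclusion,
    presentation_window = presentation_window,
    adult_age = adult_age
  )
  nums <- unlist(th[setdiff(names(th), "ratio_bands")])
  if (any(!is.finite(nums)) || any(nums <= 0)) {
    abort("all staging thresholds must be positive finite numbers",
          class = "pkipr_param_error")
  }
  if (length(ratio_bands) != 3L || any(diff(ratio_bands) <= 0)) {
    abort("ratio_bands must be three strictly increasing cut points",
          class = "pkipr_param_error")
  }
  if (uo_coverage > 1) {
    abort("uo_coverage must be a fraction in (0, 1]",
          class = "pkipr_param_error")
  }
  structure(th, class = "kdigo_thresholds")
}

#' Five-group risk bins
#'
#' Four ascending cut points on the predicted AKI probability define the
#' groups minimal / low / moderate / high / severe. Intervals are half-open,
#' lower-inclusive: `[0, c1) [c1, c2) [c2, c3) [c3, c4) [c4, 1]`, so a
#' probability exactly at the top cut (default 0.43) falls in the severe
#' group.
#'
#' Only the top cut (0.43, the severe boundary used in pesticide-poisoning
#' risk stratification) is an anchored constant; the lower three are
#' package defaults.
#'
#' @param cuts Four strictly increasing probabilities in (0, 1).
#' @return An object of class `risk_bins`.
#' @export
#' @examples
#' assign_risk_group(tibble::tibble(prob = c(0, 0.2, 0.43)), bins = risk_bins())
risk_bins <- function(cuts = c(0.05, 0.15, 0.30, 0.43)) {
  if (length(cuts) != 4L || any(diff(cuts) <= 0) ||
      any(cuts <= 0) || any(cuts >= 1)) {
    abort("cuts must be four strictly increasing values inside (0, 1)",
          class = "pkipr_param_error")
  }
  structure(list(cuts = cuts,
                 labels = c("minimal", "low", "moderate", "high", "severe")),
            class = "risk_bins")
}
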