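#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold with out-of-fold discrimination metrics.
#'
#' @param x A `pkip_cv` object.
#' @param ... Unused.
#' @return A tibble: `fold`, `n`, `auroc`, `auprc`.
#' @export
tidy.pkip_cv <- function(x, ...) {
  x$per_fold
}

#' Glance at a cross-validation result
#'
#' @param x A `pkip_cv` object.
#' @param ... Unused.
#' @return A one-row tibble with pooled AUROC/AUPRC (with 95% bootstrap
#'   CIs), Brier score and the accuracy-optimal threshold metrics.
#' @export
glance.pkip_cv <- function(x, ...) {
  tibble(
    learner = x$learner,
    auroc = x$auroc, auroc_lo = x$auroc_ci[1], auroc_hi = x$auroc_ci[2],
    auprc = x$auprc, auprc_lo = x$auprc_ci[1], auprc_hi = x$auprc_ci[2],
    brier = x$brier,
    threshold = x$threshold$threshold,
    accuracy = x$threshold$accuracy,
    precision = x$threshold$precision,
    recall = x$threshold$recall,
    f1 = x$threshold$f1
  )
}

#' Tidy a risk stratification
#'
#' @param x A `pkip_stratification` object.
#' @param ... Unused.
#' @return The per-group summary tibble with event counts.
#' @export
tidy.pkip_stratification <- function(x, ...) {
  x$by_group
}

#' Glance at a risk stratification
#'
#' @param x A `pkip_stratification` object.
#' @param ... Unused.
#' @return A one-row tibble with the two trend statistics and the top-group
#'   hazard ratios.
#' @export
glance.pkip_stratification <- function(x, ...) {
  top_aki <- x$aki$hr[nrow(x$aki$hr), ]
  top_death <- x$death$hr[nrow(x$death$hr), ]
  tibble(
    trend_aki_z = x$trend_aki$statistic, trend_aki_p = x$trend_aki$p,
    trend_death_z = x$trend_death$statistic,
    trend_death_p = x$trend_death$p,
    hr_aki_top = top_aki$hr, hr_death_top = top_death$hr
  )
}
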