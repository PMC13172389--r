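#' Assign five-group risk categories
#'
#' Maps predicted AKI probabilities into the ordered groups minimal / low /
#' moderate / high / severe by half-open, lower-inclusive intervals; a
#' probability exactly at the top cut (default 0.43) is severe.
#'
#' @param data Data frame with a probability column (or a bare numeric
#'   vector).
#' @param prob_col Name of the probability column.
#' @param bins A [risk_bins()] object.
#' @return `data` with an added ordered factor column `risk_group` (or the
#'   factor itself when `data` is a vector).
#' @export
assign_risk_group <- function(data, prob_col = "prob", bins = risk_bins()) {
  vec_in <- is.numeric(data)
  p <- if (vec_in) data else data[[prob_col]]
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("probabilities must lie in [0, 1]", class = "pkipr_param_error")
  }
  idx <- findInterval(p, bins$cuts) + 1L
  grp <- factor(bins$labels[idx], levels = bins$labels, ordered = TRUE)
  if (vec_in) {
    return(grp)
  }
  mutate(data, risk_group = grp)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator with right censoring, one curve per group.
#'
#' @param data Data frame of survival records.
#' @param time_col,event_col,group_col Column names for follow-up time
#'   (positive hours), event indicator and group.
#' @return A tibble of class `pkip_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(data, time_col = "time", event_col = "event",
                        group_col = "group") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  group <- data[[group_col]]
  if (any(time <= 0)) {
    abort("survival times must be positive", class = "pkipr_param_error")
  }
  if (any(table(group) == 0L) || length(time) == 0L) {
    abort("every group needs at least one record",
          class = "pkipr_param_error")
  }
  out <- purrr::map_dfr(split(seq_along(time), group), function(idx) {
    fit <- survival::survfit(
      survival::Surv(time[idx], event[idx]) ~ 1)
    tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
           n_censor = fit$n.censor, survival = fit$surv)
  }, .id = "group")
  class(out) <- c("pkip_km", class(out))
  out
}

#' Pairwise log-rank tests
#'
#' Standard log-rank statistic for every pair of groups, two-sided p from
#' the chi-square distribution with one degree of freedom. P-values are
#' reported unadjusted by default; `adjust` passes a method to
#' [stats::p.adjust()].
#'
#' @inheritParams km_estimate
#' @param adjust Multiplicity adjustment method (default `"none"`).
#' @return A tibble: `group1`, `group2`, `statistic`, `p` (and `p_adj` when
#'   adjusted).
#' @export
logrank_pairwise <- function(data, time_col = "time", event_col = "event",
                             group_col = "group", adjust = "none") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  group <- factor(data[[group_col]])
  lev <- levels(group)
  if (length(lev) < 2L) {
    abort("need at least two groups", class = "pkipr_param_error")
  }
  pairs <- utils::combn(lev, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    idx <- group %in% c(g1, g2)
    if (sum(event[idx]) == 0L) {
      warn(sprintf("no events in pair %s vs %s; p set to 1", g1, g2))
      return(tibble(group1 = g1, group2 = g2, statistic = 0, p = 1))
    }
    sd <- survival::survdiff(
      survival::Surv(time[idx], event[idx]) ~ g,
      data = tibble(g = droplevels(group[idx])))
    tibble(group1 = g1, group2 = g2, statistic = sd$chisq,
           p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  })
  if (adjust != "none") {
    res <- mutate(res, p_adj = stats::p.adjust(.data$p, method = adjust))
  }
  res
}

#' Cochran-Armitage trend test
#'
#' Tests for a monotone trend in a binary outcome across ordered groups
#' with integer scores 1..k; the two-sided p-value comes from the standard
#' normal reference of the signed trend statistic (equivalently the
#' one-degree chi-square of its square).
#'
#' @param events Event counts per ordered group (or a data frame with
#'   `events` and `totals` columns).
#' @param totals Group sizes.
#' @param scores Group scores; default integer ranks.
#' @return A tibble with the signed `statistic` (z) and two-sided `p`.
#' @export
cochran_armitage_trend <- function(events, totals = NULL,
                                   scores = NULL) {
  if (is.data.frame(events)) {
    totals <- events$totals
    events <- events$events
  }
  k <- length(events)
  if (k < 2L) {
    abort("need at least two ordered groups", class = "pkipr_param_error")
  }
  if (any(events > totals) || any(totals <= 0)) {
    abort("need totals >= events > -1 in every group",
          class = "pkipr_param_error")
  }
  if (is.null(scores)) {
    scores <- seq_len(k)
  }
  tt <- prop.trend.test(events, totals, score = scores)
  chi <- unname(tt$statistic)
  # sign from the score-weighted deviation of event counts
  p_bar <- sum(events) / sum(totals)
  slope <- sum(scores * (events - totals * p_bar))
  z <- sign(slope) * sqrt(chi)
  tibble(statistic = z, p = unname(tt$p.value))
}

#' Hazard ratios of each risk group against a reference
#'
#' Cox proportional-hazards fit on group indicators with the reference
#' level omitted; Wald confidence intervals and p-values per group. The
#' reference row is included with HR fixed at 1.
#'
#' @inheritParams km_estimate
#' @param reference Reference group level (default `"moderate"`).
#' @return A tibble of class `pkip_hr`: `group`, `hr`, `ci_lo`, `ci_hi`,
#'   `p`, `reference`.
#' @export
hazard_ratios_vs_reference <- function(data, time_col = "time",
                                       event_col = "event",
                                       group_col = "group",
                                       reference = "moderate") {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  group <- factor(data[[group_col]], ordered = FALSE)
  if (!reference %in% levels(group) ||
      sum(group == reference, na.rm = TRUE) == 0L) {
    abort("reference group is empty", class = "pkipr_param_error")
  }
  ev_by_group <- tapply(event, group, sum)
  if (any(ev_by_group == 0L, na.rm = TRUE)) {
    warn(paste0("group(s) without events give unstable estimates: ",
                paste(names(ev_by_group)[which(ev_by_group == 0L)],
                      collapse = ", ")))
  }
  group <- stats::relevel(group, ref = reference)
  fit <- survival::coxph(survival::Surv(time, event) ~ g,
                         data = tibble(time = time, event = event,
                                       g = group))
  s <- summary(fit)
  est <- tibble(
    group = sub("^g", "", rownames(s$coefficients)),
    hr = unname(s$conf.int[, "exp(coef)"]),
    ci_lo = unname(s$conf.int[, "lower .95"]),
    ci_hi = unname(s$conf.int[, "upper .95"]),
    p = unname(s$coefficients[, "Pr(>|z|)"])
  )
  out <- bind_rows(
    tibble(group = reference, hr = 1, ci_lo = 1, ci_hi = 1, p = NA_real_),
    est) %>%
    mutate(reference = reference)
  class(out) <- c("pkip_hr", class(out))
  out
}

#' Risk stratification report
#'
#' Bundles the five-group stratification of out-of-fold probabilities with
#' the outcome analyses: per-group AKI/death counts, the Cochran-Armitage
#' trend across groups, pairwise log-rank tests, Kaplan-Meier tables and
#' hazard ratios against the moderate group, for both AKI occurrence (onset
#' time as event time, discharge censoring) and mortality.
#'
#' @param data Data frame with columns `prob`, `aki` (0/1), `aki_time`,
#'   `death` (0/1), `death_time`.
#' @param bins A [risk_bins()] object.
#' @param reference Reference group for the hazard ratios.
#' @return A list of class `pkip_stratification`: `groups`, `by_group`,
#'   `trend_aki`, `trend_death`, and per-outcome `km`, `logrank`, `hr`.
#' @export
risk_stratification <- function(data, bins = risk_bins(),
                                reference = "moderate") {
  data <- assign_risk_group(data, "prob", bins)
  by_group <- data %>%
    group_by(group = .data$risk_group) %>%
    summarise(n = n(), aki = sum(.data$aki), deaths = sum(.data$death),
              .groups = "drop")
  analyse <- function(time_col, event_col) {
    d <- tibble(time = data[[time_col]], event = data[[event_col]],
                group = droplevels(data$risk_group))
    list(km = km_estimate(d),
         logrank = logrank_pairwise(d),
         hr = hazard_ratios_vs_reference(d, reference = reference))
  }
  out <- list(
    groups = data,
    by_group = by_group,
    trend_aki = cochran_armitage_trend(by_group$aki, by_group$n),
    trend_death = cochran_armitage_trend(by_group$deaths, by_group$n),
    aki = analyse("aki_time", "aki"),
    death = analyse("death_time", "death")
  )
  class(out) <- "pkip_stratification"
  out
}

#' @export
print.pkip_stratification <- function(x, ...) {
  cat("<pkip_stratification>\n")
  print(x$by_group)
  cat(sprintf("AKI trend z = %.2f (p = %.2g); mortality trend z = %.2f (p = %.2g)\n",
              x$trend_aki$statistic, x$trend_aki$p,
              x$trend_death$statistic, x$trend_death$p))
  invisible(x)
}
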