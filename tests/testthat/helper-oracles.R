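# Independent brute-force oracles and random-instance builders. Everything
# here is deliberately naive (explicit loops, direct formulas) and shares no
# code with the package internals it checks.

make_record <- function(scr = NULL, uo = NULL, dialysis = NULL,
                        weight = 60, end_time = 168.5, age = 50,
                        death = FALSE, id = "T1", ...) {
  patient_record(
    tibble::tibble(patient_id = id, age = age, weight = weight,
                   end_time = end_time, death = death, ...),
    scr = scr, uo = uo, dialysis = dialysis)
}

# exhaustive scan for the rolling-minimum baseline with first-window fallback
brute_baseline <- function(scr, t, lookback, sub_window = 2,
                           strict = FALSE) {
  vals <- c()
  for (i in seq_len(nrow(scr))) {
    if (scr$time_h[i] >= t - lookback && scr$time_h[i] < t) {
      vals <- c(vals, scr$value[i])
    }
  }
  if (length(vals)) {
    return(min(vals))
  }
  sub <- scr[scr$time_h >= 0 & scr$time_h <= sub_window, ]
  if (nrow(sub) == 0L) {
    return(NA_real_)
  }
  if (strict) sub$value[which.min(sub$time_h)] else min(sub$value)
}

# direct per-measurement creatinine staging
brute_scr_events <- function(scr, th, strict = FALSE) {
  out <- NULL
  eps <- 1e-9
  for (i in seq_len(nrow(scr))) {
    t <- scr$time_h[i]
    if (t > th$obs_horizon) next
    v <- scr$value[i]
    b_r <- brute_baseline(scr, t, th$ratio_lookback,
                          th$substitute_baseline_window, strict)
    b_a <- brute_baseline(scr, t, th$abs_lookback,
                          th$substitute_baseline_window, strict)
    r <- v / b_r
    st <- 0L
    if (r >= th$ratio_bands[1] - eps) st <- 1L
    if (r >= th$ratio_bands[2] - eps) st <- 2L
    if (r >= th$ratio_bands[3] - eps) st <- 3L
    crit <- "scr_ratio"
    if (st == 0L && (v - b_a) >= th$abs_increment - eps) {
      st <- 1L
      crit <- "scr_abs"
    }
    if (st > 0L) {
      out <- rbind(out, data.frame(time_h = t, stage = st,
                                   criterion = crit))
    }
  }
  if (is.null(out)) {
    data.frame(time_h = numeric(), stage = integer(),
               criterion = character())
  } else {
    out
  }
}

# every (window width, grid end) pair, volumes summed interval by interval
brute_uo_events <- function(uo, weight, th) {
  eps <- 1e-9
  ends <- sort(unique(c(uo$start_h, uo$end_h)))
  ends <- ends[ends <= th$obs_horizon + eps]
  overlap <- function(a, b) {
    tot <- 0
    cov <- 0
    for (i in seq_len(nrow(uo))) {
      o <- max(0, min(b, uo$end_h[i]) - max(a, uo$start_h[i]))
      frac <- o / (uo$end_h[i] - uo$start_h[i])
      tot <- tot + frac * uo$volume_ml[i]
      cov <- cov + o
    }
    c(tot, cov)
  }
  specs <- rbind(
    data.frame(w = th$uo_window_stage1, rate = th$uo_rate_stage1,
               stage = 1L, anuria = FALSE),
    data.frame(w = th$uo_window_stage2, rate = th$uo_rate_stage2,
               stage = 2L, anuria = FALSE),
    data.frame(w = th$uo_window_stage3, rate = th$uo_rate_stage3,
               stage = 3L, anuria = FALSE),
    data.frame(w = th$anuria_duration, rate = NA, stage = 3L,
               anuria = TRUE))
  out <- NULL
  for (s in seq_len(nrow(specs))) {
    w <- specs$w[s]
    for (e in ends) {
      if (e < w - eps) next
      vc <- overlap(e - w, e)
      if (vc[2] < th$uo_coverage * w - eps) next
      hit <- if (specs$anuria[s]) {
        vc[1] <= eps
      } else {
        vc[1] / (weight * w) < specs$rate[s] - eps
      }
      if (hit) {
        out <- rbind(out, data.frame(time_h = e, stage = specs$stage[s],
                                     criterion = "uo"))
      }
    }
  }
  if (is.null(out)) {
    data.frame(time_h = numeric(), stage = integer(),
               criterion = character())
  } else {
    out[order(out$time_h, out$stage), ]
  }
}

# merge the brute event lists exactly as the adjudication contract states
brute_adjudicate <- function(record, th, strict = FALSE) {
  cap <- min(th$obs_horizon, record$end_time)
  ev <- rbind(
    brute_scr_events(record$scr, th, strict),
    brute_uo_events(record$uo, record$weight, th),
    {
      d <- record$dialysis[record$dialysis$maintenance &
                             record$dialysis$start_h <= th$obs_horizon, ]
      if (nrow(d)) {
        data.frame(time_h = d$start_h, stage = 3L, criterion = "dialysis")
      } else {
        data.frame(time_h = numeric(), stage = integer(),
                   criterion = character())
      }
    })
  ev <- ev[ev$time_h <= cap + 1e-9, ]
  if (nrow(ev) == 0L) {
    return(list(stage = 0L, onset = NA_real_))
  }
  list(stage = max(ev$stage), onset = min(ev$time_h))
}

# hand product-limit estimator over risk sets
brute_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = tt, survival = surv)
}

# exhaustive accuracy scan over every candidate threshold
brute_threshold <- function(prob, label) {
  cand <- sort(unique(c(min(prob) - 1e-8, prob)))
  best_acc <- -1
  best_t <- NA
  for (t in cand) {
    acc <- mean((prob >= t) == label)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best_t <- t
    }
  }
  list(threshold = best_t, accuracy = best_acc)
}

# random patient records with irregular series, gaps and occasional dialysis
random_record <- function(id = "R") {
  n_scr <- sample(2:12, 1)
  scr <- tibble::tibble(time_h = sort(c(runif(1, 0, 2),
                                        runif(n_scr - 1, 0, 200))),
                        value = runif(n_scr, 0.3, 3.5))
  n_uo <- sample(5:40, 1)
  starts <- sort(sample(0:190, n_uo))
  width <- pmin(runif(n_uo, 0.5, 3), c(diff(starts), Inf))
  weight <- runif(1, 40, 100)
  uo <- tibble::tibble(start_h = starts, end_h = starts + width,
                       volume_ml = runif(n_uo, 0, 1.4) * weight * width)
  dial <- if (runif(1) < 0.15) {
    tibble::tibble(start_h = runif(1, 0, 200),
                   maintenance = runif(1) < 0.6)
  } else {
    NULL
  }
  make_record(scr = scr, uo = uo, dialysis = dial, weight = weight,
              end_time = runif(1, 24, 220), id = id)
}
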