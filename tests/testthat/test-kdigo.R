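th <- kdigo_thresholds()

test_that("rolling baseline takes the in-window minimum with a first-2h substitute", {
  scr <- tibble::tibble(time_h = c(0, 10, 60), value = c(1.0, 0.7, 1.4))
  b <- rolling_baseline(scr, t = 50, lookback = 48)
  expect_equal(b$value, 0.7)
  expect_equal(b$source, "rolling_min")
  # at t = 60 the 48 h window [12, 60) holds nothing: substitute kicks in
  b60 <- rolling_baseline(scr, t = 60, lookback = 48)
  expect_equal(b60$value, 1.0)
  expect_equal(b60$source, "substitute_first2h")

  # nothing strictly before t: first-2h minimum substitutes
  b2 <- rolling_baseline(tibble::tibble(time_h = 0, value = 0.9),
                         t = 0, lookback = 48)
  expect_equal(b2$value, 0.9)
  expect_equal(b2$source, "substitute_first2h")

  # closed left edge: a value exactly lookback hours earlier counts
  scr3 <- tibble::tibble(time_h = c(0, 48), value = c(0.5, 2.0))
  expect_equal(rolling_baseline(scr3, t = 48, lookback = 48)$value, 0.5)

  expect_equal(rolling_baseline(scr3[0, ], t = 10, lookback = 48)$source,
               "none")
})

test_that("rolling baseline matches an exhaustive scan on random series", {
  set.seed(41)
  scr <- tibble::tibble(time_h = sort(runif(200, 0, 200)),
                        value = runif(200, 0.3, 3))
  for (i in 1:500) {
    t <- runif(1, 0, 210)
    lb <- sample(c(48, 168, runif(1, 1, 200)), 1)
    got <- rolling_baseline(scr, t, lb)$value
    expect_equal(got, brute_baseline(scr, t, lb))
  }
})

test_that("creatinine staging applies ratio bands and the absolute increment", {
  # ratio 1.9 from a 0.2 baseline: stage 1 via the ratio criterion
  ev <- scr_stage_events(tibble::tibble(time_h = c(0, 24),
                                        value = c(0.2, 0.38)), th)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$stage, 1L)
  expect_equal(ev$criterion, "scr_ratio")

  # constant series never stages
  const <- tibble::tibble(time_h = c(0, 24, 48), value = 1.0)
  expect_equal(nrow(scr_stage_events(const, th)), 0L)

  # increment 0.35 >= 0.3 flags stage 1 although the ratio is 1.35
  ev3 <- scr_stage_events(tibble::tibble(time_h = c(0, 24),
                                         value = c(1.0, 1.35)), th)
  expect_equal(ev3$stage, 1L)
  expect_equal(ev3$criterion, "scr_abs")

  # band edges are lower-inclusive
  for (probe in list(c(1.5, 1L), c(1.99, 1L), c(2.0, 2L), c(3.0, 3L))) {
    ev <- scr_stage_events(
      tibble::tibble(time_h = c(0, 24), value = c(1.0, probe[1])), th)
    expect_equal(max(ev$stage), as.integer(probe[2]))
  }
})

test_that("urine-output staging finds sustained low-rate windows", {
  # 0.4 mL/kg/h for six hours at 50 kg: stage 1 at the window end
  uo <- tibble::tibble(start_h = 0:5, end_h = 1:6, volume_ml = 20)
  ev <- uo_stage_events(uo, weight = 50, th)
  expect_true(any(ev$stage == 1L & ev$time_h == 6))

  # healthy output never stages
  uo_ok <- tibble::tibble(start_h = 0:47, end_h = 1:48, volume_ml = 60)
  expect_equal(nrow(uo_stage_events(uo_ok, weight = 50, th)), 0L)

  # anuria sustained 12 h is stage 3
  uo_an <- tibble::tibble(start_h = 0:11, end_h = 1:12, volume_ml = 0)
  expect_true(any(uo_stage_events(uo_an, 50, th)$stage == 3L))

  expect_error(uo_stage_events(uo, weight = 0, th),
               class = "pkipr_record_error")
})

test_that("urine-output events equal a brute-force window scan on random records", {
  set.seed(42)
  for (i in 1:60) {
    rec <- random_record()
    got <- uo_stage_events(rec$uo, rec$weight, th)
    want <- brute_uo_events(rec$uo, rec$weight, th)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$time_h, want$time_h)
      expect_equal(got$stage, want$stage)
    }
  }
})

test_that("dialysis events stage 3 only for maintenance sessions", {
  d <- tibble::tibble(start_h = 30, maintenance = TRUE)
  ev <- dialysis_stage_events(d, th)
  expect_equal(ev$time_h, 30)
  expect_equal(ev$stage, 3L)
  expect_equal(nrow(dialysis_stage_events(
    tibble::tibble(start_h = numeric(), maintenance = logical()), th)), 0L)
  # toxin-removal session is not an AKI criterion
  expect_equal(nrow(dialysis_stage_events(
    tibble::tibble(start_h = 10, maintenance = FALSE), th)), 0L)
  # beyond the cap: ignored
  expect_equal(nrow(dialysis_stage_events(
    tibble::tibble(start_h = 169, maintenance = TRUE), th)), 0L)
})

test_that("adjudication resolves stage as max and onset as min across criteria", {
  # creatinine stage 1 at 30 h plus UO stage 2 at 50 h
  rec <- make_record(
    scr = tibble::tibble(time_h = c(0, 30), value = c(1.0, 1.6)),
    uo = tibble::tibble(start_h = c(0:37, 38:49), end_h = c(1:38, 39:50),
                        volume_ml = c(rep(60, 38), rep(10, 12))),
    weight = 50)
  lab <- adjudicate(rec, th)
  expect_true(lab$has_aki)
  expect_equal(lab$stage, 2L)
  expect_equal(lab$onset_h, 30)
  expect_equal(lab$criterion, "scr_ratio")

  # survivor with unremarkable records
  quiet <- make_record(scr = tibble::tibble(time_h = c(0, 24), value = 1.0))
  lab0 <- adjudicate(quiet, th)
  expect_false(lab0$has_aki)
  expect_equal(lab0$stage, 0L)
  expect_true(is.na(lab0$onset_h))

  # a rise first seen beyond the 168 h cap does not count
  late <- make_record(scr = tibble::tibble(time_h = c(0, 180),
                                           value = c(1.0, 2.0)),
                      end_time = 200)
  expect_false(adjudicate(late, th)$has_aki)

  # death before any event leaves the label non-AKI
  early_death <- make_record(
    scr = tibble::tibble(time_h = c(0, 40), value = c(1.0, 2.0)),
    end_time = 20, death = TRUE)
  expect_false(adjudicate(early_death, th)$has_aki)
})

test_that("adjudication agrees with the brute-force oracle on random records", {
  set.seed(43)
  for (i in 1:120) {
    rec <- random_record()
    got <- adjudicate(rec, th)
    want <- brute_adjudicate(rec, th)
    expect_equal(got$stage, want$stage)
    if (want$stage > 0) {
      expect_equal(got$onset_h, want$onset)
    }
  }
})

test_that("the ambiguity flag marks labels that vanish under the strict baseline", {
  # transient dip to 0.6 inside the first 2 h accepted as baseline
  dip <- make_record(scr = tibble::tibble(time_h = c(0, 1.5, 24),
                                          value = c(1.0, 0.6, 1.0)))
  lab <- adjudicate(dip, th)
  expect_true(lab$has_aki)
  expect_true(lab$ambiguous)
  expect_false(adjudicate(dip, th, strict = TRUE)$has_aki)

  # a monotone rise stages under either baseline convention
  rise <- make_record(scr = tibble::tibble(time_h = c(0, 1, 24),
                                           value = c(0.8, 0.9, 1.6)))
  lab2 <- adjudicate(rise, th)
  expect_true(lab2$has_aki)
  expect_false(lab2$ambiguous)
})

test_that("ambiguous flags equal the lenient/strict disagreement set on a cohort", {
  coh <- simulate_cohort(generator_params(n_patients = 80, seed = 9))
  lenient <- adjudicate_cohort(coh)
  strict <- adjudicate_cohort(coh, strict = TRUE)
  expect_equal(lenient$ambiguous, lenient$has_aki & !strict$has_aki)
})

test_that("cohort filters apply exclusion rules in fixed order", {
  scr_ok <- tibble::tibble(time_h = c(0, 1), value = 1.0)
  minor <- make_record(scr = scr_ok, age = 17)
  expect_equal(apply_cohort_filters(list(minor), th)$reason, "adult_only")

  pq <- make_record(scr = scr_ok, age = 17, paraquat = TRUE)
  # age outranks paraquat in the fixed order
  expect_equal(apply_cohort_filters(list(pq), th)$reason, "adult_only")
  pq2 <- make_record(scr = scr_ok, paraquat = TRUE)
  expect_equal(apply_cohort_filters(list(pq2), th)$reason, "paraquat")

  no_base <- make_record(scr = tibble::tibble(time_h = 5, value = 1.0))
  expect_equal(apply_cohort_filters(list(no_base), th)$reason, "no_baseline")

  high <- make_record(scr = tibble::tibble(time_h = c(0, 1, 24), value = 3.0))
  expect_equal(apply_cohort_filters(list(high), th)$reason,
               "baseline_gt_cutoff")
  # exactly 2.5 is admitted
  at_cut <- make_record(scr = tibble::tibble(time_h = c(0, 1, 24),
                                             value = 2.5))
  expect_true(apply_cohort_filters(list(at_cut), th)$included)

  early <- make_record(scr = scr_ok, end_time = 1.5)
  expect_equal(apply_cohort_filters(list(early), th)$reason,
               "event_within_2h")

  ok <- make_record(scr = scr_ok)
  dec <- apply_cohort_filters(list(ok), th)
  expect_true(dec$included)
  expect_equal(dec$reason, "none")
})

test_that("staging is monotone in the creatinine excursion and urine volume", {
  set.seed(44)
  for (i in 1:40) {
    rec <- random_record()
    lab <- adjudicate(rec, th)
    # inflate every post-2h creatinine: stage can only rise
    c_mult <- runif(1, 1, 2)
    rec_up <- rec
    late <- rec_up$scr$time_h > 2
    rec_up$scr$value[late] <- rec_up$scr$value[late] * c_mult
    expect_gte(adjudicate(rec_up, th)$stage, lab$stage)
    # add urine volume: UO stage can only fall
    rec_wet <- rec
    rec_wet$uo$volume_ml <- rec_wet$uo$volume_ml + runif(1, 0, 100)
    uo_stage <- function(r) {
      ev <- uo_stage_events(r$uo, r$weight, th)
      ev <- ev[ev$time_h <= min(th$obs_horizon, r$end_time) + 1e-9, ]
      if (nrow(ev)) max(ev$stage) else 0L
    }
    expect_lte(uo_stage(rec_wet), uo_stage(rec))
  }
})

test_that("no onset is ever emitted past the observation cap", {
  set.seed(45)
  for (i in 1:60) {
    lab <- adjudicate(random_record(), th)
    if (lab$has_aki) {
      expect_lte(lab$onset_h, th$obs_horizon)
    }
  }
})
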