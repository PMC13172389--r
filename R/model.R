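#' Univariate Cox proportional-hazards screen
#'
#' Fits one Cox model per candidate variable against time to AKI (onset for
#' cases, discharge for censored non-cases) and keeps variables with a
#' two-sided p-value below `alpha` (default 0.1). Multi-level factors are
#' tested with the likelihood-ratio test for the whole term; the reported
#' hazard ratio is that of the first non-reference level.
#'
#' @param data A data frame holding the candidate columns plus the time and
#'   event columns.
#' @param time_col,event_col Names of the follow-up time (hours, positive)
#'   and event-indicator (0/1 or logical) columns.
#' @param variables Candidate column names; defaults to every column other
#'   than the time/event columns and `patient_id`.
#' @param alpha Screening level on the p-value.
#' @return A tibble of class `pkip_screen`: `variable`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `selected`.
#' @export
univariate_cox_screen <- function(data, time_col = "time",
                                  event_col = "event",
                                  variables = NULL, alpha = 0.1) {
  time <- data[[time_col]]
  event <- as.integer(data[[event_col]])
  if (any(time <= 0)) {
    abort("follow-up times must be positive", class = "pkipr_param_error")
  }
  if (!all(event %in% c(0L, 1L))) {
    abort("event indicator must be binary", class = "pkipr_param_error")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data), c(time_col, event_col, "patient_id"))
  }
  res <- purrr::map_dfr(variables, function(nm) {
    x <- data[[nm]]
    fit <- survival::coxph(survival::Surv(time, event) ~ x,
                           data = tibble(time = time, event = event, x = x))
    s <- summary(fit)
    multi <- nrow(s$coefficients) > 1L
    p <- if (multi) {
      # term-level LRT for factors with >2 levels
      as.numeric(s$logtest["pvalue"])
    } else {
      s$coefficients[1, "Pr(>|z|)"]
    }
    tibble(variable = nm,
           hr = unname(s$conf.int[1, "exp(coef)"]),
           ci_lo = unname(s$conf.int[1, "lower .95"]),
           ci_hi = unname(s$conf.int[1, "upper .95"]),
           p = unname(p))
  })
  out <- mutate(res, selected = .data$p < alpha)
  class(out) <- c("pkip_screen", class(out))
  out
}

#' Feature-selection specification
#'
#' @param method One of `"full"`, `"clinical"`, `"stepwise"`, `"lasso"`.
#' @param clinical_vars Character vector for the clinical method.
#' @param entry_p,exit_p Stepwise entry/exit significance levels.
#' @param nfolds,seed Internal cross-validation folds and seed for the LASSO
#'   penalty choice.
#' @return A list of class `selection_spec`.
#' @export
selection_spec <- function(method = c("full", "clinical", "stepwise",
                                      "lasso"),
                           clinical_vars = NULL, entry_p = 0.05,
                           exit_p = 0.10, nfolds = 5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "clinical" && is.null(clinical_vars)) {
    abort("clinical selection needs clinical_vars",
          class = "pkipr_param_error")
  }
  structure(list(method = method, clinical_vars = clinical_vars,
                 entry_p = entry_p, exit_p = exit_p,
                 nfolds = as.integer(nfolds), seed = as.integer(seed)),
            class = "selection_spec")
}

# model matrix without intercept; factors/logicals expanded to dummies,
# with a map back to source variable names
expand_design <- function(data, variables) {
  fml <- as.formula(paste("~", paste0("`", variables, "`",
                                      collapse = " + ")))
  mm <- stats::model.matrix(fml, data = data)
  assign <- attr(mm, "assign")
  mm <- mm[, assign != 0, drop = FALSE]
  list(x = mm, map = variables[assign[assign != 0]])
}

#' Select model features
#'
#' `full` keeps every candidate; `clinical` intersects the candidates with a
#' configured list (error if the intersection is empty); `stepwise` runs
#' forward/backward logistic selection with Wald entry p 0.05 and exit p
#' 0.10; `lasso` keeps the nonzero-coefficient set of an L1-penalised
#' logistic regression with the penalty chosen by seeded internal
#' cross-validation (one-standard-error rule).
#'
#' @param data Data frame of candidate feature columns.
#' @param outcome Binary outcome vector (0/1 or logical), one per row.
#' @param spec A [selection_spec()].
#' @param variables Candidate names; defaults to all columns except
#'   `patient_id`.
#' @return Character vector of selected variable names.
#' @export
select_features <- function(data, outcome, spec = selection_spec("lasso"),
                            variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(data), "patient_id")
  }
  if (length(variables) == 0L) {
    abort("candidate set is empty", class = "pkipr_param_error")
  }
  y <- as.integer(outcome)
  switch(spec$method,
    full = variables,
    clinical = {
      keep <- intersect(variables, spec$clinical_vars)
      if (length(keep) == 0L) {
        abort("clinical list shares no variable with the candidates",
              class = "pkipr_param_error")
      }
      keep
    },
    stepwise = stepwise_logistic(data, y, variables, spec$entry_p,
                                 spec$exit_p),
    lasso = {
      d <- expand_design(data, variables)
      with_local_seed(spec$seed, {
        foldid <- sample(rep_len(seq_len(spec$nfolds), length(y)))
        cv <- glmnet::cv.glmnet(d$x, y, family = "binomial", alpha = 1,
                                foldid = foldid)
        # the sparser one-SE rule keeps false inclusions low
        beta <- as.matrix(coef(cv, s = "lambda.1se"))[-1, 1]
        unique(d$map[beta != 0])
      })
    }
  )
}

stepwise_logistic <- function(data, y, variables, entry_p, exit_p) {
  current <- character()
  df <- data
  df$.y <- y
  term_p <- function(vars) {
    fml <- as.formula(paste(".y ~", paste0("`", vars, "`",
                                           collapse = " + ")))
    fit <- glm(fml, family = binomial(), data = df)
    drop <- stats::drop1(fit, test = "LRT")
    nm <- gsub("`", "", rownames(drop)[-1], fixed = TRUE)
    setNames(drop[["Pr(>Chi)"]][-1], nm)
  }
  repeat {
    changed <- FALSE
    # forward: best candidate by LRT p-value against the current model
    cand <- setdiff(variables, current)
    if (length(cand)) {
      ps <- vapply(cand, function(v) {
        unname(term_p(c(current, v))[v])
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < entry_p) {
        current <- c(current, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward: drop the weakest retained term
    if (length(current) > 1L) {
      ps <- term_p(current)
      worst <- which.max(ps)
      if (ps[worst] > exit_p) {
        current <- current[names(ps)[worst] != current]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current
}

#' Reference learners
#'
#' Learners are pluggable through a fit/predict-probability contract: a list
#' with `name`, `fit(x, y, params)`, `predict_prob(model, x)` and a default
#' hyperparameter `grid` (a data frame, one row per grid point).
#' `learner_logistic()` is an L2-penalised logistic regression (glmnet,
#' ridge path); `learner_gbt()` gradient-boosted trees (xgboost).
#'
#' @return A `pkip_learner` object.
#' @export
learner_logistic <- function() {
  # glmnet requires >= 2 columns; pad single-feature designs with a zero
  pad <- function(x) if (ncol(x) < 2L) cbind(x, .pad = 0) else x
  structure(list(
    name = "ref-logistic",
    fit = function(x, y, params) {
      glmnet::glmnet(pad(x), y, family = "binomial", alpha = 0,
                     lambda = params$lambda)
    },
    predict_prob = function(model, x) {
      as.numeric(predict(model, newx = pad(x), type = "response"))
    },
    grid = data.frame(lambda = c(0.0001, 0.001, 0.01, 0.1))
  ), class = "pkip_learner")
}

#' @rdname learner_logistic
#' @export
learner_gbt <- function() {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    abort("the gradient-boosted learner needs the xgboost package",
          class = "pkipr_param_error")
  }
  structure(list(
    name = "ref-gbt",
    fit = function(x, y, params) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y),
        nrounds = params$nrounds, verbose = 0)
    },
    predict_prob = function(model, x) {
      as.numeric(predict(model, xgboost::xgb.DMatrix(x)))
    },
    grid = expand.grid(nrounds = c(50, 100), max_depth = c(2, 3),
                       eta = 0.1)
  ), class = "pkip_learner")
}

# stratified fold assignment: within each stratum x outcome cell, a seeded
# shuffle is dealt round-robin, so per-fold joint frequencies are within one
# patient of exact proportionality
make_stratified_folds <- function(y, strata, k, seed) {
  cells <- interaction(strata, y, drop = TRUE)
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in levels(cells)) {
      idx <- which(cells == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Rank-based AUROC
#'
#' Mann-Whitney form with midranks for ties.
#'
#' @param prob Predicted probabilities (any monotone score).
#' @param label Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(prob, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  r <- rank(prob)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average-precision AUPRC
#'
#' Step-wise average precision: mean of the precision at the rank of each
#' positive, scores sorted descending (ties grouped).
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(prob, label) {
  label <- as.integer(label)
  n_pos <- sum(label)
  if (n_pos == 0L) {
    return(NA_real_)
  }
  ord <- order(-prob)
  lab <- label[ord]
  pr <- prob[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  # members of a tied-score block share the precision at the block's end
  block_id <- cumsum(!duplicated(pr))
  end_idx <- stats::ave(seq_along(pr), block_id, FUN = max)
  sum(prec[end_idx][lab == 1L]) / n_pos
}

percentile_ci <- function(stat_fn, prob, label, n_boot = 1000L, seed = 1L) {
  with_local_seed(seed, {
    n <- length(prob)
    vals <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stat_fn(prob[idx], label[idx])
    }, numeric(1))
    quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })
}

#' Cross-validated classifier training with grid search
#'
#' Stratified k-fold cross-validation (joint outcome-by-stratum cells,
#' within one patient of proportionality). For every grid point each fold is
#' scored out-of-fold on models fit to the remaining folds; the grid point
#' with the highest pooled out-of-fold AUROC wins (ties to the first row).
#' The winner's out-of-fold probabilities feed threshold optimisation,
#' calibration and downstream risk stratification.
#'
#' @param data Feature data frame (numeric/binary/factor columns).
#' @param outcome Binary outcome vector.
#' @param strata Stratification factor (e.g. pesticide category); folds are
#'   balanced jointly on `strata` and `outcome`. `NULL` stratifies on the
#'   outcome alone.
#' @param learner A `pkip_learner` (see [learner_logistic()]).
#' @param folds Number of folds (default 5).
#' @param grid Hyperparameter data frame; defaults to the learner's grid.
#' @param seed Seed for fold assignment and bootstrap CIs.
#' @param variables Feature columns; defaults to all but `patient_id`.
#' @param n_boot Bootstrap resamples for the percentile CIs.
#' @return An object of class `pkip_cv`: fold assignment, out-of-fold
#'   probabilities, grid results, chosen hyperparameters, pooled and
#'   per-fold AUROC/AUPRC with CIs, Brier score, calibration table and the
#'   accuracy-optimal threshold with its metrics.
#' @export
train_cv <- function(data, outcome, strata = NULL, learner = learner_logistic(),
                     folds = 5L, grid = NULL, seed = 1L, variables = NULL,
                     n_boot = 1000L) {
  y <- as.integer(outcome)
  if (length(unique(y)) < 2L) {
    abort("outcome must contain both classes", class = "pkipr_param_error")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data), "patient_id")
  }
  if (is.null(strata)) {
    strata <- rep(1L, length(y))
  }
  if (is.null(grid)) {
    grid <- learner$grid
  }
  d <- expand_design(data, variables)
  fold <- make_stratified_folds(y, strata, folds, seed)
  if (any(tabulate(fold, folds) == 0L) ||
      any(vapply(seq_len(folds),
                 function(k) length(unique(y[fold == k])) < 2L,
                 logical(1)))) {
    abort("degenerate fold: a validation fold lacks one class",
          class = "pkipr_stratification_error")
  }
  grid_oof <- lapply(seq_len(nrow(grid)), function(g) {
    oof <- rep(NA_real_, length(y))
    for (k in seq_len(folds)) {
      tr <- fold != k
      model <- learner$fit(d$x[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE])
      oof[!tr] <- learner$predict_prob(model, d$x[!tr, , drop = FALSE])
    }
    oof
  })
  grid_auc <- vapply(grid_oof, auroc, numeric(1), label = y)
  best <- which.max(grid_auc)
  oof <- pmin(pmax(grid_oof[[best]], 0), 1)
  per_fold <- purrr::map_dfr(seq_len(folds), function(k) {
    tibble(fold = k, n = sum(fold == k),
           auroc = auroc(oof[fold == k], y[fold == k]),
           auprc = auprc(oof[fold == k], y[fold == k]))
  })
  thr <- optimize_threshold(oof, y)
  cal <- calibration(oof, y)
  res <- structure(list(
    learner = learner$name,
    fold = fold,
    oof = tibble(row = seq_along(y), fold = fold, prob = oof, label = y),
    grid = grid, grid_auroc = grid_auc,
    best_params = grid[best, , drop = FALSE],
    auroc = auroc(oof, y),
    auroc_ci = percentile_ci(auroc, oof, y, n_boot, seed),
    auprc = auprc(oof, y),
    auprc_ci = percentile_ci(auprc, oof, y, n_boot, seed),
    per_fold = per_fold,
    brier = cal$brier,
    calibration = cal$table,
    threshold = thr,
    seed = seed
  ), class = "pkip_cv")
  res
}

#' @export
print.pkip_cv <- function(x, ...) {
  cat(sprintf(
    paste0("<pkip_cv %s: pooled AUROC %.3f (%.3f-%.3f), AUPRC %.3f, ",
           "Brier %.3f, threshold %.3f>\n"),
    x$learner, x$auroc, x$auroc_ci[1], x$auroc_ci[2], x$auprc, x$brier,
    x$threshold$threshold))
  invisible(x)
}

#' Accuracy-optimal classification threshold
#'
#' Scans candidate thresholds (every sorted unique probability plus one
#' below the minimum, classifying `prob >= t` as positive) and returns the
#' accuracy maximiser; ties resolve to the lowest threshold. Precision,
#' recall and F1 at the optimum are reported (0 when undefined).
#'
#' @param prob Out-of-fold probabilities (or a `pkip_cv` object).
#' @param label Binary labels (ignored when `prob` is a `pkip_cv`).
#' @return A list: `threshold`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
optimize_threshold <- function(prob, label = NULL) {
  if (inherits(prob, "pkip_cv")) {
    label <- prob$oof$label
    prob <- prob$oof$prob
  }
  y <- as.integer(label)
  cand <- sort(unique(prob))
  cand <- c(cand[1] - 1e-8, cand)
  acc <- vapply(cand, function(t) mean((prob >= t) == y), numeric(1))
  t_star <- cand[which.max(acc)]
  pred <- as.integer(prob >= t_star)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(threshold = t_star, accuracy = max(acc), precision = precision,
       recall = recall, f1 = f1)
}

#' Calibration table and Brier score
#'
#' Equal-width probability bins compare mean predicted probability with the
#' observed event rate; the Brier score is the mean squared difference
#' between probability and outcome.
#'
#' @param prob Predicted probabilities (or a `pkip_cv` object).
#' @param label Binary labels.
#' @param n_bins Number of equal-width bins on `[0, 1]`.
#' @return A list with `table` (tibble: `bin`, `n`, `mean_pred`,
#'   `obs_rate`) and `brier`.
#' @export
calibration <- function(prob, label = NULL, n_bins = 10L) {
  if (inherits(prob, "pkip_cv")) {
    label <- prob$oof$label
    prob <- prob$oof$prob
  }
  y <- as.integer(label)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(prob, edges, rightmost.closed = TRUE), n_bins)
  tab <- tibble(bin = bin, prob = prob, y = y) %>%
    group_by(.data$bin) %>%
    summarise(n = n(), mean_pred = mean(.data$prob),
              obs_rate = mean(.data$y), .groups = "drop")
  list(table = tab, brier = mean((prob - y)^2))
}

#' Brier score
#'
#' @inheritParams calibration
#' @return Mean squared error of the probabilities.
#' @export
brier_score <- function(prob, label) {
  mean((prob - as.integer(label))^2)
}
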