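#' Default feature schema
#'
#' The 13 model features with their kinds: numeric labs/vitals measured
#' within the first window, plus static binaries. An optional extra feature
#' can be appended through `extra`.
#'
#' @param extra Optional one-row data frame (`name`, `kind`) for an
#'   additional variable.
#' @return A tibble with columns `name` and `kind`
#'   (`numeric`/`binary`/`categorical`).
#' @export
feature_schema <- function(extra = NULL) {
  cat <- default_feature_catalog()
  schema <- tibble(name = cat$name, kind = cat$kind)
  if (!is.null(extra)) {
    schema <- bind_rows(schema, as_tibble(extra))
  }
  schema
}

#' First-window maximum aggregation
#'
#' Collapses each patient's time-stamped measurements within `[0, window]`
#' hours of presentation (closed at the boundary) to the per-variable
#' maximum — the "worst-case" summary. Variables with no in-window
#' measurement are left missing; static fields pass through unchanged.
#'
#' @param cohort A `pkip_cohort`.
#' @param window Aggregation window in hours (default 2).
#' @param schema A [feature_schema()] tibble declaring each variable's kind.
#' @return A feature tibble (one row per patient, class `pkip_features`)
#'   with attributes `schema` and `stage = "raw"`.
#' @export
aggregate_first_window <- function(cohort, window = 2,
                                   schema = feature_schema()) {
  if (window <= 0) {
    abort("window must be positive", class = "pkipr_param_error")
  }
  ts <- cohort$timeseries %>%
    filter(.data$variable %in% schema$name,
           .data$t_start_h >= 0, .data$t_start_h <= window) %>%
    group_by(.data$patient_id, .data$variable) %>%
    summarise(value = max(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  static_cols <- intersect(schema$name, names(cohort$static))
  out <- cohort$static %>%
    select(all_of(c("patient_id", static_cols))) %>%
    left_join(ts, by = "patient_id")
  for (nm in setdiff(schema$name, names(out))) {
    out[[nm]] <- NA_real_
  }
  out <- select(out, all_of(c("patient_id", schema$name)))
  # character statics declared binary/categorical become factors
  for (nm in schema$name[schema$kind != "numeric"]) {
    if (is.character(out[[nm]])) {
      out[[nm]] <- factor(out[[nm]])
    }
  }
  new_features(out, schema, "raw")
}

# lm prediction that tolerates collinear feature subsets (e.g. a binary
# column with no variation in a small fit set) without the noisy warning
predict_quietly <- function(fit, newdata) {
  withCallingHandlers(
    predict(fit, newdata = newdata),
    warning = function(w) {
      if (grepl("rank-deficient", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

new_features <- function(data, schema, stage) {
  structure(as_tibble(data), schema = schema, stage = stage,
            class = c("pkip_features", class(as_tibble(data))))
}

#' @export
print.pkip_features <- function(x, ...) {
  cat(sprintf("<pkip_features: %d patients, stage '%s'>\n",
              nrow(x), attr(x, "stage")))
  NextMethod()
}

feature_stage <- function(x) attr(x, "stage")

#' Fit the imputation model
#'
#' Categorical and binary columns are imputed with the column mode (ties
#' resolved to the lexicographically smallest level). Numeric columns are
#' imputed by a seeded chained-equations loop: starting from column medians,
#' each incomplete numeric column is regressed on all other feature columns
#' and its missing cells replaced by the prediction plus Gaussian noise at
#' the residual scale, cycling for `iterations` rounds. The fitted object
#' stores the modes, medians and final-round regressions so held-out rows
#' are completed with training statistics only.
#'
#' @param features A raw-stage `pkip_features` tibble.
#' @param seed Integer seed; fixed seed gives deterministic completion.
#' @param iterations Number of chained-equation cycles (default 10).
#' @return An object of class `pkip_imputer`.
#' @export
fit_imputer <- function(features, seed = 1L, iterations = 10L) {
  schema <- attr(features, "schema")
  x <- features
  all_missing <- names(x)[vapply(x, function(col) all(is.na(col)),
                                 logical(1))]
  all_missing <- intersect(all_missing, schema$name)
  if (length(all_missing)) {
    abort(paste0("column(s) entirely missing: ",
                 paste(all_missing, collapse = ", ")),
          class = "pkipr_impute_error")
  }
  cat_cols <- schema$name[schema$kind != "numeric"]
  num_cols <- schema$name[schema$kind == "numeric"]
  modes <- lapply(setNames(cat_cols, cat_cols), function(nm) {
    tab <- table(x[[nm]])
    lv <- names(tab)[tab == max(tab)]
    sort(lv)[1L]
  })
  medians <- lapply(setNames(num_cols, num_cols),
                    function(nm) median(x[[nm]], na.rm = TRUE))
  filled <- impute_start(x, schema, modes, medians)
  miss_num <- num_cols[vapply(num_cols, function(nm) anyNA(x[[nm]]),
                              logical(1))]
  models <- list()
  with_local_seed(seed, {
    for (it in seq_len(iterations)) {
      for (nm in miss_num) {
        rhs <- setdiff(schema$name, nm)
        fml <- as.formula(paste0("`", nm, "` ~ ",
                                 paste0("`", rhs, "`", collapse = " + ")))
        obs <- !is.na(x[[nm]])
        fit <- lm(fml, data = filled[obs, ])
        sigma <- sqrt(sum(fit$residuals^2) /
                        max(1, fit$df.residual))
        pred <- predict_quietly(fit, filled[!obs, ])
        filled[[nm]][!obs] <- pred + rnorm(sum(!obs), 0, sigma)
        models[[nm]] <- list(fit = fit, sigma = sigma)
      }
    }
  })
  structure(list(schema = schema, modes = modes, medians = medians,
                 models = models, iterations = iterations, seed = seed,
                 completed = filled),
            class = "pkip_imputer")
}

impute_start <- function(x, schema, modes, medians) {
  for (nm in names(modes)) {
    na <- is.na(x[[nm]])
    if (any(na)) {
      val <- modes[[nm]]
      if (is.factor(x[[nm]])) {
        x[[nm]][na] <- factor(val, levels = levels(x[[nm]]))
      } else if (is.logical(x[[nm]])) {
        x[[nm]][na] <- as.logical(val)
      } else if (is.numeric(x[[nm]])) {
        x[[nm]][na] <- as.numeric(val)
      } else {
        x[[nm]][na] <- val
      }
    }
  }
  for (nm in names(medians)) {
    x[[nm]][is.na(x[[nm]])] <- medians[[nm]]
  }
  x
}

#' Impute missing feature values
#'
#' Completes a feature matrix with a fitted (or freshly fitted) imputer; the
#' result carries no missing cells and provenance stage `"imputed"`.
#' Training rows receive their chained-equations completion; new rows are
#' completed with the stored training regressions (seeded noise), never
#' refitting, so cross-validation folds stay leakage-free.
#'
#' @param features A raw-stage `pkip_features` tibble.
#' @param imputer Optional fitted [fit_imputer()]; fitted on `features` when
#'   `NULL`.
#' @param seed Seed used when fitting (ignored when `imputer` is supplied).
#' @return An imputed `pkip_features` tibble.
#' @export
impute_features <- function(features, imputer = NULL, seed = 1L) {
  if (is.null(imputer)) {
    imputer <- fit_imputer(features, seed = seed)
    out <- imputer$completed
  } else {
    out <- apply_imputer(imputer, features)
  }
  new_features(out, attr(features, "schema") %||% imputer$schema, "imputed")
}

# complete new rows with stored training modes/medians/regressions
apply_imputer <- function(imputer, newdata) {
  x <- impute_start(as_tibble(newdata), imputer$schema, imputer$modes,
                    imputer$medians)
  with_local_seed(imputer$seed, {
    for (it in seq_len(imputer$iterations)) {
      for (nm in names(imputer$models)) {
        na <- is.na(newdata[[nm]])
        if (any(na)) {
          m <- imputer$models[[nm]]
          x[[nm]][na] <- predict_quietly(m$fit, x[na, ]) +
            rnorm(sum(na), 0, m$sigma)
        }
      }
    }
  })
  x
}

#' Robust scaling of numeric features
#'
#' Transforms each numeric column as `(x - median) / IQR`, the IQR being
#' `Q3 - Q1` with linear-interpolation quantiles. A zero IQR divides by 1
#' with a warning. The fitted scaler (attached as attribute `"scaler"`, or
#' from [fit_robust_scaler()]) can be re-applied to held-out rows with
#' training statistics via [apply_scaler()].
#'
#' @param features An imputed-stage `pkip_features` tibble.
#' @param scaler Optional fitted scaler; fitted on `features` when `NULL`.
#' @return A scaled `pkip_features` tibble with attribute `scaler`.
#' @export
robust_scale <- function(features, scaler = NULL) {
  if (is.null(scaler)) {
    scaler <- fit_robust_scaler(features)
  }
  out <- apply_scaler(features, scaler)
  out <- new_features(out, attr(features, "schema"), "scaled")
  attr(out, "scaler") <- scaler
  out
}

#' @rdname robust_scale
#' @export
fit_robust_scaler <- function(features) {
  schema <- attr(features, "schema")
  num_cols <- schema$name[schema$kind == "numeric"]
  stats <- purrr::map(setNames(num_cols, num_cols), function(nm) {
    q <- quantile(features[[nm]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                  names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    if (iqr == 0) {
      warn(paste0("zero IQR in column '", nm, "'; dividing by 1"))
      iqr <- 1
    }
    c(center = q[2], scale = iqr)
  })
  structure(list(stats = stats), class = "pkip_scaler")
}

#' @rdname robust_scale
#' @param newdata A feature tibble to transform with the fitted statistics.
#' @export
apply_scaler <- function(newdata, scaler) {
  for (nm in names(scaler$stats)) {
    s <- scaler$stats[[nm]]
    newdata[[nm]] <- (newdata[[nm]] - s[["center"]]) / s[["scale"]]
  }
  newdata
}
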