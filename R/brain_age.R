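#' Assemble one subject's multimodal feature row
#'
#' Concatenates, in this fixed order: the upper triangle (excluding the
#' diagonal) of the scaled structural-connectivity matrix (`sc:i-j`), the
#' upper triangle of the functional-connectivity matrix (`fc:i-j`), the R
#' dynamic-connectivity values (`tv:k`, or `sl:i-j` upper triangle when a
#' synchronization-likelihood matrix is supplied), and the 3R tissue-density
#' values (`gm:k`, `wm:k`, `csf:k`).
#'
#' @param subject Subject record providing `tissue_density` (3 x R).
#' @param fc A [connectivity_matrix()] of kind `"fc"`.
#' @param sc A [connectivity_matrix()] of kind `"sc"`.
#' @param dynamic Either an R-vector of nodal temporal variability, or a
#'   `connectivity_matrix` of kind `"sl"`.
#' @return Named numeric feature row.
#' @export
assemble_features <- function(subject, fc, sc, dynamic) {
  fcv <- conn_values(fc)
  scv <- conn_values(sc)
  R <- nrow(fcv)
  if (nrow(scv) != R) stop("dimension mismatch: sc has ", nrow(scv),
                           " regions, fc has ", R)
  dens <- subject$tissue_density
  if (ncol(dens) != R) stop("dimension mismatch: tissue density has ",
                            ncol(dens), " regions, fc has ", R)
  ut <- which(upper.tri(fcv), arr.ind = TRUE)
  pair_names <- function(prefix) sprintf("%s:%d-%d", prefix, ut[, 1], ut[, 2])

  if (inherits(dynamic, "connectivity_matrix")) {
    dynv <- conn_values(dynamic)
    if (nrow(dynv) != R) stop("dimension mismatch: dynamic connectivity has ",
                              nrow(dynv), " regions, fc has ", R)
    dyn_block <- stats::setNames(dynv[upper.tri(dynv)], pair_names("sl"))
  } else {
    if (length(dynamic) != R) stop("dimension mismatch: temporal variability has ",
                                   length(dynamic), " values, fc has ", R, " regions")
    dyn_block <- stats::setNames(as.numeric(dynamic), sprintf("tv:%d", seq_len(R)))
  }
  c(stats::setNames(scv[upper.tri(scv)], pair_names("sc")),
    stats::setNames(fcv[upper.tri(fcv)], pair_names("fc")),
    dyn_block,
    stats::setNames(dens["gm", ], sprintf("gm:%d", seq_len(R))),
    stats::setNames(dens["wm", ], sprintf("wm:%d", seq_len(R))),
    stats::setNames(dens["csf", ], sprintf("csf:%d", seq_len(R))))
}

#' Build the cohort feature matrix
#'
#' Runs the connectivity stage for every subject (static FC, volume-scaled SC,
#' and either nodal temporal variability from sliding-window dynamic FC or a
#' synchronization-likelihood matrix) and stacks the per-subject feature rows.
#'
#' @param cohort A `cohort`.
#' @param window A [window_spec()]; defaults to length 50, step 2 over the
#'   cohort's time-series length.
#' @param dynamic_feature `"tv"` (default) or `"sl"`.
#' @param sl_params An [sl_params()] object, used when `dynamic_feature = "sl"`.
#' @param sc_convention Volume-scaling convention passed to [scale_sc()].
#' @return Numeric matrix, one row per subject (rownames are subject ids),
#'   with named columns as in [assemble_features()].
#' @export
cohort_features <- function(cohort, window = NULL,
                            dynamic_feature = c("tv", "sl"),
                            sl_params = NULL,
                            sc_convention = "sum") {
  dynamic_feature <- match.arg(dynamic_feature)
  if (is.null(sl_params)) sl_params <- connage::sl_params()
  tp <- nrow(cohort[[1]]$time_series)
  if (is.null(window)) window <- window_spec(tp)
  R <- ncol(cohort[[1]]$time_series)
  ut <- upper.tri(matrix(0, R, R))
  rows <- lapply(cohort, function(s) {
    fc <- stats::cor(s$time_series)
    if (anyNA(fc)) check_no_constant_columns(s$time_series)
    sc <- conn_values(scale_sc(s$sc_counts, s$node_volumes,
                               convention = sc_convention))
    dyn <- if (dynamic_feature == "tv") {
      fast_tv(s$time_series, window)
    } else {
      conn_values(sl_matrix(s$time_series, sl_params))[ut]
    }
    c(sc[ut], fc[ut], dyn, s$tissue_density["gm", ],
      s$tissue_density["wm", ], s$tissue_density["csf", ])
  })
  x <- do.call(rbind, rows)
  colnames(x) <- feature_names(R, dynamic_feature)
  rownames(x) <- vapply(cohort, `[[`, character(1), "subject_id")
  x
}

# Canonical feature-column names for R regions, in assembly order.
feature_names <- function(R, dynamic_feature = "tv") {
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  pair <- function(prefix) sprintf("%s:%d-%d", prefix, ut[, 1], ut[, 2])
  dyn <- if (dynamic_feature == "tv") sprintf("tv:%d", seq_len(R)) else pair("sl")
  c(pair("sc"), pair("fc"), dyn,
    sprintf("gm:%d", seq_len(R)), sprintf("wm:%d", seq_len(R)),
    sprintf("csf:%d", seq_len(R)))
}

# Cross-validated Lasso fit on a training set, deterministic internal folds.
# glmnet requires >= 2 columns; a single selected feature is padded with an
# all-zero column, which standardization leaves with a zero coefficient.
lasso_cv_fit <- function(x, y, inner_folds, seed) {
  if (ncol(x) == 1) {
    x <- cbind(x, `..pad` = 0)
  }
  foldid <- make_folds(nrow(x), inner_folds, seed)
  glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid, standardize = TRUE)
}

lasso_cv_predict <- function(cvfit, newx) {
  if ("..pad" %in% rownames(stats::coef(cvfit, s = "lambda.min")) &&
      !("..pad" %in% colnames(newx))) {
    newx <- cbind(newx, `..pad` = 0)
  }
  as.numeric(stats::predict(cvfit, newx, s = "lambda.min"))
}

#' Round-1 feature selection by cross-validated Lasso
#'
#' Splits subjects into `k` folds. For each fold, fits a Lasso on the training
#' portion with internal cross-validation choosing the regularization strength
#' (per-fold tuning), and records the features with non-zero coefficients at
#' the selected penalty. Returns the union across folds.
#'
#' @param x n x p numeric feature matrix with column names.
#' @param y Numeric vector of chronological ages.
#' @param k Number of folds (default 10).
#' @param seed RNG seed controlling the fold partition (default 42).
#' @param inner_folds Folds for the internal regularization search (default 5).
#' @return Character vector of selected feature names (union over folds), with
#'   attribute `per_fold`: list of per-fold selections.
#' @export
select_features_cv <- function(x, y, k = 10, seed = 42, inner_folds = 5) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(is.finite(y)))
  if (nrow(x) < 2 * k) stop("need at least 2k = ", 2 * k, " subjects for ",
                            k, "-fold selection")
  if (stats::sd(y) == 0) stop("outcome is constant; cannot select features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  folds <- make_folds(nrow(x), k, seed)
  per_fold <- vector("list", k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    cvfit <- lasso_cv_fit(x[tr, , drop = FALSE], y[tr], inner_folds,
                          child_seed(seed, fold))
    beta <- stats::coef(cvfit, s = "lambda.min")[-1, 1]
    per_fold[[fold]] <- colnames(x)[beta != 0]
  }
  out <- unique(unlist(per_fold))
  attr(out, "per_fold") <- per_fold
  out
}

#' Round-2 cross-validated fit and out-of-fold prediction
#'
#' Restricts the feature matrix to the selected features, re-runs k-fold
#' cross-validation with the same fold partition scheme and seed as round 1,
#' and aggregates out-of-fold predictions into accuracy metrics and the
#' per-subject brain-age gap. A final model is refit on all subjects with the
#' regularization chosen by internal cross-validation; its penalty is reported
#' as `alpha`.
#'
#' @param x n x p feature matrix (column names required).
#' @param y Chronological ages.
#' @param selected Character vector of feature names from
#'   [select_features_cv()]; must be non-empty.
#' @param k,seed,inner_folds As in [select_features_cv()].
#' @return A list with `predicted_age`, `gap`, `mae`, `rmse`, `alpha`,
#'   `fold_assignments`, and `final_fit` (the refit `cv.glmnet` object).
#' @export
fit_predict_cv <- function(x, y, selected, k = 10, seed = 42, inner_folds = 5) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(selected) == 0) {
    stop("no features were selected; fall back to the full feature set ",
         "(pass selected = colnames(x))")
  }
  missing_cols <- setdiff(selected, colnames(x))
  if (length(missing_cols) > 0) {
    stop("selected features absent from x: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  xs <- x[, selected, drop = FALSE]
  folds <- make_folds(nrow(x), k, seed)
  pred <- numeric(nrow(x))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    cvfit <- lasso_cv_fit(xs[tr, , drop = FALSE], y[tr], inner_folds,
                          child_seed(seed, 100 + fold))
    pred[!tr] <- lasso_cv_predict(cvfit, xs[!tr, , drop = FALSE])
  }
  final <- lasso_cv_fit(xs, y, inner_folds, child_seed(seed, 999))
  gap <- brain_age_gap(pred, y)
  list(predicted_age = pred, gap = gap,
       mae = mean(abs(pred - y)),
       rmse = sqrt(mean((pred - y)^2)),
       alpha = final$lambda.min,
       fold_assignments = folds,
       final_fit = final)
}

#' Per-subject brain-age gap
#'
#' @param predicted Predicted brain ages (years).
#' @param chronological Chronological ages (years).
#' @return `predicted - chronological`, elementwise.
#' @export
brain_age_gap <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("length mismatch: ", length(predicted), " predictions vs ",
         length(chronological), " ages")
  }
  predicted - chronological
}

#' Fit a cross-validated Lasso brain-age model
#'
#' The full two-round protocol: round 1 selects features as the union of
#' non-zero Lasso coefficients over k cross-validation folds
#' ([select_features_cv()]); round 2 re-runs k-fold cross-validation on the
#' selected features only and aggregates out-of-fold predictions
#' ([fit_predict_cv()]). The per-subject brain-age gap is predicted minus
#' chronological age; no age-bias correction is applied. The whole procedure
#' is deterministic given `(x, age, folds, seed)`.
#'
#' @param x n x p numeric feature matrix with named columns, e.g. from
#'   [cohort_features()].
#' @param age Chronological ages in years.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed RNG seed for the fold partitions (default 42).
#' @param inner_folds Folds of the internal regularization search (default 5).
#' @return An object of class `brainage` with components `predicted_age`,
#'   `gap`, `mae`, `rmse`, `alpha`, `selected_features`, `fold_assignments`,
#'   `age`, `seed`, and the refit `final_fit`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' cohort <- generate_cohort(cohort_config(60, n_regions = 8,
#'                                         n_timepoints = 60, seed = 7))
#' x <- cohort_features(cohort, window_spec(60, length = 30, step = 10))
#' fit <- brainage(x, vapply(cohort, `[[`, numeric(1), "age"), folds = 5)
#' fit
#' @export
brainage <- function(x, age, folds = 10, seed = 42, inner_folds = 5) {
  selected <- select_features_cv(x, age, k = folds, seed = seed,
                                 inner_folds = inner_folds)
  if (length(selected) == 0) {
    warning("round-1 selection kept no features; falling back to the full ",
            "feature set")
    selected <- colnames(x)
  }
  res <- fit_predict_cv(x, age, selected, k = folds, seed = seed,
                        inner_folds = inner_folds)
  structure(c(res,
              list(selected_features = as.character(selected),
                   per_fold_selection = attr(selected, "per_fold"),
                   feature_names = colnames(x),
                   age = age, folds = folds, seed = seed,
                   subject_ids = rownames(x), call = match.call())),
            class = "brainage")
}

#' @export
print.brainage <- function(x, ...) {
  cat("Cross-validated Lasso brain-age model\n")
  cat(sprintf("  subjects: %d   features: %d (selected %d)   folds: %d\n",
              length(x$age), length(x$feature_names),
              length(x$selected_features), x$folds))
  cat(sprintf("  MAE %.3f years   RMSE %.3f years   penalty (alpha) %.4g\n",
              x$mae, x$rmse, x$alpha))
  invisible(x)
}

#' @export
summary.brainage <- function(object, ...) {
  r <- stats::cor(object$predicted_age, object$age)
  r_gap <- stats::cor(object$gap, object$age)
  out <- list(n = length(object$age), p = length(object$feature_names),
              n_selected = length(object$selected_features),
              folds = object$folds, mae = object$mae, rmse = object$rmse,
              alpha = object$alpha, cor_pred_age = r, cor_gap_age = r_gap,
              gap_summary = summary(object$gap))
  class(out) <- "summary.brainage"
  out
}

#' @export
print.summary.brainage <- function(x, ...) {
  cat("Cross-validated Lasso brain-age model\n")
  cat(sprintf("  n = %d, p = %d, %d selected features, %d folds\n",
              x$n, x$p, x$n_selected, x$folds))
  cat(sprintf("  MAE  = %.3f years\n  RMSE = %.3f years\n  alpha = %.4g\n",
              x$mae, x$rmse, x$alpha))
  cat(sprintf("  cor(predicted, chronological) = %.3f\n", x$cor_pred_age))
  cat(sprintf("  cor(gap, chronological)       = %.3f\n", x$cor_gap_age))
  cat("  brain-age gap (years):\n")
  print(x$gap_summary)
  invisible(x)
}

#' @export
coef.brainage <- function(object, ...) {
  b <- stats::coef(object$final_fit, s = "lambda.min")
  out <- as.numeric(b)
  names(out) <- rownames(b)
  out[out != 0]
}

#' @export
fitted.brainage <- function(object, ...) object$predicted_age

#' @export
residuals.brainage <- function(object, ...) object$age - object$predicted_age

#' Predict brain age for new subjects
#'
#' @param object A `brainage` fit.
#' @param newdata Feature matrix with (at least) the selected feature columns,
#'   e.g. from [cohort_features()]. Omitted: returns the out-of-fold
#'   cross-validated predictions.
#' @param ... Unused.
#' @return Numeric vector of predicted ages in years.
#' @export
predict.brainage <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predicted_age)
  sel <- setdiff(rownames(stats::coef(object$final_fit, s = "lambda.min"))[-1],
                 "..pad")
  missing_cols <- setdiff(sel, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks selected feature columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  lasso_cv_predict(object$final_fit, newdata[, sel, drop = FALSE])
}

#' Plot a brain-age fit
#'
#' Scatter of cross-validated predicted age against chronological age with the
#' identity line, plus the brain-age gap against chronological age.
#'
#' @param x A `brainage` fit.
#' @param which `1` (predicted vs chronological), `2` (gap vs chronological),
#'   or both.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.brainage <- function(x, which = 1:2, ...) {
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(x$age, x$predicted_age,
                   xlab = "chronological age (years)",
                   ylab = "predicted brain age (years)", ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    graphics::plot(x$age, x$gap,
                   xlab = "chronological age (years)",
                   ylab = "brain-age gap (years)", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
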