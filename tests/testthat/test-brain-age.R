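test_that("feature assembly matches a hand-built concatenation oracle", {
  set.seed(51)
  R <- 4
  fcm <- matrix(rnorm(16), R, R); fcm <- (fcm + t(fcm)) / 2; diag(fcm) <- 1
  fc <- connectivity_matrix(fcm, "fc")
  counts <- matrix(rpois(16, 10), R, R); counts <- counts + t(counts)
  diag(counts) <- 0
  sc <- scale_sc(counts, rep(2, R))
  tv <- runif(R)
  dens <- matrix(runif(3 * R), 3, R, dimnames = list(c("gm", "wm", "csf"), NULL))
  subject <- list(tissue_density = dens)
  row <- assemble_features(subject, fc, sc, tv)
  # dimension arithmetic: 2 * R(R-1)/2 + R + 3R
  expect_length(row, 2 * 6 + 4 + 12)
  # name-for-name agreement with an explicit hand assembly
  expect_equal(row[["sc:1-2"]], sc$values[1, 2])
  expect_equal(row[["sc:3-4"]], sc$values[3, 4])
  expect_equal(row[["fc:2-3"]], fcm[2, 3])
  expect_equal(row[["tv:4"]], tv[4])
  expect_equal(row[["gm:1"]], unname(dens["gm", 1]))
  expect_equal(row[["csf:4"]], unname(dens["csf", 4]))
  hand <- c(sc$values[upper.tri(sc$values)], fcm[upper.tri(fcm)], tv,
            dens["gm", ], dens["wm", ], dens["csf", ])
  expect_equal(unname(row), hand)
  # all-zero off-diagonal FC produces all-zero fc features
  zero_fc <- connectivity_matrix(diag(R), "fc")
  row0 <- assemble_features(subject, zero_fc, sc, tv)
  expect_true(all(row0[grepl("^fc:", names(row0))] == 0))
  # dimension mismatches name the offending modality
  expect_error(assemble_features(subject, fc, scale_sc(matrix(0, 3, 3), rep(1, 3)), tv),
               "sc")
  expect_error(assemble_features(subject, fc, sc, runif(5)),
               "temporal variability")
})

test_that("cohort feature matrices agree with per-subject assembly", {
  co <- tiny_cohort(n = 6, R = 6, tp = 50)
  spec <- window_spec(50, length = 25, step = 5)
  x <- cohort_features(co, spec)
  expect_equal(dim(x), c(6, 2 * 15 + 6 + 18))
  s <- co[[3]]
  row <- assemble_features(s, static_fc(s$time_series),
                           scale_sc(s$sc_counts, s$node_volumes),
                           temporal_variability(dynamic_fc(s$time_series, spec)))
  expect_equal(x[3, ], row, tolerance = 1e-10)
})

test_that("a perfect predictor is selected in every fold", {
  set.seed(52)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- x[, 7] * 10 + 60
  sel <- select_features_cv(x, y, k = 5)
  expect_true("f7" %in% sel)
  per_fold <- attr(sel, "per_fold")
  expect_true(all(vapply(per_fold, function(f) "f7" %in% f, logical(1))))
})

test_that("selection under pure noise is sparse and seed-stable", {
  set.seed(53)
  sizes <- vapply(1:20, function(s) {
    x <- matrix(rnorm(100 * 50), 100, 50,
                dimnames = list(NULL, paste0("f", 1:50)))
    y <- rnorm(100)
    length(select_features_cv(x, y, k = 10, seed = s))
  }, numeric(1))
  expect_lte(median(sizes), 0.1 * 50)
  # duplicated columns, same seed: identical selection
  x <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x <- cbind(x, x[, 1, drop = FALSE])
  colnames(x)[11] <- "f1dup"
  y <- rnorm(100)
  expect_identical(as.character(select_features_cv(x, y, k = 5, seed = 4)),
                   as.character(select_features_cv(x, y, k = 5, seed = 4)))
})

test_that("a noiseless linear outcome is recovered almost exactly", {
  set.seed(54)
  n <- 80
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 3 * x[, 2] + 65
  res <- fit_predict_cv(x, y, selected = "f2", k = 5)
  # the cross-validated penalty stops at the foot of the regularization path,
  # so a small shrinkage bias remains even without noise
  expect_lt(res$mae, 0.1)
  expect_lt(res$mae / sd(y), 0.05)
  expect_lte(res$mae, res$rmse)
})

test_that("predicting the mean gives RMSE equal to the population SD", {
  y <- c(60, 62, 64, 66, 70, 71)
  pred <- rep(mean(y), length(y))
  rmse <- sqrt(mean((pred - y)^2))
  expect_equal(rmse, sqrt(mean((y - mean(y))^2)))
})

test_that("empty selection errors instruct the full-set fallback", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_predict_cv(x, rnorm(20), selected = character(0)),
               "full feature set")
})

test_that("the brain-age gap is an elementwise difference", {
  expect_equal(brain_age_gap(70, 65), 5)
  expect_equal(brain_age_gap(c(60, 70, 80), c(60, 70, 80)), c(0, 0, 0))
  set.seed(55)
  p <- rnorm(5, 65); c_ <- rnorm(5, 65)
  expect_equal(brain_age_gap(p, c_), p - c_)
  expect_error(brain_age_gap(1:3, 1:4), "length mismatch")
})

test_that("the full protocol is deterministic and self-consistent", {
  co <- tiny_cohort(n = 30, R = 6, tp = 50, seed = 77)
  x <- cohort_features(co, window_spec(50, 25, 5))
  age <- cohort_ages(co)
  fit1 <- brainage(x, age, folds = 5, seed = 42)
  fit2 <- brainage(x, age, folds = 5, seed = 42)
  expect_identical(fit1$predicted_age, fit2$predicted_age)
  expect_identical(fit1$selected_features, fit2$selected_features)
  expect_equal(fit1$gap, fit1$predicted_age - age)
  expect_lte(fit1$mae, fit1$rmse)
  expect_true(all(fit1$selected_features %in% colnames(x)))
  expect_setequal(unique(fit1$fold_assignments), 1:5)
})

test_that("brainage methods expose the fit coherently", {
  co <- tiny_cohort(n = 30, R = 6, tp = 50, seed = 78)
  x <- cohort_features(co, window_spec(50, 25, 5))
  age <- cohort_ages(co)
  fit <- brainage(x, age, folds = 5)
  expect_s3_class(fit, "brainage")
  expect_output(print(fit), "MAE")
  s <- summary(fit)
  expect_equal(s$mae, fit$mae)
  expect_output(print(s), "cor\\(predicted, chronological\\)")
  expect_equal(fitted(fit), fit$predicted_age)
  expect_equal(residuals(fit), age - fit$predicted_age)
  cf <- coef(fit)
  expect_true(all(cf != 0))
  # refit predictions on the training features are finite and age-scaled
  pr <- predict(fit, x)
  expect_length(pr, 30)
  expect_true(all(is.finite(pr)))
  expect_equal(predict(fit), fit$predicted_age)
})

test_that("brain age is decodable from cohorts with planted signal", {
  co <- generate_cohort(cohort_config(100, n_regions = 12, n_timepoints = 60,
                                      signal_strength = 0.8, seed = 91))
  x <- cohort_features(co, window_spec(60, 30, 10))
  age <- cohort_ages(co)
  fit <- brainage(x, age, folds = 5)
  ct <- cor.test(fit$predicted_age, age)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("stronger planted signal does not worsen cross-validated MAE", {
  maes <- vapply(c(0, 0.4, 0.8), function(sig) {
    co <- generate_cohort(cohort_config(80, n_regions = 10, n_timepoints = 50,
                                        signal_strength = sig, seed = 92))
    x <- cohort_features(co, window_spec(50, 25, 5))
    brainage(x, cohort_ages(co), folds = 5)$mae
  }, numeric(1))
  expect_true(all(diff(maes) <= 0))
})

test_that("without planted signal the model cannot beat the mean predictor", {
  co <- generate_cohort(cohort_config(80, n_regions = 10, n_timepoints = 50,
                                      signal_strength = 0, seed = 93))
  x <- cohort_features(co, window_spec(50, 25, 5))
  age <- cohort_ages(co)
  observed <- suppressWarnings(brainage(x, age, folds = 5)$mae)
  # permutation null: the same protocol on age vectors with severed links
  set.seed(94)
  null_mae <- vapply(1:19, function(i) {
    suppressWarnings(brainage(x, sample(age), folds = 5)$mae)
  }, numeric(1))
  # observed MAE statistically indistinguishable from the null draws
  p_perm <- (1 + sum(null_mae <= observed)) / 20
  expect_gt(p_perm, 0.05)
})
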