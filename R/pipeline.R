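#' Pipeline configuration
#'
#' Gathers every tunable of the end-to-end analysis: sliding-window settings,
#' sparsity for network binarization, cross-validation folds and seed for the
#' brain-age model, the dynamic-connectivity feature (`tv` nodal temporal
#' variability, or `sl` synchronization likelihood), permutation and k-means
#' counts for the inference stage, and input/output directories. Defaults are
#' the conventional analysis settings: 50-timepoint window (step 2), 0.1
#' sparsity, 10 folds with seed 42, 10000 permutations, 1000 k-means restarts.
#'
#' @param cohort_dir Directory written by [write_cohort()].
#' @param output_dir Directory for all artifacts (created if absent).
#' @param window_length,window_step Sliding-window settings in timepoints.
#' @param sparsity Network density in (0, 1).
#' @param folds,seed Brain-age cross-validation settings.
#' @param dynamic_feature `"tv"` or `"sl"`.
#' @param sl_params An [sl_params()] object.
#' @param permutations Canonical-correlation permutation count.
#' @param kmeans_iterations k-means restart count.
#' @param sc_convention Volume-scaling convention for [scale_sc()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir, output_dir,
                            window_length = 50, window_step = 2,
                            sparsity = 0.1, folds = 10, seed = 42,
                            dynamic_feature = c("tv", "sl"),
                            sl_params = NULL,
                            permutations = 10000,
                            kmeans_iterations = 1000,
                            sc_convention = "sum") {
  dynamic_feature <- match.arg(dynamic_feature)
  if (is.null(sl_params)) sl_params <- connage::sl_params()
  stopifnot(inherits(sl_params, "sl_params"))
  stopifnot(sparsity > 0, sparsity < 1, is_count(folds), is_count(permutations),
            is_count(kmeans_iterations), is_count(window_length),
            is_count(window_step))
  structure(list(cohort_dir = cohort_dir, output_dir = output_dir,
                 window_length = as.integer(window_length),
                 window_step = as.integer(window_step),
                 sparsity = sparsity, folds = as.integer(folds),
                 seed = as.integer(seed), dynamic_feature = dynamic_feature,
                 sl_params = sl_params,
                 permutations = as.integer(permutations),
                 kmeans_iterations = as.integer(kmeans_iterations),
                 sc_convention = sc_convention),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML file whose keys are the arguments of [pipeline_config()]
#' (`sl_params` as a nested map of [sl_params()] arguments). Absent keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sl_params)) cfg$sl_params <- do.call(sl_params, cfg$sl_params)
  do.call(pipeline_config, cfg)
}

behavioral_scales <- function() {
  c("resilience", "tenacity", "strength", "optimism", "moca", "ad8", "gds",
    "psqi", "iadl", "ucla_ls", "pss", "lsns")
}

# nuisance covariate matrix: age, gender (0/1 indicator), education in years
nuisance_covariates <- function(manifest) {
  cbind(age = manifest$age,
        gender = as.numeric(manifest$gender == "M"),
        education = manifest$education)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: connectivity construction (static FC, scaled SC, and
#' the configured dynamic feature), nodal graph metrics on sparsity-binarized
#' FC and SC networks, the two-round cross-validated Lasso brain-age model,
#' and downstream inference (covariate-adjusted partial correlations of the
#' brain-age gap with behavioral scales and nodal metrics with FDR control,
#' three canonical-correlation analyses with permutation p-values, MOCA
#' stratification with group t-tests, and repeated k-means classification).
#' All artifacts are written under `config$output_dir` together with a run
#' manifest; rerunning with an identical configuration reproduces all numeric
#' outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional in-memory `cohort`; when `NULL`, read from
#'   `config$cohort_dir`.
#' @return Invisibly, a list with the fitted `brainage` model, the feature
#'   matrix, manifest, and all inference tables.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_log <- list()
  record_stage <- function(name, t0) {
    stage_log[[name]] <<- list(seconds = round(as.numeric(Sys.time()) - t0, 3))
  }
  on_failure <- function(stage, e) {
    jsonlite::write_json(list(failed_stage = stage,
                              message = conditionMessage(e)),
                         file.path(out_dir, "failure.json"), auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  t0 <- as.numeric(Sys.time())
  if (is.null(cohort)) cohort <- read_cohort(config$cohort_dir)
  manifest <- cohort_manifest(cohort)
  record_stage("load_cohort", t0)

  # --- connectivity + graph metrics ---------------------------------------
  t0 <- as.numeric(Sys.time())
  window <- window_spec(nrow(cohort[[1]]$time_series),
                        length = config$window_length,
                        step = config$window_step)
  features <- tryCatch(
    cohort_features(cohort, window, config$dynamic_feature,
                    config$sl_params, config$sc_convention),
    error = function(e) on_failure("connectivity", e))
  record_stage("connectivity", t0)

  t0 <- as.numeric(Sys.time())
  metrics <- tryCatch(lapply(cohort, function(s) {
    fc <- static_fc(s$time_series)
    sc <- scale_sc(s$sc_counts, s$node_volumes,
                   convention = config$sc_convention)
    list(fc = nodal_metrics(binarize_sparsity(fc, config$sparsity)),
         sc = nodal_metrics(binarize_sparsity(sc, config$sparsity)))
  }), error = function(e) on_failure("graph_metrics", e))
  names(metrics) <- manifest$subject_id
  for (id in names(metrics)) {
    utils::write.table(metrics[[id]]$fc,
                       file.path(out_dir, sprintf("metrics_fc_%s.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(metrics[[id]]$sc,
                       file.path(out_dir, sprintf("metrics_sc_%s.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  record_stage("graph_metrics", t0)

  # --- brain-age model ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fit <- tryCatch(
    brainage(features, manifest$age, folds = config$folds, seed = config$seed),
    error = function(e) on_failure("brain_age_model", e))
  predictions <- data.frame(subject_id = manifest$subject_id,
                            age = manifest$age,
                            predicted_age = fit$predicted_age,
                            gap = fit$gap, fold = fit$fold_assignments)
  utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  writeLines(fit$selected_features,
             file.path(out_dir, "selected_features.txt"))
  jsonlite::write_json(list(mae = fit$mae, rmse = fit$rmse, alpha = fit$alpha),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  record_stage("brain_age_model", t0)

  # --- inference ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  inference <- tryCatch(
    run_inference(manifest, fit$gap, fit$predicted_age, metrics, config),
    error = function(e) on_failure("stats_inference", e))
  utils::write.csv(inference$partial_correlations,
                   file.path(out_dir, "partial_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(inference$nodal_partial_correlations,
                   file.path(out_dir, "nodal_partial_correlations.csv"),
                   row.names = FALSE)
  for (nm in names(inference$cca)) {
    cc <- inference$cca[[nm]]
    jsonlite::write_json(
      list(r = cc$r, p_perm = cc$p_perm, n = cc$n,
           n_permutations = cc$n_permutations,
           structure_x = as.list(cc$structure_x),
           structure_y = as.list(cc$structure_y)),
      file.path(out_dir, sprintf("cca_%s.json", nm)),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(inference$ttests, file.path(out_dir, "ttests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(inference$kmeans, file.path(out_dir, "kmeans.json"),
                       auto_unbox = TRUE, digits = NA)
  record_stage("stats_inference", t0)

  jsonlite::write_json(
    list(config = config[setdiff(names(config), "sl_params")],
         sl_params = unclass(config$sl_params),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("connage")),
         timestamp = format(Sys.time(), tz = "UTC"),
         stages = stage_log),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)

  invisible(list(fit = fit, features = features, manifest = manifest,
                 metrics = metrics, inference = inference,
                 predictions = predictions))
}

# Downstream inference on a fitted cohort; factored out for testability.
run_inference <- function(manifest, gap, predicted_age, metrics, config) {
  z <- nuisance_covariates(manifest)

  # partial correlations of the gap with each behavioral scale, one FDR family
  scales <- intersect(behavioral_scales(), names(manifest))
  pc <- lapply(scales, function(sc) {
    res <- partial_correlation(manifest[[sc]], gap, z)
    data.frame(variable = sc, rho = res$rho, p = res$p_value,
               n = res$n_effective)
  })
  pc <- do.call(rbind, pc)
  fdr <- bh_fdr(pc$p)
  pc$p_adjusted <- fdr$p_adjusted
  pc$significant_fdr <- fdr$reject

  # nodal-metric correlations: one FDR family per metric per network
  npc <- list()
  for (net in c("fc", "sc")) {
    for (metric in c("betweenness", "degree", "efficiency", "clustering")) {
      vals <- vapply(metrics, function(m) m[[net]][[metric]],
                     numeric(nrow(metrics[[1]][[net]])))
      rows <- apply(vals, 1, function(v) {
        if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
        res <- partial_correlation(v, gap, z)
        c(res$rho, res$p_value)
      })
      ok <- !is.na(rows[1, ])
      adj <- rep(NA_real_, ncol(rows))
      rej <- rep(NA, ncol(rows))
      if (any(ok)) {
        f <- bh_fdr(rows[2, ok])
        adj[ok] <- f$p_adjusted
        rej[ok] <- f$reject
      }
      npc[[paste(net, metric, sep = "_")]] <-
        data.frame(network = net, metric = metric,
                   node = seq_len(ncol(rows)), rho = rows[1, ],
                   p = rows[2, ], p_adjusted = adj, significant_fdr = rej)
    }
  }
  npc <- do.call(rbind, c(npc, make.row.names = FALSE))

  # canonical correlations: age-related set vs three criterion sets
  xset <- data.frame(gap = gap, resilience = manifest$resilience)
  cca <- list(
    cognitive = cca_first_pair(xset, manifest[, c("moca", "ad8")],
                               permutations = config$permutations,
                               seed = child_seed(config$seed, 1)),
    performance = cca_first_pair(xset, manifest[, c("iadl", "psqi", "lsns")],
                                 permutations = config$permutations,
                                 seed = child_seed(config$seed, 2)),
    emotional = cca_first_pair(xset, manifest[, c("gds", "ucla_ls", "pss")],
                               permutations = config$permutations,
                               seed = child_seed(config$seed, 3))
  )

  # MOCA stratification, group comparisons, k-means classification
  labels <- stratify_moca(manifest$moca)
  tt_vars <- c("gap", setdiff(scales, "moca"))
  tt_data <- cbind(data.frame(gap = gap), manifest[setdiff(scales, "moca")])
  ttests <- do.call(rbind, lapply(tt_vars, function(v) {
    a <- tt_data[[v]][labels == "MOCA+"]
    b <- tt_data[[v]][labels == "MOCA-"]
    res <- tryCatch(independent_t_test(a, b),
                    error = function(e) list(t = NA_real_, p_value = NA_real_,
                                             df = NA_real_,
                                             mean_a = mean(a, na.rm = TRUE),
                                             mean_b = mean(b, na.rm = TRUE)))
    data.frame(variable = v, t = res$t, p = res$p_value, df = res$df,
               mean_moca_plus = res$mean_a, mean_moca_minus = res$mean_b)
  }))

  km_sets <- list(
    all_scores_gap = cbind(tt_data[setdiff(names(tt_data), "gap")], gap = gap),
    gap_resilience = data.frame(gap = gap, resilience = manifest$resilience),
    gap_only = data.frame(gap = gap),
    resilience_only = data.frame(resilience = manifest$resilience)
  )
  kmeans_out <- lapply(seq_along(km_sets), function(i) {
    res <- kmeans_classification_accuracy(
      km_sets[[i]], labels, iterations = config$kmeans_iterations,
      seed = child_seed(config$seed, 10 + i))
    list(features = names(km_sets[[i]]), accuracy = res$accuracy,
         histogram = as.list(res$histogram))
  })
  names(kmeans_out) <- names(km_sets)

  list(partial_correlations = pc, nodal_partial_correlations = npc,
       cca = cca, ttests = ttests, kmeans = kmeans_out, labels = labels)
}
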