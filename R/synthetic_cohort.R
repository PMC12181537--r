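# Behavioral-scale marginals the generator reproduces: mean, SD, truncation
# range, and per-scale missingness rate (fractions of a 93-subject cohort).
scale_marginals <- function() {
  list(
    resilience = list(mean = 65.4,  sd = 17.29, range = c(0, 100),  miss = 23 / 93),
    moca       = list(mean = 21.78, sd = 3.24,  range = c(14, 28),  miss = 0),
    psqi       = list(mean = 6.20,  sd = 3.50,  range = c(1, 18),   miss = 1 / 93),
    iadl       = list(mean = 22.70, sd = 0.59,  range = c(21, 23),  miss = 0),
    ad8        = list(mean = 1.51,  sd = 1.56,  range = c(0, 6),    miss = 0),
    gds        = list(mean = 2.27,  sd = 1.46,  range = c(0, 5),    miss = 0),
    ucla_ls    = list(mean = 31.28, sd = 8.56,  range = c(20, 58),  miss = 0),
    pss        = list(mean = 24.10, sd = 7.40,  range = c(11, 47),  miss = 5 / 93),
    lsns       = list(mean = 17.59, sd = 4.86,  range = c(7, 29),   miss = 20 / 93)
  )
}

#' Synthetic cohort configuration
#'
#' Configuration for [generate_cohort()]. Defaults emulate the statistical
#' structure of a community cohort of older adults: ages drawn from a truncated
#' normal (mean 64.41, SD 5.66) on 53-76 years, a planted per-subject
#' brain-age gap, age-dependent functional and structural connectivity through
#' a sparse low-rank latent model, behavioral scales matched to reference-cohort
#' means/SDs/ranges, a planted negative resilience-gap correlation, and
#' per-scale missingness.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of brain regions R (default 30; use 246 to mirror a
#'   whole-brain atlas).
#' @param n_timepoints Time-series length T (default 265).
#' @param age_range Two-element years vector, low < high (default `c(53, 76)`).
#' @param age_mean,age_sd Mean and SD of the (truncated) age distribution.
#' @param gap_sd SD in years of the planted brain-age gap (default 4.4).
#' @param signal_strength In \[0, 1\]: scales every age-dependent component of
#'   the generated data; 0 removes all brain-age signal (default 0.5).
#' @param noise_sd Unitless noise multiplier for time series and tissue
#'   density (default 1).
#' @param resilience_gap_corr Target correlation between resilience and the
#'   planted gap, in (-1, 1) (default -0.35). Enforced exactly in-sample on
#'   the latent scale before truncation/rounding.
#' @param missingness Named per-scale missing probabilities; defaults follow
#'   the per-scale sample sizes of the emulated cohort.
#' @param exclusion_rates Named rates for the three recruitment exclusion
#'   flags (`missing_imaging`, `head_motion`, `gds`).
#' @param gds_threshold Depression-screen cutoff used when flagging; exposed
#'   as a parameter because screening conventions differ (default 5).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          n_regions = 30,
                          n_timepoints = 265,
                          age_range = c(53, 76),
                          age_mean = 64.41,
                          age_sd = 5.66,
                          gap_sd = 4.4,
                          signal_strength = 0.5,
                          noise_sd = 1,
                          resilience_gap_corr = -0.35,
                          missingness = NULL,
                          exclusion_rates = c(missing_imaging = 11 / 124,
                                              head_motion = 5 / 124,
                                              gds = 15 / 124),
                          gds_threshold = 5,
                          seed = 1) {
  if (!is_count(n_subjects) || !is_count(n_regions) || !is_count(n_timepoints)) {
    stop("configuration error: n_subjects, n_regions and n_timepoints must be positive integers")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("configuration error: degenerate age range")
  }
  if (abs(resilience_gap_corr) >= 1) {
    stop("configuration error: |resilience_gap_corr| must be < 1")
  }
  stopifnot(signal_strength >= 0, signal_strength <= 1, gap_sd >= 0, noise_sd >= 0)
  marg <- scale_marginals()
  miss <- vapply(marg, function(m) m$miss, numeric(1))
  if (!is.null(missingness)) {
    stopifnot(all(names(missingness) %in% names(miss)))
    miss[names(missingness)] <- missingness
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 age_range = age_range, age_mean = age_mean, age_sd = age_sd,
                 gap_sd = gap_sd, signal_strength = signal_strength,
                 noise_sd = noise_sd,
                 resilience_gap_corr = resilience_gap_corr,
                 missingness = miss, exclusion_rates = exclusion_rates,
                 gds_threshold = gds_threshold, seed = as.integer(seed)),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

clamp <- function(x, range) pmin(range[2], pmax(range[1], x))

# Integer questionnaire score with target sample mean/SD, truncated to range.
score_from_latent <- function(latent, marg) {
  z <- as.numeric(scale(latent))
  round(clamp(marg$mean + marg$sd * z, marg$range))
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subject records under the model described in
#' [cohort_config()]. Each subject's latent brain age is chronological age
#' plus a Normal(0, `gap_sd`) planted gap. Regional time series follow a
#' three-factor latent model in which one factor's loadings scale linearly
#' with standardized brain age; structural streamline counts are Poisson with
#' a log-linear brain-age effect on a sparse subset of edges; tissue densities
#' are linear in brain age on a sparse subset of region/compartment features.
#' Resilience is constructed to correlate with the planted gap at
#' `resilience_gap_corr` (exactly, in-sample, on the latent scale); MOCA loads
#' negatively on the gap and positively on resilience so that low-MOCA
#' subjects have larger gaps and lower resilience. All scale scores are
#' integer, truncated to reference-cohort ranges, with per-scale missingness.
#'
#' The returned cohort carries `attr(, "planted_features")`: the names of
#' feature-matrix columns (see [assemble_features()]) whose generating
#' distribution truly depends on brain age.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list of subject records, each with
#'   `subject_id`, `age`, `gender`, `education`, `time_series`, `sc_counts`,
#'   `node_volumes`, `tissue_density` (3 x R: gm, wm, csf), `behaviors`
#'   (named numeric, `NA` = missing), `exclusion_flags`, and the
#'   synthetic-only `true_gap` and `true_brain_age`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_subjects
  R <- config$n_regions
  tp <- config$n_timepoints
  sig <- config$signal_strength
  marg <- scale_marginals()

  age <- rtrunc_norm(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  gap <- stats::rnorm(n, 0, config$gap_sd)
  brain_age <- age + gap
  b <- as.numeric(scale(brain_age))      # standardized brain age
  gz <- as.numeric(scale(gap))

  # --- cohort-level generative parameters (drawn once per cohort) ----------
  # FC: three latent factors; factor 1's loadings are nonzero on a sparse
  # region subset and scale linearly with standardized brain age.
  fc_affected <- sort(sample.int(R, max(2, round(0.3 * R))))
  lam <- matrix(stats::rnorm(R * 3, 0, 0.5), R, 3)
  lam1_mask <- rep(0, R)
  lam1_mask[fc_affected] <- 1
  # SC: symmetric log-mean and a sparse symmetric brain-age slope.
  mu0 <- matrix(0, R, R)
  mu0[upper.tri(mu0)] <- log(60) + stats::rnorm(R * (R - 1) / 2, 0, 0.4)
  mu0 <- mu0 + t(mu0)
  slope_sc <- matrix(0, R, R)
  ut <- which(upper.tri(slope_sc))
  sc_edges <- sample(ut, round(0.25 * length(ut)))
  slope_sc[sc_edges] <- stats::rnorm(length(sc_edges), 0, 0.2)
  slope_sc <- slope_sc + t(slope_sc)
  # tissue density: base per compartment/region, sparse brain-age loadings
  dens_base <- rbind(gm = 0.60 + stats::rnorm(R, 0, 0.05),
                     wm = 0.50 + stats::rnorm(R, 0, 0.05),
                     csf = 0.20 + stats::rnorm(R, 0, 0.03))
  dens_load <- matrix(0, 3, R)
  dens_mask <- matrix(stats::runif(3 * R) < 0.3, 3, R)
  dens_load[dens_mask] <- stats::rnorm(sum(dens_mask), 0, 1)
  vol_base <- exp(stats::rnorm(R, log(4000), 0.15))
  vol_slope <- stats::runif(R, 0, 1)

  # --- behavioral latents --------------------------------------------------
  rho <- config$resilience_gap_corr
  e <- stats::rnorm(n)
  # orthogonalize against gz so the in-sample correlation is exactly rho
  e_orth <- stats::residuals(stats::lm.fit(cbind(1, gz), e))
  e_orth <- as.numeric(scale(e_orth))
  rz <- rho * gz + sqrt(1 - rho^2) * e_orth
  resilience <- score_from_latent(rz, marg$resilience)
  tenacity <- pmax(0, round(0.52 * resilience + stats::rnorm(n, 0, 4)))
  strength <- pmax(0, round(0.32 * resilience + stats::rnorm(n, 0, 3)))
  optimism <- pmax(0, round(0.16 * resilience + stats::rnorm(n, 0, 2)))

  moca_lat <- 0.35 * rz - 0.45 * gz + 0.75 * stats::rnorm(n)
  moca <- score_from_latent(moca_lat, marg$moca)
  moca_z <- as.numeric(scale(moca_lat))
  behaviors <- list(
    resilience = resilience, tenacity = tenacity, strength = strength,
    optimism = optimism, moca = moca,
    ad8 = score_from_latent(-0.6 * moca_z + 0.8 * stats::rnorm(n), marg$ad8),
    gds = score_from_latent(-0.5 * rz + 0.87 * stats::rnorm(n), marg$gds),
    psqi = score_from_latent(-0.25 * rz + 0.97 * stats::rnorm(n), marg$psqi),
    iadl = score_from_latent(0.3 * rz + 0.95 * stats::rnorm(n), marg$iadl),
    ucla_ls = score_from_latent(-0.6 * rz + 0.8 * stats::rnorm(n), marg$ucla_ls),
    pss = score_from_latent(-0.6 * rz + 0.8 * stats::rnorm(n), marg$pss),
    lsns = score_from_latent(0.55 * rz + 0.84 * stats::rnorm(n), marg$lsns)
  )

  # per-scale missingness; resilience subscales share the instrument's mask
  miss_mask <- lapply(config$missingness, function(p) stats::runif(n) < p)
  for (sc in names(miss_mask)) {
    if (sc %in% names(behaviors)) behaviors[[sc]][miss_mask[[sc]]] <- NA
  }
  for (sub in c("tenacity", "strength", "optimism")) {
    behaviors[[sub]][miss_mask$resilience] <- NA
  }

  gender <- ifelse(stats::runif(n) < 33 / 93, "M", "F")
  education <- round(clamp(stats::rnorm(n, 12, 3), c(6, 20)))

  flags <- lapply(config$exclusion_rates, function(p) stats::runif(n) < p)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    # time series: T x 3 factor scores times subject mixing, plus noise
    a_i <- lam
    a_i[, 1] <- lam[, 1] * (1 + 0.6 * sig * b[i] * lam1_mask)
    f <- matrix(stats::rnorm(tp * 3), tp, 3)
    ts <- f %*% t(a_i) + config$noise_sd * matrix(stats::rnorm(tp * R), tp, R)

    lambda <- exp(mu0 + sig * b[i] * slope_sc)
    counts <- matrix(0, R, R)
    counts[upper.tri(counts)] <- stats::rpois(R * (R - 1) / 2,
                                              lambda[upper.tri(lambda)])
    counts <- counts + t(counts)

    dens <- dens_base + 0.035 * sig * dens_load * b[i] +
      0.05 * config$noise_sd * matrix(stats::rnorm(3 * R), 3, R)
    dens[dens < 0] <- 0
    rownames(dens) <- c("gm", "wm", "csf")

    vols <- vol_base * exp(stats::rnorm(R, 0, 0.05) - 0.02 * sig * b[i] * vol_slope)

    subjects[[i]] <- list(
      subject_id = sprintf("S%04d", i),
      age = age[i], gender = gender[i], education = education[i],
      time_series = ts, sc_counts = counts, node_volumes = vols,
      tissue_density = dens,
      behaviors = lapply(behaviors, `[`, i),
      exclusion_flags = vapply(flags, `[`, logical(1), i),
      true_gap = gap[i], true_brain_age = brain_age[i]
    )
  }

  structure(subjects, class = "cohort",
            config = config,
            planted_features = planted_feature_names(R, fc_affected,
                                                     sc_edges, dens_mask))
}

# Names of feature-matrix columns whose generating law depends on brain age.
planted_feature_names <- function(R, fc_affected, sc_edges_ut, dens_mask) {
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  sc_planted <- logical(nrow(ut))
  sc_planted[match(sc_edges_ut, which(upper.tri(matrix(0, R, R))))] <- TRUE
  sc_names <- sprintf("sc:%d-%d", ut[sc_planted, 1], ut[sc_planted, 2])
  fc_hit <- ut[, 1] %in% fc_affected | ut[, 2] %in% fc_affected
  fc_names <- sprintf("fc:%d-%d", ut[fc_hit, 1], ut[fc_hit, 2])
  comp <- c("gm", "wm", "csf")
  dens_idx <- which(dens_mask, arr.ind = TRUE)
  dens_names <- sprintf("%s:%d", comp[dens_idx[, 1]], dens_idx[, 2])
  c(sc_names, fc_names, dens_names)
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cohort> %d subjects, %d regions, %d timepoints (seed %d)\n",
              length(x), cfg$n_regions, cfg$n_timepoints, cfg$seed))
  invisible(x)
}

#' Apply recruitment exclusion rules
#'
#' Removes subjects whose exclusion flags are set, rule by rule in the order
#' given, and records how many subjects each rule removed among those still
#' retained at that point (so overlapping flags count a subject only once).
#'
#' @param cohort A `cohort` (list of subject records with `exclusion_flags`).
#' @param rules Character vector of rule names to apply, in order. Each must
#'   name an entry of every subject's `exclusion_flags`.
#' @return The retained cohort, with `attr(, "exclusion_counts")`: named
#'   integer vector of removals per rule, and `attr(, "n_input")`.
#' @export
exclusion_filter <- function(cohort,
                             rules = c("missing_imaging", "head_motion", "gds")) {
  flags <- lapply(cohort, `[[`, "exclusion_flags")
  known <- names(flags[[1]])
  unknown <- setdiff(rules, known)
  if (length(unknown) > 0) {
    stop("unknown exclusion rule(s): ", paste(unknown, collapse = ", "))
  }
  retained <- seq_along(cohort)
  counts <- stats::setNames(integer(length(rules)), rules)
  for (r in rules) {
    hit <- vapply(flags[retained], `[[`, logical(1), r)
    counts[r] <- sum(hit)
    retained <- retained[!hit]
  }
  out <- cohort[retained]
  attributes(out) <- c(attributes(out),
                       list(class = "cohort", config = attr(cohort, "config"),
                            planted_features = attr(cohort, "planted_features"),
                            exclusion_counts = counts,
                            n_input = length(cohort)))
  out
}

#' Cohort manifest as a data frame
#'
#' @param cohort A `cohort`.
#' @param include_true_gap Include the synthetic-only planted gap column.
#' @return Data frame with one row per subject: id, age, gender, education,
#'   one column per behavioral scale (NA = missing).
#' @export
cohort_manifest <- function(cohort, include_true_gap = FALSE) {
  beh <- do.call(rbind, lapply(cohort, function(s) {
    as.data.frame(lapply(s$behaviors, function(v) v %||% NA_real_))
  }))
  out <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    age = vapply(cohort, `[[`, numeric(1), "age"),
    gender = vapply(cohort, `[[`, character(1), "gender"),
    education = vapply(cohort, `[[`, numeric(1), "education"),
    beh,
    row.names = NULL
  )
  if (include_true_gap) {
    out$true_gap <- vapply(cohort, `[[`, numeric(1), "true_gap")
  }
  out
}

#' Write a cohort directory
#'
#' Writes `manifest.csv` plus per-subject tab-delimited matrices:
#' `ts_<id>.tsv` (T x R), `sc_<id>.tsv` (R x R), `volumes_<id>.tsv` (R x 1)
#' and `density_<id>.tsv` (3 x R), all headerless and at full precision.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort_manifest(cohort), file.path(dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  for (s in cohort) {
    write_matrix(s$time_series, file.path(dir, sprintf("ts_%s.tsv", s$subject_id)))
    write_matrix(s$sc_counts, file.path(dir, sprintf("sc_%s.tsv", s$subject_id)))
    write_matrix(s$node_volumes, file.path(dir, sprintf("volumes_%s.tsv", s$subject_id)))
    write_matrix(s$tissue_density, file.path(dir, sprintf("density_%s.tsv", s$subject_id)))
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()] for the fields a real study would provide
#' (synthetic-only fields such as the planted gap are not part of the on-disk
#' format).
#'
#' @param dir Cohort directory containing `manifest.csv` and per-subject
#'   matrices.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  scale_cols <- setdiff(names(manifest),
                        c("subject_id", "age", "gender", "education", "true_gap"))
  missing_files <- character(0)
  subjects <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    paths <- file.path(dir, sprintf(c("ts_%s.tsv", "sc_%s.tsv",
                                      "volumes_%s.tsv", "density_%s.tsv"), id))
    if (!all(file.exists(paths))) {
      missing_files <- c(missing_files, id)
      next
    }
    dens <- read_matrix(paths[4])
    rownames(dens) <- c("gm", "wm", "csf")
    subjects[[i]] <- list(
      subject_id = id, age = manifest$age[i], gender = manifest$gender[i],
      education = manifest$education[i],
      time_series = read_matrix(paths[1]),
      sc_counts = read_matrix(paths[2]),
      node_volumes = as.numeric(read_matrix(paths[3])),
      tissue_density = dens,
      behaviors = as.list(manifest[i, scale_cols]),
      exclusion_flags = c(missing_imaging = FALSE, head_motion = FALSE,
                          gds = FALSE),
      true_gap = NA_real_, true_brain_age = NA_real_
    )
  }
  if (length(missing_files) > 0) {
    stop("missing matrix files for subject(s): ",
         paste(missing_files, collapse = ", "))
  }
  structure(subjects, class = "cohort")
}
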