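#' Covariate-adjusted partial correlation
#'
#' Correlates the least-squares residuals of `x` and `y` after regressing each
#' on an intercept plus the covariates. With `method = "spearman"` (default),
#' `x`, `y` and the covariates are rank-transformed first, giving a Spearman
#' partial correlation. Rows with any missing value are dropped (listwise
#' deletion). The p-value uses the t distribution with `n - c - 2` degrees of
#' freedom, where `c` is the number of covariate columns.
#'
#' @param x,y Numeric vectors.
#' @param z Optional n x c numeric covariate matrix (or data frame); `NULL`
#'   gives the plain correlation.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `partial_corr`: list with `rho`, `p_value`,
#'   `n_effective`, `df`, `covariates`, `method`.
#' @export
partial_correlation <- function(x, y, z = NULL,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(z)) {
    z <- as.matrix(as.data.frame(z))
    storage.mode(z) <- "double"
    stopifnot(nrow(z) == length(x))
  }
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y, if (is.null(z)) rep(0, length(x)) else z)
  x <- x[keep]; y <- y[keep]
  if (!is.null(z)) z <- z[keep, , drop = FALSE]
  n <- length(x)
  c_ <- if (is.null(z)) 0L else ncol(z)
  if (n <= c_ + 2) stop("too few complete observations (n = ", n,
                        ") for ", c_, " covariates")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (!is.null(z)) z <- apply(z, 2, rank)
  }
  design <- if (is.null(z)) matrix(1, n, 1) else cbind(1, z)
  rx <- stats::residuals(stats::lm.fit(design, x))
  ry <- stats::residuals(stats::lm.fit(design, y))
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    stop("zero-variance residual: a variable lies in the span of the covariates")
  }
  rho <- stats::cor(rx, ry)
  df <- n - c_ - 2
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(rho = rho, p_value = p, n_effective = n, df = df,
                 covariates = colnames(z), method = method),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial correlation (%s): rho = %.3f, p = %.4g, n = %d\n",
              x$method, x$rho, x$p_value, x$n_effective))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject all hypotheses with `p <= p_(k*)` where `k*` is the largest
#' `k` with `p_(k) <= k q / m`. Adjusted p-values come from
#' `p.adjust(method = "BH")`; rejection is `p_adjusted <= q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical), `p_adjusted`, `q`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, q = q)
}

#' First-pair canonical correlation analysis
#'
#' Standardizes both variable sets, drops incomplete rows, and extracts the
#' first canonical pair: the linear combinations `u = X a`, `v = Y b`
#' maximizing `cor(u, v)` (the maximum-correlation method). Canonical variates
#' are scaled to unit variance and the sign convention makes `r >= 0`.
#' Structure coefficients are the correlations of each original column with
#' its own set's variate. Optionally attaches a permutation p-value for `r`
#' obtained by permuting the subject indices of `v`.
#'
#' @param x,y Numeric matrices (n x p and n x q) with `n > p + q`.
#' @param permutations Number of permutations for the p-value (0 = skip).
#' @param seed RNG seed for the permutations.
#' @return An object of class `cca_result`: `weights_x`, `weights_y`,
#'   `variates_u`, `variates_v`, `r`, `structure_x`, `structure_y`, `p_perm`,
#'   `n_permutations`, `n`.
#' @export
cca_first_pair <- function(x, y, permutations = 0, seed = NULL) {
  x <- as.matrix(as.data.frame(x)); storage.mode(x) <- "double"
  y <- as.matrix(as.data.frame(y)); storage.mode(y) <- "double"
  stopifnot(nrow(x) == nrow(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  n <- nrow(x)
  if (n <= ncol(x) + ncol(y)) {
    stop("need n > p + q complete rows (n = ", n, ")")
  }
  xs <- scale(x); ys <- scale(y)
  if (anyNA(xs) || anyNA(ys)) stop("constant column in one variable set")
  if (qr(xs)$rank < ncol(xs) || qr(ys)$rank < ncol(ys)) {
    stop("rank-deficient variable set; remove collinear columns")
  }
  cc <- stats::cancor(xs, ys)
  a <- cc$xcoef[, 1]; b <- cc$ycoef[, 1]
  u <- as.numeric(xs %*% a); v <- as.numeric(ys %*% b)
  if (stats::cor(u, v) < 0) { b <- -b; v <- -v }
  a <- a / stats::sd(u); b <- b / stats::sd(v)
  u <- u / stats::sd(u); v <- v / stats::sd(v)
  r <- stats::cor(u, v)
  p_perm <- NA_real_
  if (permutations > 0) {
    p_perm <- permutation_pvalue(u, v, B = permutations, seed = seed)
  }
  structure(list(weights_x = a, weights_y = b,
                 variates_u = u, variates_v = v, r = r,
                 structure_x = drop(stats::cor(x, u)),
                 structure_y = drop(stats::cor(y, v)),
                 p_perm = as.numeric(p_perm),
                 n_permutations = permutations, n = n),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("first canonical pair: r = %.3f (n = %d)", x$r, x$n))
  if (!is.na(x$p_perm)) {
    cat(sprintf(", permutation p = %.4g (%d permutations)",
                x$p_perm, x$n_permutations))
  }
  cat("\nstructure coefficients (x):\n"); print(round(x$structure_x, 3))
  cat("structure coefficients (y):\n"); print(round(x$structure_y, 3))
  invisible(x)
}

#' Permutation p-value for a correlation
#'
#' Builds a null distribution by permuting the subject indices of `v` and
#' recomputing `cor(u, v_perm)` (the variates are held fixed, no refitting).
#' The two-sided p-value is `(1 + #{|r_null| >= |r_obs|}) / (B + 1)`.
#'
#' @param u,v Numeric vectors of equal length.
#' @param B Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return The p-value, with attributes `r_observed` and `B`.
#' @export
permutation_pvalue <- function(u, v, B = 10000, seed = NULL) {
  stopifnot(length(u) == length(v), B >= 1)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("constant vector: correlation undefined")
  }
  r_obs <- stats::cor(u, v)
  n <- length(u)
  with_seed(seed, {
    r_null <- vapply(seq_len(B),
                     function(b) stats::cor(u, v[sample.int(n)]),
                     numeric(1))
  })
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (B + 1)
  attr(p, "r_observed") <- r_obs
  attr(p, "B") <- B
  p
}

#' Stratify subjects by cognitive screening score
#'
#' Labels each subject `"MOCA-"` when the score is below `lower` (default 18),
#' `"MOCA+"` when at or above `upper` (default 25), and `"excluded"` otherwise
#' (including missing scores).
#'
#' @param scores Numeric vector of MOCA scores, `NA` = missing.
#' @param lower,upper Stratification cutoffs.
#' @return Factor with levels `MOCA-`, `MOCA+`, `excluded`.
#' @export
stratify_moca <- function(scores, lower = 18, upper = 25) {
  lab <- rep("excluded", length(scores))
  lab[!is.na(scores) & scores < lower] <- "MOCA-"
  lab[!is.na(scores) & scores >= upper] <- "MOCA+"
  factor(lab, levels = c("MOCA-", "MOCA+", "excluded"))
}

#' Independent two-sample t-test
#'
#' Equal-variance (pooled) form by default; Welch's unequal-variance form via
#' `welch = TRUE`.
#'
#' @param a,b Numeric vectors (each of length >= 2; missing values dropped).
#' @param welch Use the Welch form.
#' @return List with `t`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
independent_t_test <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("zero pooled variance: both groups constant")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Classification accuracy of repeated k-means against cognitive groups
#'
#' Restricts to labelled (`MOCA+`/`MOCA-`) subjects, standardizes the feature
#' columns, and runs k-means `iterations` times, each with a fresh random
#' initialization. In each iteration, clusters are mapped to the group labels
#' by the assignment maximizing agreement, and the agreement fraction is the
#' iteration's accuracy. The reported accuracy is the modal accuracy over
#' iterations, ties broken toward the larger value.
#'
#' @param features n x d numeric matrix (rows ordered as `labels`).
#' @param labels Factor from [stratify_moca()] (or any two-level labelling
#'   with `"excluded"` ignored).
#' @param iterations Number of k-means restarts (default 1000).
#' @param k Number of clusters (default 2).
#' @param seed RNG seed.
#' @return List with `accuracy` (modal), `iteration_accuracies`, and
#'   `histogram` (table of accuracies).
#' @export
kmeans_classification_accuracy <- function(features, labels, iterations = 1000,
                                           k = 2, seed = NULL) {
  features <- as.matrix(as.data.frame(features))
  storage.mode(features) <- "double"
  stopifnot(nrow(features) == length(labels))
  keep <- labels != "excluded" & stats::complete.cases(features)
  labs <- droplevels(factor(labels[keep]))
  if (nlevels(labs) < 2 || any(table(labs) == 0)) {
    stop("both cognitive groups must be non-empty")
  }
  fs <- scale(features[keep, , drop = FALSE])
  fs <- fs[, !apply(fs, 2, anyNA), drop = FALSE]
  if (ncol(fs) == 0) stop("no non-constant feature columns")
  y <- as.integer(labs)
  acc <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      km <- stats::kmeans(fs, centers = k, nstart = 1, iter.max = 100)
      cl <- km$cluster
      # best cluster-to-label assignment (k = 2: identity or swap)
      agree <- function(map) mean(map[cl] == y)
      if (k == 2) {
        max(agree(c(1L, 2L)), agree(c(2L, 1L)))
      } else {
        best <- 0
        for (perm in asplit(perms_of(k), 1)) best <- max(best, agree(perm))
        best
      }
    }, numeric(1))
  })
  tab <- table(acc)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  list(accuracy = max(modal), iteration_accuracies = acc, histogram = tab)
}

# All permutations of 1:k (k small); used only for k > 2.
perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}
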