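#' Connectivity matrix container
#'
#' Lightweight container for a symmetric region-by-region connectivity matrix.
#' Functional connectivity (`fc`) has unit diagonal and entries in \[-1, 1\];
#' structural (`sc`) and synchronization-likelihood (`sl`) matrices have zero
#' diagonal.
#'
#' @param values Symmetric R x R numeric matrix.
#' @param kind One of `"fc"`, `"sc"`, `"sl"`.
#' @param region_labels Optional character vector of R region names.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("fc", "sc", "sl"),
                                region_labels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8) {
    stop("connectivity matrix must be symmetric")
  }
  if (is.null(region_labels)) {
    region_labels <- as.character(seq_len(nrow(values)))
  }
  stopifnot(length(region_labels) == nrow(values))
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, kind = kind, region_labels = region_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> kind=%s, %d x %d regions\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept either a connectivity_matrix or a plain matrix.
conn_values <- function(m) {
  if (inherits(m, "connectivity_matrix")) m$values else m
}

check_no_constant_columns <- function(ts, context = "time series") {
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))
    stop("degenerate input: constant ", context, " column for region(s) ",
         paste(bad, collapse = ", "))
  }
  invisible(NULL)
}

#' Static functional connectivity
#'
#' Pearson correlation between every pair of regional time series, yielding a
#' symmetric correlation matrix with unit diagonal.
#'
#' @param ts T x R numeric matrix: T timepoints by R regions.
#' @param region_labels Optional region names.
#' @return A [connectivity_matrix()] of kind `"fc"`.
#' @export
static_fc <- function(ts, region_labels = NULL) {
  stopifnot(is.matrix(ts), nrow(ts) >= 3)
  check_no_constant_columns(ts)
  fc <- stats::cor(ts)
  diag(fc) <- 1
  fc <- (fc + t(fc)) / 2
  connectivity_matrix(fc, "fc", region_labels)
}

#' Sliding-window specification
#'
#' Describes a rectangular sliding window over a regional time series. The
#' default 50-timepoint window with a step of 2 yields 108 windows on a
#' 265-timepoint series: `floor((265 - 50) / 2) + 1`.
#'
#' @param n_timepoints Total series length T.
#' @param length Window length in timepoints (default 50).
#' @param step Window step in timepoints (default 2).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(n_timepoints, length = 50, step = 2) {
  stopifnot(is_count(n_timepoints), is_count(length), is_count(step))
  if (length > n_timepoints) {
    stop("window length (", length, ") exceeds series length (", n_timepoints, ")")
  }
  structure(list(n_timepoints = as.integer(n_timepoints),
                 length = as.integer(length), step = as.integer(step)),
            class = "window_spec")
}

#' Enumerate sliding windows
#'
#' @param spec A [window_spec()].
#' @return Integer matrix with columns `start` and `end`: half-open, 0-based
#'   intervals `[start, start + length)`, ordered by start. Row i covers R rows
#'   `(start + 1):end` of the time-series matrix.
#' @export
make_windows <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  n_win <- (spec$n_timepoints - spec$length) %/% spec$step + 1L
  start <- (seq_len(n_win) - 1L) * spec$step
  cbind(start = start, end = start + spec$length)
}

#' Sliding-window dynamic functional connectivity
#'
#' Computes [static_fc()] within each sliding window.
#'
#' @param ts T x R numeric time-series matrix.
#' @param spec A [window_spec()]; its `n_timepoints` must equal `nrow(ts)`.
#' @param region_labels Optional region names.
#' @return An object of class `windowed_fc`: a list with `windows` (list of
#'   `connectivity_matrix`) and `spec`.
#' @export
dynamic_fc <- function(ts, spec, region_labels = NULL) {
  stopifnot(is.matrix(ts), inherits(spec, "window_spec"))
  if (spec$n_timepoints != nrow(ts)) {
    stop("window spec declares ", spec$n_timepoints,
         " timepoints but series has ", nrow(ts))
  }
  win <- make_windows(spec)
  windows <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    rows <- (win[i, "start"] + 1L):win[i, "end"]
    seg <- ts[rows, , drop = FALSE]
    sds <- apply(seg, 2, stats::sd)
    if (any(sds == 0)) {
      stop("degenerate input: constant column for region ",
           which(sds == 0)[1], " in window ", i)
    }
    windows[[i]] <- static_fc(seg, region_labels)
  }
  structure(list(windows = windows, spec = spec), class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat(sprintf("<windowed_fc> %d windows of length %d (step %d) over %d timepoints\n",
              length(x$windows), x$spec$length, x$spec$step, x$spec$n_timepoints))
  invisible(x)
}

#' Nodal temporal variability of dynamic functional connectivity
#'
#' For each node k, the connectivity profile in window i is row k of that
#' window's correlation matrix with the (constant) self-entry removed. The
#' temporal variability of node k is
#' \deqn{V_k = 1 - \frac{\sum_{i \ne j} \rho_{F_{i,k} F_{j,k}}}{n(n-1)}}
#' i.e. one minus the mean Pearson correlation between the node's profiles over
#' all ordered pairs of distinct windows. Values lie in \[0, 2\]: 0 for a
#' perfectly stable profile, 2 when profiles anti-correlate perfectly.
#'
#' @param wfc A `windowed_fc` object from [dynamic_fc()], or a plain list of
#'   R x R matrices.
#' @return Numeric vector of length R.
#' @export
temporal_variability <- function(wfc) {
  mats <- if (inherits(wfc, "windowed_fc")) {
    lapply(wfc$windows, conn_values)
  } else {
    lapply(wfc, conn_values)
  }
  n <- length(mats)
  if (n < 2) stop("temporal variability needs at least 2 windows")
  R <- nrow(mats[[1]])
  v <- numeric(R)
  for (k in seq_len(R)) {
    # profiles: one column per window, self-entry dropped
    prof <- vapply(mats, function(m) m[k, -k], numeric(R - 1))
    sds <- apply(prof, 2, stats::sd)
    if (any(sds == 0)) {
      stop("degenerate input: constant connectivity profile for node ", k,
           " in window ", which(sds == 0)[1])
    }
    cc <- stats::cor(prof)
    v[k] <- 1 - (sum(cc) - n) / (n * (n - 1))
  }
  names(v) <- rownames(mats[[1]]) %||% as.character(seq_len(R))
  v
}

# Vectorized temporal variability straight from a time series: numerically
# equivalent to temporal_variability(dynamic_fc(ts, spec)) (tested to 1e-10)
# but avoids per-window object construction. For node k with standardized
# profiles S (one column per window), sum of the pairwise correlation matrix
# is ||S 1||^2, so the mean off-diagonal correlation needs no explicit loop.
fast_tv <- function(ts, spec) {
  win <- make_windows(spec)
  n <- nrow(win)
  R <- ncol(ts)
  len <- spec$length
  ut <- which(upper.tri(diag(R)), arr.ind = TRUE)
  # sliding first/second moments from padded cumulative sums
  wsum <- function(m) {
    csp <- rbind(0, apply(m, 2, cumsum))
    csp[win[, "end"] + 1L, , drop = FALSE] - csp[win[, "start"] + 1L, , drop = FALSE]
  }
  s1 <- wsum(ts)
  s2 <- wsum(ts^2)
  sx <- wsum(ts[, ut[, 1], drop = FALSE] * ts[, ut[, 2], drop = FALSE])
  mu <- s1 / len
  va <- (s2 - len * mu^2) / (len - 1)
  if (any(va <= 0)) {
    bad <- which(va <= 0, arr.ind = TRUE)[1, ]
    stop("degenerate input: constant column for region ", bad[2],
         " in window ", bad[1])
  }
  cov <- (sx - len * mu[, ut[, 1], drop = FALSE] * mu[, ut[, 2], drop = FALSE]) / (len - 1)
  corw <- cov / sqrt(va[, ut[, 1], drop = FALSE] * va[, ut[, 2], drop = FALSE])
  v <- numeric(R)
  for (k in seq_len(R)) {
    prof <- t(corw[, ut[, 1] == k | ut[, 2] == k, drop = FALSE]) # (R-1) x n
    cen <- prof - rep(colMeans(prof), each = R - 1)
    ss <- sqrt(colSums(cen^2))
    if (any(ss == 0)) {
      stop("degenerate input: constant connectivity profile for node ", k)
    }
    s <- cen / rep(ss, each = R - 1)
    total <- sum(rowSums(s)^2)      # = sum of the n x n correlation matrix
    v[k] <- 1 - (total - n) / (n * (n - 1))
  }
  v
}

#' Volume-scaled structural connectivity
#'
#' Scales a streamline-count matrix by the inverse of the mean of the two node
#' volumes: entry (i, j) becomes `counts[i, j] * 2 / (v_i + v_j)`. The product
#' convention `counts[i, j] / (v_i * v_j)` is available via `convention`.
#'
#' @param counts Symmetric nonnegative R x R streamline-count matrix, zero
#'   diagonal.
#' @param volumes Positive numeric vector of R node volumes.
#' @param convention `"sum"` (default) or `"product"`.
#' @param region_labels Optional region names.
#' @return A [connectivity_matrix()] of kind `"sc"`.
#' @export
scale_sc <- function(counts, volumes, convention = c("sum", "product"),
                     region_labels = NULL) {
  convention <- match.arg(convention)
  counts <- conn_values(counts)
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            length(volumes) == nrow(counts))
  if (any(counts < 0)) stop("streamline counts must be nonnegative")
  if (any(volumes <= 0)) {
    stop("non-positive node volume for region ", which(volumes <= 0)[1])
  }
  denom <- if (convention == "sum") {
    outer(volumes, volumes, `+`) / 2
  } else {
    outer(volumes, volumes, `*`)
  }
  scaled <- counts / denom
  diag(scaled) <- 0
  connectivity_matrix(scaled, "sc", region_labels)
}
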