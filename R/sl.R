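#' Synchronization-likelihood parameters
#'
#' Parameters of the synchronization-likelihood (SL) estimate of generalized
#' synchronization between two time series: `m` embedding dimension, `lag`
#' embedding lag in timepoints, `w1`/`w2` inner and outer Theiler windows
#' (pairs with `w1 < |i - j| < w2` are valid recurrence candidates), and
#' `p_ref` the target recurrence probability. An outer window exceeding the
#' embedded-series length simply disables the upper bound.
#'
#' @param m Embedding dimension (default 25).
#' @param lag Embedding lag in timepoints (default 20).
#' @param w1 Inner Theiler window (default 960).
#' @param w2 Outer Theiler window (default 1959).
#' @param p_ref Recurrence probability in (0, 1) (default 0.05).
#' @return An object of class `sl_params`.
#' @export
sl_params <- function(m = 25, lag = 20, w1 = 960, w2 = 1959, p_ref = 0.05) {
  stopifnot(is_count(m), m >= 2, is_count(lag),
            is.numeric(w1), w1 >= 0, is.numeric(w2), w2 > w1,
            is.numeric(p_ref), p_ref > 0, p_ref < 1)
  structure(list(m = as.integer(m), lag = as.integer(lag),
                 w1 = w1, w2 = w2, p_ref = p_ref),
            class = "sl_params")
}

# Time-delay embedding: row i is (x_i, x_{i+lag}, ..., x_{i+(m-1)lag}).
embed_delay <- function(x, m, lag) {
  n_emb <- length(x) - (m - 1) * lag
  idx <- outer(seq_len(n_emb), (seq_len(m) - 1L) * lag, `+`)
  matrix(x[idx], nrow = n_emb, ncol = m)
}

#' Synchronization likelihood between two time series
#'
#' Both series are time-delay embedded. For each reference point i, a critical
#' distance per channel is set to the k-th smallest distance to the valid
#' neighbours (those j with `w1 < |i - j| < w2`), where
#' `k = max(1, round(p_ref * n_valid))`, so each channel recurs with
#' probability about `p_ref`. The synchronization likelihood at i is the number
#' of joint recurrences (both channels within their critical distance) divided
#' by k; the reported SL is the average over reference points, clipped to
#' \[0, 1\]. Identical channels give SL = 1; independent channels give SL
#' close to `p_ref`.
#'
#' @param x,y Numeric vectors of equal length T, with
#'   `T >= (m - 1) * lag + 2`.
#' @param params An [sl_params()] object.
#' @return Scalar SL in \[0, 1\].
#' @export
synchronization_likelihood <- function(x, y, params = sl_params()) {
  stopifnot(inherits(params, "sl_params"), length(x) == length(y))
  t_min <- (params$m - 1) * params$lag + 2
  if (length(x) < t_min) {
    stop("series too short for embedding: need at least ", t_min,
         " timepoints for m = ", params$m, ", lag = ", params$lag)
  }
  ex <- embed_delay(x, params$m, params$lag)
  ey <- embed_delay(y, params$m, params$lag)
  n <- nrow(ex)
  dx <- as.matrix(stats::dist(ex))
  dy <- as.matrix(stats::dist(ey))
  lagdiff <- abs(outer(seq_len(n), seq_len(n), `-`))
  valid <- lagdiff > params$w1 & lagdiff < params$w2
  if (!any(valid)) {
    stop("Theiler windows (w1 = ", params$w1, ", w2 = ", params$w2,
         ") leave no valid pairs for an embedded series of length ", n)
  }
  sl_i <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vj <- which(valid[i, ])
    if (length(vj) == 0) next
    k <- max(1L, as.integer(round(params$p_ref * length(vj))))
    eps_x <- sort(dx[i, vj], partial = k)[k]
    eps_y <- sort(dy[i, vj], partial = k)[k]
    joint <- sum(dx[i, vj] <= eps_x & dy[i, vj] <= eps_y)
    sl_i[i] <- joint / k
  }
  min(1, max(0, mean(sl_i, na.rm = TRUE)))
}

#' Pairwise synchronization-likelihood matrix
#'
#' Applies [synchronization_likelihood()] to every pair of regional time
#' series, yielding one symmetric R x R matrix per subject (zero diagonal).
#'
#' @param ts T x R time-series matrix.
#' @param params An [sl_params()] object.
#' @param region_labels Optional region names.
#' @return A [connectivity_matrix()] of kind `"sl"`.
#' @export
sl_matrix <- function(ts, params = sl_params(), region_labels = NULL) {
  stopifnot(is.matrix(ts))
  R <- ncol(ts)
  out <- matrix(0, R, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      out[i, j] <- out[j, i] <- synchronization_likelihood(ts[, i], ts[, j], params)
    }
  }
  connectivity_matrix(out, "sl", region_labels)
}
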