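# Independent from-definition oracles used across the test files. These are
# deliberately naive (loops, matrix powers, closed forms) and share no code
# with the package internals they check.

# --- graph oracles ---------------------------------------------------------

# all-pairs shortest-path lengths by matrix powers (walk counting)
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  pow <- diag(1, n)
  for (len in seq_len(max(1, n - 1))) {
    pow <- pow %*% adj
    d[pow > 0 & is.infinite(d)] <- len
  }
  d
}

# number of shortest paths between every pair: walks of exactly length d(i,j)
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  pows <- vector("list", n)
  pows[[1]] <- diag(1, n)
  for (len in seq_len(n - 1)) pows[[len + 1]] <- pows[[len]] %*% adj
  cnt <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) cnt[i, j] <- pows[[d[i, j] + 1]][i, j]
  }
  cnt
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s != t && s != v && t != v && is.finite(d[s, t]) &&
          is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2)) else b
}

oracle_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) sum(1 / d[v, -v]) / (n - 1), numeric(1))
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      tri <- tri + (adj[nb[a], nb[b]] > 0)
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

random_graph <- function(n, p_edge = NULL) {
  if (is.null(p_edge)) p_edge <- stats::runif(1, 0.2, 0.8)
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- as.integer(stats::runif(sum(ut)) < p_edge)
  adj + t(adj)
}

# --- statistics oracles ----------------------------------------------------

fisher_z_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

# first-order partial correlation controlling one covariate
oracle_partial_3var <- function(x, y, z) {
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Benjamini-Hochberg step-up rejection set applied literally
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# first canonical correlation via the generalized eigenvalue problem
oracle_cca_r <- function(x, y) {
  sxx <- stats::cov(x); syy <- stats::cov(y)
  sxy <- stats::cov(x, y)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  sqrt(max(Re(eigen(m)$values)))
}

# pooled-variance two-sample t statistic from the textbook formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# --- connectivity oracles --------------------------------------------------

# temporal variability by explicit double loop over window pairs
oracle_tv <- function(mats) {
  n <- length(mats)
  R <- nrow(mats[[1]])
  vapply(seq_len(R), function(k) {
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) tot <- tot + stats::cor(mats[[i]][k, -k], mats[[j]][k, -k])
    }
    1 - tot / (n * (n - 1))
  }, numeric(1))
}

# synchronization likelihood by all-pairs brute-force recurrence counting,
# from the documented definition (k-th nearest neighbour critical distance,
# joint recurrences divided by k, averaged, clipped)
oracle_sl <- function(x, y, m, lag, w1, w2, p_ref) {
  n_emb <- length(x) - (m - 1) * lag
  embed1 <- function(v) {
    t(vapply(seq_len(n_emb), function(i) v[i + (seq_len(m) - 1) * lag],
             numeric(m)))
  }
  ex <- embed1(x); ey <- embed1(y)
  vals <- c()
  for (i in seq_len(n_emb)) {
    dxi <- dyi <- c(); js <- c()
    for (j in seq_len(n_emb)) {
      if (abs(i - j) > w1 && abs(i - j) < w2) {
        dxi <- c(dxi, sqrt(sum((ex[i, ] - ex[j, ])^2)))
        dyi <- c(dyi, sqrt(sum((ey[i, ] - ey[j, ])^2)))
        js <- c(js, j)
      }
    }
    if (length(js) == 0) next
    k <- max(1, round(p_ref * length(js)))
    ex_eps <- sort(dxi)[k]; ey_eps <- sort(dyi)[k]
    vals <- c(vals, sum(dxi <= ex_eps & dyi <= ey_eps) / k)
  }
  min(1, max(0, mean(vals)))
}

# --- shared fixtures -------------------------------------------------------

# a small, quick cohort reused by several test files
tiny_cohort <- function(n = 40, R = 8, tp = 60, seed = 101, ...) {
  generate_cohort(cohort_config(n, n_regions = R, n_timepoints = tp,
                                seed = seed, ...))
}

cohort_ages <- function(cohort) vapply(cohort, `[[`, numeric(1), "age")
cohort_gaps <- function(cohort) vapply(cohort, `[[`, numeric(1), "true_gap")
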