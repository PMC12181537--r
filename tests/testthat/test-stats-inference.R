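test_that("partial correlation reduces to plain correlation without covariates", {
  set.seed(61)
  x <- rnorm(40); y <- rnorm(40)
  res <- partial_correlation(x, y, method = "pearson")
  expect_equal(res$rho, cor(x, y), tolerance = 1e-12)
  sp <- partial_correlation(x, y, method = "spearman")
  expect_equal(sp$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("three-variable partial correlation matches the closed form", {
  set.seed(62)
  for (rep in 1:50) {
    z <- rnorm(30)
    x <- 0.5 * z + rnorm(30)
    y <- -0.3 * z + rnorm(30)
    res <- partial_correlation(x, y, z, method = "pearson")
    expect_equal(res$rho, oracle_partial_3var(x, y, z), tolerance = 1e-10)
  }
})

test_that("a perfect linear relation survives independent covariates", {
  set.seed(63)
  x <- rnorm(50)
  y <- 2 * x + 3
  z <- cbind(rnorm(50), rnorm(50))
  res <- partial_correlation(x, y, z, method = "pearson")
  expect_equal(res$rho, 1, tolerance = 1e-10)
})

test_that("partial correlation is symmetric, handles missing rows, and errors on collinearity", {
  set.seed(64)
  x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  expect_equal(partial_correlation(x, y, z)$rho,
               partial_correlation(y, x, z)$rho, tolerance = 1e-12)
  x2 <- x; x2[c(3, 9)] <- NA
  res <- partial_correlation(x2, y, z)
  expect_equal(res$n_effective, 38)
  expect_error(partial_correlation(2 * z + 1, y, z, method = "pearson"),
               "zero-variance residual")
})

test_that("BH rejection matches the hand step-up rule", {
  res <- bh_fdr(c(0.01, 0.02, 0.5), q = 0.05)
  expect_equal(sum(res$reject), 2)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE))
  expect_equal(sum(bh_fdr(rep(1, 10))$reject), 0)
  expect_true(bh_fdr(0.05, q = 0.05)$reject)
  expect_false(bh_fdr(0.051, q = 0.05)$reject)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("CCA degenerate cases: duplicated sets and bivariate reduction", {
  set.seed(65)
  x <- matrix(rnorm(60), 30, 2)
  dup <- cca_first_pair(x, x + 0)
  expect_equal(dup$r, 1, tolerance = 1e-8)
  a <- rnorm(30); b <- 0.6 * a + rnorm(30)
  biv <- cca_first_pair(cbind(a), cbind(b))
  expect_equal(biv$r, abs(cor(a, b)), tolerance = 1e-10)
  expect_equal(abs(unname(biv$structure_x)), 1, tolerance = 1e-10)
  expect_equal(abs(unname(biv$structure_y)), 1, tolerance = 1e-10)
})

test_that("CCA canonical correlation matches the eigen oracle", {
  set.seed(66)
  for (rep in 1:20) {
    n <- 50
    z <- rnorm(n)
    x <- cbind(z + rnorm(n), rnorm(n))
    y <- cbind(rnorm(n), 0.7 * z + rnorm(n))
    res <- cca_first_pair(x, y)
    expect_equal(res$r, oracle_cca_r(x, y), tolerance = 1e-8)
    # invariant to affine rescaling of a column
    x2 <- x; x2[, 1] <- -3 * x2[, 1] + 7
    expect_equal(cca_first_pair(x2, y)$r, res$r, tolerance = 1e-8)
    # variates have unit variance, r nonnegative, structure coefs in [-1, 1]
    expect_equal(sd(res$variates_u), 1, tolerance = 1e-10)
    expect_equal(sd(res$variates_v), 1, tolerance = 1e-10)
    expect_gte(res$r, 0)
    expect_true(all(abs(c(res$structure_x, res$structure_y)) <= 1 + 1e-10))
  }
  expect_error(cca_first_pair(cbind(z = rnorm(30), z2 = rnorm(30) * 0 + 1),
                              cbind(rnorm(30))), "constant|rank")
})

test_that("permutation p-values hit their discrete closed forms", {
  set.seed(67)
  u <- rnorm(50)
  expect_equal(as.numeric(permutation_pvalue(u, u, B = 200, seed = 1)),
               1 / 201)
  p1 <- as.numeric(permutation_pvalue(rnorm(20), rnorm(20), B = 1, seed = 2))
  expect_true(p1 %in% c(1 / 2, 1))
  expect_error(permutation_pvalue(u, rep(1, 50)), "constant")
})

test_that("permutation p-values are reproducible given a seed", {
  set.seed(68)
  u <- rnorm(30); v <- rnorm(30)
  expect_identical(as.numeric(permutation_pvalue(u, v, B = 99, seed = 5)),
                   as.numeric(permutation_pvalue(u, v, B = 99, seed = 5)))
})

test_that("MOCA stratification respects its boundaries and missingness", {
  lab <- stratify_moca(c(14, 18, 24, 25, 28))
  expect_equal(as.character(lab),
               c("MOCA-", "excluded", "excluded", "MOCA+", "MOCA+"))
  expect_true(all(stratify_moca(c(NA, NA)) == "excluded"))
  set.seed(69)
  scores <- sample(c(10:30, NA), 100, replace = TRUE)
  lab <- stratify_moca(scores)
  # direct comparison-loop oracle
  want <- vapply(scores, function(s) {
    if (is.na(s)) "excluded" else if (s < 18) "MOCA-" else if (s >= 25) "MOCA+"
    else "excluded"
  }, character(1))
  expect_equal(as.character(lab), want)
})

test_that("the pooled t-test matches the textbook formula and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- independent_t_test(a, b)
  expect_equal(res$t, oracle_pooled_t(a, b), tolerance = 1e-12)
  rev <- independent_t_test(b, a)
  expect_equal(rev$t, -res$t, tolerance = 1e-12)
  expect_equal(rev$p_value, res$p_value, tolerance = 1e-12)
  same <- independent_t_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(independent_t_test(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("k-means separates label-aligned clouds perfectly and swaps labels freely", {
  set.seed(70)
  f <- rbind(matrix(rnorm(60, mean = 0, sd = 0.2), 30, 2),
             matrix(rnorm(60, mean = 5, sd = 0.2), 30, 2))
  lab <- factor(rep(c("MOCA-", "MOCA+"), each = 30),
                levels = c("MOCA-", "MOCA+", "excluded"))
  res <- kmeans_classification_accuracy(f, lab, iterations = 50, seed = 3)
  expect_equal(res$accuracy, 1)
  swapped <- factor(rep(c("MOCA+", "MOCA-"), each = 30),
                    levels = c("MOCA-", "MOCA+", "excluded"))
  res2 <- kmeans_classification_accuracy(f, swapped, iterations = 50, seed = 3)
  expect_equal(res2$accuracy, res$accuracy)
  expect_error(kmeans_classification_accuracy(
    f, factor(rep("MOCA+", 60), levels = levels(lab))), "non-empty")
})

test_that("random labels yield the chance-plus-matching accuracy level", {
  set.seed(71)
  n <- 200
  # with arbitrary labels, the best of the two cluster-label assignments on
  # n = 200 sits near 0.5 plus the optimal-matching inflation ~ E|Binom
  # excess|; a Monte-Carlo over independent replicates pins the level
  accs <- vapply(1:30, function(i) {
    f <- matrix(rnorm(n * 2), n, 2)
    lab <- factor(sample(rep(c("MOCA-", "MOCA+"), each = n / 2)),
                  levels = c("MOCA-", "MOCA+", "excluded"))
    kmeans_classification_accuracy(f, lab, iterations = 20, seed = i)$accuracy
  }, numeric(1))
  # null accuracy stays well below a genuinely separable configuration but
  # above 0.5 by construction of the best-assignment mapping
  expect_gt(mean(accs), 0.5)
  expect_lt(mean(accs), 0.65)
})
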