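test_that("standardize centers and scales with the N-1 denominator", {
  set.seed(1)
  x <- matrix(rnorm(50, 5, 3), 10, 5)
  z <- standardize(x)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5))
  expect_equal(matrix(standardize(z), 10, 5), matrix(z, 10, 5),
               tolerance = 1e-12)
  expect_equal(as.numeric(standardize(matrix(c(0, 2), 2, 1))),
               c(-1, 1) / sqrt(2))
  xc <- cbind(a = x[, 1], flat = rep(3, 10))
  expect_error(standardize(xc), "flat")
})

test_that("a 1x1 CCA recovers the absolute Pearson correlation", {
  set.seed(2)
  x <- rnorm(40)
  y <- -0.6 * x + rnorm(40)
  fit <- dopacca(cbind(x), cbind(y))
  expect_equal(fit$cancor, abs(cor(x, y)), tolerance = 1e-10)
  # and the Rao F equals the squared t of the correlation test
  n <- 40
  F1 <- fit$dimension_tests$F[1]
  expect_equal(F1, fit$r_squared / (1 - fit$r_squared) * (n - 2),
               tolerance = 1e-10)
  expect_equal(F1, unname(cor.test(x, y)$statistic)^2, tolerance = 1e-8)
})

test_that("identical sets give unit correlations; independent sets near zero", {
  set.seed(3)
  x <- matrix(rnorm(90), 30, 3)
  fit_same <- dopacca(x, x)
  expect_equal(fit_same$cancor, rep(1, 3), tolerance = 1e-8)
  xn <- matrix(rnorm(2e4), 1e4, 2)
  yn <- matrix(rnorm(2e4), 1e4, 2)
  fit_null <- dopacca(xn, yn)
  expect_true(all(fit_null$cancor < 0.05))
})

test_that("decomposition matches a grid-search oracle on 2x2 problems", {
  set.seed(4)
  x <- matrix(rnorm(160), 80, 2)
  y <- cbind(0.7 * x[, 1] + rnorm(80, 0, 0.8),
             -0.4 * x[, 2] + rnorm(80, 0, 1.2))
  fit <- dopacca(x, y)
  expect_equal(fit$cancor[1], grid_cca_r1(x, y), tolerance = 1e-3)
})

test_that("canonical correlations agree with stats::cancor on standardized data", {
  set.seed(5)
  x <- matrix(rnorm(35 * 5), 35, 5)
  y <- x %*% matrix(rnorm(25, 0, 0.3), 5, 5) + matrix(rnorm(35 * 5), 35, 5)
  fit <- dopacca(x, y)
  ref <- stats::cancor(scale(x), scale(y))
  expect_equal(fit$cancor, ref$cor, tolerance = 1e-8)
})

test_that("variates are unit-variance, mutually uncorrelated, and maximal", {
  set.seed(6)
  x <- matrix(rnorm(200), 50, 4)
  y <- x[, 1:3] %*% diag(c(0.8, 0.5, 0.2)) + matrix(rnorm(150), 50, 3)
  colnames(y) <- paste0("m", 1:3)
  fit <- dopacca(x, y)
  expect_equal(unname(apply(fit$scores_x, 2, sd)), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(unname(apply(fit$scores_y, 2, sd)), rep(1, 3),
               tolerance = 1e-10)
  cx <- cor(fit$scores_x)
  expect_true(all(abs(cx[upper.tri(cx)]) < 1e-8))
  cy <- cor(fit$scores_y)
  expect_true(all(abs(cy[upper.tri(cy)]) < 1e-8))
  expect_true(all(diff(fit$cancor) <= 1e-12))      # descending
  # first canonical correlation dominates every pairwise correlation
  expect_gte(fit$cancor[1] + 1e-12, max(abs(cor(x, y))))
  # scores reproduce the canonical correlations
  expect_equal(unname(diag(cor(fit$scores_x, fit$scores_y))), fit$cancor,
               tolerance = 1e-10)
  # structure coefficients are variable-variate correlations
  expect_equal(unname(fit$ystructure), unname(cor(y, fit$scores_y)),
               tolerance = 1e-10)
})

test_that("Wilks product identity and rescaling invariance hold", {
  set.seed(7)
  x <- matrix(rnorm(35 * 5), 35, 5)
  y <- x %*% matrix(rnorm(25, 0, 0.3), 5, 5) + matrix(rnorm(35 * 5), 35, 5)
  fit <- dopacca(x, y)
  expect_equal(prod(1 - fit$r_squared), fit$dimension_tests$wilks[1],
               tolerance = 1e-12)
  x2 <- sweep(sweep(x, 2, c(2, -3, 0.5, 10, 1), `*`), 2, 1:5, `+`)
  y2 <- sweep(y, 2, c(100, -0.01, 5, 2, 3), `*`)
  fit2 <- dopacca(x2, y2)
  expect_equal(fit2$cancor, fit$cancor, tolerance = 1e-10)
})

test_that("sign orientation makes the top criterion loading positive", {
  set.seed(8)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- cbind(a = -x[, 1] + rnorm(40, 0, 0.4), b = rnorm(40))
  fit <- dopacca(x, y)
  for (j in seq_along(fit$cancor)) {
    top <- which.max(abs(fit$ystructure[, j]))
    expect_gt(fit$ystructure[top, j], 0)
  }
  # orientation is idempotent and leaves the correlations untouched
  fit2 <- orient_signs(fit)
  expect_identical(fit2$xcoef, fit$xcoef)
  expect_identical(fit2$cancor, fit$cancor)
  # joint flips preserve variable-variate geometry
  expect_equal(unname(diag(cor(fit$scores_x, fit$scores_y))), fit$cancor,
               tolerance = 1e-10)
})

test_that("dimension-test degrees of freedom reproduce the N=35 reference", {
  r2 <- c(0.581, 0.351, 0.072, 0.028, 0.005)
  dt <- wilks_dimension_tests(r2, 35, 5, 5)
  expect_equal(dt$df1, c(25, 16, 9, 4, 1))
  expect_equal(round(dt$df2[1], 3), 94.373)
  expect_equal(round(dt$df2[2:4], 2), c(80.07, 65.86, 56.00))
  expect_equal(dt$df2[5], 29)
  expect_equal(dt$roots, paste(1:5, "to", 5))
  expect_error(wilks_dimension_tests(r2, 10, 5, 5), "N must exceed")
  expect_error(wilks_dimension_tests(r2[1:3], 35, 5, 5), "expected 5")
  expect_error(wilks_dimension_tests(c(1.2, r2[2:5]), 35, 5, 5), "lie in")
})

test_that("rank-deficient sets error unless a fallback is enabled", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  x <- cbind(x, x[, 1] + x[, 2])  # exact collinearity
  y <- matrix(rnorm(40), 20, 2)
  expect_error(dopacca(x, y), "singular")
  fit <- dopacca(x, y, pseudo_inverse = TRUE)
  expect_true(all(is.finite(fit$cancor)))
  fit_r <- dopacca(x, y, ridge = 1e-6)
  expect_true(all(is.finite(fit_r$cancor)))
})

test_that("permutation p-value flags strong signal and is calibrated at null", {
  set.seed(10)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- cbind(x[, 1] + rnorm(40, 0, 0.2), rnorm(40))
  fit <- dopacca(x, y, permutations = 199)
  expect_lt(fit$perm_p, 0.05)
  # under independence the permutation test is exact: across replicate null
  # datasets the rejection rate stays inside the binomial 99% band
  rejections <- vapply(1:40, function(i) {
    xn <- matrix(rnorm(80), 40, 2)
    yn <- matrix(rnorm(80), 40, 2)
    dopacca(xn, yn, permutations = 99)$perm_p < 0.05
  }, logical(1))
  expect_lte(sum(rejections), qbinom(0.995, 40, 0.05))
})

test_that("age residualization removes age from every column", {
  set.seed(11)
  n <- 60
  age <- runif(n, 26, 79)
  x <- cbind(age = age,
             amygdala = -0.02 * age + rnorm(n),
             insula = rnorm(n))
  y <- cbind(m1 = 0.01 * age + rnorm(n), m2 = rnorm(n))
  rr <- residualize_age(x, y)
  expect_equal(colnames(rr$x), c("amygdala", "insula"))
  for (j in seq_len(ncol(rr$x)))
    expect_lt(abs(cor(rr$x[, j], age)), 1e-10)
  for (j in seq_len(ncol(rr$y)))
    expect_lt(abs(cor(rr$y[, j], age)), 1e-10)
  # a column already orthogonal to age is unchanged
  ortho <- residuals(lm(x[, "insula"] ~ age))
  rr2 <- residualize_age(cbind(age = age, insula = ortho), y)
  expect_equal(unname(rr2$x[, "insula"]), unname(ortho - mean(ortho)),
               tolerance = 1e-10)
  # perfect collinearity with age leaves a flagged constant column
  expect_warning(residualize_age(cbind(age = age, double_age = 2 * age), y),
                 "double_age")
  expect_error(residualize_age(cbind(age = rep(50, n), v = rnorm(n)), y),
               "constant")
})

test_that("print, summary, coef and plot methods run on a fit", {
  set.seed(12)
  x <- matrix(rnorm(90), 30, 3)
  y <- cbind(x[, 1] + rnorm(30, 0, 0.7), rnorm(30))
  colnames(x) <- c("age", "amy", "ins")
  colnames(y) <- c("inflex", "opt")
  fit <- dopacca(x, y)
  expect_output(print(fit), "Canonical correlations")
  expect_output(print(summary(fit)), "r_s")
  expect_identical(coef(fit, "x"), fit$xcoef)
  expect_identical(coef(fit, "y", "structure"), fit$ystructure)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
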