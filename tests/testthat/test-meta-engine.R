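test_that("fixed-effect limit reproduces the inverse-variance closed form", {
  d <- data.frame(D = c(1, 2, 3), V = c(1, 1, 1))
  fit <- rangeshift_meta(D ~ 1, data = d, vi = V, fix_t2s = 0)
  expect_equal(unname(coef(fit)), 2)
  expect_equal(unname(fit$se), sqrt(1 / 3))
  # unequal variances: beta = sum(w y) / sum(w)
  d2 <- data.frame(D = c(0, 6), V = c(1, 2))
  f2 <- rangeshift_meta(D ~ 1, data = d2, vi = V, fix_t2s = 0, test = "z")
  w <- 1 / d2$V
  expect_equal(unname(coef(f2)), sum(w * d2$D) / sum(w))
  expect_equal(unname(f2$se), sqrt(1 / sum(w)))
})

test_that("balanced case: pooled mean equals the arithmetic mean", {
  set.seed(3)
  d <- data.frame(D = rnorm(12, -20, 10), V = rep(4, 12))
  fit <- rangeshift_meta(D ~ 1, data = d, vi = V)
  expect_equal(unname(coef(fit)), mean(d$D), tolerance = 1e-9)
  # and with R = I supplied explicitly the fit is unchanged
  R <- diag(12)
  dimnames(R) <- list(paste0("s", 1:12), paste0("s", 1:12))
  d$species <- paste0("s", 1:12)
  fitR <- rangeshift_meta(D ~ 1, data = d, vi = V, R = R, fix_t2p = 0)
  expect_equal(coef(fitR), coef(fit), tolerance = 1e-9)
})

test_that("marginal covariance assembles the three components", {
  expect_equal(marginal_covariance(c(1, 2, 3), 0, 0), diag(c(1, 2, 3)))
  # R = I puts V + T2s + T2p on the diagonal (the classic weight denominator)
  S <- marginal_covariance(c(1, 2), 3, 4, diag(2))
  expect_equal(S, diag(c(8, 9)))
  # worked 3x3 case on the 3-taxon tree correlation
  R3 <- vcv_to_correlation(brownian_vcv(tree3(), c("A", "B", "C")))
  S3 <- marginal_covariance(c(1, 1, 1), 2, 4, R3)
  expect_equal(unname(S3), rbind(c(7, 2, 0), c(2, 7, 0), c(0, 0, 7)))
  expect_error(marginal_covariance(c(1, 1), 0, 2), "requires")
})

test_that("Q statistic matches the explicit weighted-sum oracle", {
  q <- q_statistic(c(0, 2), c(1, 1))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)

  expect_equal(q_statistic(rep(5, 6), runif(6, 1, 2))$Q, 0)

  set.seed(9)
  n <- 20
  y <- rnorm(n); V <- rlnorm(n, 0, 1); X <- cbind(1, rnorm(n))
  q2 <- q_statistic(y, V, X)
  w <- 1 / V
  bfe <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  expect_equal(q2$Q, sum(w * (y - X %*% bfe)^2), tolerance = 1e-10)
  expect_equal(q2$df, n - 2)
  expect_equal(q2$pval, pchisq(q2$Q, n - 2, lower.tail = FALSE))
})

test_that("I2 decomposition follows the typical-variance formula", {
  i2 <- i_squared(1, 1, V = c(2, 2, 2))  # s2 = 2 for equal variances
  expect_equal(i2$s2_typical, 2)
  expect_equal(i2$I2_t, 50)
  expect_equal(i2$I2_s, 25)
  expect_equal(i2$I2_p, 25)

  expect_equal(i_squared(0, 0, c(1, 2))$I2_t, 0)

  V <- c(1, 2, 3)
  w <- 1 + 0.5 + 1 / 3
  s2_oracle <- 2 * w / (w^2 - (1 + 0.25 + 1 / 9))
  expect_equal(i_squared(5, 0, V)$s2_typical, s2_oracle, tolerance = 1e-12)

  # additivity holds exactly for arbitrary components
  set.seed(2)
  for (i in 1:20) {
    t2s <- runif(1, 0, 100); t2p <- runif(1, 0, 100)
    Vr <- rlnorm(5, 1, 1)
    d <- i_squared(t2s, t2p, Vr)
    expect_equal(d$I2_s + d$I2_p, d$I2_t, tolerance = 1e-9)
    expect_true(d$I2_t >= 0 && d$I2_t <= 100)
  }
  # all-zero sampling variances: heterogeneity is everything
  expect_equal(i_squared(3, 1, c(0, 0, 0))$I2_t, 100)
})

test_that("pseudo R2 is the proportional T2 reduction, truncated to [0,1]", {
  expect_equal(pseudo_r2(4, 3), 0.25)
  expect_equal(pseudo_r2(4, 4), 0)
  expect_equal(pseudo_r2(4, 5), 0)   # negative truncated
  expect_true(is.na(pseudo_r2(0, 1)))
})

test_that("effective weights are reciprocal total variances", {
  w <- effective_weights(c(0, 1), 0.5, 0.5)
  expect_equal(w$raw, c(1, 0.5))
  expect_equal(w$normalized, c(2 / 3, 1 / 3))
  expect_equal(effective_weights(rep(2, 5), 1, 0)$normalized, rep(0.2, 5))
  # monotone decreasing in V
  V <- sort(rlnorm(10, 0, 1))
  expect_true(all(diff(effective_weights(V, 3, 2)$raw) < 0))
})

test_that("degenerate all-zero-variance data yield a flagged zero fit", {
  d <- data.frame(D = rep(0, 5), V = rep(0, 5))
  expect_warning(fit <- rangeshift_meta(D ~ 1, data = d, vi = V),
                 "degenerate")
  expect_equal(unname(coef(fit)), 0)
  expect_equal(fit$t2s, 0)
  expect_true(fit$degenerate)
  expect_equal(fit$QE, 0)
  expect_equal(fit$QE_df, 4)
})

test_that("rank-deficient designs report the aliased column", {
  d <- data.frame(D = rnorm(10), V = rep(1, 10), z = rep(2, 10))
  d$z2 <- d$z
  expect_error(rangeshift_meta(D ~ z + z2, data = d, vi = V), "aliased")
})

test_that("model methods are coherent", {
  set.seed(8)
  d <- data.frame(D = rnorm(30, -10, 15), V = rlnorm(30, log(50), 0.5),
                  x = runif(30))
  fit <- rangeshift_meta(D ~ x, data = d, vi = V)
  expect_equal(unname(fitted(fit) + residuals(fit)), d$D)
  expect_equal(unname(predict(fit, newdata = data.frame(x = c(0, 1)))),
               unname(c(coef(fit)[1], sum(coef(fit)))))
  expect_equal(dim(vcov(fit)), c(2, 2))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_equal(sum(weights(fit)), 1)
  s <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(s), c(30, 3))
  expect_output(print(fit), "T2 \\(species\\)")
  # standardized residuals have roughly unit scale under the fitted model
  rs <- residuals(fit, type = "standardized")
  expect_true(sd(rs) > 0.5 && sd(rs) < 2)
})
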