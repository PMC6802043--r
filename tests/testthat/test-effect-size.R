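test_that("proportional shift follows its definition and edge rules", {
  expect_equal(compute_dij(100, 100), 0)
  expect_equal(compute_dij(50, 100), -50)
  expect_equal(compute_dij(300, 100), 200)
  expect_true(is.na(compute_dij(5, 0)))
  # scale invariance and zero-at-identity across many baselines
  x <- c(1, 7, 40, 1000)
  expect_equal(compute_dij(x, x), rep(0, 4))
  for (c_ in c(0.5, 3, 117))
    expect_equal(compute_dij(c_ * c(30, 80), c_ * c(60, 40)),
                 compute_dij(c(30, 80), c(60, 40)))
})

test_that("species effect is the mean and k-1 variance of the shifts", {
  st <- species_effect(c(-40, -50, -60))
  expect_equal(st$D, -50)
  expect_equal(st$V, 100)
  expect_equal(st$k, 3)

  st0 <- species_effect(c(7, 7, 7, 7))
  expect_equal(st0$D, 7)
  expect_equal(st0$V, 0)

  set.seed(101)
  d <- rnorm(8, -25, 20)
  st8 <- species_effect(d)
  or <- oracle_mean_var(d)
  expect_equal(st8$D, or$mean, tolerance = 1e-12)
  expect_equal(st8$V, or$var, tolerance = 1e-12)

  # permutation invariance
  perm <- sample(d)
  expect_identical(species_effect(perm)$D, mean(perm))
  expect_equal(species_effect(perm)$V, st8$V)
})

test_that("CI classification matches the normal-quantile rule", {
  z <- qnorm(0.975)
  expect_equal(classify_effect(-50, 100), "negative")
  expect_equal(-50 + z * 10 < 0, TRUE)  # the CI (-69.6, -30.4) excludes 0
  expect_equal(classify_effect(-5, 100), "nonsignificant")
  expect_equal(classify_effect(0, 0), "nonsignificant")  # boundary inclusion
  expect_equal(classify_effect(-1e-9, 0), "negative")
  expect_equal(classify_effect(40, 100), "positive")
  # invariance under positive rescaling of (D, sqrt(V))
  for (c_ in c(0.01, 1, 250)) {
    expect_equal(classify_effect(-50 * c_, 100 * c_^2), "negative")
    expect_equal(classify_effect(5 * c_, 100 * c_^2), "nonsignificant")
  }
})

test_that("species_effects aggregates a projection table per AOGCM", {
  proj <- data.frame(
    species = rep(c("a", "b"), each = 3),
    aogcm = "CCSM3",
    enm = rep(c("m1", "m2", "m3"), 2),
    baseline = c(100, 100, 100, 10, 10, 0),
    future = c(60, 50, 40, 10, 10, 3))
  eff <- species_effects(proj)
  expect_equal(eff$D[eff$species == "a"], -50)
  expect_equal(eff$V[eff$species == "a"], 100)
  # species b: zero-baseline ENM excluded, k = 2, identical shifts
  expect_equal(eff$k[eff$species == "b"], 2)
  expect_equal(eff$D[eff$species == "b"], 0)
  expect_true(eff$degenerate[eff$species == "b"])

  # min_k filter drops the species when too few ENMs survive
  expect_message(eff3 <- species_effects(proj, min_k = 3), "dropped")
  expect_equal(eff3$species, "a")
  expect_equal(attr(eff3, "dropped")$species, "b")

  # variance-of-mean switch divides V by k
  effm <- species_effects(proj, variance_of_mean = TRUE)
  expect_equal(effm$V[effm$species == "a"], 100 / 3)
})

test_that("class summaries count and average correctly", {
  eff <- data.frame(aogcm = "X", D = c(-50, -60, 0),
                    class = c("negative", "negative", "nonsignificant"))
  s <- summarize_classes(eff)
  expect_equal(s$n_negative, 2)
  expect_equal(s$n_nonsignificant, 1)
  expect_equal(s$n_positive, 0)
  expect_equal(s$mean_negative, -55)
  expect_equal(s$sd_negative, sqrt(50), tolerance = 1e-12)
  expect_true(is.na(s$mean_positive))

  allns <- data.frame(aogcm = "X", D = c(1, -1),
                      class = "nonsignificant")
  s2 <- summarize_classes(allns)
  expect_equal(s2$n_negative, 0)
  expect_true(is.na(s2$mean_negative))

  # simulation bookkeeping: counts equal the label tally
  set.seed(7)
  n <- 200
  D <- rnorm(n, 0, 60)
  V <- rlnorm(n, log(100), 1)
  eff3 <- data.frame(aogcm = sample(c("A", "B"), n, TRUE), D = D,
                     class = classify_effect(D, V))
  s3 <- summarize_classes(eff3)
  for (ao in c("A", "B")) {
    sub <- eff3[eff3$aogcm == ao, ]
    expect_equal(s3$n_negative[s3$aogcm == ao],
                 sum(sub$class == "negative"))
    expect_equal(s3$n[s3$aogcm == ao], nrow(sub))
  }
  expect_equal(sum(s3$n_negative + s3$n_nonsignificant + s3$n_positive), n)
})

test_that("unweighted mean uses the normal SD/sqrt(n) interval", {
  set.seed(1)
  d <- rnorm(50, -10, 20)
  uw <- unweighted_mean(d)
  expect_equal(uw$mean, mean(d))
  expect_equal(uw$half_width, qnorm(0.975) * sd(d) / sqrt(50))
})
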