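test_that("identical baseline and future climates give y = x everywhere", {
  base <- make_gradient_grid()
  set.seed(12)
  occ <- paste0("c", sample(100, 15))
  for (res in list(distance_model(occ, base, base, "euclidean"),
                   distance_model(occ, base, base, "gower"))) {
    expect_equal(res$y, res$x)
    expect_setequal(res$baseline_cells, res$future_cells)
    # lowest-presence threshold: every presence cell predicted present
    expect_true(all(occ %in% res$baseline_cells))
  }
  env <- envelope_model(occ, base, base, q = 0.1)
  expect_equal(env$y, env$x)
  expect_setequal(env$baseline_cells, env$future_cells)
  # the q = 0 envelope keeps every presence cell; q > 0 may trim extremes
  env0 <- envelope_model(occ, base, base, q = 0)
  expect_true(all(occ %in% env0$baseline_cells))
})

test_that("q = 0 envelope spanning the full grid range predicts all cells", {
  base <- make_gradient_grid()
  # presences at the four value extremes of both layers
  occ <- c("c1", "c10", "c91", "c100")
  res <- envelope_model(occ, base, base, q = 0)
  expect_equal(res$x, 100)
  expect_error(envelope_model("c5", base, base, q = 0.1), "degenerate")
})

test_that("warming shifts the envelope range along the gradient", {
  # 1-layer step gradient: layer value = row index; presence rows 4-6
  g <- expand.grid(row = 1:10, col = 1:10)
  g$cell <- paste0("c", seq_len(nrow(g)))
  g$temp <- as.numeric(g$row)
  base <- climate_grid(g[, c("cell", "row", "col", "temp")])
  for (delta in c(2, 5)) {
    gf <- g
    gf$temp <- gf$temp + delta
    fut <- climate_grid(gf[, c("cell", "row", "col", "temp")])
    occ <- g$cell[g$row %in% 4:6]
    res <- envelope_model(occ, base, fut, q = 0)
    # direct enumeration: a future cell is suitable iff its shifted value
    # still lies in [4, 6], i.e. its row is in [4 - delta, 6 - delta]
    expected <- g$cell[g$row >= 4 - delta & g$row <= 6 - delta]
    expect_setequal(res$future_cells, expected)
    expect_equal(res$x, 30)
    expect_equal(res$y, length(expected))
  }
})

test_that("3-cell distance model matches the hand enumeration", {
  g <- data.frame(cell = c("a", "b", "c"), env = c(0, 1, 10))
  base <- climate_grid(g)
  occ <- c("a", "b")

  # euclidean: z-scores at mean 11/3, sd sqrt(30 + 1/3); centroid of the
  # presence z-scores; threshold = min presence suitability
  mu <- 11 / 3
  sd_ <- sqrt(sum((c(0, 1, 10) - mu)^2) / 2)
  z <- (c(0, 1, 10) - mu) / sd_
  cen <- mean(z[1:2])
  suit <- -abs(z - cen)
  thr <- min(suit[1:2])
  res <- distance_model(occ, base, base, "euclidean")
  expect_equal(res$threshold, thr, tolerance = 1e-12)
  expect_setequal(res$baseline_cells, c("a", "b"))

  # gower: range-scaled to (0, 0.1, 1); centroid 0.05; threshold -0.05
  resg <- distance_model(occ, base, base, "gower")
  expect_equal(resg$threshold, -0.05, tolerance = 1e-12)
  expect_setequal(resg$baseline_cells, c("a", "b"))

  # warming by +2 pushes every cell below the euclidean threshold
  gf <- data.frame(cell = g$cell, env = g$env + 2)
  fut <- climate_grid(gf)
  zf <- (c(2, 3, 12) - mu) / sd_
  expect_equal(distance_model(occ, base, fut, "euclidean")$y,
               sum(-abs(zf - cen) >= thr))

  # single presence cell: distance zero at that cell, always predicted
  res1 <- distance_model("a", base, base, "euclidean")
  expect_true("a" %in% res1$baseline_cells)
  expect_equal(res1$threshold, 0)
})

test_that("zero-range layers are skipped with a warning under gower", {
  g <- data.frame(cell = c("a", "b", "c"), env = c(0, 1, 10),
                  flat = c(5, 5, 5))
  base <- climate_grid(g)
  expect_warning(res <- distance_model(c("a", "b"), base, base, "gower"),
                 "flat")
  expect_setequal(res$baseline_cells, c("a", "b"))
})

test_that("projection tables enumerate species x model x AOGCM", {
  base <- make_gradient_grid()
  futs <- list(CCSM3 = make_gradient_grid(3), UKMO = make_gradient_grid(6))
  set.seed(5)
  occs <- list(spA = paste0("c", sample(100, 20)),
               spB = paste0("c", sample(100, 25)))
  pt <- build_projection_table(occs, base, futs)
  expect_equal(nrow(pt), 2 * 3 * 2)
  expect_setequal(unique(pt$enm), c("bioclim", "euclidean", "gower"))
  # deterministic: same inputs, same table
  pt2 <- build_projection_table(occs, base, futs)
  expect_identical(pt, pt2)
  # counts equal direct per-model recomputation
  for (i in seq_len(nrow(pt))) {
    row <- pt[i, ]
    res <- switch(row$enm,
      bioclim = envelope_model(occs[[row$species]], base,
                               futs[[row$aogcm]], q = 0.05),
      euclidean = distance_model(occs[[row$species]], base,
                                 futs[[row$aogcm]], "euclidean"),
      gower = distance_model(occs[[row$species]], base,
                             futs[[row$aogcm]], "gower"))
    expect_equal(row$baseline, res$x)
    expect_equal(row$future, res$y)
  }
  expect_error(build_projection_table(occs, base, futs,
                                      models = "bioclim"))
})
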