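## A deliberately small, fully specified ENM ensemble: a bioclimatic
## envelope model and two distance-based suitability models, with a
## lowest-presence threshold to turn continuous suitability into
## presence/absence. It exists so the meta-analytic layer can be exercised
## end to end on synthetic climate grids; it makes no claim to emulate any
## production ENM.

#' Construct a climate grid
#'
#' @param cells data frame with a `cell` id column, optional `row`/`col`
#'   coordinates, and one numeric column per climate layer (e.g. mean
#'   annual rainfall, rainfall variability, warmest-month and
#'   coldest-month mean temperature).
#' @return object of class `climate_grid`.
#' @export
climate_grid <- function(cells) {
  stopifnot(is.data.frame(cells), "cell" %in% names(cells))
  if (anyDuplicated(cells$cell)) stop("duplicated cell ids")
  layers <- setdiff(names(cells), c("cell", "row", "col"))
  if (!length(layers)) stop("at least one climate layer is required")
  for (l in layers)
    if (!is.numeric(cells[[l]]) || anyNA(cells[[l]]))
      stop("layer '", l, "' must be numeric with no missing cells")
  structure(list(cells = cells, layers = layers), class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("climate_grid:", nrow(x$cells), "cells,",
      length(x$layers), "layers (", paste(x$layers, collapse = ", "), ")\n")
  invisible(x)
}

.check_pair <- function(baseline, future) {
  stopifnot(inherits(baseline, "climate_grid"), inherits(future, "climate_grid"))
  if (!identical(baseline$cells$cell, future$cells$cell))
    stop("baseline and future grids must share the same cell set and order")
  if (!identical(baseline$layers, future$layers))
    stop("baseline and future grids must share the same layers")
}

.check_occ <- function(occ, grid) {
  stopifnot(length(occ) >= 1)
  if (!all(occ %in% grid$cells$cell))
    stop("occurrence cells not in grid: ",
         paste(utils::head(setdiff(occ, grid$cells$cell), 5), collapse = ", "))
  unique(occ)
}

#' Bioclimatic envelope model
#'
#' A cell is predicted present iff every layer value lies within the
#' `[q, 1-q]` quantile envelope of the values observed at the presence
#' cells in the baseline climate; the same envelope is applied to the
#' future climate.
#'
#' @param occ vector of presence cell ids.
#' @param baseline,future [climate_grid()] objects on the same cells.
#' @param q envelope trimming quantile in `[0, 0.5)`; `q = 0` is the full
#'   min-max envelope.
#' @return list with `x` (baseline predicted cell count), `y` (future
#'   count), and the predicted cell id vectors `baseline_cells`,
#'   `future_cells`.
#' @export
envelope_model <- function(occ, baseline, future, q = 0.05) {
  .check_pair(baseline, future)
  occ <- .check_occ(occ, baseline)
  stopifnot(q >= 0, q < 0.5)
  if (length(occ) == 1 && q > 0)
    stop("envelope is degenerate: a single presence cell with q > 0")
  pres <- baseline$cells[match(occ, baseline$cells$cell), , drop = FALSE]
  lims <- lapply(baseline$layers, function(l)
    stats::quantile(pres[[l]], c(q, 1 - q), names = FALSE, type = 7))
  names(lims) <- baseline$layers
  inside <- function(grid) {
    ok <- rep(TRUE, nrow(grid$cells))
    for (l in grid$layers)
      ok <- ok & grid$cells[[l]] >= lims[[l]][1] & grid$cells[[l]] <= lims[[l]][2]
    grid$cells$cell[ok]
  }
  bc <- inside(baseline)
  fc <- inside(future)
  list(x = length(bc), y = length(fc), baseline_cells = bc, future_cells = fc)
}

#' Distance-based suitability model
#'
#' Suitability of a cell is the negative distance between its climate and
#' the centroid of the presence cells: euclidean distance in z-scored
#' layer space, or the Gower-style mean of range-normalized absolute layer
#' differences. Standardization parameters (means/SDs or ranges) and the
#' centroid come from the baseline climate only. Presence is assigned by
#' the lowest-presence threshold: the minimum suitability observed at a
#' baseline presence cell, applied to both climates — so every presence
#' cell is predicted present in the baseline by construction.
#'
#' @param occ vector of presence cell ids.
#' @param baseline,future [climate_grid()] objects on the same cells.
#' @param metric `"euclidean"` or `"gower"`.
#' @return list with `x`, `y`, `threshold`, `baseline_cells`,
#'   `future_cells`.
#' @export
distance_model <- function(occ, baseline, future,
                           metric = c("euclidean", "gower")) {
  .check_pair(baseline, future)
  metric <- match.arg(metric)
  occ <- .check_occ(occ, baseline)
  layers <- baseline$layers
  base_vals <- as.matrix(baseline$cells[layers])
  fut_vals <- as.matrix(future$cells[layers])

  if (metric == "euclidean") {
    mu <- colMeans(base_vals)
    sd_ <- apply(base_vals, 2, stats::sd)
    usable <- sd_ > 0
    if (!any(usable)) stop("all layers are constant; no distance defined")
    if (!all(usable))
      warning("constant layer(s) skipped: ",
              paste(layers[!usable], collapse = ", "))
    scale_fn <- function(m)
      sweep(sweep(m[, usable, drop = FALSE], 2, mu[usable]), 2,
            sd_[usable], "/")
  } else {
    rng <- apply(base_vals, 2, function(v) diff(range(v)))
    usable <- rng > 0
    if (!any(usable)) stop("all layers have zero range; no distance defined")
    if (!all(usable))
      warning("zero-range layer(s) skipped: ",
              paste(layers[!usable], collapse = ", "))
    lo <- apply(base_vals, 2, min)
    scale_fn <- function(m)
      sweep(sweep(m[, usable, drop = FALSE], 2, lo[usable]), 2,
            rng[usable], "/")
  }

  zb <- scale_fn(base_vals)
  zf <- scale_fn(fut_vals)
  centroid <- colMeans(zb[match(occ, baseline$cells$cell), , drop = FALSE])
  suit <- function(z) {
    dev <- sweep(z, 2, centroid)
    if (metric == "euclidean") -sqrt(rowSums(dev^2)) else -rowMeans(abs(dev))
  }
  sb <- suit(zb)
  sf <- suit(zf)
  thr <- min(sb[match(occ, baseline$cells$cell)])
  bc <- baseline$cells$cell[sb >= thr]
  fc <- future$cells$cell[sf >= thr]
  list(x = length(bc), y = length(fc), threshold = thr,
       baseline_cells = bc, future_cells = fc)
}

#' Run the toy ENM ensemble into a projection table
#'
#' Applies each model of the ensemble to every species and AOGCM and
#' assembles the long-format projection table the effect-size stage
#' consumes: one row per (species, AOGCM, ENM) with baseline and future
#' predicted range sizes.
#'
#' @param occurrences named list: one vector of presence cell ids per
#'   species.
#' @param baseline baseline [climate_grid()].
#' @param futures named list of future [climate_grid()]s, one per AOGCM.
#' @param models subset of `c("bioclim", "euclidean", "gower")` (at least
#'   two, so a cross-ENM variance exists).
#' @param q envelope quantile for the bioclim model.
#' @return validated projection table data frame.
#' @export
build_projection_table <- function(occurrences, baseline, futures,
                                   models = c("bioclim", "euclidean",
                                              "gower"),
                                   q = 0.05) {
  stopifnot(length(models) >= 2, length(occurrences) >= 1,
            !is.null(names(occurrences)), !is.null(names(futures)))
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (sp in names(occurrences)) {
    for (ao in names(futures)) {
      for (m in models) {
        res <- switch(m,
          bioclim = envelope_model(occurrences[[sp]], baseline,
                                   futures[[ao]], q = q),
          euclidean = distance_model(occurrences[[sp]], baseline,
                                     futures[[ao]], metric = "euclidean"),
          gower = distance_model(occurrences[[sp]], baseline,
                                 futures[[ao]], metric = "gower"))
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, aogcm = ao, enm = m,
          baseline = res$x, future = res$y, stringsAsFactors = FALSE)
      }
    }
  }
  validate_projections(do.call(rbind, rows))
}
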