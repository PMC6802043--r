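#' Proportional range-shift of one ENM projection
#'
#' `D_ij = (y_ij - x_ij) / x_ij * 100`: the percent change between the
#' future (`y`) and baseline (`x`) projected range sizes (grid-cell
#' counts) of species i under ENM j. Negative values are projected range
#' losses. Undefined when the baseline range is empty (`x = 0`); those
#' entries return `NA` and the caller decides how to treat the ENM.
#'
#' @param y future range size(s), non-negative.
#' @param x baseline range size(s), non-negative; recycled against `y`.
#' @return numeric vector of percent shifts (`NA` where `x == 0`).
#' @examples
#' compute_dij(50, 100)   # -50: half the baseline range is lost
#' compute_dij(300, 100)  # +200
#' @export
compute_dij <- function(y, x) {
  stopifnot(all(y >= 0, na.rm = TRUE), all(x >= 0, na.rm = TRUE))
  ifelse(x > 0, (y - x) / x * 100, NA_real_)
}

#' Per-species effect sizes from a projection table
#'
#' For every species within an AOGCM, computes `D_ij` for each ENM,
#' averages across the ensemble to the effect size `D_i`, and measures the
#' cross-ENM uncertainty as the sample variance `V_i` of the `D_ij`
#' (denominator `k - 1`). ENMs with an empty baseline range are excluded
#' for that species; species with fewer than `min_k` usable ENMs are
#' dropped (reported in the `"dropped"` attribute). Species whose ENMs all
#' agree exactly (`V_i = 0`) are retained and flagged `degenerate`.
#'
#' @param proj projection table as returned by [read_projections()] or
#'   [build_projection_table()].
#' @param aogcm optional AOGCM name(s) to restrict to.
#' @param min_k minimum number of contributing ENMs (default 2).
#' @param variance_of_mean if `TRUE`, report `V_i / k` — the sampling
#'   variance of the ensemble mean `D_i` — instead of the raw cross-ENM
#'   variance. The raw variance (default) treats ensemble spread itself as
#'   the uncertainty; the divided form is the usual meta-analytic squared
#'   standard error of a mean of k replicates.
#' @param alpha significance level for the CI-based effect classification.
#' @return data frame with columns `species`, `aogcm`, `D`, `V`, `k`,
#'   `degenerate`, `class`, plus attribute `dropped`.
#' @export
species_effects <- function(proj, aogcm = NULL, min_k = 2,
                            variance_of_mean = FALSE, alpha = 0.05) {
  stopifnot(is.data.frame(proj),
            all(c("species", "aogcm", "enm", "baseline", "future") %in%
                  names(proj)))
  if (!is.null(aogcm)) proj <- proj[proj$aogcm %in% aogcm, , drop = FALSE]
  if (!nrow(proj)) stop("no projection rows for the requested AOGCM(s)")
  proj$dij <- compute_dij(proj$future, proj$baseline)

  key <- interaction(proj$species, proj$aogcm, drop = TRUE)
  pieces <- split(proj, key)
  rows <- lapply(pieces, function(g) {
    d <- g$dij[!is.na(g$dij)]
    k <- length(d)
    if (k < min_k)
      return(data.frame(species = g$species[1], aogcm = g$aogcm[1],
                        D = NA_real_, V = NA_real_, k = k,
                        degenerate = NA, class = NA_character_))
    st <- species_effect(d)
    data.frame(species = g$species[1], aogcm = g$aogcm[1],
               D = st$D, V = st$V, k = st$k,
               degenerate = st$V == 0,
               class = classify_effect(st$D, st$V, alpha = alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- out[is.na(out$D), c("species", "aogcm", "k")]
  if (nrow(dropped))
    message(nrow(dropped), " species x AOGCM combinations dropped ",
            "(fewer than ", min_k, " usable ENMs)")
  out <- out[!is.na(out$D), , drop = FALSE]
  if (!nrow(out)) stop("no species left after the min_k filter")
  if (variance_of_mean) out$V <- out$V / out$k
  out <- out[order(match(out$aogcm, unique(out$aogcm)), out$species), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Mean and cross-ENM variance of one species' shift estimates
#'
#' @param d numeric vector of `D_ij` values for one species within one
#'   AOGCM (one per ENM).
#' @return list with `D` (arithmetic mean), `V` (sample variance,
#'   denominator `k - 1`), and `k`.
#' @examples
#' species_effect(c(-40, -50, -60))  # D = -50, V = 100, k = 3
#' @export
species_effect <- function(d) {
  stopifnot(is.numeric(d), length(d) >= 2, all(is.finite(d)))
  list(D = mean(d), V = stats::var(d), k = length(d))
}

#' Classify an effect size by its confidence interval
#'
#' Normal-quantile interval `D +- z_{1-alpha/2} sqrt(V)`; `"negative"` when
#' the upper limit is below zero, `"positive"` when the lower limit is
#' above zero, `"nonsignificant"` otherwise. An interval touching zero —
#' including the zero-width interval of a degenerate `D = 0, V = 0`
#' effect — counts as including it.
#'
#' @param D effect size(s), percent.
#' @param V non-negative variance(s).
#' @param alpha significance level (default 0.05).
#' @return character vector in `{"negative", "positive", "nonsignificant"}`.
#' @export
classify_effect <- function(D, V, alpha = 0.05) {
  stopifnot(all(is.finite(D)), all(is.finite(V)), all(V >= 0))
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(V)
  ifelse(D + half < 0, "negative",
         ifelse(D - half > 0, "positive", "nonsignificant"))
}

#' Class counts and within-class summaries of species effects
#'
#' Per AOGCM: how many species are projected to decrease (negative CI),
#' neither (CI includes zero), or increase (positive CI), with the
#' unweighted mean and SD of `D_i` inside the negative and positive
#' classes (NA when a class is empty).
#'
#' @param effects data frame from [species_effects()].
#' @return data frame, one row per AOGCM.
#' @export
summarize_classes <- function(effects) {
  stopifnot(nrow(effects) > 0,
            all(c("aogcm", "D", "class") %in% names(effects)))
  one <- function(g) {
    neg <- g$D[g$class == "negative"]
    pos <- g$D[g$class == "positive"]
    data.frame(
      aogcm = g$aogcm[1],
      n = nrow(g),
      n_negative = length(neg),
      n_nonsignificant = sum(g$class == "nonsignificant"),
      n_positive = length(pos),
      mean_negative = if (length(neg)) mean(neg) else NA_real_,
      sd_negative = if (length(neg) > 1) stats::sd(neg) else NA_real_,
      mean_positive = if (length(pos)) mean(pos) else NA_real_,
      sd_positive = if (length(pos) > 1) stats::sd(pos) else NA_real_)
  }
  out <- do.call(rbind, lapply(split(effects, effects$aogcm), one))
  rownames(out) <- NULL
  out
}

#' Unweighted mean shift with a normal confidence interval
#'
#' The sensitivity contrast to the weighted mean: the simple mean of the
#' `D_i` with CI `mean +- z SD/sqrt(n)`.
#' @param D effect sizes.
#' @param level confidence level.
#' @return list with `mean`, `ci_lb`, `ci_ub`, `half_width`, `n`.
#' @export
unweighted_mean <- function(D, level = 0.95) {
  n <- length(D)
  stopifnot(n >= 2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(D)
  half <- z * stats::sd(D) / sqrt(n)
  list(mean = m, ci_lb = m - half, ci_ub = m + half,
       half_width = half, n = n)
}
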