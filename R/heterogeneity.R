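#' Marginal covariance of the multilevel model
#'
#' `Sigma = T2_s I + T2_p R + diag(V)`: unstructured species heterogeneity,
#' phylogenetically structured heterogeneity, and known within-species
#' sampling variance. With `R = I` the diagonal reduces to
#' `V_i + T2_s + T2_p`, the denominator of the classical random-effects
#' weight.
#'
#' @param V numeric vector of non-negative sampling variances.
#' @param t2s,t2p non-negative variance components.
#' @param R optional correlation matrix (defaults to no phylogenetic term).
#' @return symmetric covariance matrix.
#' @export
marginal_covariance <- function(V, t2s, t2p = 0, R = NULL) {
  stopifnot(t2s >= 0, t2p >= 0, all(V >= 0))
  n <- length(V)
  Sigma <- diag(V + t2s, n)
  if (t2p > 0) {
    if (is.null(R)) stop("t2p > 0 requires a correlation matrix R")
    stopifnot(nrow(R) == n, ncol(R) == n)
    Sigma <- Sigma + t2p * as.matrix(R)
  }
  Sigma
}

#' Cochran's Q statistic for residual heterogeneity
#'
#' Weighted sum of squared deviations of the effect sizes from the
#' fixed-effects (inverse-variance weighted) fit, with weights `1/V_i`,
#' referred to a chi-square with `n - p` degrees of freedom. The weights
#' are fixed-effects weights, independent of any random-effects fit.
#'
#' Zero sampling variances would give infinite weights; if the effects are
#' all identical Q is 0 by definition, otherwise zero variances are
#' replaced by the smallest positive variance (with a warning).
#'
#' @param y effect sizes.
#' @param V sampling variances.
#' @param X design matrix; defaults to intercept only.
#' @return list with `Q`, `df`, `pval`.
#' @export
q_statistic <- function(y, V, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  df <- n - p
  if (max(y) - min(y) == 0 || df <= 0)
    return(list(Q = 0, df = df, pval = if (df > 0) 1 else NA_real_))
  if (any(V == 0)) {
    pos <- V[V > 0]
    if (!length(pos)) stop("all sampling variances are zero but effects differ")
    warning("zero sampling variances replaced by smallest positive V for Q")
    V[V == 0] <- min(pos)
  }
  w <- 1 / V
  fit <- stats::lm.wfit(X, y, w)
  Q <- sum(w * fit$residuals^2)
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity decomposition
#'
#' Proportion of total effect-size variance attributable to true
#' between-species differences rather than within-species (ENM ensemble)
#' sampling variance, split into an unstructured species share and a
#' phylogenetically structured share:
#' `I2_t = 100 (T2_s + T2_p) / (T2_s + T2_p + s2)` with `s2` the typical
#' within-species variance `s2 = (n - 1) sum(w) / (sum(w)^2 - sum(w^2))`,
#' `w = 1/V`. `I2_s` and `I2_p` put `T2_s` or `T2_p` alone in the
#' numerator, so `I2_s + I2_p = I2_t` exactly.
#'
#' @param t2s,t2p non-negative heterogeneity variances.
#' @param V sampling variances (zero entries are excluded from the typical
#'   variance with a warning; if all are zero, `s2 = 0`).
#' @return list with `I2_t`, `I2_s`, `I2_p` (percentages) and `s2_typical`.
#' @export
i_squared <- function(t2s, t2p, V) {
  stopifnot(t2s >= 0, t2p >= 0, length(V) >= 2)
  if (all(V == 0)) {
    s2 <- 0
  } else {
    if (any(V == 0)) {
      warning("zero sampling variances excluded from typical-variance s2")
      V <- V[V > 0]
    }
    w <- 1 / V
    n <- length(V)
    s2 <- (n - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  }
  tot <- t2s + t2p + s2
  if (tot == 0) {
    i2t <- i2s <- i2p <- 0
  } else {
    i2t <- 100 * (t2s + t2p) / tot
    i2s <- 100 * t2s / tot
    i2p <- 100 * t2p / tot
  }
  list(I2_t = i2t, I2_s = i2s, I2_p = i2p, s2_typical = s2)
}

#' Pseudo R-squared of a meta-regression
#'
#' Proportional reduction in total heterogeneity variance when moderators
#' are added: `R2 = max(0, 1 - T2_mod / T2_null)`, with `T2` the sum of the
#' species-level and phylogenetic components (or the species component
#' alone, if `components = "species"`). Undefined (NA) when the null model
#' has no heterogeneity.
#'
#' @param fit_null intercept-only `rangeshift_meta` fit.
#' @param fit_mod moderated fit on the same species and random-effects
#'   structure.
#' @param components `"total"` (default) or `"species"`.
#' @return proportion in `[0, 1]`, or `NA` if undefined.
#' @export
pseudo_r2 <- function(fit_null, fit_mod, components = c("total", "species")) {
  components <- match.arg(components)
  pick <- function(f) {
    if (inherits(f, "rangeshift_meta")) {
      if (components == "total") f$t2s + f$t2p else f$t2s
    } else as.numeric(f)
  }
  t2_null <- pick(fit_null)
  t2_mod <- pick(fit_mod)
  if (t2_null <= 0) return(NA_real_)
  min(max(0, 1 - t2_mod / t2_null), 1)
}

#' Random-effects weights from variances
#'
#' `W_i = 1 / (V_i + T2_s + T2_p)`, plus the same weights normalized to sum
#' to one (forest-plot circle sizes).
#' @param V sampling variances.
#' @param t2s,t2p heterogeneity variances.
#' @return list with `raw` and `normalized` numeric vectors.
#' @export
effective_weights <- function(V, t2s, t2p = 0) {
  stopifnot(all(V >= 0), t2s >= 0, t2p >= 0)
  raw <- 1 / (V + t2s + t2p)
  list(raw = raw, normalized = raw / sum(raw))
}
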