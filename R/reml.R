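## ---------------------------------------------------------------------------
## Restricted-likelihood engine for the multilevel random-effects model
##
##   D ~ N(X beta, Sigma),   Sigma = T2_s I + T2_p R + diag(V)
##
## with V the known per-species sampling variances, R a phylogenetic
## correlation matrix, and (T2_s, T2_p) the species-level and
## phylogenetically structured heterogeneity variances. Variances are
## optimized on the log scale (gamma = log T2) so the boundary T2 = 0 is
## approached smoothly; gamma below GAMMA_FLOOR is reported as T2 = 0.
## ---------------------------------------------------------------------------

.GAMMA_FLOOR <- -30
.GAMMA_CEIL <- 20

## Restricted (or full) log-likelihood and its analytic gradient in gamma.
## free: character vector among c("t2s", "t2p") naming the free components.
.ll_eval <- function(gam, free, fixed, y, X, V, R, method, want_grad = FALSE) {
  t2 <- fixed
  t2[free] <- exp(gam)
  n <- length(y)
  p <- ncol(X)
  Sigma <- diag(V + t2[["t2s"]], n)
  if (!is.null(R) && t2[["t2p"]] > 0) Sigma <- Sigma + t2[["t2p"]] * R
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -1e10, grad = rep(0, length(gam))))
  ldS <- 2 * sum(log(diag(ch)))
  Xt <- backsolve(ch, X, transpose = TRUE)   # L^-1 X
  yt <- backsolve(ch, y, transpose = TRUE)   # L^-1 y
  XtX <- crossprod(Xt)                       # X' Sigma^-1 X
  cb <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(cb)) return(list(ll = -1e10, grad = rep(0, length(gam))))
  beta <- backsolve(cb, backsolve(cb, crossprod(Xt, yt), transpose = TRUE))
  rt <- yt - Xt %*% beta
  quad <- sum(rt^2)
  if (method == "REML") {
    ldXSX <- 2 * sum(log(diag(cb)))
    ll <- -0.5 * ((n - p) * log(2 * pi) + ldS + ldXSX + quad)
  } else {
    ll <- -0.5 * (n * log(2 * pi) + ldS + quad)
  }
  out <- list(ll = ll, beta = drop(beta), XtX = XtX, chol_Sigma = ch)
  if (want_grad && length(gam)) {
    Si <- chol2inv(ch)                       # Sigma^-1
    A <- Si %*% X
    K <- chol2inv(cb)                        # (X' Sigma^-1 X)^-1
    B <- A %*% K
    z <- Si %*% (y - X %*% beta)             # P y (residual form)
    grad <- numeric(length(gam))
    for (j in seq_along(free)) {
      if (free[j] == "t2s") {
        trP <- sum(diag(Si)) - if (method == "REML") sum(A * B) else 0
        dll <- -0.5 * (trP - sum(z^2))
      } else {
        trPR <- sum(Si * R) - if (method == "REML") sum(B * (R %*% A)) else 0
        dll <- -0.5 * (trPR - drop(crossprod(z, R %*% z)))
      }
      grad[j] <- dll * t2[[free[j]]]         # chain rule d ll / d gamma
    }
    out$grad <- grad
  }
  out
}

## Central-difference Hessian of the restricted log-likelihood in gamma,
## used for delta-method standard errors of the T2 estimates.
.num_hessian <- function(fn, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h
      ej[j] <- h
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

## DerSimonian-Laird moment estimate, used only as an optimizer start.
.dl_start <- function(y, X, V) {
  Vp <- pmax(V, max(V, 1) * 1e-8)
  w <- 1 / Vp
  fit <- stats::lm.wfit(X, y, w)
  Q <- sum(w * fit$residuals^2)
  df <- length(y) - ncol(X)
  denom <- sum(w) - sum(w^2) / sum(w)
  max((Q - df) / max(denom, .Machine$double.eps), 0)
}

#' Fit the multilevel random-effects model by (restricted) maximum likelihood
#'
#' Low-level engine behind [rangeshift_meta()]. Estimates the species-level
#' variance `T2_s` and (when a phylogenetic correlation matrix is supplied)
#' the phylogenetically structured variance `T2_p` by maximizing the
#' restricted log-likelihood of `y ~ N(X beta, T2_s I + T2_p R + diag(V))`
#' over log-variances, with multiple random restarts.
#'
#' @param y numeric vector of effect sizes.
#' @param X design matrix (full column rank).
#' @param V numeric vector of non-negative sampling variances.
#' @param R optional species-by-species phylogenetic correlation matrix in
#'   the same order as `y`; `NULL` drops the phylogenetic component.
#' @param fix_t2s,fix_t2p optionally fix a variance component at a
#'   non-negative value instead of estimating it.
#' @param method `"REML"` (default) or `"ML"`.
#' @param restarts number of additional random restarts of the optimizer.
#' @param reltol relative convergence tolerance passed to [stats::nlminb()].
#' @return list with elements `beta`, `vb` (covariance of beta), `t2s`,
#'   `t2p`, `se_t2s`, `se_t2p`, `loglik`, `converged`, `sigma_chol`.
#' @keywords internal
reml_engine <- function(y, X, V, R = NULL, fix_t2s = NULL, fix_t2p = NULL,
                        method = c("REML", "ML"), restarts = 3,
                        reltol = 1e-12) {
  method <- match.arg(method)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(V) == n, all(V >= 0))
  if (!is.null(R)) stopifnot(nrow(R) == n, ncol(R) == n)
  if (n <= p) stop("need more observations than fixed-effect columns")
  qx <- qr(X)
  if (qx$rank < p)
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))

  free <- character(0)
  fixed <- c(t2s = 0, t2p = 0)
  if (is.null(fix_t2s)) free <- c(free, "t2s") else fixed[["t2s"]] <- fix_t2s
  if (is.null(R)) {
    if (!is.null(fix_t2p) && fix_t2p > 0)
      stop("cannot fix t2p > 0 without a correlation matrix R")
  } else if (is.null(fix_t2p)) {
    free <- c(free, "t2p")
  } else {
    fixed[["t2p"]] <- fix_t2p
  }

  ## Degenerate data: no sampling variance and no residual spread at all.
  ols <- stats::lm.fit(X, y)
  if (all(V == 0) && sum(ols$residuals^2) < 1e-24 && length(free)) {
    warning("all sampling variances are zero and effects are collinear with ",
            "the design: returning a degenerate fit with T2 = 0")
    return(list(beta = ols$coefficients, vb = matrix(0, p, p,
                  dimnames = list(colnames(X), colnames(X))),
                t2s = 0, t2p = 0, se_t2s = NA_real_, se_t2p = NA_real_,
                loglik = NA_real_, converged = TRUE, degenerate = TRUE))
  }

  obj <- function(gam) -.ll_eval(gam, free, fixed, y, X, V, R, method)$ll
  gr <- function(gam)
    -.ll_eval(gam, free, fixed, y, X, V, R, method, want_grad = TRUE)$grad

  if (length(free)) {
    t2_dl <- .dl_start(y, X, V)
    start0 <- log(pmax(c(t2s = t2_dl, t2p = t2_dl / 5)[free], 1e-3))
    starts <- list(start0)
    if (restarts > 0) {
      for (r in seq_len(restarts))
        starts[[r + 1]] <- start0 + stats::runif(length(free), -3, 3)
    }
    best <- NULL
    for (s in starts) {
      op <- tryCatch(
        stats::nlminb(s, obj, gradient = gr,
                      lower = .GAMMA_FLOOR, upper = .GAMMA_CEIL,
                      control = list(rel.tol = reltol, iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$objective < best$objective))
        best <- op
    }
    if (is.null(best)) stop("REML optimization failed from every start")
    gam_hat <- best$par
    converged <- best$convergence == 0
    if (!converged) {
      ## nlminb sometimes flags "false convergence" at a genuine optimum;
      ## accept when first-order conditions hold (zero gradient in the
      ## interior, non-descending at the lower bound)
      g <- gr(gam_hat)
      at_lb <- gam_hat <= .GAMMA_FLOOR + 1e-6
      tol_g <- 1e-3 * max(1, abs(best$objective))
      converged <- all(abs(g[!at_lb]) < tol_g) && all(g[at_lb] > -tol_g)
    }
  } else {
    gam_hat <- numeric(0)
    converged <- TRUE
  }

  fin <- .ll_eval(gam_hat, free, fixed, y, X, V, R, method)
  if (fin$ll <= -1e9)
    stop("marginal covariance not positive definite at the optimum")

  t2 <- fixed
  t2[free] <- exp(gam_hat)
  at_floor <- free[gam_hat <= .GAMMA_FLOOR + 1e-6]
  t2[at_floor] <- 0

  se_t2 <- c(t2s = NA_real_, t2p = NA_real_)
  interior <- setdiff(free, at_floor)
  if (length(interior)) {
    idx <- match(interior, free)
    H <- tryCatch(.num_hessian(function(g) -obj(g), gam_hat), # ll Hessian
                  error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- H[idx, idx, drop = FALSE]
      Vg <- tryCatch(solve(-Hi), error = function(e) NULL)
      if (!is.null(Vg)) {
        vg <- diag(Vg)
        ok <- vg > 0
        ## delta method: SE(T2) = T2 * SE(log T2)
        se_t2[interior[ok]] <- t2[interior[ok]] * sqrt(vg[ok])
      }
    }
  }

  vb <- chol2inv(chol(fin$XtX))
  dimnames(vb) <- list(colnames(X), colnames(X))
  beta <- fin$beta
  names(beta) <- colnames(X)
  list(beta = beta, vb = vb, t2s = unname(t2[["t2s"]]),
       t2p = unname(t2[["t2p"]]), se_t2s = unname(se_t2[["t2s"]]),
       se_t2p = unname(se_t2[["t2p"]]), loglik = fin$ll,
       converged = converged, degenerate = FALSE,
       sigma_chol = fin$chol_Sigma)
}

#' Phylogenetic multilevel meta-analysis of range-shift effect sizes
#'
#' Fits the random-effects model `D_i = x_i' beta + u_s,i + u_p,i + e_i`
#' where `u_s ~ N(0, T2_s I)` captures unstructured between-species
#' heterogeneity, `u_p ~ N(0, T2_p R)` captures phylogenetically structured
#' heterogeneity (with `R` a Brownian-motion correlation matrix from
#' [phylo_correlation()]), and `e_i ~ N(0, V_i)` carries the known
#' within-species (cross-ENM) sampling variance. Variance components are
#' estimated by REML; the intercept of the null model `D ~ 1` is the
#' weighted mean range shift `M`.
#'
#' @param formula model formula, e.g. `D ~ 1` for the pooled mean or
#'   `D ~ clutch_size + iucn_ordinal` for a meta-regression. Factor
#'   moderators are coded with sum-to-zero (deviation) contrasts.
#' @param data data frame containing the response, the moderators, and
#'   (if `R` is supplied) a `species` column or row names matching the
#'   dimnames of `R`.
#' @param vi sampling variances: a bare column name evaluated in `data`,
#'   or a numeric vector.
#' @param R optional phylogenetic correlation matrix with dimnames; it is
#'   re-ordered to match the rows of `data`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param test `"t"` (default; df = n - p, matching meta-regression tables
#'   that print t statistics) or `"z"` for normal-based inference.
#' @param level confidence level for intervals (default 0.95).
#' @param fix_t2s,fix_t2p optionally pin a variance component.
#' @param restarts random optimizer restarts (default 3).
#' @return an object of class `"rangeshift_meta"`; see [summary.rangeshift_meta()].
#' @examples
#' set.seed(42)
#' d <- data.frame(D = rnorm(20, -25, 15), V = rlnorm(20, log(100), 0.5))
#' fit <- rangeshift_meta(D ~ 1, data = d, vi = V)
#' coef(fit)
#' @seealso [i_squared()], [q_statistic()], [pseudo_r2()], [meta_regression()]
#' @export
rangeshift_meta <- function(formula, data, vi, R = NULL,
                            method = c("REML", "ML"), test = c("t", "z"),
                            level = 0.95, fix_t2s = NULL, fix_t2p = NULL,
                            restarts = 3) {
  method <- match.arg(method)
  test <- match.arg(test)
  cl <- match.call()
  data <- as.data.frame(data)

  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  ## deviation coding for factors: Table-2-style contrasts vs the reference
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)

  V <- tryCatch(eval(substitute(vi), data, parent.frame()),
                error = function(e) NULL)
  if (is.null(V)) stop("could not evaluate 'vi' in 'data'")
  V <- as.numeric(V)
  if (length(V) != n) stop("'vi' must have one value per row of 'data'")
  if (any(!is.finite(V)) || any(V < 0))
    stop("sampling variances must be finite and non-negative")

  species <- if (!is.null(data$species)) as.character(data$species)
             else rownames(data)
  if (!is.null(R)) {
    R <- as.matrix(R)
    if (is.null(rownames(R)))
      stop("'R' must carry species names as dimnames")
    missing_sp <- setdiff(species, rownames(R))
    if (length(missing_sp))
      stop("species missing from correlation matrix R: ",
           paste(utils::head(missing_sp, 5), collapse = ", "))
    R <- R[species, species, drop = FALSE]
  }

  eng <- reml_engine(y, X, V, R = R, fix_t2s = fix_t2s, fix_t2p = fix_t2p,
                     method = method, restarts = restarts)

  p <- ncol(X)
  se <- sqrt(diag(eng$vb))
  stat <- eng$beta / se
  stat[se == 0] <- 0
  if (test == "t") {
    df_b <- n - p
    crit <- stats::qt(1 - (1 - level) / 2, df_b)
    pvals <- 2 * stats::pt(-abs(stat), df_b)
  } else {
    df_b <- Inf
    crit <- stats::qnorm(1 - (1 - level) / 2)
    pvals <- 2 * stats::pnorm(-abs(stat))
  }

  qe <- q_statistic(y, V, X)
  i2 <- i_squared(eng$t2s, eng$t2p, V)

  structure(list(
    call = cl, formula = formula, method = method, test = test,
    level = level, n = n, p = p, species = species,
    beta = eng$beta, se = se, stat = stat, pval = pvals, df = df_b,
    ci_lb = eng$beta - crit * se, ci_ub = eng$beta + crit * se,
    vb = eng$vb, t2s = eng$t2s, t2p = eng$t2p,
    se_t2s = eng$se_t2s, se_t2p = eng$se_t2p,
    QE = qe$Q, QE_df = qe$df, QE_p = qe$pval,
    I2 = i2, loglik = eng$loglik, converged = eng$converged,
    degenerate = isTRUE(eng$degenerate),
    yi = y, vi = V, X = X, R = R
  ), class = "rangeshift_meta")
}

#' @export
print.rangeshift_meta <- function(x, digits = 4, ...) {
  cat("Phylogenetic multilevel random-effects meta-analysis (",
      x$method, ")\n", sep = "")
  cat("n =", x$n, "species;",
      if (is.null(x$R)) "no phylogenetic component" else
        "phylogenetic correlation supplied", "\n\n")
  cat(sprintf("T2 (species):      %.*g (SE %.*g)\n", digits, x$t2s,
              digits, x$se_t2s))
  if (!is.null(x$R))
    cat(sprintf("T2 (phylogenetic): %.*g (SE %.*g)\n", digits, x$t2p,
                digits, x$se_t2p))
  cat(sprintf("I2 total %.1f%% (species %.1f%%, phylogenetic %.1f%%)\n",
              x$I2$I2_t, x$I2$I2_s, x$I2$I2_p))
  cat(sprintf("Q = %.2f, df = %d, p %s\n\n", x$QE, x$QE_df,
              format.pval(x$QE_p, digits = 3)))
  print(coef_table(x), digits = digits)
  invisible(x)
}

#' Coefficient table of a fitted meta-analysis
#' @param x a `rangeshift_meta` fit.
#' @return data frame with estimate, SE, CI bounds, test statistic, p value.
#' @export
coef_table <- function(x) {
  stopifnot(inherits(x, "rangeshift_meta"))
  data.frame(estimate = x$beta, se = x$se, ci_lb = x$ci_lb, ci_ub = x$ci_ub,
             stat = x$stat, pval = x$pval,
             row.names = names(x$beta))
}

#' @export
summary.rangeshift_meta <- function(object, ...) {
  structure(list(fit = object, coefs = coef_table(object)),
            class = "summary.rangeshift_meta")
}

#' @export
print.summary.rangeshift_meta <- function(x, ...) {
  print(x$fit, ...)
  invisible(x)
}

#' @export
coef.rangeshift_meta <- function(object, ...) object$beta

#' @export
vcov.rangeshift_meta <- function(object, ...) object$vb

#' @export
logLik.rangeshift_meta <- function(object, ...) {
  structure(object$loglik, df = object$p +
              (object$t2s > 0) + (object$t2p > 0),
            class = "logLik")
}

#' @export
confint.rangeshift_meta <- function(object, parm, level = NULL, ...) {
  ci <- cbind(object$ci_lb, object$ci_ub)
  rownames(ci) <- names(object$beta)
  colnames(ci) <- c("ci_lb", "ci_ub")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.rangeshift_meta <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(drop(object$X %*% object$beta))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  tt <- stats::delete.response(stats::terms(object$formula))
  mf <- stats::model.frame(tt, as.data.frame(newdata))
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$beta)
}

#' @export
residuals.rangeshift_meta <- function(object,
                                      type = c("response", "standardized"),
                                      ...) {
  type <- match.arg(type)
  r <- object$yi - drop(object$X %*% object$beta)
  if (type == "standardized")
    r <- r / sqrt(object$vi + object$t2s + object$t2p)
  r
}

#' @export
fitted.rangeshift_meta <- function(object, ...)
  drop(object$X %*% object$beta)

#' Effective meta-analytic weights
#'
#' `W_i = 1 / (V_i + T2_s + T2_p)`: the reciprocal of the within-species
#' variance plus the total between-species variance, normalized to sum to
#' one (the circle sizes of a forest plot).
#' @param object a `rangeshift_meta` fit.
#' @param normalize divide by the total weight (default `TRUE`).
#' @param ... unused.
#' @export
weights.rangeshift_meta <- function(object, normalize = TRUE, ...) {
  w <- effective_weights(object$vi, object$t2s, object$t2p)
  if (!normalize) return(w$raw)
  stats::setNames(w$normalized, object$species)
}

#' Simulate effect sizes from a fitted meta-analysis
#'
#' Draws new effect-size vectors from the fitted marginal distribution
#' `N(X beta, T2_s I + T2_p R + diag(V))`.
#' @param object a `rangeshift_meta` fit.
#' @param nsim number of simulated vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.rangeshift_meta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- marginal_covariance(object$vi, object$t2s, object$t2p, object$R)
  ch <- chol(Sigma)
  mu <- drop(object$X %*% object$beta)
  out <- as.data.frame(
    mu + t(ch) %*% matrix(stats::rnorm(object$n * nsim), object$n))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$species
  out
}

#' Forest plot of species effect sizes
#'
#' Base-graphics forest plot: one confidence interval per species with the
#' point size proportional to its meta-analytic weight and the pooled mean
#' as a dashed vertical line.
#' @param x a `rangeshift_meta` fit of an intercept-only model.
#' @param alpha confidence level complement for the per-species intervals.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rangeshift_meta <- function(x, alpha = 0.05, ...) {
  z <- stats::qnorm(1 - alpha / 2)
  ord <- order(x$yi)
  d <- x$yi[ord]
  half <- z * sqrt(x$vi[ord])
  w <- weights(x)[ord]
  n <- length(d)
  graphics::plot(d, seq_len(n), xlim = range(d - half, d + half),
                 pch = 16, cex = 0.5 + 2 * w / max(w),
                 xlab = "Range shift (%)", ylab = "Species (ordered)", ...)
  graphics::segments(d - half, seq_len(n), d + half, seq_len(n),
                     col = "grey60")
  graphics::abline(v = 0)
  if ("(Intercept)" %in% names(x$beta))
    graphics::abline(v = x$beta[["(Intercept)"]], lty = 2)
  invisible(x)
}
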