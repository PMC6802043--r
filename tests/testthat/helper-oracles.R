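# Independent oracles used across the suite. These deliberately share no
# code with the package: the restricted likelihood is written out with
# dense solve()/determinant(), the Brownian VCV is recomputed by walking
# the edge matrix, and optima are located by grid search with repeated
# zooming.

# Restricted log-likelihood of y ~ N(X b, t2s I + t2p R + diag(V)),
# evaluated directly from the definition.
oracle_reml_ll <- function(t2s, t2p, y, X, V, R = NULL) {
  n <- length(y)
  p <- ncol(X)
  Sigma <- t2s * diag(n) + diag(V, n)
  if (!is.null(R)) Sigma <- Sigma + t2p * R
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  b <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% b
  -0.5 * ((n - p) * log(2 * pi) +
            determinant(Sigma)$modulus +
            determinant(XtSiX)$modulus +
            t(r) %*% Si %*% r)[1]
}

# GLS coefficients at given variance components.
oracle_gls_beta <- function(t2s, t2p, y, X, V, R = NULL) {
  n <- length(y)
  Sigma <- t2s * diag(n) + diag(V, n)
  if (!is.null(R)) Sigma <- Sigma + t2p * R
  Si <- solve(Sigma)
  drop(solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y))
}

# 2-D grid search of the restricted likelihood over (t2s, t2p), with
# repeated zooming around the best grid point down to a fine resolution.
oracle_grid_reml <- function(y, X, V, R, lo = 1e-4, hi = 1e5,
                             n_grid = 41, zooms = 12) {
  gs <- exp(seq(log(lo), log(hi), length.out = n_grid))
  gp <- gs
  best <- c(NA, NA)
  for (z in seq_len(zooms)) {
    ll <- outer(gs, gp, Vectorize(function(a, b)
      oracle_reml_ll(a, b, y, X, V, R)))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(gs[idx[1]], gp[idx[2]])
    span_s <- diff(range(log(gs))) / 4
    span_p <- diff(range(log(gp))) / 4
    gs <- exp(seq(log(best[1]) - span_s, log(best[1]) + span_s,
                  length.out = n_grid))
    gp <- exp(seq(log(best[2]) - span_p, log(best[2]) + span_p,
                  length.out = n_grid))
  }
  list(t2s = best[1], t2p = best[2],
       beta = oracle_gls_beta(best[1], best[2], y, X, V, R))
}

# Brownian VCV by brute force: root-to-tip paths from the edge matrix,
# C[i, j] = length of the shared part of the two root paths.
oracle_brownian_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    node <- tip
    out <- integer(0)
    while (node != root) {
      out <- c(out, node)   # edge identified by its child node
      node <- parent_of[node]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(len_of[shared])
    }
  }
  C
}

# Two-pass mean/variance, written out longhand.
oracle_mean_var <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, var = sum((x - m)^2) / (n - 1))
}
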