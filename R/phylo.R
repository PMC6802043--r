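#' Brownian-motion phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j — the expected covariance of a trait
#' evolving by Brownian motion; the diagonal holds each tip's root-to-tip
#' distance. Computed with [ape::vcv()] and re-ordered to the requested
#' canonical species order.
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @param species optional species order (defaults to the tree's tip
#'   order); every entry must be a tip of the tree.
#' @return symmetric positive semi-definite matrix with species dimnames.
#' @export
brownian_vcv <- function(tree, species = NULL) {
  validate_tree(tree)
  C <- ape::vcv(tree)
  if (is.null(species)) species <- tree$tip.label
  missing_sp <- setdiff(species, rownames(C))
  if (length(missing_sp))
    stop("species not in tree: ", paste(missing_sp, collapse = ", "))
  C[species, species, drop = FALSE]
}

#' Convert a phylogenetic covariance matrix to a correlation matrix
#'
#' `R[i, j] = C[i, j] / sqrt(C[i, i] C[j, j])`. The correlation form is
#' scale-free — rescaling every branch length leaves it unchanged — so the
#' phylogenetic variance component `T2_p` carries the variance scale. For
#' an ultrametric tree this is simply `C / depth`.
#'
#' @param C covariance matrix from [brownian_vcv()]; the diagonal must be
#'   strictly positive (a tip at zero distance from the root has no
#'   defined correlation).
#' @param jitter_tol eigenvalues in `(-jitter_tol, 0)` are repaired by
#'   adding `1e-10` to the diagonal; anything more negative is an error.
#' @return correlation matrix with unit diagonal.
#' @export
vcv_to_correlation <- function(C, jitter_tol = 1e-8) {
  C <- as.matrix(C)
  d <- diag(C)
  if (any(d <= 0))
    stop("zero root-to-tip distance for: ",
         paste(rownames(C)[d <= 0], collapse = ", "))
  s <- 1 / sqrt(d)
  R <- C * tcrossprod(s)
  diag(R) <- 1
  lam_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < -jitter_tol)
    stop("correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", signif(lam_min, 3), "); corrupt tree?")
  if (lam_min < 0) diag(R) <- diag(R) + 1e-10
  R
}

#' Phylogenetic correlation matrix in canonical order
#'
#' Convenience composition of [brownian_vcv()] and [vcv_to_correlation()].
#' @inheritParams brownian_vcv
#' @return correlation matrix indexed by `species`.
#' @export
phylo_correlation <- function(tree, species = NULL) {
  vcv_to_correlation(brownian_vcv(tree, species))
}
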