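#' Trait meta-regression of species range shifts
#'
#' Merges per-species effect sizes with a trait table and fits a
#' phylogenetic multilevel meta-regression with [rangeshift_meta()].
#' Continuous moderators enter uncentered; the IUCN category is a single
#' ordinal 0-4 numeric (one coefficient per unit of category); migration
#' is deviation-coded (+1 absence, -1 presence), so its coefficient is the
#' deviation of migration absence from the level midpoint.
#'
#' @param effects data frame from [species_effects()], restricted to one
#'   AOGCM.
#' @param traits validated trait table (see [read_traits()]).
#' @param R optional phylogenetic correlation matrix (dimnames = species).
#' @param moderators character vector among `"body_size"`,
#'   `"altitude_midpoint"`, `"iucn_ordinal"`, `"clutch_size"`,
#'   `"migration"`; the default uses all five.
#' @param ... passed on to [rangeshift_meta()] (e.g. `test`, `restarts`).
#' @return a `rangeshift_meta` fit.
#' @export
meta_regression <- function(effects, traits, R = NULL,
                            moderators = c("body_size", "altitude_midpoint",
                                           "iucn_ordinal", "clutch_size",
                                           "migration"),
                            ...) {
  stopifnot(length(unique(effects$aogcm)) <= 1)
  bad <- setdiff(moderators, c("body_size", "altitude_midpoint",
                               "iucn_ordinal", "clutch_size", "migration"))
  if (length(bad)) stop("unknown moderator(s): ", paste(bad, collapse = ", "))
  dat <- merge(effects, traits, by = "species", sort = FALSE)
  if (!nrow(dat)) stop("effects and traits share no species")
  if (nrow(dat) < nrow(effects))
    message(nrow(effects) - nrow(dat), " species without traits dropped")
  if (!is.null(R)) {
    keep <- dat$species %in% rownames(R)
    if (!all(keep)) {
      message(sum(!keep), " species absent from the tree dropped")
      dat <- dat[keep, , drop = FALSE]
    }
    ## canonical (tree) order
    dat <- dat[order(match(dat$species, rownames(R))), , drop = FALSE]
  }
  if ("migration" %in% moderators)
    dat$migration <- factor(dat$migration, levels = c("absence", "presence"))
  fml <- stats::reformulate(moderators, response = "D")
  fit <- rangeshift_meta(fml, data = dat, vi = V, R = R, ...)
  names(fit$beta) <- sub("^migration1$", "migration_absence",
                         names(fit$beta))
  dimnames(fit$vb) <- list(names(fit$beta), names(fit$beta))
  fit
}
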