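## Readers, writers and shared validation. All tables are plain CSV with a
## header; column names are configurable so existing exports can be read
## without renaming.

.default_proj_cols <- c(species = "species", aogcm = "aogcm", enm = "enm",
                        baseline = "baseline", future = "future")

#' Read a projection table
#'
#' Long-format table with one row per (species, AOGCM, ENM): the baseline
#' and future potential range sizes as counts of occupied grid cells.
#'
#' @param path CSV file path.
#' @param cols named character vector mapping the canonical names
#'   `species`, `aogcm`, `enm`, `baseline`, `future` to the column names
#'   used in the file.
#' @return data frame with canonical column names, validated: unique
#'   (species, aogcm, enm) triples and non-negative integer cell counts.
#' @export
read_projections <- function(path, cols = .default_proj_cols) {
  cols <- c(cols, .default_proj_cols[setdiff(names(.default_proj_cols),
                                             names(cols))])
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(cols[names(.default_proj_cols)]), names(df))
  if (length(missing_cols))
    stop("projection file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(species = as.character(df[[cols[["species"]]]]),
                    aogcm = as.character(df[[cols[["aogcm"]]]]),
                    enm = as.character(df[[cols[["enm"]]]]),
                    baseline = df[[cols[["baseline"]]]],
                    future = df[[cols[["future"]]]],
                    stringsAsFactors = FALSE)
  validate_projections(out)
}

#' Validate a projection table
#' @param proj data frame with canonical projection columns.
#' @return the validated data frame (invisibly the same object).
#' @export
validate_projections <- function(proj) {
  for (col in c("baseline", "future")) {
    v <- proj[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                   as.numeric(v) < 0 | as.numeric(v) %% 1 != 0)
    if (length(bad))
      stop("non-integer or negative '", col, "' cell count at row ",
           bad[1], " (value '", v[bad[1]], "')")
    proj[[col]] <- as.integer(v)
  }
  key <- paste(proj$species, proj$aogcm, proj$enm, sep = " / ")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicated (species, aogcm, enm) triple: ", dup[1])
  proj
}

#' Read a species trait table
#'
#' One row per species with the moderators used in trait meta-regressions:
#' body size, altitude midpoint (mean of the range's maximum and minimum
#' altitude, m), IUCN extinction-risk category coded ordinally
#' (LC = 0, NT = 1, VU = 2, EN = 3, CR = 4), clutch size, and migratory
#' behavior (`"presence"`/`"absence"`). Species with any missing trait are
#' dropped (complete-case analysis) with a message; they are listed in the
#' `"dropped"` attribute.
#'
#' @param path CSV file path with columns `species`, `body_size`,
#'   `altitude_midpoint`, `iucn_ordinal`, `clutch_size`, `migration`.
#' @return validated data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "body_size", "altitude_midpoint", "iucn_ordinal",
            "clutch_size", "migration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trait file lacks column(s): ", paste(missing_cols, collapse = ", "))
  validate_traits(df[need])
}

#' Validate a trait table
#' @param traits data frame with canonical trait columns.
#' @return the validated data frame, complete cases only, with a
#'   `"dropped"` attribute listing removed species.
#' @export
validate_traits <- function(traits) {
  if (anyDuplicated(traits$species))
    stop("duplicated species in trait table: ",
         traits$species[duplicated(traits$species)][1])
  keep <- stats::complete.cases(traits)
  dropped <- traits$species[!keep]
  if (length(dropped))
    message(length(dropped), " species dropped for missing trait values")
  traits <- traits[keep, , drop = FALSE]
  if (!nrow(traits)) stop("no species with complete traits")
  if (any(traits$body_size <= 0)) stop("body_size must be positive")
  if (any(traits$clutch_size <= 0)) stop("clutch_size must be positive")
  if (!all(traits$iucn_ordinal %in% 0:4))
    stop("iucn_ordinal must be an integer in 0..4 (LC=0 ... CR=4)")
  if (!all(traits$migration %in% c("presence", "absence")))
    stop("migration must be 'presence' or 'absence'")
  rownames(traits) <- NULL
  attr(traits, "dropped") <- dropped
  traits
}

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] with the validation the
#' meta-analysis needs: a single rooted tree, unique tip labels,
#' non-negative branch lengths.
#'
#' @param path Newick file, single tree.
#' @return an [ape::phylo] object.
#' @export
read_tree_file <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("could not parse Newick file '", path, "': ", conditionMessage(e)))
  if (is.null(tree)) stop("could not parse Newick file '", path, "'")
  if (inherits(tree, "multiPhylo"))
    stop("file contains more than one tree; a single tree is required")
  validate_tree(tree)
}

#' Validate a phylogeny
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly validated.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n == 0) stop("tree has no tips")
  if (n == 1) warning("tree has a single tip; phylogenetic structure is trivial")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  tree
}

#' Align species across projections, traits and tree
#'
#' Returns the species present in all three sources, ordered by the tree's
#' tip order. That order is the canonical index of every downstream matrix
#' and vector, so the phylogenetic correlation and the effect-size vector
#' can never be silently misaligned. Species dropped from any source are
#' reported in the `"dropped"` attribute with the reason.
#'
#' @param proj projection table (or any data frame with a `species` column).
#' @param traits trait table, or `NULL` to skip.
#' @param tree [ape::phylo] tree, or `NULL` to skip (then the projection
#'   order is canonical).
#' @return character vector of species ids in canonical order.
#' @export
align_species <- function(proj, traits = NULL, tree = NULL) {
  sets <- list(projections = unique(as.character(proj$species)))
  if (!is.null(traits)) sets$traits <- unique(as.character(traits$species))
  if (!is.null(tree)) sets$tree <- tree$tip.label
  common <- Reduce(intersect, sets)
  if (!length(common))
    stop("no species shared by all inputs (",
         paste(names(sets), vapply(sets, length, 1L), collapse = ", "), ")")
  order_ref <- if (!is.null(tree)) tree$tip.label else sets$projections
  out <- order_ref[order_ref %in% common]
  dropped <- do.call(rbind, lapply(names(sets), function(nm) {
    d <- setdiff(sets[[nm]], common)
    if (!length(d)) return(NULL)
    data.frame(species = d, absent_from = paste(
      setdiff(names(sets), nm)[!vapply(
        setdiff(names(sets), nm), function(o) all(d %in% sets[[o]]), TRUE)],
      collapse = ","), source = nm)
  }))
  if (!is.null(dropped) && nrow(dropped))
    message(nrow(dropped), " species not shared by all inputs were dropped")
  attr(out, "dropped") <- dropped
  out
}

#' Export the forest-plot table
#'
#' The data behind a forest plot: one row per species with the effect
#' size, its normal CI, the normalized meta-analytic weight and the
#' CI-based classification.
#'
#' @param effects data frame from [species_effects()] (single AOGCM).
#' @param fit the corresponding intercept-only [rangeshift_meta()] fit.
#' @param path optional CSV destination; omit to just return the table.
#' @param alpha per-species CI level complement.
#' @return the forest table data frame (invisibly if written).
#' @export
forest_table <- function(effects, fit, path = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "rangeshift_meta"),
            nrow(effects) == fit$n)
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(effects$V)
  out <- data.frame(species = effects$species,
                    D = effects$D,
                    ci_low = effects$D - half,
                    ci_high = effects$D + half,
                    weight = unname(weights(fit)),
                    class = effects$class)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
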