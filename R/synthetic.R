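## Synthetic-data generator with known ground truth: Yule trees, effect
## sizes with species-level and phylogenetically structured heterogeneity,
## heteroscedastic ENM-replicate noise, and trait moderators with known
## coefficients. Defaults reproduce the study conditions the statistical
## machinery is meant for: 500 species, 8 ENM replicates, a weighted mean
## shift of -25%, between-species variance 500 and phylogenetic variance
## 50 (the magnitudes of the bird analysis), with log-normal
## within-species noise (median SD 15%, geometric SD 2) so that
## meta-analytic weights vary realistically across species.

#' Simulation configuration
#'
#' @param n_species number of species (tips), at least 4.
#' @param k_enms ENM replicates per species (default 8).
#' @param mu_true true weighted mean range shift, percent (default -25).
#' @param t2s_true true species-level heterogeneity variance (default 500).
#' @param t2p_true true phylogenetic heterogeneity variance (default 50).
#' @param sigma_median,sigma_gsd median and geometric SD of the log-normal
#'   distribution of the within-species replicate SD `sigma_i` (defaults
#'   15 and 2).
#' @param beta_true optional named vector of true moderator coefficients
#'   (names among the trait moderators, `"migration"` coded +1 for
#'   absence); omitted moderators have zero effect.
#' @param birth_rate Yule birth rate for the simulated tree (default 1).
#' @param seed integer seed; mandatory, so every dataset is reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_species = 500, k_enms = 8, mu_true = -25,
                       t2s_true = 500, t2p_true = 50,
                       sigma_median = 15, sigma_gsd = 2,
                       beta_true = NULL, birth_rate = 1, seed) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  stopifnot(n_species >= 4, k_enms >= 2, t2s_true >= 0, t2p_true >= 0,
            sigma_median >= 0, sigma_gsd >= 1, birth_rate > 0)
  if (!is.null(beta_true)) {
    ok <- c("body_size", "altitude_midpoint", "iucn_ordinal",
            "clutch_size", "migration")
    stopifnot(!is.null(names(beta_true)), all(names(beta_true) %in% ok))
  }
  structure(list(n_species = as.integer(n_species),
                 k_enms = as.integer(k_enms), mu_true = mu_true,
                 t2s_true = t2s_true, t2p_true = t2p_true,
                 sigma_median = sigma_median, sigma_gsd = sigma_gsd,
                 beta_true = beta_true, birth_rate = birth_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Crown-conditioned pure-birth process: two lineages at the crown, each
#' lineage splitting at rate `birth`; after the n-th lineage appears the
#' tree is extended to the present by one further exponential waiting time
#' at the full rate, so terminal branches are positive. The tree is
#' ultrametric with expected height `(H_n - 1) / birth`, where `H_n` is
#' the n-th harmonic number.
#'
#' @param n number of tips (>= 2).
#' @param birth per-lineage speciation rate (default 1).
#' @param seed optional integer seed.
#' @param labels optional tip labels (default `t1..tn`, in order of
#'   appearance).
#' @return an ultrametric [ape::phylo] tree.
#' @export
simulate_tree <- function(n, birth = 1, seed = NULL, labels = NULL) {
  stopifnot(n >= 2, birth > 0)
  if (!is.null(seed)) set.seed(seed)
  ## active lineages: parent (temp internal id), start time
  n_internal <- n - 1
  parent <- c(1, 1)          # root is internal temp id 1
  start <- c(0, 0)
  t <- 0
  next_internal <- 1
  edges <- matrix(0, 0, 2)
  lengths <- numeric(0)
  tips_parent <- NULL
  if (n > 2) {
    for (k in 2:(n - 1)) {
      t <- t + stats::rexp(1, birth * k)
      i <- sample.int(k, 1)
      next_internal <- next_internal + 1
      edges <- rbind(edges, c(parent[i], next_internal))
      lengths <- c(lengths, t - start[i])
      parent <- c(parent[-i], next_internal, next_internal)
      start <- c(start[-i], t, t)
    }
  }
  t_end <- t + stats::rexp(1, birth * n)
  tip_edges <- cbind(parent, seq_len(n) * -1L)  # negative marks tips
  tip_lengths <- t_end - start
  edge <- rbind(edges, tip_edges)
  edge_len <- c(lengths, tip_lengths)
  ## renumber: tips 1..n, internal temp j -> n + j
  edge[edge > 0] <- edge[edge > 0] + n
  edge[edge < 0] <- -edge[edge < 0]
  storage.mode(edge) <- "integer"
  dimnames(edge) <- NULL
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n)
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = labels, Nnode = n_internal),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate species effects with known ground truth
#'
#' Draws `u_p ~ MVN(0, t2p R)` on the tree's Brownian correlation `R`,
#' `u_s ~ N(0, t2s)`, sets the true per-species shift
#' `D_true = mu + X beta + u_s + u_p`, and adds per-ENM replicate noise
#' `D_ij = D_true_i + e_ij`, `e_ij ~ N(0, sigma_i^2)` with `sigma_i`
#' log-normal. Traits are drawn from pragmatic distributions (body size
#' log-normal, altitude uniform on 0-3000 m, IUCN categorical weighted
#' toward least concern, clutch size 1 + Poisson, migration Bernoulli) —
#' they exist to exercise the meta-regression, not to mimic real birds.
#'
#' @param cfg a [sim_config()].
#' @param tree optional tree to reuse (default: a fresh Yule tree).
#' @param traits optional trait table to reuse.
#' @return object of class `rangeshift_sim`: list with `tree`, `traits`,
#'   `dij` (species-by-ENM matrix), `R`, `sigma`, `truth` (true values of
#'   every component) and `config`.
#' @export
simulate_effects <- function(cfg, tree = NULL, traits = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_species
  if (is.null(tree)) tree <- simulate_tree(n, cfg$birth_rate)
  stopifnot(length(tree$tip.label) == n)
  species <- tree$tip.label
  R <- phylo_correlation(tree)

  if (is.null(traits)) {
    traits <- data.frame(
      species = species,
      body_size = stats::rlnorm(n, log(50), 1),
      altitude_midpoint = stats::runif(n, 0, 3000),
      iucn_ordinal = sample(0:4, n, replace = TRUE,
                            prob = c(0.70, 0.15, 0.08, 0.05, 0.02)),
      clutch_size = 1 + stats::rpois(n, 2),
      migration = ifelse(stats::rbinom(n, 1, 0.25) == 1,
                         "absence", "presence"),
      stringsAsFactors = FALSE)
  }
  stopifnot(identical(traits$species, species))

  fixed <- rep(cfg$mu_true, n)
  if (!is.null(cfg$beta_true)) {
    for (nm in names(cfg$beta_true)) {
      xcol <- if (nm == "migration")
        ifelse(traits$migration == "absence", 1, -1)
      else traits[[nm]]
      fixed <- fixed + cfg$beta_true[[nm]] * xcol
    }
  }

  u_p <- if (cfg$t2p_true > 0)
    drop(t(chol(R)) %*% stats::rnorm(n)) * sqrt(cfg$t2p_true)
  else numeric(n)
  u_s <- stats::rnorm(n, 0, sqrt(cfg$t2s_true))
  d_true <- fixed + u_s + u_p

  sigma <- if (cfg$sigma_median > 0)
    stats::rlnorm(n, log(cfg$sigma_median), log(cfg$sigma_gsd))
  else rep(0, n)
  dij <- matrix(d_true, n, cfg$k_enms) +
    matrix(stats::rnorm(n * cfg$k_enms), n) * sigma
  dimnames(dij) <- list(species, paste0("enm", seq_len(cfg$k_enms)))

  structure(list(tree = tree, traits = traits, dij = dij, R = R,
                 sigma = sigma,
                 truth = list(mu = cfg$mu_true, beta = cfg$beta_true,
                              t2s = cfg$t2s_true, t2p = cfg$t2p_true,
                              d_true = stats::setNames(d_true, species),
                              u_s = u_s, u_p = u_p),
                 config = cfg),
            class = "rangeshift_sim")
}

#' @export
print.rangeshift_sim <- function(x, ...) {
  cat("rangeshift_sim:", nrow(x$dij), "species x", ncol(x$dij),
      "ENM replicates; true mu =", x$truth$mu,
      ", T2_s =", x$truth$t2s, ", T2_p =", x$truth$t2p, "\n")
  invisible(x)
}

#' Effect-size table of a simulated dataset
#'
#' Collapses the simulated `D_ij` matrix to the per-species effect table
#' the meta-analysis consumes (same shape as [species_effects()]).
#'
#' @param sim a [simulate_effects()] result.
#' @param variance_of_mean report `V_i / k` (the squared standard error of
#'   the ensemble mean) instead of the raw cross-ENM variance. Default
#'   `TRUE`: for simulated replicate noise this is the sampling variance
#'   of `D_i`, which is what valid CI coverage requires.
#' @param alpha classification CI level complement.
#' @param aogcm label for the `aogcm` column (default `"SIM"`).
#' @return data frame with `species`, `aogcm`, `D`, `V`, `k`, `class`.
#' @export
sim_effects_table <- function(sim, variance_of_mean = TRUE, alpha = 0.05,
                              aogcm = "SIM") {
  stopifnot(inherits(sim, "rangeshift_sim"))
  k <- ncol(sim$dij)
  D <- rowMeans(sim$dij)
  V <- apply(sim$dij, 1, stats::var)
  if (variance_of_mean) V <- V / k
  data.frame(species = rownames(sim$dij), aogcm = aogcm, D = D, V = V,
             k = k, degenerate = V == 0,
             class = classify_effect(D, V, alpha = alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates data under a known configuration, fits the
#' phylogenetic multilevel model to each replicate, and reports coverage
#' of the 95% CI for the mean shift together with bias and RMSE of every
#' variance component.
#'
#' @param cfg a [sim_config()]; its seed is ignored in favor of
#'   per-replicate seeds derived from `seed`.
#' @param n_replicates number of replicates (>= 10).
#' @param seed master seed for the experiment.
#' @param variance_of_mean passed to [sim_effects_table()].
#' @param restarts optimizer restarts per fit (default 1: the restricted
#'   likelihood surface is well behaved at these sizes, and one start from
#'   the moment estimate is reliable).
#' @param level CI level for coverage (default 0.95).
#' @return object of class `recovery_report`: per-replicate estimates and
#'   a summary with coverage, bias and RMSE.
#' @export
recovery_experiment <- function(cfg, n_replicates = 100, seed,
                                variance_of_mean = TRUE, restarts = 1,
                                level = 0.95) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 10)
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_replicates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    sim <- simulate_effects(cfg_r)
    eff <- sim_effects_table(sim, variance_of_mean = variance_of_mean)
    fit <- rangeshift_meta(D ~ 1, data = eff, vi = V, R = sim$R,
                           level = level, restarts = restarts)
    rows[[r]] <- data.frame(
      replicate = r, seed = rep_seeds[r],
      M = unname(fit$beta[1]), se_M = unname(fit$se[1]),
      ci_lb = unname(fit$ci_lb[1]), ci_ub = unname(fit$ci_ub[1]),
      covered = cfg$mu_true >= fit$ci_lb[1] & cfg$mu_true <= fit$ci_ub[1],
      t2s = fit$t2s, t2p = fit$t2p, converged = fit$converged)
  }
  reps <- do.call(rbind, rows)
  summary <- list(
    n_replicates = n_replicates,
    coverage_M = mean(reps$covered),
    bias_M = mean(reps$M) - cfg$mu_true,
    rmse_M = sqrt(mean((reps$M - cfg$mu_true)^2)),
    mean_t2s = mean(reps$t2s), median_t2s = stats::median(reps$t2s),
    bias_t2s = mean(reps$t2s) - cfg$t2s_true,
    mean_t2p = mean(reps$t2p), median_t2p = stats::median(reps$t2p),
    bias_t2p = mean(reps$t2p) - cfg$t2p_true)
  structure(list(replicates = reps, summary = summary, config = cfg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat("Recovery over", s$n_replicates, "replicates (n =",
      x$config$n_species, "species, k =", x$config$k_enms, "ENMs)\n")
  cat(sprintf("  CI coverage of mu: %.2f\n", s$coverage_M))
  cat(sprintf("  M:    bias %+.2f, RMSE %.2f (truth %.1f)\n",
              s$bias_M, s$rmse_M, x$config$mu_true))
  cat(sprintf("  T2_s: median %.1f (truth %.1f)\n",
              s$median_t2s, x$config$t2s_true))
  cat(sprintf("  T2_p: median %.1f (truth %.1f)\n",
              s$median_t2p, x$config$t2p_true))
  invisible(x)
}
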