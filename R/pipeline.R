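## Config-driven orchestration: simulate or read inputs, compute effects,
## fit the null model and the trait meta-regression per AOGCM, and write
## the result tables (heterogeneity table, coefficient table, class
## counts, unweighted-mean sensitivity, forest table) plus a run log.

#' Run the full range-shift meta-analysis pipeline
#'
#' The configuration is a named list (or a YAML file path, read with the
#' `yaml` package) with either file inputs
#' (`projections`, `traits`, `tree` paths) or a `simulate` block with
#' [sim_config()] fields. Optional settings: `aogcms` (restrict/label),
#' `alpha` (default 0.05), `min_enms` (default 2), `variance_of_mean`
#' (default `FALSE` for projection input, `TRUE` for simulated replicate
#' noise), `phylo_matrix` (`"correlation"`, `"covariance"` or `"none"`),
#' `moderators` (default: all five traits; empty vector skips the
#' meta-regression), `seed`, `out_dir`.
#'
#' Every AOGCM is analyzed independently: per-species effects, the
#' intercept-only multilevel fit (weighted mean shift M plus
#' heterogeneity decomposition), the trait meta-regression with
#' pseudo-R2, CI-based class counts, and the unweighted-mean sensitivity
#' contrast.
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory; overrides `config$out_dir`; `NULL`
#'   (and no `config$out_dir`) skips writing and just returns results.
#' @return invisible list with one element per AOGCM (`effects`, `fit`,
#'   `metareg`, `pseudo_r2`, `classes`, `unweighted`, `forest`) plus
#'   `log` lines.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  min_k <- config$min_enms %||% 2
  phylo_matrix <- config$phylo_matrix %||% "correlation"
  moderators <- config$moderators %||%
    c("body_size", "altitude_midpoint", "iucn_ordinal", "clutch_size",
      "migration")
  seed <- config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir
  log_lines <- c(
    paste0("rangemeta ", as.character(utils::packageVersion("rangemeta"))),
    paste0("run started ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed ", seed),
    paste0("config md5 ", .config_hash(config)))

  if (!is.null(config$simulate)) {
    vom <- config$variance_of_mean %||% TRUE
    sim_args <- config$simulate
    aogcms <- config$aogcms %||% "SIM"
    set.seed(seed)
    sub_seeds <- sample.int(2^31 - 2, length(aogcms))
    tree <- NULL; traits <- NULL
    effects_all <- NULL
    for (i in seq_along(aogcms)) {
      cfg <- do.call(sim_config, c(sim_args, list(seed = sub_seeds[i])))
      sim <- simulate_effects(cfg, tree = tree, traits = traits)
      tree <- sim$tree; traits <- sim$traits
      eff <- sim_effects_table(sim, variance_of_mean = vom, alpha = alpha,
                               aogcm = aogcms[i])
      effects_all <- rbind(effects_all, eff)
    }
    log_lines <- c(log_lines, paste0("simulated ", length(tree$tip.label),
                                     " species x ", ncol(sim$dij),
                                     " ENMs for ", length(aogcms), " AOGCM(s)"))
  } else {
    vom <- config$variance_of_mean %||% FALSE
    proj <- read_projections(config$projections)
    traits <- if (!is.null(config$traits)) read_traits(config$traits)
    tree <- if (!is.null(config$tree)) read_tree_file(config$tree)
    sp_order <- align_species(proj, traits, tree)
    proj <- proj[proj$species %in% sp_order, , drop = FALSE]
    if (!is.null(traits))
      traits <- traits[traits$species %in% sp_order, , drop = FALSE]
    if (!is.null(tree))
      tree <- ape::keep.tip(tree, sp_order)
    aogcms <- config$aogcms %||% unique(proj$aogcm)
    effects_all <- species_effects(proj, aogcm = aogcms, min_k = min_k,
                                   variance_of_mean = vom, alpha = alpha)
    log_lines <- c(log_lines, paste0(length(sp_order),
                                     " species aligned across inputs"))
  }

  results <- list()
  for (ao in aogcms) {
    eff <- effects_all[effects_all$aogcm == ao, , drop = FALSE]
    R <- NULL
    if (!is.null(tree) && phylo_matrix != "none") {
      sp <- tree$tip.label[tree$tip.label %in% eff$species]
      eff <- eff[match(sp, eff$species), , drop = FALSE]
      C <- brownian_vcv(tree, sp)
      R <- if (phylo_matrix == "correlation") vcv_to_correlation(C) else C
    }
    fit <- rangeshift_meta(D ~ 1, data = eff, vi = V, R = R, level = 0.95)
    mr <- NULL; pr2 <- NA_real_
    if (length(moderators) && !is.null(traits)) {
      mr <- meta_regression(eff, traits, R = R, moderators = moderators)
      pr2 <- pseudo_r2(fit, mr)
    }
    results[[ao]] <- list(
      effects = eff, fit = fit, metareg = mr, pseudo_r2 = pr2,
      classes = summarize_classes(eff),
      unweighted = unweighted_mean(eff$D),
      forest = forest_table(eff, fit, alpha = alpha))
    log_lines <- c(log_lines, sprintf(
      "%s: n=%d, M=%.2f, T2s=%.1f, T2p=%.1f, I2t=%.1f, pseudoR2=%.3f",
      ao, fit$n, fit$beta[1], fit$t2s, fit$t2p, fit$I2$I2_t, pr2))
  }
  results$log <- log_lines

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    het <- do.call(rbind, lapply(aogcms, function(ao) {
      f <- results[[ao]]$fit
      data.frame(aogcm = ao, n = f$n, M = f$beta[1],
                 M_ci_lb = f$ci_lb[1], M_ci_ub = f$ci_ub[1],
                 Q = f$QE, df = f$QE_df, Q_p = f$QE_p,
                 Ts2 = f$t2s, Ts2_se = f$se_t2s,
                 Tp2 = f$t2p, Tp2_se = f$se_t2p,
                 It2 = f$I2$I2_t, Is2 = f$I2$I2_s, Ip2 = f$I2$I2_p,
                 pseudo_R2 = results[[ao]]$pseudo_r2)
    }))
    utils::write.csv(het, file.path(out_dir, "heterogeneity.csv"),
                     row.names = FALSE)
    for (ao in aogcms) {
      res <- results[[ao]]
      utils::write.csv(res$effects,
                       file.path(out_dir, paste0("effects_", ao, ".csv")),
                       row.names = FALSE)
      utils::write.csv(res$forest,
                       file.path(out_dir, paste0("forest_", ao, ".csv")),
                       row.names = FALSE)
      utils::write.csv(res$classes,
                       file.path(out_dir, paste0("classes_", ao, ".csv")),
                       row.names = FALSE)
      if (!is.null(res$metareg)) {
        tab <- coef_table(res$metareg)
        tab <- cbind(variable = rownames(tab), tab)
        utils::write.csv(tab,
                         file.path(out_dir, paste0("metareg_", ao, ".csv")),
                         row.names = FALSE)
      }
      uw <- res$unweighted
      utils::write.csv(data.frame(aogcm = ao, mean = uw$mean,
                                  ci_lb = uw$ci_lb, ci_ub = uw$ci_ub),
                       file.path(out_dir, paste0("unweighted_", ao, ".csv")),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}
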