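#' Run the full MET stability pipeline
#'
#' Orchestrates validation, joint ANOVA + AMMI + Gollob tests + ASV, BLUP
#' variance components + WAASB/WAASBY with weight scenarios, quadrants and
#' rank-profile clusters, RMSPD cross-validation, the GGE patterns, and the
#' scalar indices, and joins everything into one wide per-genotype
#' stability table.
#'
#' @param trial a balanced [met_trial()]; exactly one of `trial`/`sim`.
#' @param sim a [sim_config()] (or argument list for one) to simulate the
#'   input trial instead of supplying one.
#' @param theta_y yield weight (percent) of the WAASBY index; stability
#'   weight is `100 - theta_y`.
#' @param waasb_axes axes retained in WAASB/WAAS (`"all"` or integer).
#' @param scenario_step weight increment of the scenario grid, percent.
#' @param k_clusters number of rank-profile clusters.
#' @param alpha Annicchiarico confidence coefficient.
#' @param n_resamples cross-validation resamples (ignored if `do_cv =
#'   FALSE`).
#' @param svp_www,svp_patterns singular value partitioning used for the
#'   which-won-where fit (default symmetric, 3) and for the
#'   mean-vs-stability / ranking / discriminativeness patterns (default
#'   environment-focused, 2).
#' @param do_cv,do_gge,do_indices module toggles.
#' @param seed optional seed (simulation and cross-validation).
#' @param out_dir optional directory: per-module CSV artifacts plus a run
#'   log are written there (only after the whole pipeline has succeeded).
#' @return A `met_stability` object: `stability` (wide per-genotype table),
#'   the per-module fits (`anova`, `ammi`, `blup`, `waasb`, `scenarios`,
#'   `quadrants`, `clusters`, `cv`, `gge_www`, `gge`, `indices`), and
#'   `log` (resolved parameters).
#' @export
run_met_stability <- function(trial = NULL, sim = NULL, theta_y = 65,
                              waasb_axes = "all", scenario_step = 5,
                              k_clusters = 4, alpha = 0.25,
                              n_resamples = 1000, svp_www = 3,
                              svp_patterns = 2, do_cv = TRUE, do_gge = TRUE,
                              do_indices = TRUE, seed = NULL,
                              out_dir = NULL) {
  if (is.null(trial) == is.null(sim))
    met_stop("provide exactly one of 'trial' or 'sim'", "config")
  sim_truth <- NULL
  if (!is.null(sim)) {
    if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
    if (is.null(sim$seed)) sim$seed <- seed
    s <- simulate_met(sim)
    trial <- s$trial
    sim_truth <- s$truth
  }
  stopifnot(inherits(trial, "met_trial"))

  cm <- cell_means(trial)
  an <- joint_anova(trial)
  am <- fit_ammi(cm)
  an_pc <- gollob_test(am, an)
  asv_tab <- asv(am)
  bl <- fit_blup(trial)
  wb <- waasb(bl, waasb_axes)
  wa <- waas(am, waasb_axes)
  gm <- cm$gen_means
  wy <- waasby(wb, gm, theta_y)
  scen <- weight_scenarios(wb, gm, scenario_step)
  quad <- classify_quadrants(wb, gm)
  clus <- cluster_rank_profiles(scen, k_clusters)

  cv <- NULL
  if (do_cv)
    cv <- rmspd_cv(trial, n_resamples = n_resamples, seed = seed)

  gge_www_fit <- gge_fit <- www <- mvs <- rig <- dvr <- NULL
  if (do_gge) {
    gge_www_fit <- fit_gge(cm, svp = svp_www)
    gge_fit <- fit_gge(cm, svp = svp_patterns)
    www <- which_won_where(gge_www_fit)
    mvs <- mean_vs_stability(gge_fit)
    rig <- rank_vs_ideal_genotype(gge_fit)
    dvr <- discrim_vs_repr(gge_fit)
  }

  anni <- envidx <- hsi_res <- NULL
  if (do_indices) {
    anni <- annicchiarico(cm, alpha)
    envidx <- environmental_index(cm)
    if (!is.null(attr(trial, "env_meta")))
      hsi_res <- tryCatch(hsi_pairs(trial), metstab_error = function(e) NULL)
  }

  stab <- data.frame(genotype = rownames(cm$matrix),
                     mean = unname(gm),
                     ASV = asv_tab$ASV, rank_ASV = asv_tab$rank,
                     WAAS = wa$table$WAAS,
                     WAASB = wb$table$WAASB, rank_WAASB = wb$table$rank,
                     WAASBY = wy$WAASBY, rank_WAASBY = wy$rank,
                     quadrant = quad$quadrant,
                     cluster = unname(clus),
                     stringsAsFactors = FALSE)
  if (!is.null(anni)) {
    stab$omega <- anni$omega
    stab$rank_omega <- anni$rank
  }
  if (!is.null(rig)) {
    stab$gge_ideal_distance <- rig$distance
    stab$rank_gge <- rig$rank
  }
  if (!is.null(hsi_res)) {
    stab$mean_HSI <- unname(hsi_res$mean_hsi)
    stab$HSI_class <- unname(hsi_res$mean_class)
  }

  log <- list(package_version = as.character(utils::packageVersion("metstab")),
              seed = seed, theta_y = theta_y, theta_s = 100 - theta_y,
              waasb_axes = waasb_axes, scenario_step = scenario_step,
              k_clusters = k_clusters, alpha = alpha,
              n_resamples = if (do_cv) n_resamples else NA,
              svp_www = svp_www, svp_patterns = svp_patterns,
              do_cv = do_cv, do_gge = do_gge, do_indices = do_indices,
              simulated = !is.null(sim_truth),
              g = nrow(cm$matrix), e = ncol(cm$matrix), r = cm$r)

  res <- structure(list(stability = stab, anova = an_pc, ammi = am,
                        blup = bl, waasb = wb, waas = wa, waasby = wy,
                        scenarios = scen, quadrants = quad, clusters = clus,
                        cv = cv, gge_www = www, gge = gge_fit,
                        mean_vs_stability = mvs, gge_ranking = rig,
                        discrim_vs_repr = dvr,
                        indices = list(annicchiarico = anni,
                                       environmental_index = envidx,
                                       hsi = hsi_res),
                        sim_truth = sim_truth, log = log),
                   class = "met_stability")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  w(res$stability, "stability.csv")
  w(as.data.frame(res$anova), "anova.csv")
  w(res$waasby, "waasby.csv")
  w(data.frame(genotype = rownames(res$scenarios), res$scenarios,
               check.names = FALSE), "scenarios.csv")
  w(res$quadrants, "quadrants.csv")
  if (!is.null(res$cv)) w(summarize_cv(res$cv), "rmspd_summary.csv")
  if (!is.null(res$gge_www)) w(res$gge_www$environments, "gge_sectors.csv")
  if (!is.null(res$indices$annicchiarico))
    w(res$indices$annicchiarico, "recommendation.csv")
  if (!is.null(res$indices$environmental_index))
    w(res$indices$environmental_index, "env_index.csv")
  log_lines <- vapply(names(res$log),
                      function(n) paste0(n, ": ",
                                         paste(res$log[[n]], collapse = " ")),
                      "")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.met_stability <- function(x, ...) {
  cat("MET stability pipeline:", nrow(x$stability), "genotypes,",
      x$log$e, "environments,", x$log$r, "replicates\n")
  cat("  WAASBY weights:", x$log$theta_y, "/", x$log$theta_s, "\n")
  top <- x$stability[order(x$stability$rank_WAASBY), ]
  cat("  top genotypes by WAASBY:\n")
  print(utils::head(top[, c("genotype", "mean", "WAASB", "WAASBY",
                            "quadrant")], 5), row.names = FALSE)
  invisible(x)
}
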