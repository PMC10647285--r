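#' Configuration for the synthetic MET generator
#'
#' Defaults emulate a balanced 42-genotype x 12-environment x 3-replicate
#' chickpea-scale yield trial: grand mean 174.5 g/plot, residual CV about
#' 37.5%, and variance components back-derived (by expected mean squares)
#' from the mean squares of a joint ANOVA with sum-of-squares shares of
#' roughly 18.5% environment, 4% replication-within-environment, 16.2%
#' genotype and 21.3% genotype-by-environment interaction. The interaction
#' is low-rank (default rank 4, axis energies decaying 0.4/0.3/0.2/0.1) so
#' genuinely stable genotypes (small factor loadings) exist by construction.
#'
#' @param g,e,r genotype, environment, replicate counts (all >= 2).
#' @param mu grand mean, g/plot.
#' @param sigma2_env,sigma2_rep,sigma2_gen,sigma2_gei,sigma2_err variance
#'   components (g^2/plot^2) of the environment, replicate-within-environment,
#'   genotype, interaction and residual terms.
#' @param gei_rank rank of the interaction factor model,
#'   `0 <= gei_rank <= min(g - 1, e - 1)`.
#' @param gei_shares optional vector of length `gei_rank` giving the share of
#'   interaction energy per axis (positive, summed to 1); default linear decay
#'   `(gei_rank:1)/sum(gei_rank:1)`.
#' @param seed optional integer seed; same seed gives bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(g = 42, e = 12, r = 3, mu = 174.5151,
                       sigma2_env = 2700.671, sigma2_rep = 798.6184,
                       sigma2_gen = 2173.523, sigma2_gei = 2120.221,
                       sigma2_err = 4273.178,
                       gei_rank = 4, gei_shares = NULL, seed = NULL) {
  if (g < 2 || e < 2 || r < 2)
    met_stop("g, e and r must all be >= 2", "config")
  s2 <- c(sigma2_env, sigma2_rep, sigma2_gen, sigma2_gei, sigma2_err)
  if (any(s2 < 0))
    met_stop("variance components must be non-negative", "config")
  if (gei_rank < 0 || gei_rank > min(g - 1, e - 1))
    met_stop("gei_rank must be between 0 and min(g - 1, e - 1)", "config")
  if (is.null(gei_shares) && gei_rank > 0)
    gei_shares <- (gei_rank:1) / sum(gei_rank:1)
  if (gei_rank > 0) {
    if (length(gei_shares) != gei_rank || any(gei_shares <= 0))
      met_stop("gei_shares must be positive and of length gei_rank", "config")
    gei_shares <- gei_shares / sum(gei_shares)
  }
  structure(list(g = g, e = e, r = r, mu = mu,
                 sigma2_env = sigma2_env, sigma2_rep = sigma2_rep,
                 sigma2_gen = sigma2_gen, sigma2_gei = sigma2_gei,
                 sigma2_err = sigma2_err,
                 gei_rank = gei_rank, gei_shares = gei_shares, seed = seed),
            class = "sim_config")
}

# Draw a zero-mean vector standardized so sum(x^2) equals `ss` exactly.
# (Drawn Gaussian, centered, then norm-scaled: the realized component
# variance equals its target exactly, which keeps EMS recovery unbiased.)
draw_effect <- function(n, ss) {
  if (ss == 0) return(numeric(n))
  x <- stats::rnorm(n)
  x <- x - mean(x)
  while (sum(x^2) == 0) { x <- stats::rnorm(n); x <- x - mean(x) }
  x * sqrt(ss / sum(x^2))
}

# Low-rank GEI draw. Returns the double-centered interaction matrix plus the
# row/column margins of the raw draw (standardized separately), which the
# generator folds into the main effects so that classical expected-mean-square
# algebra holds exactly for the simulated data.
draw_gei <- function(g, e, rank, shares, sigma2_gei) {
  zero <- list(ge = matrix(0, g, e), row_margin = numeric(g),
               col_margin = numeric(e))
  if (rank == 0 || sigma2_gei == 0) return(zero)
  tmat <- matrix(0, g, e)
  for (k in seq_len(rank)) {
    a <- stats::rnorm(g); a <- a / sqrt(sum(a^2))
    b <- stats::rnorm(e); b <- b / sqrt(sum(b^2))
    tmat <- tmat + sqrt(shares[k]) * tcrossprod(a, b)
  }
  rm_ <- rowMeans(tmat); cm_ <- colMeans(tmat); gm <- mean(tmat)
  z <- tmat - outer(rm_, rep(1, e)) - outer(rep(1, g), cm_) + gm
  scale_to <- function(x, ss) {
    s <- sum(x^2)
    if (s == 0) x else x * sqrt(ss / s)
  }
  list(ge = scale_to(z, (g - 1) * (e - 1) * sigma2_gei),
       row_margin = scale_to(rm_ - gm, (g - 1) * sigma2_gei / e),
       col_margin = scale_to(cm_ - gm, (e - 1) * sigma2_gei / g))
}

# Shared core: build expectations + noise for one trial.
simulate_core <- function(cfg) {
  g <- cfg$g; e <- cfg$e; r <- cfg$r
  gen_eff0 <- draw_effect(g, (g - 1) * cfg$sigma2_gen)
  env_eff0 <- draw_effect(e, (e - 1) * cfg$sigma2_env)
  gei <- draw_gei(g, e, cfg$gei_rank, cfg$gei_shares, cfg$sigma2_gei)
  gen_eff <- gen_eff0 + gei$row_margin
  env_eff <- env_eff0 + gei$col_margin
  expectation <- cfg$mu + outer(gen_eff, env_eff, "+") + gei$ge
  list(gen_eff = gen_eff, env_eff = env_eff, ge = gei$ge,
       expectation = expectation)
}

# Observations around a g x e expectation matrix; returns long data.frame.
observe_trial <- function(expectation, r, sigma2_rep, sigma2_err,
                          env_labels, gen_labels) {
  g <- nrow(expectation); e <- ncol(expectation)
  rep_eff <- matrix(stats::rnorm(e * r, sd = sqrt(sigma2_rep)), e, r)
  recs <- expand.grid(gi = seq_len(g), ei = seq_len(e), ri = seq_len(r))
  y <- expectation[cbind(recs$gi, recs$ei)] +
    rep_eff[cbind(recs$ei, recs$ri)] +
    stats::rnorm(nrow(recs), sd = sqrt(sigma2_err))
  n_trunc <- sum(y < 0)
  if (n_trunc > 0) {
    warning(n_trunc, " simulated yield(s) below 0 truncated to 0")
    y <- pmax(y, 0)
  }
  list(data = data.frame(ENV = env_labels[recs$ei], GEN = gen_labels[recs$gi],
                         REP = paste0("R", recs$ri), Y = y,
                         stringsAsFactors = FALSE),
       rep_eff = rep_eff, n_truncated = n_trunc)
}

#' Simulate a balanced multi-environment trial with known truth
#'
#' Generates `y_ger = mu + E_e + R_r(e) + G_g + GE_ge + err` with each term
#' drawn from a zero-mean Gaussian and standardized to its configured
#' variance (exactly, for the genotype, environment and interaction terms).
#' The interaction is a low-rank factor matrix, double-centered; its raw
#' margins are folded into the main effects. Negative simulated yields are
#' truncated to 0 with a warning (yields are physical quantities).
#'
#' @param config a [sim_config()], or arguments passed to it via `...`.
#' @param ... passed to [sim_config()] when `config` is missing.
#' @return List of class `met_sim` with elements `trial` (a [met_trial()])
#'   and `truth` (true effects, GEI matrix, per-genotype root-mean-square
#'   GEI stability score, replicate effects, truncation count, config).
#' @examples
#' sim <- simulate_met(sim_config(g = 6, e = 4, r = 2, seed = 1))
#' sim$trial
#' @export
simulate_met <- function(config = sim_config(...), ...) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- config$g; e <- config$e; r <- config$r
  gen_labels <- sprintf("G%02d", seq_len(g))
  env_labels <- sprintf("E%02d", seq_len(e))
  core <- simulate_core(config)
  obs <- observe_trial(core$expectation, r, config$sigma2_rep,
                       config$sigma2_err, env_labels, gen_labels)
  trial <- met_trial(obs$data)
  truth <- list(gen_eff = stats::setNames(core$gen_eff, gen_labels),
                env_eff = stats::setNames(core$env_eff, env_labels),
                ge = matrix(core$ge, g, e,
                            dimnames = list(gen_labels, env_labels)),
                gei_rms = stats::setNames(sqrt(rowMeans(core$ge^2)),
                                          gen_labels),
                rep_eff = obs$rep_eff,
                expectation = matrix(core$expectation, g, e,
                                     dimnames = list(gen_labels, env_labels)),
                n_truncated = obs$n_truncated,
                config = config)
  structure(list(trial = trial, truth = truth), class = "met_sim")
}

#' Simulate paired normal/late-sown trials with genotype-specific heat effects
#'
#' The late-sown cell expectation is `(1 - d_g)` times the normal-sown cell
#' expectation, so each genotype has a known true heat-induced reduction and
#' hence a known true heat susceptibility index.
#'
#' @param config a [sim_config()] for the normal-sown trial.
#' @param d per-genotype reduction fractions, `0 <= d_g < 1`, length `g`.
#' @return List of class `met_sim_pair`: `normal` and `late` [met_trial()]s,
#'   `combined` (both regimes in one trial with pairing metadata usable by
#'   [hsi_pairs()]), and `truth` including `d` and `true_hsi`.
#' @export
simulate_heat_pairs <- function(config, d) {
  stopifnot(inherits(config, "sim_config"))
  if (length(d) != config$g)
    met_stop("d must have one reduction fraction per genotype", "config")
  if (any(d < 0) || any(d >= 1))
    met_stop("reduction fractions d must satisfy 0 <= d < 1", "value")
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- config$g; e <- config$e; r <- config$r
  gen_labels <- sprintf("G%02d", seq_len(g))
  env_n <- sprintf("E%02dN", seq_len(e))
  env_l <- sprintf("E%02dL", seq_len(e))
  core <- simulate_core(config)
  exp_late <- (1 - d) * core$expectation
  obs_n <- observe_trial(core$expectation, r, config$sigma2_rep,
                         config$sigma2_err, env_n, gen_labels)
  obs_l <- observe_trial(exp_late, r, config$sigma2_rep,
                         config$sigma2_err, env_l, gen_labels)
  normal <- met_trial(obs_n$data)
  late <- met_trial(obs_l$data)
  meta <- data.frame(env = c(env_n, env_l),
                     location = rep(sprintf("L%02d", seq_len(e)), 2),
                     year = 1L,
                     sowing = rep(c("normal", "late"), each = e),
                     stringsAsFactors = FALSE)
  combined <- met_trial(rbind(obs_n$data, obs_l$data), env_meta = meta)
  yn <- rowMeans(core$expectation)
  yh <- (1 - d) * yn
  si <- 1 - mean(yh) / mean(yn)
  true_hsi <- if (si > 0) (1 - yh / yn) / si else rep(NA_real_, g)
  truth <- list(gen_eff = stats::setNames(core$gen_eff, gen_labels),
                env_eff = core$env_eff, ge = core$ge,
                d = stats::setNames(d, gen_labels),
                true_hsi = stats::setNames(true_hsi, gen_labels),
                stress_intensity = si,
                n_truncated = obs_n$n_truncated + obs_l$n_truncated,
                config = config)
  structure(list(normal = normal, late = late, combined = combined,
                 truth = truth),
            class = "met_sim_pair")
}

#' @export
print.met_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat("Simulated MET:", cfg$g, "genotypes x", cfg$e, "environments x",
      cfg$r, "replicates\n")
  cat("  mu =", cfg$mu, " GEI rank =", cfg$gei_rank, "\n")
  if (x$truth$n_truncated > 0)
    cat("  truncated yields:", x$truth$n_truncated, "\n")
  invisible(x)
}
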