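#' Variance components of a balanced MET
#'
#' Genotype and genotype-by-environment effects random; environments and
#' replicates-within-environments fixed. Two routes:
#' `"EMS"` solves the expected-mean-square equations of the balanced joint
#' ANOVA in closed form (`sigma2_err = MS_res`,
#' `sigma2_gei = (MS_GE - MS_res)/r`, `sigma2_gen = (MS_G - MS_GE)/(r e)`,
#' `sigma2_rep = (MS_REP - MS_res)/g`); `"REML"` maximizes the restricted
#' likelihood via [lme4::lmer()] and agrees with EMS on balanced data.
#' Negative EMS estimates are truncated to zero and flagged.
#'
#' @param trial a balanced [met_trial()] with `r >= 2`.
#' @param method `"EMS"` (default) or `"REML"`.
#' @return A `variance_components` list: `sigma2_gen`, `sigma2_gei`,
#'   `sigma2_err`, `sigma2_rep` (NA under REML, where replicates are fixed),
#'   `sigma2_env` (EMS only), `method`, `truncated` (named logical).
#' @export
variance_components <- function(trial, method = c("EMS", "REML")) {
  stopifnot(inherits(trial, "met_trial"))
  method <- match.arg(method)
  an <- joint_anova(trial)
  g <- attr(an, "g"); e <- attr(an, "e"); r <- attr(an, "r")
  ms <- stats::setNames(an$MS, an$Source)
  if (method == "EMS") {
    raw <- c(gen = (ms[["GEN"]] - ms[["GEN:ENV"]]) / (r * e),
             gei = (ms[["GEN:ENV"]] - ms[["Residuals"]]) / r,
             err = ms[["Residuals"]],
             rep = (ms[["REP(ENV)"]] - ms[["Residuals"]]) / g,
             env = (ms[["ENV"]] - ms[["REP(ENV)"]]) / (g * r))
    truncated <- raw < 0
    est <- pmax(raw, 0)
    return(structure(list(sigma2_gen = est[["gen"]],
                          sigma2_gei = est[["gei"]],
                          sigma2_err = est[["err"]],
                          sigma2_rep = est[["rep"]],
                          sigma2_env = est[["env"]],
                          method = "EMS", truncated = truncated,
                          g = g, e = e, r = r),
                     class = "variance_components"))
  }
  d <- data.frame(y = trial$yield,
                  gen = factor(trial$gen),
                  env = factor(trial$env),
                  er = factor(paste(trial$env, trial$rep, sep = ":")))
  fit <- tryCatch(
    lme4::lmer(y ~ 0 + er + (1 | gen) + (1 | gen:env), data = d,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           optCtrl = list(rhoend = 1e-12),
                                           calc.derivs = FALSE)),
    error = function(cond)
      met_stop(paste0("REML fit failed: ", conditionMessage(cond)),
               "convergence"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(nm) vc$vcov[match(nm, vc$grp)]
  structure(list(sigma2_gen = pick("gen"),
                 sigma2_gei = pick("gen:env"),
                 sigma2_err = pick("Residual"),
                 sigma2_rep = NA_real_,
                 sigma2_env = NA_real_,
                 method = "REML",
                 truncated = c(gen = FALSE, gei = FALSE, err = FALSE),
                 g = g, e = e, r = r),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("MET variance components (", x$method, ")\n", sep = "")
  v <- c(genotype = x$sigma2_gen, GEI = x$sigma2_gei,
         residual = x$sigma2_err, "rep(env)" = x$sigma2_rep,
         environment = x$sigma2_env)
  print(round(v, 3))
  if (any(x$truncated, na.rm = TRUE))
    cat("  (negative estimate(s) truncated to 0:",
        paste(names(x$truncated)[x$truncated], collapse = ", "), ")\n")
  invisible(x)
}

#' Broad-sense heritability
#'
#' `H^2 = VG / VP`. On the plot basis
#' `VP = VG + sigma2_gei + sigma2_err`; on the entry-mean basis (default,
#' the repeatability of a genotype mean over `e` environments and `r`
#' replicates) `VP = VG + sigma2_gei / e + sigma2_err / (r e)`.
#'
#' @param vc a [variance_components()] object.
#' @param e,r environment and replicate counts (default: taken from `vc`).
#' @param basis `"entry_mean"` (default) or `"plot"`.
#' @return `H^2` in `[0, 1]`, or `NA` when all components are zero.
#' @export
heritability <- function(vc, e = vc$e, r = vc$r,
                         basis = c("entry_mean", "plot")) {
  stopifnot(inherits(vc, "variance_components"))
  basis <- match.arg(basis)
  vg <- vc$sigma2_gen
  vp <- if (basis == "plot") vg + vc$sigma2_gei + vc$sigma2_err
        else vg + vc$sigma2_gei / e + vc$sigma2_err / (r * e)
  if (vp == 0) return(NA_real_)
  vg / vp
}

#' BLUPs for genotype and interaction effects in a balanced MET
#'
#' Closed-form shrinkage for balanced data with environments and replicates
#' fixed: `BLUP_g = c_g (ybar_g. - ybar..)` with
#' `c_g = VG / (VG + sigma2_gei/e + sigma2_err/(r e))`, and
#' `BLUP_ge = c_ge Z_ge` with `c_ge = sigma2_gei / (sigma2_gei +
#' sigma2_err/r)`, `Z` the doubly-centered cell means. Predicted cell value
#' `mu + beta_e + BLUP_g + BLUP_ge`.
#'
#' @param trial a balanced [met_trial()].
#' @param vc optional precomputed [variance_components()]; default EMS.
#' @return A `met_blup` object: `mu`, fixed environment effects `beta`,
#'   `blup_g`, `blup_ge` (g x e), predicted genotype means `pred_gen`
#'   (`mu + BLUP_g`), shrinkage factors `c_g` and `c_ge`, entry-mean
#'   heritability `H2`, and the variance components.
#' @export
fit_blup <- function(trial, vc = NULL) {
  cm <- cell_means(trial)
  if (is.null(vc)) vc <- variance_components(trial, "EMS")
  stopifnot(inherits(vc, "variance_components"))
  g <- nrow(cm$matrix); e <- ncol(cm$matrix); r <- cm$r
  vg <- vc$sigma2_gen; vge <- vc$sigma2_gei; ve <- vc$sigma2_err
  den_g <- vg + vge / e + ve / (r * e)
  c_g <- if (den_g > 0) vg / den_g else 0
  den_ge <- vge + ve / r
  c_ge <- if (den_ge > 0) vge / den_ge else 0
  z <- double_center(cm$matrix)
  blup_g <- c_g * (cm$gen_means - cm$grand_mean)
  blup_ge <- c_ge * z
  structure(list(mu = cm$grand_mean,
                 beta = cm$env_means - cm$grand_mean,
                 blup_g = blup_g,
                 blup_ge = blup_ge,
                 pred_gen = cm$grand_mean + blup_g,
                 c_g = c_g, c_ge = c_ge,
                 H2 = heritability(vc, e, r, "entry_mean"),
                 vc = vc,
                 genotypes = rownames(cm$matrix),
                 environments = colnames(cm$matrix),
                 cell_means = cm),
            class = "met_blup")
}

#' @export
print.met_blup <- function(x, ...) {
  cat("MET BLUP fit:", length(x$blup_g), "genotypes x", length(x$beta),
      "environments\n")
  cat("  shrinkage: genotype", round(x$c_g, 4), " GEI", round(x$c_ge, 4),
      "\n")
  cat("  entry-mean H2:", round(x$H2, 4), "\n")
  invisible(x)
}

#' @export
coef.met_blup <- function(object, ...) {
  list(mu = object$mu, beta = object$beta, blup_g = object$blup_g,
       blup_ge = object$blup_ge)
}

#' @export
predict.met_blup <- function(object, ...) {
  pred <- object$mu + outer(object$blup_g, object$beta, "+") +
    object$blup_ge
  dimnames(pred) <- list(object$genotypes, object$environments)
  pred
}

# Shared WAASB/WAAS machinery: weighted average of absolute scores across
# the first p axes, weights = per-axis explained proportions.
waas_core <- function(scores, ep, genotypes, n_axes) {
  kmax <- ncol(scores)
  p_all <- seq_len(kmax)
  by_p <- vapply(p_all, function(p) {
    w <- ep[seq_len(p)]
    if (sum(w) == 0) return(numeric(nrow(scores)))
    as.numeric(abs(scores[, seq_len(p), drop = FALSE]) %*% w / sum(w))
  }, numeric(nrow(scores)))
  by_p <- matrix(by_p, nrow = nrow(scores),
                 dimnames = list(genotypes, paste0("p", p_all)))
  p_use <- if (identical(n_axes, "all")) kmax else n_axes
  if (p_use < 1 || p_use > kmax)
    met_stop("n_axes must be between 1 and min(g - 1, e - 1)", "value")
  val <- by_p[, p_use]
  rank_by_p <- apply(by_p, 2, rank_asc)
  list(table = data.frame(genotype = genotypes, value = val,
                          rank = rank_asc(val), stringsAsFactors = FALSE),
       by_p = by_p, rank_by_p = rank_by_p, n_axes = p_use)
}

#' WAASB: weighted average of absolute BLUP interaction scores
#'
#' SVD of the BLUP interaction matrix; genotype scores on axis `k` are
#' `sqrt(lambda_k) * gamma_gk` (the same symmetric scaling used elsewhere),
#' and `WAASB_g = sum_{k<=p} |s_gk| EP_k / sum_{k<=p} EP_k` with `EP_k` the
#' axis explained proportion. Smaller is more stable. The ranking for every
#' number of retained axes `p = 1..min(g-1, e-1)` is returned, since the
#' ranking can be unstable for small `p`.
#'
#' @param fit a [fit_blup()] object.
#' @param n_axes number of retained axes, or `"all"` (default).
#' @return A `waasb` list: `table` (genotype, WAASB, rank at `n_axes`),
#'   `by_p` and `rank_by_p` matrices (genotype x p), `EP`, `n_axes`.
#' @export
waasb <- function(fit, n_axes = "all") {
  stopifnot(inherits(fit, "met_blup"))
  sv <- fix_svd_signs(svd(fit$blup_ge))
  kmax <- min(length(fit$blup_g) - 1, length(fit$beta) - 1)
  lambda <- sv$d[seq_len(kmax)]
  scores <- sweep(sv$u[, seq_len(kmax), drop = FALSE], 2, sqrt(lambda), "*")
  tot <- sum(lambda^2)
  ep <- if (tot > 0) lambda^2 / tot else rep(0, kmax)
  out <- waas_core(scores, ep, fit$genotypes, n_axes)
  names(out$table)[2] <- "WAASB"
  structure(c(out, list(EP = ep, index = "WAASB")), class = "waasb")
}

#' WAAS: the same weighted average applied to fixed-effect AMMI scores
#'
#' @param fit an [fit_ammi()] object.
#' @param n_axes number of retained axes, or `"all"` (default).
#' @return A `waasb`-style list with column `WAAS`.
#' @export
waas <- function(fit, n_axes = "all") {
  stopifnot(inherits(fit, "ammi"))
  scores <- sweep(fit$gamma, 2, sqrt(fit$lambda), "*")
  out <- waas_core(scores, fit$EP, fit$genotypes, n_axes)
  names(out$table)[2] <- "WAAS"
  structure(c(out, list(EP = fit$EP, index = "WAAS")), class = "waasb")
}

#' @export
print.waasb <- function(x, ...) {
  cat(x$index, "stability index (", x$n_axes, "axes )\n")
  print(utils::head(x$table[order(x$table$rank), ], 10), row.names = FALSE)
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' WAASBY simultaneous selection index
#'
#' Yield is rescaled so the highest-yielding genotype scores 100
#' (`rY`); the stability index is rescaled so the most stable (smallest
#' WAASB) genotype scores 100 (`rW`). `WAASBY = (theta_y * rY + theta_s *
#' rW) / 100`; rank 1 is the largest.
#'
#' @param waasb_values per-genotype WAASB (or WAAS) values, named or in the
#'   same order as `means`; a `waasb` object is also accepted.
#' @param means per-genotype mean yields (g/plot).
#' @param theta_y,theta_s percentage weights for yield and stability; must
#'   sum to 100 (defaults 65/35).
#' @return data.frame with `genotype`, `rY`, `rW`, `WAASBY`, `rank`.
#' @export
waasby <- function(waasb_values, means, theta_y = 65, theta_s = 100 - theta_y) {
  if (inherits(waasb_values, "waasb")) {
    gens <- waasb_values$table$genotype
    waasb_values <- waasb_values$table[[2]]
  } else {
    gens <- names(waasb_values)
    if (is.null(gens)) gens <- names(means)
    if (is.null(gens)) gens <- paste0("G", seq_along(waasb_values))
  }
  if (length(waasb_values) != length(means))
    met_stop("waasb_values and means must have the same length", "value")
  if (theta_y + theta_s != 100)
    met_stop("theta_y + theta_s must equal 100", "value")
  ry <- rescale100(means, larger_is_better = TRUE)
  rw <- rescale100(waasb_values, larger_is_better = FALSE)
  val <- (theta_y * ry + theta_s * rw) / 100
  data.frame(genotype = gens, rY = ry, rW = rw, WAASBY = val,
             rank = rank_desc(val), stringsAsFactors = FALSE)
}

#' Genotype rankings across yield/stability weight scenarios
#'
#' Recomputes the WAASBY ranking for yield weights `theta_y = 0, step, ...,
#' 100`: the first column ranks on stability alone, the last on yield
#' alone.
#'
#' @param waasb_values per-genotype WAASB values (or a `waasb` object).
#' @param means per-genotype mean yields.
#' @param step weight increment in percent; must divide 100 (default 5).
#' @return genotype x scenario integer matrix of ranks, columns named by
#'   `theta_y`.
#' @export
weight_scenarios <- function(waasb_values, means, step = 5) {
  if (100 %% step != 0)
    met_stop("step must divide 100", "value")
  thetas <- seq(0, 100, by = step)
  ranks <- vapply(thetas,
                  function(ty) waasby(waasb_values, means, ty)$rank,
                  numeric(if (inherits(waasb_values, "waasb"))
                    nrow(waasb_values$table) else length(waasb_values)))
  gens <- if (inherits(waasb_values, "waasb")) waasb_values$table$genotype
          else names(means)
  if (is.null(gens)) gens <- paste0("G", seq_len(nrow(ranks)))
  matrix(as.integer(ranks), nrow = nrow(ranks),
         dimnames = list(gens, thetas))
}

#' Yield/stability quadrant classification
#'
#' Genotypes split at the mean yield (x) and mean WAASB (y):
#' quadrant IV = above-mean yield and below-mean WAASB (productive and
#' stable), II = above-mean yield, above-mean WAASB (productive, unstable),
#' I = below-mean yield, above-mean WAASB, III = below-mean yield,
#' below-mean WAASB (stable, unproductive). Boundary convention: yield
#' exactly at the mean counts as "above" (`>=`); WAASB exactly at the mean
#' counts as "unstable" (`>=`).
#'
#' @param waasb_values per-genotype WAASB values (or a `waasb` object).
#' @param means per-genotype mean yields.
#' @return data.frame `genotype`, `mean`, `WAASB`, `quadrant`; attribute
#'   `thresholds` holds the two split points.
#' @export
classify_quadrants <- function(waasb_values, means) {
  if (inherits(waasb_values, "waasb")) {
    gens <- waasb_values$table$genotype
    waasb_values <- waasb_values$table[[2]]
  } else {
    gens <- names(means)
    if (is.null(gens)) gens <- paste0("G", seq_along(means))
  }
  my <- mean(means); mw <- mean(waasb_values)
  hi_y <- means >= my; hi_w <- waasb_values >= mw
  quad <- ifelse(hi_y & !hi_w, "IV",
          ifelse(hi_y & hi_w, "II",
          ifelse(!hi_y & hi_w, "I", "III")))
  structure(data.frame(genotype = gens, mean = means, WAASB = waasb_values,
                       quadrant = quad, stringsAsFactors = FALSE),
            thresholds = c(mean = my, WAASB = mw))
}

#' Cluster genotypes by their scenario-rank profiles
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances between the
#' rows of the scenario-rank matrix), cut at `k` groups. Deterministic.
#'
#' @param rank_matrix genotype x scenario rank matrix from
#'   [weight_scenarios()].
#' @param k number of clusters (default 4).
#' @return Named integer vector of cluster ids.
#' @export
cluster_rank_profiles <- function(rank_matrix, k = 4) {
  if (k < 1) met_stop("k must be at least 1", "value")
  if (k > nrow(rank_matrix))
    met_stop("k cannot exceed the number of genotypes", "value")
  hc <- stats::hclust(stats::dist(rank_matrix), method = "ward.D2")
  stats::cutree(hc, k = k)
}
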