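#' Joint ANOVA for a balanced multi-environment trial
#'
#' Standard balanced two-way-with-replicates decomposition: environments
#' tested against replicates-within-environments, genotypes and the
#' genotype-by-environment interaction tested against the pooled residual.
#' Degrees of freedom: ENV `e - 1`, REP(ENV) `e(r - 1)`, GEN `g - 1`,
#' GEN:ENV `(g - 1)(e - 1)`, Residuals `e(g - 1)(r - 1)`.
#'
#' @param trial a balanced [met_trial()] with `r >= 2` replicates.
#' @return A `met_anova`: data.frame with columns `Source`, `Df`, `SS`, `MS`,
#'   `F`, `p`, plus attributes `grand_mean`, `cv` (percent,
#'   `100 * sqrt(MS_resid) / grand mean`), `g`, `e`, `r`, `ms_res`, `ss_ge`.
#' @export
joint_anova <- function(trial) {
  stopifnot(inherits(trial, "met_trial"))
  cm <- cell_means(trial)            # errors if unbalanced
  g <- nrow(cm$matrix); e <- ncol(cm$matrix); r <- cm$r
  if (r < 2)
    met_stop("r = 1 leaves no residual stratum; need >= 2 replicates",
             "value")
  mu <- cm$grand_mean
  ss_env <- g * r * sum((cm$env_means - mu)^2)
  ss_gen <- e * r * sum((cm$gen_means - mu)^2)
  z <- double_center(cm$matrix)
  ss_ge <- r * sum(z^2)
  # replicate means within environment; rep labels must be consistent
  # within each environment (REP(ENV) stratum)
  er_n <- table(trial$env, trial$rep)
  if (any(er_n != 0 & er_n != g))
    met_stop("replicate labels are not consistent within environments",
             "balance")
  er_means <- tapply(trial$yield, list(trial$env, trial$rep), mean)
  env_of <- rownames(er_means)[row(er_means)]
  ss_rep <- g * sum((er_means - cm$env_means[env_of])^2, na.rm = TRUE)
  ss_tot <- sum((trial$yield - mu)^2)
  ss_res <- ss_tot - ss_env - ss_gen - ss_ge - ss_rep

  df <- c(e - 1, e * (r - 1), g - 1, (g - 1) * (e - 1), e * (g - 1) * (r - 1))
  ss <- c(ss_env, ss_rep, ss_gen, ss_ge, ss_res)
  ms <- ss / df
  denom <- c(ms[2], ms[5], ms[5], ms[5], NA)   # ENV vs REP(ENV), rest vs resid
  fval <- ms / denom
  fval[!is.finite(fval)] <- NA
  denom_df <- c(df[2], df[5], df[5], df[5], NA)
  p <- ifelse(is.na(fval), NA,
              stats::pf(fval, df, denom_df, lower.tail = FALSE))
  out <- data.frame(Source = c("ENV", "REP(ENV)", "GEN", "GEN:ENV",
                               "Residuals"),
                    Df = df, SS = ss, MS = ms, F = fval, p = p,
                    stringsAsFactors = FALSE)
  structure(out,
            grand_mean = mu, cv = 100 * sqrt(ms[5]) / mu,
            g = g, e = e, r = r, ms_res = ms[5], df_res = df[5],
            ss_ge = ss_ge,
            class = c("met_anova", "data.frame"))
}

#' @export
print.met_anova <- function(x, digits = 4, ...) {
  cat("Joint ANOVA (balanced MET)\n")
  d <- as.data.frame(x)
  d$SS <- signif(d$SS, 7); d$MS <- signif(d$MS, 7)
  d$F <- signif(d$F, digits)
  d$p <- format.pval(d$p, digits = 3)
  print(d, row.names = FALSE)
  cat("Overall mean:", format(attr(x, "grand_mean"), digits = 7),
      "  CV%:", format(attr(x, "cv"), digits = 6), "\n")
  invisible(x)
}

#' Fit the AMMI model to a balanced trial
#'
#' Additive main effects by least squares on the cell means, then an SVD of
#' the doubly-centered interaction residuals
#' `Z_ge = ybar_ge - ybar_g. - ybar_.e + ybar..`. The SVD sign ambiguity is
#' fixed by making, for each axis, the environment-score entry of largest
#' magnitude positive, so coordinates are reproducible.
#'
#' @param trial a balanced [met_trial()], or a [cell_means()] object.
#' @return An object of class `ammi`: grand mean `mu`, genotype effects
#'   `alpha`, environment effects `beta`, singular values `lambda`
#'   (descending), orthonormal score matrices `gamma` (g x K) and `delta`
#'   (e x K), per-axis explained proportions `EP`, `n_axes_max`, and the
#'   underlying `cell_means`.
#' @examples
#' sim <- simulate_met(sim_config(g = 8, e = 5, r = 2, seed = 4))
#' fit <- fit_ammi(sim$trial)
#' fit$EP
#' @export
fit_ammi <- function(trial) {
  cm <- if (inherits(trial, "cell_means")) trial else cell_means(trial)
  g <- nrow(cm$matrix); e <- ncol(cm$matrix)
  kmax <- min(g - 1, e - 1)
  z <- double_center(cm$matrix)
  sv <- fix_svd_signs(svd(z))
  lambda <- sv$d[seq_len(kmax)]
  tot <- sum(lambda^2)
  structure(list(mu = cm$grand_mean,
                 alpha = cm$gen_means - cm$grand_mean,
                 beta = cm$env_means - cm$grand_mean,
                 lambda = lambda,
                 gamma = sv$u[, seq_len(kmax), drop = FALSE],
                 delta = sv$v[, seq_len(kmax), drop = FALSE],
                 EP = if (tot > 0) lambda^2 / tot else rep(0, kmax),
                 n_axes_max = kmax,
                 genotypes = rownames(cm$matrix),
                 environments = colnames(cm$matrix),
                 cell_means = cm),
            class = "ammi")
}

#' @export
print.ammi <- function(x, ...) {
  cat("AMMI fit:", length(x$alpha), "genotypes x", length(x$beta),
      "environments,", x$n_axes_max, "multiplicative axes\n")
  cat("  grand mean:", format(x$mu, digits = 6), "g/plot\n")
  cat("  axis proportions (%):",
      paste(sprintf("%.1f", 100 * x$EP[seq_len(min(5, x$n_axes_max))]),
            collapse = ", "),
      if (x$n_axes_max > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
coef.ammi <- function(object, ...) {
  list(mu = object$mu, alpha = object$alpha, beta = object$beta,
       lambda = object$lambda)
}

#' Degrees of freedom of an interaction principal component axis
#'
#' Gollob's rule: axis `k` of a `g x e` interaction carries
#' `g + e - 1 - 2k` degrees of freedom.
#'
#' @param g,e genotype and environment counts.
#' @param k axis index, `1 <= k <= min(g - 1, e - 1)`.
#' @return Integer degrees of freedom.
#' @examples
#' ipca_df(42, 12, 1)  # 51
#' @export
ipca_df <- function(g, e, k) {
  if (any(k < 1) || any(k > min(g - 1, e - 1)))
    met_stop("axis index k must satisfy 1 <= k <= min(g - 1, e - 1)", "value")
  as.integer(g + e - 1 - 2 * k)
}

#' Per-axis Gollob F-tests appended to the joint ANOVA
#'
#' Partitions the GEN:ENV sum of squares into interaction principal
#' component axes: `SS_k = r * lambda_k^2` (replicate scale, commensurate
#' with the ANOVA table), `df_k = g + e - 1 - 2k`, F against the pooled
#' residual mean square. Also adds the percent of interaction SS per axis
#' and its accumulation.
#'
#' @param fit an [fit_ammi()] object.
#' @param anova a [joint_anova()] table from the same trial.
#' @return A `met_anova` with one `PCk` row per axis inserted before the
#'   residual row, plus `Proportion` and `Accumulated` columns.
#' @export
gollob_test <- function(fit, anova) {
  stopifnot(inherits(fit, "ammi"), inherits(anova, "met_anova"))
  g <- attr(anova, "g"); e <- attr(anova, "e"); r <- attr(anova, "r")
  if (g != length(fit$alpha) || e != length(fit$beta))
    met_stop("AMMI fit and ANOVA table have mismatched dimensions", "value")
  k <- seq_len(fit$n_axes_max)
  ss_k <- r * fit$lambda^2
  df_k <- ipca_df(g, e, k)
  ms_k <- ss_k / df_k
  ms_res <- attr(anova, "ms_res")
  f_k <- if (ms_res > 0) ms_k / ms_res else rep(NA_real_, length(k))
  p_k <- stats::pf(f_k, df_k, attr(anova, "df_res"), lower.tail = FALSE)
  tot <- sum(fit$lambda^2)
  prop <- if (tot > 0) 100 * fit$lambda^2 / tot else rep(0, length(k))
  pc <- data.frame(Source = paste0("PC", k), Df = df_k, SS = ss_k, MS = ms_k,
                   F = f_k, p = p_k, Proportion = prop,
                   Accumulated = cumsum(prop), stringsAsFactors = FALSE)
  base <- as.data.frame(anova)
  base$Proportion <- NA_real_; base$Accumulated <- NA_real_
  res_row <- base$Source == "Residuals"
  out <- rbind(base[!res_row, ], pc, base[res_row, ])
  rownames(out) <- NULL
  attrs <- attributes(anova)
  structure(out,
            grand_mean = attrs$grand_mean, cv = attrs$cv,
            g = g, e = e, r = r, ms_res = ms_res,
            df_res = attrs$df_res, ss_ge = attrs$ss_ge,
            class = c("met_anova", "data.frame"))
}

#' AMMI stability value
#'
#' Purchase-style ASV: with genotype scores on the symmetric scaling
#' `s_gk = sqrt(lambda_k) * gamma_gk`,
#' `ASV_g = sqrt((SS1/SS2 * s_g1)^2 + s_g2^2)`, where `SS1/SS2` is the ratio
#' of the first two axis sums of squares. Smaller is more stable; rank 1 is
#' the smallest, ties broken by genotype order.
#'
#' @param fit an [fit_ammi()] object with at least 2 axes.
#' @return data.frame with columns `genotype`, `ASV`, `rank`.
#' @export
asv <- function(fit) {
  stopifnot(inherits(fit, "ammi"))
  if (fit$n_axes_max < 2)
    met_stop("ASV needs at least two multiplicative axes", "value")
  if (fit$lambda[2] == 0)
    met_stop("second-axis SS is zero; ASV weight SS1/SS2 is undefined",
             "degenerate")
  w <- fit$lambda[1]^2 / fit$lambda[2]^2
  s1 <- sqrt(fit$lambda[1]) * fit$gamma[, 1]
  s2 <- sqrt(fit$lambda[2]) * fit$gamma[, 2]
  val <- sqrt((w * s1)^2 + s2^2)
  data.frame(genotype = fit$genotypes, ASV = val, rank = rank_asc(val),
             stringsAsFactors = FALSE)
}

#' Predictions from a truncated AMMI model
#'
#' `yhat_ge = mu + alpha_g + beta_e + sum_{k <= n_axes} lambda_k
#' gamma_gk delta_ek`. `n_axes = 0` is the purely additive AMMI0;
#' `n_axes = min(g - 1, e - 1)` is the full-rank AMMIF, which reproduces the
#' cell means exactly.
#'
#' @param object an [fit_ammi()] object.
#' @param n_axes number of multiplicative axes retained,
#'   `0 <= n_axes <= n_axes_max`.
#' @param ... unused.
#' @return A genotype x environment matrix of predicted cell means.
#' @export
predict.ammi <- function(object, n_axes = object$n_axes_max, ...) {
  if (length(n_axes) != 1 || n_axes < 0 || n_axes > object$n_axes_max)
    met_stop("n_axes must be between 0 and n_axes_max", "value")
  pred <- object$mu + outer(object$alpha, object$beta, "+")
  if (n_axes > 0) {
    k <- seq_len(n_axes)
    pred <- pred + object$gamma[, k, drop = FALSE] %*%
      (fit_diag(object$lambda[k]) %*% t(object$delta[, k, drop = FALSE]))
  }
  dimnames(pred) <- list(object$genotypes, object$environments)
  pred
}

# diag() that stays a matrix for length-1 input
fit_diag <- function(x) diag(x, nrow = length(x))

#' Biplot coordinates for AMMI1 and AMMI2 displays
#'
#' AMMI1: abscissa = main-effect mean (`mu + alpha_g` for genotypes,
#' `mu + beta_e` for environments), ordinate = first-axis score. AMMI2:
#' scores on a requested pair of axes. Scores use the symmetric scaling
#' `sqrt(lambda)` split between genotype and environment. For AMMI2 the
#' environment vector lengths and pairwise angles (degrees) are included,
#' since angles between environment vectors carry the correlation
#' interpretation of the display.
#'
#' @param fit an [fit_ammi()] object.
#' @param kind `"AMMI1"` or `"AMMI2"`.
#' @param axes pair of axis indices for AMMI2 (default `c(1, 2)`); for AMMI1
#'   the single score axis used is `axes[1]`.
#' @return List with data.frames `genotypes` and `environments` (label, x,
#'   y, vector length) and, for AMMI2, matrix `env_angles`.
#' @export
ammi_biplot_coords <- function(fit, kind = c("AMMI1", "AMMI2"),
                               axes = c(1, 2)) {
  stopifnot(inherits(fit, "ammi"))
  kind <- match.arg(kind)
  if (any(axes < 1) || any(axes > fit$n_axes_max))
    met_stop("requested axes not present in the fit", "value")
  sc_g <- sweep(fit$gamma, 2, sqrt(fit$lambda), "*")
  sc_e <- sweep(fit$delta, 2, sqrt(fit$lambda), "*")
  if (kind == "AMMI1") {
    k <- axes[1]
    gen <- data.frame(label = fit$genotypes, x = fit$mu + fit$alpha,
                      y = sc_g[, k], stringsAsFactors = FALSE)
    env <- data.frame(label = fit$environments, x = fit$mu + fit$beta,
                      y = sc_e[, k], stringsAsFactors = FALSE)
    return(list(kind = kind, genotypes = gen, environments = env))
  }
  i <- axes[1]; j <- axes[2]
  gen <- data.frame(label = fit$genotypes, x = sc_g[, i], y = sc_g[, j],
                    length = sqrt(sc_g[, i]^2 + sc_g[, j]^2),
                    stringsAsFactors = FALSE)
  env <- data.frame(label = fit$environments, x = sc_e[, i], y = sc_e[, j],
                    length = sqrt(sc_e[, i]^2 + sc_e[, j]^2),
                    stringsAsFactors = FALSE)
  pts <- cbind(env$x, env$y)
  nrm <- sqrt(rowSums(pts^2))
  cosmat <- tcrossprod(pts) / outer(nrm, nrm)
  cosmat[!is.finite(cosmat)] <- NA
  ang <- acos(pmin(pmax(cosmat, -1), 1)) * 180 / pi
  dimnames(ang) <- list(fit$environments, fit$environments)
  list(kind = kind, genotypes = gen, environments = env, env_angles = ang)
}

#' Biplot display of an AMMI fit
#'
#' @param x an [fit_ammi()] object.
#' @param kind `"AMMI1"` (mean vs PC1) or `"AMMI2"` (PC1 vs PC2).
#' @param axes axes passed to [ammi_biplot_coords()].
#' @param ... further arguments to [graphics::plot()].
#' @return The coordinate list, invisibly.
#' @export
plot.ammi <- function(x, kind = c("AMMI2", "AMMI1"), axes = c(1, 2), ...) {
  kind <- match.arg(kind)
  co <- ammi_biplot_coords(x, kind, axes)
  all_x <- c(co$genotypes$x, co$environments$x)
  all_y <- c(co$genotypes$y, co$environments$y)
  graphics::plot(all_x, all_y, type = "n",
                 xlab = if (kind == "AMMI1") "mean yield (g/plot)"
                        else paste0("PC", axes[1]),
                 ylab = paste0("PC", if (kind == "AMMI1") axes[1]
                               else axes[2]),
                 main = paste(kind, "biplot"), ...)
  graphics::abline(h = 0, v = if (kind == "AMMI1") x$mu else 0,
                   col = "grey70")
  graphics::text(co$genotypes$x, co$genotypes$y, co$genotypes$label,
                 cex = 0.7)
  graphics::text(co$environments$x, co$environments$y,
                 co$environments$label, cex = 0.8, col = "red3")
  if (kind == "AMMI2")
    graphics::segments(0, 0, co$environments$x, co$environments$y,
                       col = "red3", lty = 3)
  invisible(co)
}

#' @export
summary.ammi <- function(object, ...) {
  d <- data.frame(axis = seq_len(object$n_axes_max),
                  lambda = object$lambda,
                  proportion = 100 * object$EP,
                  accumulated = cumsum(100 * object$EP))
  structure(list(mu = object$mu, axes = d), class = "summary.ammi")
}

#' @export
print.summary.ammi <- function(x, ...) {
  cat("AMMI multiplicative axes\n")
  print(transform(x$axes, lambda = signif(lambda, 6),
                  proportion = round(proportion, 2),
                  accumulated = round(accumulated, 2)), row.names = FALSE)
  invisible(x)
}
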