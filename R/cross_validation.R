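# RMSPD cross-validation of the AMMI family against BLUP predictors.
#
# Split scheme: within each environment one replicate is assigned at random
# to the validation set and the remaining r - 1 replicates form the
# modeling set, which therefore stays balanced.

# Fast internal ANOVA mean squares from a g x e x r yield array.
array_anova_ms <- function(arr) {
  g <- dim(arr)[1]; e <- dim(arr)[2]; r <- dim(arr)[3]
  cellm <- apply(arr, c(1, 2), mean)
  mu <- mean(cellm)
  gm <- rowMeans(cellm); em <- colMeans(cellm)
  z <- cellm - outer(gm, rep(1, e)) - outer(rep(1, g), em) + mu
  ms_g <- e * r * sum((gm - mu)^2) / (g - 1)
  ms_ge <- r * sum(z^2) / ((g - 1) * (e - 1))
  ms_res <- if (r >= 2)
    sum((arr - array(cellm, dim(arr)))^2) / (e * g * (r - 1)) else NA_real_
  list(cellm = cellm, mu = mu, gm = gm, em = em, z = z,
       ms_g = ms_g, ms_ge = ms_ge, ms_res = ms_res, g = g, e = e, r = r)
}

# Predicted cell means from the modeling array for one model label.
cv_predict <- function(an, sv, label) {
  g <- an$g; e <- an$e
  additive <- an$mu + outer(an$gm - an$mu, an$em - an$mu, "+")
  if (grepl("^AMMI", label)) {
    kmax <- min(g - 1, e - 1)
    n <- if (label == "AMMIF") kmax else as.integer(sub("AMMI", "", label))
    if (is.na(n) || n < 0 || n > kmax)
      met_stop(paste0("unknown or out-of-range model label: ", label),
               "value")
    if (n == 0) return(additive)
    k <- seq_len(n)
    return(additive + sv$u[, k, drop = FALSE] %*%
             (diag(sv$d[k], n) %*% t(sv$v[, k, drop = FALSE])))
  }
  if (label %in% c("BLUP_g", "BLUP_ge")) {
    if (an$r < 2)
      met_stop("BLUP models need >= 2 modeling replicates (r >= 3 overall)",
               "value")
    r <- an$r
    vg <- max((an$ms_g - an$ms_ge) / (r * e), 0)
    vge <- max((an$ms_ge - an$ms_res) / r, 0)
    ve <- an$ms_res
    den_g <- vg + vge / e + ve / (r * e)
    c_g <- if (den_g > 0) vg / den_g else 0
    den_ge <- vge + ve / r
    c_ge <- if (den_ge > 0) vge / den_ge else 0
    pred <- an$mu + outer(c_g * (an$gm - an$mu), an$em - an$mu, "+")
    if (label == "BLUP_ge") pred <- pred + c_ge * an$z
    return(pred)
  }
  met_stop(paste0("unknown model label: ", label), "value")
}

#' RMSPD cross-validation of AMMI-family and BLUP predictors
#'
#' For each resample, one replicate per environment is randomly held out for
#' validation; every model is fitted on the cell means of the remaining
#' replicates and the root mean square prediction difference
#' `RMSPD = sqrt(mean((yhat_ge - y_val,ge)^2))` over all g x e held-out
#' observations is recorded. Model labels: `"AMMI0"` ... `"AMMI<k>"`,
#' `"AMMIF"` (full rank), `"BLUP_g"` (genotype BLUPs only) and `"BLUP_ge"`
#' (genotype + interaction BLUPs).
#'
#' @param trial a balanced [met_trial()] with `r >= 2` (BLUP models need
#'   `r >= 3`, so that the modeling set retains a residual stratum).
#' @param models character vector of model labels; default is the full AMMI
#'   family plus both BLUP predictors.
#' @param n_resamples number of random splits (default 1000).
#' @param seed optional integer seed.
#' @return A `cv_rmspd` object: matrix `rmspd` (n_resamples x model),
#'   `models`, `n_resamples`, `seed`, and the split `scheme` tag.
#' @export
rmspd_cv <- function(trial, models = NULL, n_resamples = 1000, seed = NULL) {
  cm <- cell_means(trial)
  g <- nrow(cm$matrix); e <- ncol(cm$matrix); r <- cm$r
  if (r < 2)
    met_stop("cross-validation needs at least 2 replicates", "value")
  kmax <- min(g - 1, e - 1)
  if (is.null(models))
    models <- c(paste0("AMMI", 0:(kmax - 1)), "AMMIF",
                if (r >= 3) c("BLUP_g", "BLUP_ge"))
  # replicate index within environment, by label order
  envs <- colnames(cm$matrix); gens <- rownames(cm$matrix)
  arr <- array(NA_real_, c(g, e, r))
  for (j in seq_len(e)) {
    sub <- trial[trial$env == envs[j], ]
    reps <- sort(unique(sub$rep))
    if (length(reps) != r)
      met_stop("replicate labels are not consistent within environments",
               "balance")
    for (k in seq_len(r)) {
      sk <- sub[sub$rep == reps[k], ]
      arr[, j, k] <- sk$yield[match(gens, sk$gen)]
    }
  }
  if (anyNA(arr))
    met_stop("replicate labels are not consistent within environments",
             "balance")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n_resamples, length(models),
                dimnames = list(NULL, models))
  for (b in seq_len(n_resamples)) {
    val_idx <- sample.int(r, e, replace = TRUE)
    val <- matrix(NA_real_, g, e)
    model_arr <- array(NA_real_, c(g, e, r - 1))
    for (j in seq_len(e)) {
      val[, j] <- arr[, j, val_idx[j]]
      model_arr[, j, ] <- arr[, j, -val_idx[j]]
    }
    an <- array_anova_ms(model_arr)
    sv <- svd(an$z)
    for (m in models) {
      pred <- cv_predict(an, sv, m)
      out[b, m] <- sqrt(mean((pred - val)^2))
    }
  }
  structure(list(rmspd = out, models = models, n_resamples = n_resamples,
                 seed = seed,
                 scheme = "leave-one-replicate-per-environment"),
            class = "cv_rmspd")
}

#' Summarize and rank RMSPD distributions
#'
#' @param dist a `cv_rmspd` object from [rmspd_cv()].
#' @return data.frame `model`, `median`, `mean`, `sd`, `rank`, sorted by
#'   ascending median RMSPD (rank 1 = most accurate).
#' @export
summarize_cv <- function(dist) {
  stopifnot(inherits(dist, "cv_rmspd"))
  if (nrow(dist$rmspd) == 0)
    met_stop("empty RMSPD distributions", "value")
  d <- data.frame(model = dist$models,
                  median = apply(dist$rmspd, 2, stats::median),
                  mean = colMeans(dist$rmspd),
                  sd = apply(dist$rmspd, 2, stats::sd),
                  stringsAsFactors = FALSE)
  d$rank <- rank_asc(d$median)
  d[order(d$rank), , drop = FALSE]
}

#' @export
print.cv_rmspd <- function(x, ...) {
  cat("RMSPD cross-validation (", x$scheme, ")\n", sep = "")
  cat("  resamples:", x$n_resamples, " models:", length(x$models), "\n")
  print(utils::head(summarize_cv(x), 8), row.names = FALSE)
  invisible(x)
}

#' Boxplot of RMSPD distributions by model
#'
#' @param x a `cv_rmspd` object.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.cv_rmspd <- function(x, ...) {
  ord <- summarize_cv(x)$model
  graphics::boxplot(x$rmspd[, ord, drop = FALSE], las = 2,
                    ylab = "RMSPD (g/plot)", ...)
  invisible(x)
}
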