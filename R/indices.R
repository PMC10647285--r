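# Scalar stress/stability indices: Fischer-Maurer heat susceptibility index
# with tolerance classes, Annicchiarico recommendation index, environmental
# index.

#' Heat susceptibility index (Fischer-Maurer)
#'
#' `S_g = (1 - Yh_g / Yn_g) / (1 - Xh / Xn)` where `Yn`/`Yh` are a
#' genotype's mean yields under normal and heat-stressed (late-sown)
#' conditions and `Xn`/`Xh` the corresponding trial-wide means; the
#' denominator `SI = 1 - Xh/Xn` is the stress intensity. `S` is
#' scale-invariant and unitless.
#'
#' @param normal,stress per-genotype mean yields under the two regimes:
#'   named numeric vectors or [cell_means()] objects (row means are used).
#'   Genotype sets must match.
#' @return data.frame `genotype`, `Yn`, `Yh`, `HSI`, `class` (from
#'   [classify_hsi()]); attribute `stress_intensity`.
#' @examples
#' hsi(c(A = 200, B = 200), c(A = 180, B = 140))
#' @export
hsi <- function(normal, stress) {
  as_means <- function(x) if (inherits(x, "cell_means")) rowMeans(x$matrix)
                          else x
  yn <- as_means(normal); yh <- as_means(stress)
  if (length(yn) != length(yh))
    met_stop("normal and stress genotype sets differ in size", "value")
  if (!is.null(names(yn)) && !is.null(names(yh))) {
    if (!setequal(names(yn), names(yh)))
      met_stop("normal and stress genotype sets differ", "value")
    yh <- yh[names(yn)]
  }
  if (any(yn == 0))
    met_stop("zero normal-condition yield; HSI undefined", "value")
  xn <- mean(yn); xh <- mean(yh)
  si <- 1 - xh / xn
  if (si <= 0)
    met_stop("stress intensity 1 - Xh/Xn is not positive: stress did not reduce mean yield",
             "stress_intensity")
  s <- (1 - yh / yn) / si
  gens <- names(yn)
  if (is.null(gens)) gens <- paste0("G", seq_along(yn))
  structure(data.frame(genotype = gens, Yn = unname(yn), Yh = unname(yh),
                       HSI = unname(s), class = classify_hsi(s),
                       stringsAsFactors = FALSE),
            stress_intensity = si)
}

#' Heat-tolerance class from an HSI value
#'
#' Boundaries as conventionally printed: highly tolerant `HSI < 0.50`,
#' tolerant `0.51-0.75`, moderately tolerant `0.76-1.00`, susceptible
#' `HSI > 1.00`. Values falling in the printed gaps (e.g. between 0.50 and
#' 0.51) are assigned to the lower class.
#'
#' @param S numeric vector of HSI values.
#' @return character vector of class labels.
#' @export
classify_hsi <- function(S) {
  if (any(!is.finite(S)))
    met_stop("HSI values must be finite", "value")
  ifelse(S < 0.51, "highly tolerant",
  ifelse(S < 0.76, "tolerant",
  ifelse(S <= 1.00, "moderately tolerant", "susceptible")))
}

#' Per-pair HSI from a trial with normal/late environment metadata
#'
#' Environments sharing (location, year) with one `"normal"` and one
#' `"late"` sowing form a pair; [hsi()] is computed per pair on the
#' within-pair genotype means, and an across-pairs mean HSI (a derived
#' summary, not part of the index definition) is appended.
#'
#' @param trial a [met_trial()] whose `env_meta` attribute carries
#'   `location`, `year`, `sowing`.
#' @return list with `pairs` (the pairing table), `hsi` (genotype x pair
#'   matrix of HSI values), `mean_hsi` (named vector with tolerance class),
#'   `stress_intensity` (per pair).
#' @export
hsi_pairs <- function(trial) {
  stopifnot(inherits(trial, "met_trial"))
  meta <- attr(trial, "env_meta")
  if (is.null(meta))
    met_stop("trial has no env_meta; cannot pair normal/late environments",
             "value")
  cm <- cell_means(trial)
  key <- paste(meta$location, meta$year, sep = "_")
  pairs <- list()
  for (k in unique(key)) {
    sub <- meta[key == k, ]
    en <- sub$env[sub$sowing == "normal"]
    el <- sub$env[sub$sowing == "late"]
    if (length(en) == 1 && length(el) == 1)
      pairs[[k]] <- c(normal = en, late = el)
  }
  if (length(pairs) == 0)
    met_stop("env_meta contains no complete normal/late pair", "value")
  pair_tab <- data.frame(pair = names(pairs),
                         normal = vapply(pairs, `[`, "", "normal"),
                         late = vapply(pairs, `[`, "", "late"),
                         stringsAsFactors = FALSE)
  hmat <- matrix(NA_real_, nrow(cm$matrix), length(pairs),
                 dimnames = list(rownames(cm$matrix), names(pairs)))
  si <- stats::setNames(numeric(length(pairs)), names(pairs))
  for (k in names(pairs)) {
    h <- hsi(cm$matrix[, pairs[[k]]["normal"]],
             cm$matrix[, pairs[[k]]["late"]])
    hmat[, k] <- h$HSI
    si[k] <- attr(h, "stress_intensity")
  }
  mh <- rowMeans(hmat)
  list(pairs = pair_tab, hsi = hmat,
       mean_hsi = mh, mean_class = classify_hsi(mh),
       stress_intensity = si)
}

#' Annicchiarico recommendation index
#'
#' Yields are expressed as percentages of each environment's mean (so every
#' environment averages 100); the index is
#' `omega_g = mean_e(p_ge) - z_(1-alpha) * sd_e(p_ge)` with the sample
#' standard deviation (`e - 1` denominator). Larger means a safer
#' recommendation: a genotype with high `omega` rarely falls far below the
#' environment mean.
#'
#' @param x a [cell_means()] object, a [met_trial()], or a genotype x
#'   environment matrix of means.
#' @param alpha confidence coefficient (default 0.25, `z ~ 0.6745`).
#' @return data.frame `genotype`, `mean_pct`, `sd_pct`, `omega`, `rank`
#'   (1 = largest omega); attribute `alpha`.
#' @export
annicchiarico <- function(x, alpha = 0.25) {
  m <- if (inherits(x, "cell_means")) x$matrix
       else if (inherits(x, "met_trial")) cell_means(x)$matrix
       else as.matrix(x)
  if (ncol(m) < 2)
    met_stop("at least 2 environments required", "value")
  em <- colMeans(m)
  if (any(em == 0))
    met_stop("an environment mean is zero; percentages undefined", "value")
  p <- 100 * sweep(m, 2, em, "/")
  mp <- rowMeans(p)
  sp <- apply(p, 1, stats::sd)
  z <- stats::qnorm(1 - alpha)
  omega <- mp - z * sp
  gens <- rownames(m)
  if (is.null(gens)) gens <- paste0("G", seq_len(nrow(m)))
  structure(data.frame(genotype = gens, mean_pct = mp, sd_pct = sp,
                       omega = omega, rank = rank_desc(omega),
                       stringsAsFactors = FALSE),
            alpha = alpha)
}

#' Environmental index and favorability
#'
#' `I_e = ybar_.e - ybar..`: positive means a favorable (above-average)
#' environment. The best genotype (argmax of the cell means, ties to the
#' first genotype) is reported per environment.
#'
#' @param means a [cell_means()] object or genotype x environment matrix.
#' @return data.frame `environment`, `index`, `favorable`, `best_genotype`.
#' @export
environmental_index <- function(means) {
  m <- if (inherits(means, "cell_means")) means$matrix
       else if (inherits(means, "met_trial")) cell_means(means)$matrix
       else as.matrix(means)
  idx <- colMeans(m) - mean(m)
  gens <- rownames(m)
  if (is.null(gens)) gens <- paste0("G", seq_len(nrow(m)))
  envs <- colnames(m)
  if (is.null(envs)) envs <- paste0("E", seq_len(ncol(m)))
  data.frame(environment = envs, index = unname(idx),
             favorable = unname(idx > 0),
             best_genotype = gens[apply(m, 2, which.max)],
             stringsAsFactors = FALSE)
}
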