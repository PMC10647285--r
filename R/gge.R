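# GGE biplot computation and the interpretation patterns as coordinate and
# ranking tables. All patterns operate on the rank-2 factorization, and each
# geometric rule agrees with the algebraic rank-2 reconstruction (argmax /
# sign) of the centered matrix -- that identity is the correctness contract.

norm2 <- function(x) sqrt(sum(x^2))

#' Fit a GGE (genotype + genotype-by-environment) biplot model
#'
#' Centers the cell-mean matrix (default: environment-centered, so the
#' genotype main effect stays in the matrix), optionally scales columns by
#' their standard deviation, and takes the SVD. Coordinates on axes 1-2
#' depend on the singular value partitioning (SVP): genotype-focused
#' (`1`: genotype coords `U L`, environment coords `V`),
#' environment-focused (`2`: `U`, `V L`) or symmetric (`3`:
#' `U L^0.5`, `V L^0.5`). Axes with a null singular value get zero
#' coordinates. The sign convention makes the largest-magnitude environment
#' score on each axis positive.
#'
#' @param x a [cell_means()] object, a [met_trial()], or a plain genotype x
#'   environment matrix of means.
#' @param centering `0`/`"none"`, `1`/`"global"`, or `2`/`"environment"`
#'   (default).
#' @param scaling `0`/`"none"` (default) or `1`/`"sd"`.
#' @param svp `1`/`"genotype"`, `2`/`"environment"`, or `3`/`"symmetric"`
#'   (default).
#' @return A `gge` object: centered matrix `M`, `d`/`U`/`V` (full SVD),
#'   2-D `gen_coord` and `env_coord`, axis variance `proportion`, the
#'   option codes, and the rank-2 reconstruction `M2`.
#' @export
fit_gge <- function(x, centering = 2, scaling = 0, svp = 3) {
  m <- if (inherits(x, "cell_means")) x$matrix
       else if (inherits(x, "met_trial")) cell_means(x)$matrix
       else as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("E", seq_len(ncol(m)))
  centering <- match_code(centering, c(none = 0, global = 1, environment = 2))
  scaling <- match_code(scaling, c(none = 0, sd = 1))
  svp <- match_code(svp, c(genotype = 1, environment = 2, symmetric = 3))
  if (nrow(m) < 3 || ncol(m) < 3)
    warning("fewer than 3 genotypes or environments; ",
            "2-D patterns may be degenerate")
  M <- switch(as.character(centering),
              "0" = m,
              "1" = m - mean(m),
              "2" = sweep(m, 2, colMeans(m)))
  if (scaling == 1) {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
      met_stop("cannot scale: some environment has zero variance", "value")
    M <- sweep(M, 2, sds, "/")
  }
  sv <- fix_svd_signs(svd(M))
  d <- sv$d
  # null axes contribute nothing: zero their coordinates
  act <- d > max(d[1], .Machine$double.eps) * 1e-12
  scale_pair <- switch(as.character(svp),
                       "1" = list(gd = d, ed = as.numeric(act)),
                       "2" = list(gd = as.numeric(act), ed = d),
                       "3" = list(gd = sqrt(d), ed = sqrt(d)))
  gen_coord <- sweep(sv$u[, 1:2, drop = FALSE], 2, scale_pair$gd[1:2], "*")
  env_coord <- sweep(sv$v[, 1:2, drop = FALSE], 2, scale_pair$ed[1:2], "*")
  gen_coord[, !act[1:2]] <- 0
  env_coord[, !act[1:2]] <- 0
  rownames(gen_coord) <- rownames(m)
  rownames(env_coord) <- colnames(m)
  tot <- sum(d^2)
  M2 <- sv$u[, 1:2, drop = FALSE] %*% diag(d[1:2], 2) %*%
    t(sv$v[, 1:2, drop = FALSE])
  dimnames(M2) <- dimnames(m)
  structure(list(M = M, d = d, U = sv$u, V = sv$v,
                 gen_coord = gen_coord, env_coord = env_coord,
                 proportion = if (tot > 0) d^2 / tot else d * 0,
                 centering = centering, scaling = scaling, svp = svp,
                 genotypes = rownames(m), environments = colnames(m),
                 M2 = M2),
            class = "gge")
}

match_code <- function(x, codes) {
  if (is.character(x)) {
    if (!x %in% names(codes))
      met_stop(paste0("invalid option '", x, "'"), "value")
    return(unname(codes[x]))
  }
  if (!x %in% codes)
    met_stop(paste0("invalid option code ", x), "value")
  as.integer(x)
}

#' @export
print.gge <- function(x, ...) {
  cat("GGE biplot fit:", length(x$genotypes), "genotypes x",
      length(x$environments), "environments\n")
  cat("  centering =", x$centering, " scaling =", x$scaling,
      " SVP =", x$svp, "\n")
  cat("  axes 1-2 explain",
      sprintf("%.1f%% + %.1f%% = %.1f%%", 100 * x$proportion[1],
              100 * x$proportion[2], 100 * sum(x$proportion[1:2])), "\n")
  invisible(x)
}

# Average-environment axis (unit vector toward the mean environment point).
aea_vector <- function(fit) {
  avg <- colMeans(fit$env_coord)
  n <- norm2(avg)
  if (n < .Machine$double.eps^0.5 * max(norm2(fit$env_coord), 1))
    met_stop("average environment lies at the origin; AEA undefined",
             "degenerate")
  avg / n
}

#' Which-won-where sector partition of a GGE biplot
#'
#' Convex hull of the genotype markers; perpendiculars from the origin to
#' the hull edges bound sectors, and every environment falls in the sector
#' whose vertex genotype wins it. The winner always equals the argmax over
#' genotypes of the rank-2 reconstructed centered matrix for that
#' environment. Degenerate geometry (fewer than 3 distinct, non-collinear
#' markers) falls back to the direct argmax, flagged.
#'
#' @param fit a [fit_gge()] object.
#' @return A `gge_www` list: ordered hull `vertices`, `boundary_angles`
#'   (degrees, one per hull edge), data.frame `environments`
#'   (environment, sector, winner), and `degenerate` flag.
#' @export
which_won_where <- function(fit) {
  stopifnot(inherits(fit, "gge"))
  pts <- fit$gen_coord
  tol <- 1e-9 * max(fit$d[1], 1)
  uniq <- unique(round(pts / max(tol, 1e-300), 0))
  collinear <- FALSE
  hull <- NULL
  if (nrow(uniq) >= 3) {
    hull <- grDevices::chull(pts)
    if (length(hull) < 3) collinear <- TRUE
  }
  degenerate <- nrow(uniq) < 3 || collinear
  env_pts <- fit$env_coord
  if (degenerate) {
    winner_idx <- apply(fit$M2, 2, which.max)
    env_tab <- data.frame(environment = fit$environments,
                          sector = NA_integer_,
                          winner = fit$genotypes[winner_idx],
                          stringsAsFactors = FALSE)
    return(structure(list(vertices = character(0),
                          boundary_angles = numeric(0),
                          environments = env_tab, degenerate = TRUE),
                     class = "gge_www"))
  }
  # order hull vertices counterclockwise by polar angle
  hp <- pts[hull, , drop = FALSE]
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hull <- hull[ord]
  hp <- pts[hull, , drop = FALSE]
  nh <- length(hull)
  # winner per environment: hull vertex maximizing the inner product with
  # the environment marker; boundary ties go to the counterclockwise vertex
  proj <- hp %*% t(env_pts)                      # nh x e
  win_pos <- integer(ncol(proj))
  for (j in seq_len(ncol(proj))) {
    mx <- max(proj[, j])
    tied <- which(proj[, j] >= mx - tol * max(1, abs(mx)))
    win_pos[j] <- tied[length(tied)]
  }
  # boundary angles: tie direction between adjacent (ccw) hull vertices
  bnd <- numeric(nh)
  for (i in seq_len(nh)) {
    v1 <- hp[i, ]; v2 <- hp[i %% nh + 1, ]
    edge <- v1 - v2
    u <- c(-edge[2], edge[1])
    if (sum(u * (v1 + v2)) < 0) u <- -u
    bnd[i] <- atan2(u[2], u[1]) * 180 / pi
  }
  env_tab <- data.frame(environment = fit$environments,
                        sector = win_pos,
                        winner = fit$genotypes[hull][win_pos],
                        stringsAsFactors = FALSE)
  structure(list(vertices = fit$genotypes[hull], boundary_angles = bnd,
                 environments = env_tab, degenerate = FALSE),
            class = "gge_www")
}

#' @export
print.gge_www <- function(x, ...) {
  cat("GGE which-won-where partition\n")
  if (x$degenerate) cat("  (degenerate geometry: direct argmax fallback)\n")
  else cat("  hull vertices:", paste(x$vertices, collapse = ", "), "\n")
  cat("  winners:\n")
  print(x$environments, row.names = FALSE)
  invisible(x)
}

#' Mean performance vs stability along the average-environment axis
#'
#' Projects each genotype marker onto the average-environment axis (AEA):
#' the projection orders mean performance, the signed perpendicular
#' component measures instability.
#'
#' @param fit a [fit_gge()] object.
#' @return data.frame `genotype`, `mean_score` (projection on the AEA),
#'   `stability` (signed perpendicular component), `rank_mean`
#'   (1 = largest projection), `rank_stability` (1 = smallest magnitude).
#' @export
mean_vs_stability <- function(fit) {
  stopifnot(inherits(fit, "gge"))
  aea <- aea_vector(fit)
  perp <- c(-aea[2], aea[1])
  proj <- as.numeric(fit$gen_coord %*% aea)
  dev <- as.numeric(fit$gen_coord %*% perp)
  data.frame(genotype = fit$genotypes, mean_score = proj, stability = dev,
             rank_mean = rank_desc(proj),
             rank_stability = rank_asc(abs(dev)),
             stringsAsFactors = FALSE)
}

#' Genotype ranking relative to the ideal genotype
#'
#' The ideal genotype sits on the average-environment axis at the largest
#' observed projection; genotypes are ranked by Euclidean distance to it
#' (rank 1 = closest; ties broken by genotype order).
#'
#' @param fit a [fit_gge()] object.
#' @return data.frame `genotype`, `distance`, `rank`; attribute `ideal`
#'   holds the ideal point.
#' @export
rank_vs_ideal_genotype <- function(fit) {
  stopifnot(inherits(fit, "gge"))
  aea <- aea_vector(fit)
  proj <- as.numeric(fit$gen_coord %*% aea)
  ideal <- aea * max(proj)
  d <- sqrt((fit$gen_coord[, 1] - ideal[1])^2 +
              (fit$gen_coord[, 2] - ideal[2])^2)
  structure(data.frame(genotype = fit$genotypes, distance = d,
                       rank = rank_asc(d), stringsAsFactors = FALSE),
            ideal = ideal)
}

#' Environment discriminativeness vs representativeness
#'
#' Discriminativeness = environment vector length; representativeness =
#' cosine of the angle between the environment vector and the
#' average-environment axis. Environments are also ranked by distance to
#' the ideal environment (on the AEA, at the longest environment vector).
#'
#' @param fit a [fit_gge()] object.
#' @return data.frame `environment`, `length`, `cos_aea` (NA for a
#'   zero-length vector), `distance_ideal`, `rank`.
#' @export
discrim_vs_repr <- function(fit) {
  stopifnot(inherits(fit, "gge"))
  aea <- aea_vector(fit)
  len <- sqrt(rowSums(fit$env_coord^2))
  cosang <- ifelse(len > 0,
                   as.numeric(fit$env_coord %*% aea) / len, NA_real_)
  ideal <- aea * max(len)
  d <- sqrt((fit$env_coord[, 1] - ideal[1])^2 +
              (fit$env_coord[, 2] - ideal[2])^2)
  data.frame(environment = fit$environments, length = len, cos_aea = cosang,
             distance_ideal = d, rank = rank_asc(d),
             stringsAsFactors = FALSE)
}

#' Pairwise genotype comparison along the equality line
#'
#' The equality line is the perpendicular through the origin to the segment
#' joining the two genotype markers; each environment is assigned to the
#' nearer genotype's side, which equals the sign of the rank-2
#' reconstructed difference for that environment.
#'
#' @param fit a [fit_gge()] object.
#' @param g1,g2 genotype labels, `g1 != g2`.
#' @return data.frame `environment`, `score` (positive favors `g1`),
#'   `favored` (`g1`, `g2`, or `"tie"`); attribute `coincident` flags
#'   coincident markers (all ties).
#' @export
compare_pair <- function(fit, g1, g2) {
  stopifnot(inherits(fit, "gge"))
  if (identical(g1, g2)) met_stop("g1 and g2 must differ", "value")
  i1 <- match(g1, fit$genotypes); i2 <- match(g2, fit$genotypes)
  if (is.na(i1) || is.na(i2))
    met_stop("genotype label not present in the fit", "value")
  diffv <- fit$gen_coord[i1, ] - fit$gen_coord[i2, ]
  tol <- 1e-9 * max(fit$d[1], 1)
  coincident <- norm2(diffv) <= tol
  score <- as.numeric(fit$env_coord %*% diffv)
  favored <- ifelse(coincident | abs(score) <= tol, "tie",
                    ifelse(score > 0, g1, g2))
  structure(data.frame(environment = fit$environments, score = score,
                       favored = favored, stringsAsFactors = FALSE),
            coincident = coincident)
}

#' Environment evaluation relative to one genotype
#'
#' Projects environment markers onto the axis through the origin and the
#' genotype marker: a positive projection means the genotype performs above
#' (environment-centered) average in that environment; the call equals the
#' sign of the genotype's rank-2 reconstructed value there.
#'
#' @param fit a [fit_gge()] object.
#' @param genotype genotype label.
#' @return data.frame `environment`, `projection`, `call`
#'   (`"above"`/`"below"`/`"average"`).
#' @export
environment_profile <- function(fit, genotype) {
  stopifnot(inherits(fit, "gge"))
  i <- match(genotype, fit$genotypes)
  if (is.na(i)) met_stop("genotype label not present in the fit", "value")
  gv <- fit$gen_coord[i, ]
  tol <- 1e-9 * max(fit$d[1], 1)
  if (norm2(gv) <= tol)
    met_stop("genotype marker at the origin; its axis is undefined",
             "degenerate")
  proj <- as.numeric(fit$env_coord %*% gv)
  call <- ifelse(abs(proj) <= tol, "average",
                 ifelse(proj > 0, "above", "below"))
  data.frame(environment = fit$environments, projection = proj,
             call = call, stringsAsFactors = FALSE)
}

#' Scatter display of a GGE biplot
#'
#' @param x a [fit_gge()] object.
#' @param hull draw the genotype convex hull (which-won-where view)?
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gge <- function(x, hull = FALSE, ...) {
  allx <- c(x$gen_coord[, 1], x$env_coord[, 1])
  ally <- c(x$gen_coord[, 2], x$env_coord[, 2])
  graphics::plot(allx, ally, type = "n",
                 xlab = sprintf("Axis 1 (%.1f%%)", 100 * x$proportion[1]),
                 ylab = sprintf("Axis 2 (%.1f%%)", 100 * x$proportion[2]),
                 main = "GGE biplot", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::segments(0, 0, x$env_coord[, 1], x$env_coord[, 2],
                     col = "red3", lty = 3)
  graphics::text(x$env_coord[, 1], x$env_coord[, 2], x$environments,
                 col = "red3", cex = 0.8)
  graphics::text(x$gen_coord[, 1], x$gen_coord[, 2], x$genotypes,
                 cex = 0.7)
  if (hull) {
    h <- grDevices::chull(x$gen_coord)
    graphics::polygon(x$gen_coord[h, 1], x$gen_coord[h, 2], border = "blue3")
  }
  invisible(x)
}
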