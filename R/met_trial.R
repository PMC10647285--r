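#' Construct a multi-environment trial object
#'
#' Validates replicate-level yield records and returns a `met_trial`, the
#' input container for every analysis in the package. One row per
#' (environment, genotype, replicate) with grain yield in g/plot.
#' Replicate labels are interpreted as nested within environments
#' (the `REP(ENV)` stratum of the joint ANOVA).
#'
#' @param data data.frame with one row per observation.
#' @param env,gen,rep,yield names of the environment, genotype, replicate
#'   and yield columns in `data` (defaults `ENV`, `GEN`, `REP`, `Y`).
#' @param env_meta optional data.frame of environment metadata with columns
#'   `env`, `location`, `year`, `sowing` (`"normal"` or `"late"`); used to
#'   pair normal/late-sown environments for the heat susceptibility index.
#' @return A `met_trial`: a data.frame with standardized columns
#'   `env`, `gen`, `rep`, `yield` and attribute `env_meta`.
#' @examples
#' d <- expand.grid(ENV = c("E1", "E2"), GEN = c("G1", "G2"), REP = c("R1", "R2"))
#' d$Y <- rnorm(nrow(d), 100, 5)
#' tr <- met_trial(d)
#' check_balance(tr)
#' @export
met_trial <- function(data, env = "ENV", gen = "GEN", rep = "REP", yield = "Y",
                      env_meta = NULL) {
  if (!is.data.frame(data))
    met_stop("'data' must be a data.frame", "schema")
  need <- c(env, gen, rep, yield)
  miss <- setdiff(need, names(data))
  if (length(miss))
    met_stop(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "schema")
  if (nrow(data) == 0)
    met_stop("trial has no records", "value")
  y <- data[[yield]]
  if (!is.numeric(y)) {
    y <- suppressWarnings(as.numeric(as.character(y)))
  }
  if (anyNA(y))
    met_stop("yield column contains missing or non-numeric values", "value")
  if (any(y < 0))
    met_stop("yield values must be non-negative (g/plot)", "value")

  out <- data.frame(env   = as.character(data[[env]]),
                    gen   = as.character(data[[gen]]),
                    rep   = as.character(data[[rep]]),
                    yield = as.numeric(y),
                    stringsAsFactors = FALSE)
  key <- paste(out$env, out$gen, out$rep, sep = "\r")
  if (anyDuplicated(key))
    met_stop("duplicate (env, gen, rep) records present", "integrity")
  if (length(unique(out$gen)) < 2)
    met_stop("at least 2 genotypes required", "value")
  if (length(unique(out$env)) < 2)
    met_stop("at least 2 environments required", "value")
  if (!is.null(env_meta)) {
    em_need <- c("env", "location", "year", "sowing")
    if (!is.data.frame(env_meta) || !all(em_need %in% names(env_meta)))
      met_stop("env_meta needs columns env, location, year, sowing", "schema")
    if (!all(env_meta$sowing %in% c("normal", "late")))
      met_stop("env_meta$sowing must be 'normal' or 'late'", "value")
  }
  structure(out, env_meta = env_meta, class = c("met_trial", "data.frame"))
}

#' Read a multi-environment trial from a CSV file
#'
#' Long format only: one row per (environment, genotype, replicate), UTF-8,
#' header row. Column names are configurable via `column_map`.
#'
#' @param path path to a CSV file.
#' @param column_map named list/vector mapping the roles `env`, `gen`, `rep`,
#'   `yield` to column names in the file; defaults to
#'   `c(env = "ENV", gen = "GEN", rep = "REP", yield = "Y")`.
#' @param env_meta optional environment metadata (see [met_trial()]), either a
#'   data.frame or a path to a CSV file with the same columns.
#' @return A validated [met_trial()].
#' @export
read_met_trial <- function(path,
                           column_map = c(env = "ENV", gen = "GEN",
                                          rep = "REP", yield = "Y"),
                           env_meta = NULL) {
  if (!file.exists(path))
    met_stop(paste0("file not found: ", path), "value")
  cm <- as.list(column_map)
  for (role in c("env", "gen", "rep", "yield"))
    if (is.null(cm[[role]]))
      met_stop(paste0("column_map is missing role '", role, "'"), "schema")
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(env_meta))
    env_meta <- utils::read.csv(env_meta, stringsAsFactors = FALSE)
  met_trial(d, env = cm$env, gen = cm$gen, rep = cm$rep, yield = cm$yield,
            env_meta = env_meta)
}

#' Write a trial back to CSV (long format, default column names)
#'
#' @param trial a [met_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_met_trial <- function(trial, path) {
  stopifnot(inherits(trial, "met_trial"))
  d <- data.frame(ENV = trial$env, GEN = trial$gen, REP = trial$rep,
                  Y = trial$yield)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check replicate balance of a trial
#'
#' @param trial a [met_trial()].
#' @return A `balance_report`: list with `is_balanced`, `missing_cells`
#'   (data.frame of absent (env, gen) pairs) and `rep_counts`
#'   (genotype x environment matrix of replicate counts).
#' @export
check_balance <- function(trial) {
  stopifnot(inherits(trial, "met_trial"))
  gens <- unique(trial$gen)
  envs <- unique(trial$env)
  counts <- table(factor(trial$gen, levels = gens),
                  factor(trial$env, levels = envs))
  counts <- matrix(as.integer(counts), nrow = length(gens),
                   dimnames = list(gens, envs))
  missing_idx <- which(counts == 0, arr.ind = TRUE)
  missing_cells <- data.frame(env = envs[missing_idx[, 2]],
                              gen = gens[missing_idx[, 1]],
                              stringsAsFactors = FALSE)
  is_balanced <- nrow(missing_cells) == 0 && length(unique(c(counts))) == 1
  structure(list(is_balanced = is_balanced,
                 missing_cells = missing_cells,
                 rep_counts = counts),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("MET balance report\n")
  cat("  balanced:", x$is_balanced, "\n")
  cat("  missing (env, gen) cells:", nrow(x$missing_cells), "\n")
  cat("  replicate counts:", paste(sort(unique(c(x$rep_counts))),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Replicate-level to cell-mean aggregation
#'
#' Averages replicates within each (genotype, environment) cell of a balanced
#' trial. The resulting genotype x environment matrix (and its marginal
#' means) is the input to the AMMI and GGE decompositions.
#'
#' @param trial a balanced [met_trial()].
#' @return A `cell_means` object: list with `matrix` (genotypes as rows),
#'   `r` (replicate count), `grand_mean`, `gen_means`, `env_means`.
#' @export
cell_means <- function(trial) {
  stopifnot(inherits(trial, "met_trial"))
  bal <- check_balance(trial)
  if (!bal$is_balanced)
    met_stop("trial is unbalanced; cell_means requires equal replicate counts",
             "balance")
  gens <- rownames(bal$rep_counts)
  envs <- colnames(bal$rep_counts)
  m <- tapply(trial$yield,
              list(factor(trial$gen, levels = gens),
                   factor(trial$env, levels = envs)),
              mean)
  m <- matrix(m, nrow = length(gens), dimnames = list(gens, envs))
  structure(list(matrix = m,
                 r = unname(bal$rep_counts[1, 1]),
                 grand_mean = mean(m),
                 gen_means = rowMeans(m),
                 env_means = colMeans(m)),
            class = "cell_means")
}

#' @export
print.cell_means <- function(x, ...) {
  cat("MET cell means:", nrow(x$matrix), "genotypes x", ncol(x$matrix),
      "environments (r =", x$r, "replicates)\n")
  cat("  grand mean:", format(x$grand_mean, digits = 6), "g/plot\n")
  invisible(x)
}

#' Write cell means to CSV (genotypes as rows, environments as columns)
#'
#' @param cm a [cell_means()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_means <- function(cm, path) {
  stopifnot(inherits(cm, "cell_means"))
  d <- data.frame(GEN = rownames(cm$matrix), cm$matrix, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.met_trial <- function(x, ...) {
  g <- length(unique(x$gen)); e <- length(unique(x$env))
  cat("MET trial:", nrow(x), "records;", g, "genotypes x", e, "environments\n")
  bal <- check_balance(x)
  cat("  balanced:", bal$is_balanced, "\n")
  cat("  mean yield:", format(mean(x$yield), digits = 6), "g/plot\n")
  if (!is.null(attr(x, "env_meta")))
    cat("  environment metadata: present\n")
  invisible(x)
}

#' @export
summary.met_trial <- function(object, ...) {
  bal <- check_balance(object)
  env_means <- tapply(object$yield, object$env, mean)
  structure(list(n = nrow(object),
                 g = length(unique(object$gen)),
                 e = length(unique(object$env)),
                 balanced = bal$is_balanced,
                 grand_mean = mean(object$yield),
                 env_means = env_means),
            class = "summary.met_trial")
}

#' @export
print.summary.met_trial <- function(x, ...) {
  cat("MET trial summary\n")
  cat("  records:", x$n, " genotypes:", x$g, " environments:", x$e, "\n")
  cat("  balanced:", x$balanced, "\n")
  cat("  grand mean:", format(x$grand_mean, digits = 6), "g/plot\n")
  cat("  environment means:\n")
  print(round(x$env_means, 2))
  invisible(x)
}
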