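# Internal helpers shared across the package.

# Classed conditions so callers/tests can distinguish failure modes.
met_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("metstab_", class, "_error"),
                                     "metstab_error")))
}

# rank with rank 1 = smallest, ties broken by position (i.e. label order)
rank_asc <- function(x) rank(x, ties.method = "first")

# rank with rank 1 = largest, ties broken by position
rank_desc <- function(x) rank(-x, ties.method = "first")

# min/max rescaling to [0, 100]; constant input is an error where used
rescale100 <- function(x, larger_is_better = TRUE) {
  rng <- range(x)
  if (diff(rng) == 0)
    met_stop("cannot rescale a constant vector to [0, 100]", "value")
  if (larger_is_better) 100 * (x - rng[1]) / diff(rng)
  else                  100 * (rng[2] - x) / diff(rng)
}

# Fix the SVD sign ambiguity: for each axis make the environment-score
# (right singular vector) entry of largest magnitude positive.
fix_svd_signs <- function(sv) {
  k <- length(sv$d)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  sv
}

# Double-center a matrix (remove row means, column means, add grand mean).
double_center <- function(m) {
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}
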