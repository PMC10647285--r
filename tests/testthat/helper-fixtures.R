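# Fixture builders: balanced trials from a deterministic cell-expectation
# function plus optional iid replicate noise.

make_trial <- function(g, e, r, cellfun = function(i, j) 100 + 5 * i + 3 * j,
                       noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- expand.grid(gi = seq_len(g), ei = seq_len(e), ri = seq_len(r))
  mu <- mapply(cellfun, d$gi, d$ei)
  y <- mu + if (noise_sd > 0) rnorm(nrow(d), 0, noise_sd) else 0
  met_trial(data.frame(ENV = sprintf("E%02d", d$ei),
                       GEN = sprintf("G%02d", d$gi),
                       REP = paste0("R", d$ri), Y = y))
}

# cell function with an explicit rank-1 interaction a_i * b_j
rank1_cellfun <- function(a, b, base = 150, gslope = 2, eslope = 3) {
  function(i, j) base + gslope * i + eslope * j + a[i] * b[j]
}

# a small random balanced trial (positive yields, genuine interaction)
random_trial <- function(g, e, r, seed) {
  make_trial(g, e, r,
             cellfun = function(i, j)
               250 + 8 * i - 5 * j + 30 * sin(i * j + seed),
             noise_sd = 20, seed = seed)
}

# brute-force joint ANOVA sums of squares straight from the observations
# (independent oracle: explicit loops, no matrix algebra)
brute_force_ss <- function(trial) {
  gens <- unique(trial$gen); envs <- unique(trial$env)
  mu <- mean(trial$yield)
  ss <- c(env = 0, rep = 0, gen = 0, ge = 0, res = 0)
  gmean <- sapply(gens, function(gg) mean(trial$yield[trial$gen == gg]))
  emean <- sapply(envs, function(ee) mean(trial$yield[trial$env == ee]))
  for (ee in envs) {
    sub_e <- trial[trial$env == ee, ]
    for (rr in unique(sub_e$rep)) {
      ermean <- mean(sub_e$yield[sub_e$rep == rr])
      ss["rep"] <- ss["rep"] +
        sum(sub_e$rep == rr) * (ermean - emean[ee])^2
    }
  }
  for (gg in gens) {
    ng <- sum(trial$gen == gg)
    ss["gen"] <- ss["gen"] + ng * (gmean[gg] - mu)^2
  }
  for (ee in envs) {
    ne <- sum(trial$env == ee)
    ss["env"] <- ss["env"] + ne * (emean[ee] - mu)^2
  }
  for (gg in gens) for (ee in envs) {
    cell <- trial$yield[trial$gen == gg & trial$env == ee]
    cmn <- mean(cell)
    ss["ge"] <- ss["ge"] +
      length(cell) * (cmn - gmean[gg] - emean[ee] + mu)^2
  }
  # residual = genotype x replicate interaction within environments
  for (k in seq_len(nrow(trial))) {
    row <- trial[k, ]
    cellmean <- mean(trial$yield[trial$gen == row$gen &
                                   trial$env == row$env])
    repmean <- mean(trial$yield[trial$env == row$env &
                                  trial$rep == row$rep])
    ss["res"] <- ss["res"] +
      (row$yield - cellmean - repmean + emean[row$env])^2
  }
  ss
}

# minimal hand-built AMMI-classed object for score-formula unit tests
fake_ammi <- function(lambda, gamma, genotypes = NULL) {
  g <- nrow(gamma)
  if (is.null(genotypes)) genotypes <- paste0("G", seq_len(g))
  ep <- lambda^2 / sum(lambda^2)
  structure(list(lambda = lambda, gamma = gamma, EP = ep,
                 genotypes = genotypes, n_axes_max = length(lambda)),
            class = "ammi")
}
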