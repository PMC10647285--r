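test_that("joint ANOVA matches a brute-force per-observation computation", {
  for (s in 1:4) {
    tr <- random_trial(4, 3, 2, seed = s)
    an <- joint_anova(tr)
    bf <- brute_force_ss(tr)
    expect_equal(an$SS, unname(bf[c("env", "rep", "gen", "ge", "res")]),
                 tolerance = 1e-8)
  }
  tr5 <- random_trial(5, 5, 3, seed = 99)
  expect_equal(joint_anova(tr5)$SS,
               unname(brute_force_ss(tr5)[c("env", "rep", "gen", "ge",
                                            "res")]),
               tolerance = 1e-8)
})

test_that("joint ANOVA df, CV and error handling follow the balanced layout", {
  tr <- random_trial(6, 4, 3, seed = 1)
  an <- joint_anova(tr)
  expect_equal(an$Df, c(3, 8, 5, 15, 40))
  expect_equal(attr(an, "cv"),
               100 * sqrt(an$MS[5]) / attr(an, "grand_mean"))
  # constant data: all SS zero, F undefined
  anc <- joint_anova(make_trial(3, 3, 2, cellfun = function(i, j) 50))
  expect_true(all(abs(anc$SS) < 1e-18))
  expect_true(all(is.na(anc$F)))
  # single replicate leaves no residual stratum
  expect_error(joint_anova(make_trial(3, 3, 1)),
               class = "metstab_value_error")
})

test_that("AMMI decomposition satisfies the SVD identities", {
  tr <- random_trial(7, 5, 2, seed = 4)
  cm <- cell_means(tr)
  fit <- fit_ammi(tr)
  z <- cm$matrix - outer(cm$gen_means, rep(1, 5)) -
    outer(rep(1, 7), cm$env_means) + cm$grand_mean
  expect_equal(sum(fit$lambda^2), sum(z^2))               # energy identity
  expect_false(is.unsorted(rev(fit$lambda)))              # descending
  expect_equal(crossprod(fit$gamma), diag(4), tolerance = 1e-10)
  expect_equal(crossprod(fit$delta), diag(4), tolerance = 1e-10)
  expect_equal(unname(predict(fit)), unname(cm$matrix), tolerance = 1e-10)
  # additive-only data: all singular values vanish
  fita <- fit_ammi(make_trial(4, 4, 2))
  expect_lt(max(fita$lambda), 1e-9)
  expect_equal(unname(predict(fita, 0)),
               unname(cell_means(make_trial(4, 4, 2))$matrix),
               tolerance = 1e-9)
})

test_that("rank-1 interaction is captured by a single axis", {
  tr <- make_trial(6, 4, 2, cellfun = rank1_cellfun(a = (1:6) - 3.5,
                                                    b = c(-3, -1, 1, 3)))
  fit <- fit_ammi(tr)
  expect_equal(fit$EP[1], 1, tolerance = 1e-12)
  # truncation identity: residual SS after n axes = sum of dropped lambda^2
  tr2 <- random_trial(6, 5, 2, seed = 12)
  fit2 <- fit_ammi(tr2)
  cm2 <- cell_means(tr2)$matrix
  for (n in 0:3) {
    res_ss <- sum((predict(fit2, n) - cm2)^2)
    expect_equal(res_ss,
                 sum(fit2$lambda^2) - sum(fit2$lambda[seq_len(n)]^2),
                 tolerance = 1e-8)
  }
  expect_error(predict(fit2, 99), class = "metstab_value_error")
})

test_that("rank-truncated AMMI beats random same-rank perturbations", {
  tr <- random_trial(6, 5, 2, seed = 21)
  fit <- fit_ammi(tr)
  cm <- cell_means(tr)$matrix
  best <- sum((predict(fit, 1) - cm)^2)
  additive <- predict(fit, 0)
  set.seed(1)
  for (i in 1:20) {
    u <- rnorm(6); v <- rnorm(5)
    u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
    rival <- additive + fit$lambda[1] * tcrossprod(u, v)
    expect_gte(sum((rival - cm)^2), best - 1e-8)
  }
})

test_that("Gollob axis df follow g + e - 1 - 2k", {
  expect_equal(ipca_df(42, 12, 1), 51L)
  expect_equal(ipca_df(42, 12, 11), 31L)
  expect_equal(ipca_df(3, 3, 1), 3L)
  expect_equal(ipca_df(3, 3, 1) + ipca_df(3, 3, 2), (3 - 1) * (3 - 1))
  expect_equal(ipca_df(42, 12, 1:11), seq(51L, 31L, by = -2L))
  expect_error(ipca_df(42, 12, 12), class = "metstab_value_error")
  expect_error(ipca_df(42, 12, 0), class = "metstab_value_error")
})

test_that("Gollob rows partition the interaction SS and test against residual", {
  tr <- random_trial(6, 4, 3, seed = 5)
  an <- joint_anova(tr)
  fit <- fit_ammi(tr)
  full <- gollob_test(fit, an)
  pc <- full[grepl("^PC", full$Source), ]
  expect_equal(nrow(pc), 3)
  expect_equal(sum(pc$Df), (6 - 1) * (4 - 1))
  expect_equal(sum(pc$SS), an$SS[an$Source == "GEN:ENV"], tolerance = 1e-8)
  expect_equal(pc$F, pc$MS / attr(an, "ms_res"))
  expect_equal(pc$Accumulated[3], 100, tolerance = 1e-8)
  # a null axis gets F = 0, p = 1: additive cell means, residual spread
  # from a genotype x replicate pattern that cancels within each cell
  tra <- make_trial(4, 4, 2)
  delta <- c(1, -1, 1, -1)
  gi <- as.integer(sub("G", "", tra$gen))
  tra$yield <- tra$yield + delta[gi] * ifelse(tra$rep == "R1", 1, -1)
  ana <- joint_anova(tra)
  fita <- fit_ammi(tra)
  pca <- gollob_test(fita, ana)
  last <- pca[pca$Source == "PC3", ]
  expect_equal(last$F, 0, tolerance = 1e-12)
  expect_equal(last$p, 1, tolerance = 1e-12)
})

test_that("rank-2 signal axes are declared significant at large effect size", {
  hits <- vapply(1:100, function(s) {
    sim <- simulate_met(sim_config(g = 12, e = 6, r = 3, mu = 500,
                                   sigma2_env = 500, sigma2_rep = 100,
                                   sigma2_gen = 500, sigma2_gei = 2000,
                                   sigma2_err = 500, gei_rank = 2,
                                   seed = s))
    full <- gollob_test(fit_ammi(sim$trial), joint_anova(sim$trial))
    all(full$p[full$Source %in% c("PC1", "PC2")] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ASV reproduces its defining arithmetic and scaling law", {
  # two genotypes: scores (0, 2) and (1, 0) on axes with SS ratio 4
  gamma <- matrix(c(0, 1 / sqrt(2), 2, 0), 2, 2)
  fit <- fake_ammi(lambda = c(2, 1), gamma = gamma)
  out <- asv(fit)
  expect_equal(out$ASV, c(2, 4), tolerance = 1e-12)
  expect_equal(out$rank, c(1L, 2L))
  # homogeneity: scaling both scores by c scales ASV by c
  fit2 <- fake_ammi(lambda = c(2, 1), gamma = 3 * gamma)
  expect_equal(asv(fit2)$ASV, 3 * out$ASV, tolerance = 1e-12)
  # degenerate second axis
  fit3 <- fake_ammi(lambda = c(2, 0), gamma = gamma)
  expect_error(asv(fit3), class = "metstab_degenerate_error")
})

test_that("a genotype without interaction loadings earns the best ASV", {
  a <- c(0, 2, -1, 1.5, -2.5)           # genotype 1 carries no interaction
  b <- c(-2, 0, 1, 1)
  a2 <- c(0, 1, 2, -2, -1)
  b2 <- c(1, -1, 2, -2)
  cf <- function(i, j) 150 + 2 * i + 3 * j + 4 * a[i] * b[j] + a2[i] * b2[j]
  fit <- fit_ammi(make_trial(5, 4, 2, cellfun = cf))
  expect_equal(asv(fit)$rank[1], 1L)
  wb <- waas(fit)
  expect_lt(wb$table$WAAS[1], min(wb$table$WAAS[-1]))
})

test_that("biplot coordinates encode means, scores and vector angles", {
  a <- c(0, 2, -1, 1.5, -2.5); b <- c(-2, 0, 1, 1)
  cf <- function(i, j) 150 + 2 * i + 3 * j + 4 * a[i] * b[j]
  tr <- make_trial(5, 4, 2, cellfun = cf)
  fit <- fit_ammi(tr)
  co1 <- ammi_biplot_coords(fit, "AMMI1")
  cm <- cell_means(tr)
  expect_equal(co1$genotypes$x, unname(cm$gen_means))
  expect_equal(co1$genotypes$y[1], 0, tolerance = 1e-9)  # no-GEI genotype
  # additive data: AMMI2 coordinates collapse to the origin
  co2 <- ammi_biplot_coords(fit_ammi(make_trial(4, 4, 2)), "AMMI2")
  expect_lt(max(abs(c(co2$genotypes$x, co2$genotypes$y))), 1e-6)
  expect_error(ammi_biplot_coords(fit, "AMMI2", axes = c(1, 9)),
               class = "metstab_value_error")
  # duplicated environment columns of the centered matrix: angle 0
  b3 <- c(1, 1, -1, -1)                  # E1 and E2 identical loadings
  cf3 <- function(i, j) 150 + 2 * i + 3 * j + a[i] * b3[j]
  co3 <- ammi_biplot_coords(fit_ammi(make_trial(5, 4, 2, cellfun = cf3)),
                            "AMMI2")
  expect_equal(co3$env_angles["E01", "E02"], 0, tolerance = 1e-6)
})
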