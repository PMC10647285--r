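make_vc <- function(gen, gei, err, rep = 0, e = 12, r = 3) {
  structure(list(sigma2_gen = gen, sigma2_gei = gei, sigma2_err = err,
                 sigma2_rep = rep, sigma2_env = 0, method = "EMS",
                 truncated = c(gen = FALSE, gei = FALSE, err = FALSE),
                 g = 42, e = e, r = r),
            class = "variance_components")
}

test_that("EMS components vanish (truncated) when the data carry no signal", {
  tr <- make_trial(8, 5, 3, cellfun = function(i, j) 100 + 3 * j,
                   noise_sd = 4, seed = 2)
  vc <- variance_components(tr, "EMS")
  # no genotype or interaction signal: estimates near 0, never negative
  expect_gte(vc$sigma2_gen, 0)
  expect_gte(vc$sigma2_gei, 0)
  expect_lt(vc$sigma2_gen, 4)
  expect_lt(vc$sigma2_gei, 8)
  expect_equal(vc$sigma2_err, attr(joint_anova(tr), "ms_res"))
})

test_that("EMS and REML agree on balanced data", {
  sim <- simulate_met(sim_config(g = 10, e = 5, r = 3, mu = 500,
                                 sigma2_env = 800, sigma2_rep = 200,
                                 sigma2_gen = 900, sigma2_gei = 700,
                                 sigma2_err = 1200, gei_rank = 2, seed = 9))
  ems <- variance_components(sim$trial, "EMS")
  reml <- variance_components(sim$trial, "REML")
  for (f in c("sigma2_gen", "sigma2_gei", "sigma2_err"))
    expect_equal(reml[[f]], ems[[f]], tolerance = 1e-6)
})

test_that("heritability follows its defining ratios on both bases", {
  expect_equal(heritability(make_vc(1, 0, 0)), 1)
  expect_equal(heritability(make_vc(1, 0, 0), basis = "plot"), 1)
  expect_equal(heritability(make_vc(1, 1, 1, e = 12, r = 3)),
               1 / (1 + 1 / 12 + 1 / 36))
  expect_equal(heritability(make_vc(1, 1, 1), basis = "plot"), 1 / 3)
  expect_true(is.na(heritability(make_vc(0, 0, 0))))
})

test_that("a simulation dialed to a target entry-mean heritability recovers it", {
  # VG = 1000, gei = 600, err = 1800, e = 8, r = 3: H2 = 1000 / (1000 +
  # 600/8 + 1800/24) = 0.8695...
  target <- 1000 / (1000 + 600 / 8 + 1800 / 24)
  h2 <- vapply(1:40, function(s) {
    sim <- simulate_met(sim_config(g = 30, e = 8, r = 3, mu = 500,
                                   sigma2_env = 500, sigma2_rep = 100,
                                   sigma2_gen = 1000, sigma2_gei = 600,
                                   sigma2_err = 1800, gei_rank = 2,
                                   seed = s))
    fit_blup(sim$trial)$H2
  }, 0)
  expect_lt(abs(mean(h2) - target), 0.02)
})

test_that("BLUP shrinkage has the closed balanced form and its limits", {
  sim <- simulate_met(sim_config(g = 8, e = 5, r = 3, mu = 400,
                                 sigma2_gen = 800, sigma2_gei = 500,
                                 sigma2_err = 900, gei_rank = 2, seed = 4))
  bl <- fit_blup(sim$trial)
  cm <- cell_means(sim$trial)
  vc <- bl$vc
  c_g <- vc$sigma2_gen /
    (vc$sigma2_gen + vc$sigma2_gei / 5 + vc$sigma2_err / 15)
  expect_equal(bl$c_g, c_g)
  expect_equal(bl$blup_g, c_g * (cm$gen_means - cm$grand_mean))
  expect_lt(abs(sum(bl$blup_g)), 1e-8)
  expect_lt(max(abs(rowSums(bl$blup_ge))), 1e-8)
  expect_true(bl$c_g >= 0 && bl$c_g <= 1 && bl$c_ge >= 0 && bl$c_ge <= 1)
  # no residual noise: the interaction BLUP is the raw centered matrix
  bl0 <- fit_blup(sim$trial, vc = make_vc(800, 500, 0, e = 5, r = 3))
  expect_equal(bl0$c_ge, 1)
  # and with no interaction either, genotype BLUPs are the raw deviations
  bl00 <- fit_blup(sim$trial, vc = make_vc(800, 0, 0, e = 5, r = 3))
  expect_equal(bl00$c_g, 1)
  expect_equal(bl00$blup_g, cm$gen_means - cm$grand_mean)
  # no genotypic variance: all genotype BLUPs are zero
  blv <- fit_blup(sim$trial, vc = make_vc(0, 500, 900, e = 5, r = 3))
  expect_true(all(blv$blup_g == 0))
})

test_that("shrinkage lowers the error of genotype-mean prediction", {
  err_raw <- err_blup <- numeric(40)
  for (s in 1:40) {
    sim <- simulate_met(sim_config(g = 30, e = 6, r = 2, mu = 500,
                                   sigma2_env = 400, sigma2_rep = 100,
                                   sigma2_gen = 200, sigma2_gei = 300,
                                   sigma2_err = 3000, gei_rank = 2,
                                   seed = s))
    cm <- cell_means(sim$trial)
    bl <- fit_blup(sim$trial)
    truth <- sim$truth$gen_eff
    err_raw[s] <- mean((cm$gen_means - cm$grand_mean - truth)^2)
    err_blup[s] <- mean((bl$blup_g - truth)^2)
  }
  expect_lt(mean(err_blup), mean(err_raw))
})

test_that("WAASB and WAAS follow the weighted-absolute-score formula", {
  # fabricated scores: |s| = (3, 1) on two axes with equal energy
  gamma <- matrix(c(3 / sqrt(2), 0, -1, 0.5), 2, 2)
  fit <- fake_ammi(lambda = c(2, 1), gamma = gamma)
  # axis scores: sqrt(2)*gamma1 = (3, 0); sqrt(1)*gamma2 = (-1, 0.5)
  ep <- c(4, 1) / 5
  out <- waas(fit)
  expect_equal(out$table$WAAS,
               (abs(c(3, 0)) * ep[1] + abs(c(-1, 0.5)) * ep[2]) / sum(ep))
  out1 <- waas(fit, 1)
  expect_equal(out1$table$WAAS, c(3, 0))          # p = 1: |first score|
  expect_equal(unname(out$by_p[, 1]), c(3, 0))
  # equal-energy case from first principles
  fit2 <- fake_ammi(lambda = c(1, 1),
                    gamma = matrix(c(3, 0, 1, 0), 2, 2))
  expect_equal(waas(fit2)$table$WAAS[1], 2)
  expect_error(waas(fit, 99), class = "metstab_value_error")
})

test_that("WAASB ranking is what WAAS gives when shrinkage is uniform", {
  sim <- simulate_met(sim_config(g = 10, e = 5, r = 3, mu = 400,
                                 sigma2_gen = 500, sigma2_gei = 900,
                                 sigma2_err = 700, gei_rank = 2, seed = 13))
  wb <- waasb(fit_blup(sim$trial))
  wa <- waas(fit_ammi(sim$trial))
  expect_gt(cor(wb$table$rank, wa$table$rank, method = "spearman"), 0.9)
  expect_true(all(wb$table$WAASB >= 0))
  expect_equal(dim(wb$rank_by_p), c(10, 4))
  expect_true(all(apply(wb$rank_by_p, 2, sort) == 1:10))
})

test_that("WAASBY blends rescaled yield and stability with stated weights", {
  w <- c(A = 2, B = 10, C = 5)    # smaller WAASB = more stable
  y <- c(A = 80, B = 100, C = 60)
  out <- waasby(w, y, theta_y = 65)
  # A: rY = (80-60)/(100-60)*100 = 50, rW = (10-2)/8*100 = 100
  expect_equal(out$WAASBY[out$genotype == "A"],
               (65 * 50 + 35 * 100) / 100)
  # B: max yield (rY = 100) but least stable (rW = 0): 65 at weights 65/35
  expect_equal(out$WAASBY[out$genotype == "B"], 65)
  # C: min yield, rW = (10-5)/8*100 = 62.5
  expect_equal(out$WAASBY[out$genotype == "C"], 35 * 62.5 / 100)
})

test_that("WAASBY limits, errors and monotonicity behave", {
  w <- c(A = 1, B = 5, C = 10)
  y <- c(A = 100, B = 80, C = 60)
  out <- waasby(w, y)
  expect_equal(out$WAASBY[1], 100)     # best on both axes, any weights
  expect_equal(waasby(w, y, theta_y = 10)$WAASBY[1], 100)
  # yield-only weights reproduce the yield ranking
  expect_equal(waasby(w, y, theta_y = 100)$rank,
               unname(rank(-y, ties.method = "first")))
  # stability-only weights reproduce the WAASB ranking
  expect_equal(waasby(w, y, theta_y = 0)$rank,
               unname(rank(w, ties.method = "first")))
  expect_error(waasby(w, y, theta_y = 60, theta_s = 60),
               class = "metstab_value_error")
  expect_error(waasby(w, c(50, 50, 50)), class = "metstab_value_error")
  # raising one genotype's yield never lowers its WAASBY at theta_y > 0
  set.seed(3)
  for (i in 1:10) {
    w0 <- runif(6); y0 <- runif(6, 50, 150)
    base <- waasby(w0, y0, theta_y = 65)$WAASBY[2]
    y1 <- y0; y1[2] <- y1[2] + 10
    expect_gte(waasby(w0, y1, theta_y = 65)$WAASBY[2], base - 1e-10)
  }
})

test_that("the weight-scenario grid spans stability-only to yield-only", {
  w <- c(A = 1, B = 5, C = 10, D = 3)
  y <- c(A = 100, B = 80, C = 90, D = 60)
  sc <- weight_scenarios(w, y, step = 5)
  expect_equal(dim(sc), c(4, 21))
  expect_equal(colnames(sc), as.character(seq(0, 100, 5)))
  expect_equal(unname(sc[, "0"]), unname(rank(w, ties.method = "first")))
  expect_equal(unname(sc[, "100"]),
               unname(rank(-y, ties.method = "first")))
  expect_true(all(sc["A", ] == 1))     # best on both axes everywhere
  expect_error(weight_scenarios(w, y, step = 7),
               class = "metstab_value_error")
})

test_that("quadrant classification uses the documented boundary convention", {
  w <- c(1, 1, 10, 10)
  y <- c(100, 60, 100, 60)
  q <- classify_quadrants(w, y)
  expect_equal(q$quadrant, c("IV", "III", "II", "I"))
  # a genotype exactly at both means lands in quadrant II (>= convention)
  q2 <- classify_quadrants(c(2, 2, 2), c(50, 50, 50))
  expect_true(all(q2$quadrant == "II"))
  # the (max yield, min WAASB) genotype is always in IV
  expect_equal(q$quadrant[which.max(y * (w == min(w)))], "IV")
})

test_that("rank-profile clustering groups identical and separated profiles", {
  m <- rbind(p1 = c(1, 1, 1, 2), p2 = c(1, 1, 1, 2),
             p3 = c(9, 9, 8, 9), p4 = c(9, 8, 9, 9))
  cl <- cluster_rank_profiles(m, k = 2)
  expect_equal(cl[["p1"]], cl[["p2"]])
  expect_equal(cl[["p3"]], cl[["p4"]])
  expect_true(cl[["p1"]] != cl[["p3"]])
  # permutation invariance up to label renaming
  perm <- c(3, 1, 4, 2)
  clp <- cluster_rank_profiles(m[perm, ], k = 2)
  expect_equal(unname(clp[rownames(m)] == clp[["p1"]]),
               unname(cl == cl[["p1"]]))
  expect_error(cluster_rank_profiles(m, 0), class = "metstab_value_error")
  expect_error(cluster_rank_profiles(m, 9), class = "metstab_value_error")
})
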