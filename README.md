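# metstab

Multi-model genotype-by-environment (GEI) stability analysis for balanced
multi-environment yield trials (METs), written for plant breeders and
quantitative geneticists who need to pick high-yielding *and* stable
genotypes from replicated trials run across locations, seasons and sowing
regimes.

## What it computes

For a balanced trial `y_ger = mu + E_e + R_r(e) + G_g + (GE)_ge + eps_ger`
(g genotypes x e environments x r replicates):

- **Joint ANOVA + AMMI.** Additive main effects plus an SVD of the
  doubly-centered interaction residuals
  `Z_ge = ybar_ge - ybar_g. - ybar_.e + ybar..` = sum_k lambda_k
  gamma_gk delta_ek. Each interaction principal component axis (IPCA) k is
  F-tested with Gollob degrees of freedom `g + e - 1 - 2k` against the
  pooled residual, with its share of the GEN:ENV sum of squares
  (`SS_k = r lambda_k^2`). AMMI stability values
  `ASV_g = sqrt((SS1/SS2 * s_g1)^2 + s_g2^2)` and AMMI1/AMMI2 biplot
  coordinates are derived from the same fit.
- **BLUP / WAASB / WAASBY.** Variance components by closed-form expected
  mean squares (or REML via lme4), broad-sense heritability
  `H^2 = VG/VP` (entry-mean or plot basis), shrinkage BLUPs of genotype
  and interaction effects, the weighted average of absolute IPCA scores of
  the BLUP interaction matrix (WAASB, smaller = more stable), and the
  simultaneous selection index `WAASBY = (theta_Y rY + theta_S rW)/100`
  (default weights 65/35), with rankings across the whole 0..100 weight
  grid, yield/stability quadrants and Ward clusters of rank profiles.
- **RMSPD cross-validation.** One replicate per environment held out at
  random; AMMI0..AMMIF and BLUP predictors are ranked by the root mean
  square prediction difference over the held-out observations.
- **GGE biplot patterns** (environment-centered SVD, configurable
  centering/scaling/singular-value partitioning) as coordinate and ranking
  tables: which-won-where sectors, mean vs stability along the
  average-environment axis, ranking against the ideal genotype,
  discriminativeness vs representativeness, pairwise genotype comparison,
  per-genotype environment evaluation. Every geometric rule is tested
  against the rank-2 algebraic reconstruction it visualizes.
- **Stress/stability indices.** Fischer-Maurer heat susceptibility index
  `S = (1 - Yh/Yn)/(1 - Xh/Xn)` with tolerance classes, the Annicchiarico
  recommendation index `omega_g = mean(p_ge) - z_(1-alpha) sd(p_ge)`, and
  the environmental index `I_e = ybar_.e - ybar..`.
- **A synthetic MET generator** with known truth (variance components,
  low-rank interaction, per-genotype heat reductions) so that every stage
  is testable; its defaults emulate a 42 x 12 x 3 chickpea-scale trial
  (grand mean 174.5 g/plot, residual CV about 37.5%).

## Worked example

```r
library(metstab)
sim <- suppressWarnings(simulate_met(sim_config(seed = 42)))   # 42 x 12 x 3
res <- run_met_stability(trial = sim$trial, n_resamples = 200, seed = 42)
res
#> MET stability pipeline: 42 genotypes, 12 environments, 3 replicates
#>   WAASBY weights: 65 / 35
#>   top genotypes by WAASBY:
#>  genotype     mean    WAASB   WAASBY quadrant
#>       G09 267.1181 1.231041 94.96808       IV
#>       G24 234.7242 1.012940 85.45099       IV
#>       G25 247.7059 1.777091 83.10945       IV
#>       G07 261.7794 2.504651 81.48836       II
#>       G20 258.4924 2.580016 79.63586       II
```

G09 combines the near-best mean yield with a small WAASB, so it tops the
65/35 blend and sits in quadrant IV (productive and stable); G07 yields
slightly less and is noticeably less stable, landing in quadrant II.

The ANOVA with the Gollob partition of the interaction:

```r
head(as.data.frame(res$anova), 7)
#>     Source  Df        SS         MS         F             p Proportion
#> 1      ENV  11 3653767.3 332160.664  7.461002  2.149961e-05         NA
#> 2 REP(ENV)  24 1068469.9  44519.581 11.033387  5.957942e-37         NA
#> 3      GEN  41 3369387.3  82180.179 20.366898 1.181527e-103         NA
#> 4  GEN:ENV 451 4179802.0   9267.854  2.296873  2.772949e-27         NA
#> 5      PC1  51 1505055.4  29510.891  7.313750  2.389071e-41   36.00782
#> 6      PC2  49  760974.4  15530.089  3.848857  2.605855e-16   18.20599
#> 7      PC3  47  433117.9   9215.274  2.283842  3.243452e-06   10.36216
```

The df column (11, 24, 41, 451, then 51, 49, 47, ...) is fixed by the
42 x 12 x 3 layout; the F for ENV uses REP(ENV) as its denominator, the
rest use the pooled residual. Cross-validation ranks the candidate
predictors by median RMSPD (here low-rank AMMI and the BLUP predictor
lead, the full-rank AMMIF overfits):

```r
head(summarize_cv(res$cv), 4)
#>           model   median     mean       sd rank
#> AMMI2     AMMI2 80.89308 81.01695 3.229950    1
#> BLUP_ge BLUP_ge 81.71481 81.69637 2.706520    2
#> AMMI1     AMMI1 82.03031 81.93874 3.162426    3
#> AMMI3     AMMI3 82.10451 82.06677 3.129593    4
```

Entry-mean heritability for this run is `res$blup$H2 = 0.8872` and the
residual CV is 35.5%. See `vignettes/met-stability.Rmd` for the methods
and modelling choices.

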