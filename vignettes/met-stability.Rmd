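---
title: "Multi-model stability analysis of multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model stability analysis of multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The model and its assumptions

Everything in this package starts from the balanced two-way-with-replicates
model for a multi-environment trial (MET),

$$y_{ger} = \mu + E_e + R_{r(e)} + G_g + (GE)_{ge} + \varepsilon_{ger},$$

with $g$ genotypes, $e$ environments and $r$ replicates nested within
environments, and yields recorded in g/plot. Balance is assumed
throughout: unbalanced data are rejected rather than imputed, because the
exact degrees-of-freedom partition (and the closed-form shrinkage BLUPs)
presume it. Environments and replicates are treated as fixed; genotypes
and the interaction are the random, selectable part.

### AMMI and the Gollob tests

`fit_ammi()` double-centers the cell means,
$Z_{ge} = \bar y_{ge} - \bar y_{g.} - \bar y_{.e} + \bar y_{..}$, and
takes its SVD $Z = \sum_k \lambda_k \gamma_k \delta_k^\top$. The per-axis
F-tests appended by `gollob_test()` use Gollob's rule
$\mathrm{df}_k = g + e - 1 - 2k$, with $SS_k = r\lambda_k^2$ (replicate
scale, so the axes partition the GEN:ENV sum of squares of the joint
ANOVA exactly) and the pooled residual mean square as the denominator.
The environment main effect is tested against REP(ENV); genotype and
interaction against the residual. These conventions were chosen because
they make the printed partition internally consistent: the axis df sum to
$(g-1)(e-1)$ and the axis SS sum to the interaction SS.

Two numerical conventions matter for reproducibility:

* **Sign fixing.** The SVD sign ambiguity is resolved by making the
  largest-magnitude environment score on each axis positive.
* **Score scaling.** Biplot scores, ASV and the WAAS/WAASB indices use the
  symmetric split $s_{gk} = \sqrt{\lambda_k}\,\gamma_{gk}$ (and likewise
  for environments). The literature is not unanimous here; the symmetric
  convention keeps genotype and environment markers on one scale.

`asv()` implements the Purchase-style AMMI stability value
$\mathrm{ASV}_g = \sqrt{(SS_1/SS_2 \cdot s_{g1})^2 + s_{g2}^2}$. It is
undefined when the second axis is null (the weight $SS_1/SS_2$ diverges),
and the function says so rather than returning a number. Rank ties are
broken by genotype order, which is documented rather than silent.

### Variance components, BLUP, WAASB

For balanced data the expected-mean-square (EMS) equations have the
closed-form solution

$$\hat\sigma^2_\varepsilon = MS_{res},\quad
  \hat\sigma^2_{ge} = (MS_{GE} - MS_{res})/r,\quad
  \hat\sigma^2_{g} = (MS_{G} - MS_{GE})/(re),$$

with negative estimates truncated to zero and flagged (standard practice;
the truncation is reported, not hidden). The REML route fits
`y ~ 0 + env:rep + (1|gen) + (1|gen:env)` with lme4 and is required by the
test suite to agree with EMS to within $10^{-6}$ relative on balanced
data — a cross-check of both routes, run with a tightened optimizer
tolerance since the default stopping rule is coarser than that bound.

Broad-sense heritability is $H^2 = V_G/V_P$. The default basis is the
**entry mean**, $V_P = V_G + \sigma^2_{ge}/e + \sigma^2_\varepsilon/(re)$,
i.e. the repeatability of a genotype mean over the whole trial; the plot
basis $V_P = V_G + \sigma^2_{ge} + \sigma^2_\varepsilon$ is available. For
high-CV field trials the entry-mean basis is the one under which reported
heritabilities in the 70–90% range are plausible, which is why it is the
default.

`fit_blup()` uses the balanced shrinkage forms
$\mathrm{BLUP}_g = c_g(\bar y_{g.} - \bar y_{..})$ with
$c_g = V_G/(V_G + \sigma^2_{ge}/e + \sigma^2_\varepsilon/(re))$ and
$\mathrm{BLUP}_{ge} = c_{ge} Z_{ge}$ with
$c_{ge} = \sigma^2_{ge}/(\sigma^2_{ge} + \sigma^2_\varepsilon/r)$. Note
that $c_g < 1$ whenever the interaction variance is positive, even with
zero residual noise: the interaction acts as noise on genotype means. With
$\sigma^2_\varepsilon = 0$ the interaction BLUP equals the raw centered
matrix exactly.

`waasb()` takes the SVD of the BLUP interaction matrix and computes the
weighted average of absolute scores,
$\mathrm{WAASB}_g = \sum_{k \le p} |s_{gk}| EP_k / \sum_{k \le p} EP_k$,
with $EP_k$ the axis's explained proportion. The default retains **all**
axes, but the full ranking-by-$p$ table is always emitted because the
ranking can be unstable for small $p$ (typically up to about four axes).
Because the balanced interaction BLUP is a uniform rescaling of $Z$
($c_{ge}$ is a scalar), WAASB and the fixed-effect WAAS produce identical
rankings here; the two entry points are kept separate because they
diverge under unbalanced/heteroscedastic extensions.

`waasby()` rescales yield (100 = best) and WAASB (100 = most stable) to
[0, 100] and blends them with percentage weights (default 65 yield / 35
stability). Constant input vectors make the rescaling undefined and raise
an error with a message, rather than producing NaN. Quadrants split at
the two means with a `>=` convention on both axes (a genotype exactly at
both means is "high-yield, unstable", quadrant II). Rank-profile clusters
use Ward linkage (`ward.D2`) on Euclidean distances between scenario-rank
rows with $k = 4$ groups by default — the algorithm, distance and $k$ are
all configurable since no single choice is canonical.

### RMSPD cross-validation

`rmspd_cv()` holds out one replicate per environment (chosen uniformly at
random each resample), fits every candidate model on the cell means of the
remaining replicates, and scores
$\mathrm{RMSPD} = \sqrt{\tfrac{1}{ge}\sum (\hat y_{ge} - y^{val}_{ge})^2}$
against the held-out **observations** (not their means). This
leave-one-replicate-per-environment scheme keeps the modeling set balanced
so that all models see the same design; the scheme tag is recorded in the
output. The default of 1000 resamples is configurable (tests use 200).
BLUP predictors need the modeling set to retain a residual stratum, hence
$r \ge 3$ overall for those labels; two BLUP variants are provided because
"prediction with genotype BLUPs" is ambiguous: `BLUP_g` predicts cells
from genotype BLUPs and environment means only, `BLUP_ge` adds the
interaction BLUPs.

### GGE patterns

`fit_gge()` centers by environment (default), so the matrix retains
genotype main effects plus interaction — the "G + GE" that gives GGE its
name — and takes the SVD. Coordinates on axes 1–2 follow the singular
value partitioning: genotype-focused ($U\Lambda$, $V$),
environment-focused ($U$, $V\Lambda$) or symmetric
($U\Lambda^{1/2}$, $V\Lambda^{1/2}$). Default SVP per pattern follows
common practice for these displays: symmetric for which-won-where,
environment-focused for mean-vs-stability, genotype ranking and
discriminativeness (all overridable). Null axes get zero coordinates, so
a zero matrix yields all-zero markers under every SVP.

The central correctness property — enforced by the test suite on random
matrices — is that every geometric decision rule agrees with the rank-2
algebraic reconstruction $\hat M = U_2 \Lambda_2 V_2^\top$:

* which-won-where sector winners equal $\arg\max_g \hat M_{ge}$;
* pairwise-comparison sides equal $\mathrm{sign}(\hat M_{g_1 e} - \hat M_{g_2 e})$;
* per-genotype environment calls equal $\mathrm{sign}(\hat M_{ge})$.

These identities hold for every SVP because the per-axis scalings multiply
to $\lambda_k$ in all three. Sector assignment is computed in angle space
around the origin (robust to hull edges that do not face the origin);
boundary ties go to the counterclockwise sector; hulls with fewer than
three distinct, non-collinear genotype markers fall back to the direct
argmax with a `degenerate` flag.

### Indices

The heat susceptibility index is
$S_g = (1 - Y^h_g/Y^n_g) / (1 - X^h/X^n)$, computed per normal/late
environment pair; pairs are formed from environment metadata by matching
(location, year) with opposite sowing labels, and the pairing table is
emitted for audit. An across-pairs mean HSI is also reported, flagged as a
derived summary. Tolerance classes use the conventional printed
boundaries (< 0.50 highly tolerant, 0.51–0.75 tolerant, 0.76–1.00
moderately tolerant, > 1.00 susceptible); values in the printed gaps are
assigned downward, so 0.505 is still "highly tolerant". Whether such
indices should be computed from cell means or BLUPs is genuinely open; we
use cell means, the simpler and more common choice.

The Annicchiarico recommendation index expresses yields as percentages of
each environment mean and subtracts a confidence multiple of their
standard deviation ($e - 1$ denominator):
$\omega_g = \bar p_g - z_{1-\alpha} s_g$. The confidence coefficient
defaults to $\alpha = 0.25$ ($z \approx 0.6745$), the method's original
choice, and is configurable.

## The synthetic generator

`simulate_met()` draws each term of the model from a zero-mean Gaussian
and then **standardizes the genotype, environment and interaction draws to
their exact target sums of squares** ($(g-1)\sigma^2_g$, etc.). The
interaction is built as a low-rank factor matrix (default rank 4, axis
energies decaying 0.4/0.3/0.2/0.1) and double-centered; the row and
column margins of the raw draw are folded back into the main effects,
each margin standardized to the sum of squares that classical
expected-mean-square algebra attributes to interaction leakage
($(g-1)\sigma^2_{ge}/e$ for genotypes). This is a deliberate design
choice: with a double-centered interaction truth and *no* folded margins,
the textbook EMS estimator of $\sigma^2_g$ would be biased by
$-\sigma^2_{ge}/e$ on the generator's own data, and parameter-recovery
tests would conflate generator artifacts with estimator defects. With the
folding, all three EMS estimators are exactly unbiased under the
generator, which the suite verifies to within three standard errors over
200 seeds.

Default parameters are back-derived from the joint-ANOVA mean squares of
a published chickpea-scale landrace trial layout (42 genotypes, 12
environments, 3 replicates): grand mean 174.5 g/plot,
$\sigma^2_\varepsilon = 4273$, $\sigma^2_{ge} = 2120$,
$\sigma^2_g = 2174$, $\sigma^2_{rep} = 799$, $\sigma^2_{env} = 2701$
(g²/plot²), giving a residual CV near 37.5% and sum-of-squares shares of
roughly 18.5% environment, 4% replication, 16.2% genotype and 21.3%
interaction. These are defaults describing a realistic trial, not
requirements. Negative simulated yields are truncated at zero with a
warning (yields are physical quantities); under the default, high-CV
configuration this affects several percent of observations and slightly
perturbs realized means and variance shares, which is why the share-
recovery test uses a three-percentage-point Monte-Carlo band.

`simulate_heat_pairs()` multiplies each genotype's normal-sown cell
expectations by $(1 - d_g)$ for the late sowing, so the true HSI is known
in closed form and class-recovery can be scored exactly.

**What the generator does not emulate:** alpha-lattice incomplete-block
structure (replicates are complete blocks here), spatial field trend,
non-Gaussian error, weather-driven environment covariates, and
unbalanced designs. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to these
real-data complications.

## Problem sizes used in the test suite

Deterministic identities are checked on small random trials
($g \le 10$, $e \le 8$). Stochastic recovery uses 200 seeds of a
60 × 12 × 3 trial for variance components, 30 seeds for the
WAASB-vs-truth rank correlation, 100 seeds for HSI class recovery, and
50 independent experiments of 200 resamples each for the
cross-validation ordering — sizes chosen so that Monte-Carlo error is
well below the asserted margins while the whole suite stays quick.

## Known limitations

* Balanced trials only; no EM-style imputation of missing cells.
* REML is provided as a cross-check on balanced data, not as an engine
  for unbalanced designs.
* The GGE patterns use axes 1–2 only, as the displays they tabulate are
  two-dimensional.
* With balanced data and a scalar interaction shrinkage, WAAS and WAASB
  rankings coincide by construction; differences between them only appear
  under extensions this package does not implement.
* One printed-convention discrepancy is resolved in favour of the
  formula: the Gollob df of axis 1 of a 3 × 3 trial is
  $3 + 3 - 1 - 2 = 3$ (so that the two axes' df sum to
  $(g-1)(e-1) = 4$).
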