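---
title: "Methods: lactation-curve genetics by single-step GWAS"
author: "lactgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lactation-curve genetics by single-step GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models, the
numerical choices behind them, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open and a
choice had to be made.

## 1. The lactation curve and its derived traits

Daily milk yield at $t$ days in milk (DIM) is modelled as

$$y(t) = a\left(1 - \tfrac{1}{2}e^{(c-t)/b}\right)e^{-dt},$$

with scale $a$ (kg/day; theoretical maximum daily yield), ramp $b$
(days; rate of rise in early lactation), offset $c$ (days; lag between
parturition and the onset of secretion) and decay $d$ (1/day; rate of
senescence of secretory capacity). Decay is stored in natural units
everywhere; the "$\times 1000$" convention seen in summary tables is
applied only when printing.

Setting $dy/dt = 0$ gives $e^{(c-t)/b} = 2db/(db+1)$, hence

$$t_{\text{peak}} = -b\,\log\frac{2db}{db+1} + c ,$$

valid when $db < 1$; otherwise the curve declines from $t = 0$ and the
peak traits are undefined (flagged `NA`). Published renderings of this
expression are typographically ambiguous, so the package treats the
stationarity condition as the definition and the test suite verifies
the formula against a numeric arg-max oracle over random parameter
draws rather than trusting any printed form. Peak yield is the curve
evaluated at $t_{\text{peak}}$, and the 305-day yield is the exact
integral

$$M305 = \frac{a(1 - e^{-305d})}{d}
  + \frac{ab\,e^{c/b}\left(e^{-305(1/b+d)} - 1\right)}{2(1+bd)},$$

checked against adaptive quadrature to $10^{-6}$ relative error over
1,000 random draws. An overflow guard rejects $c/b > 500$.

### Fitting

`fit_milkbot()` minimizes the residual sum of squares by bounded
Levenberg–Marquardt (via minpack.lm) with the analytic Jacobian.
Choices the data do not dictate:

* **Starting values** — $a_0 = 1.05\times$ max observed yield,
  $b_0 = 20$ d, $c_0 = 0$, $d_0$ from the log-ratio of early to late
  mean yield over the elapsed days (clamped to $[10^{-5}, 0.05]$).
  Stable across the simulated range; three multiplicative jittered
  restarts on failure.
* **Parameter box** — $a \in (0, 200]$ kg/day, $b \in [5, 100]$ d,
  $c \in [-15, 15]$ d, $d \in (0, 0.05]$ /day. The $(b, c)$ pair is
  weakly identified when the first record falls after the ramp: an
  unconstrained fit can drift to $b \to 0$, $c > 0$ curves that pass
  through every observed test day yet diverge wildly below the first
  DIM, corrupting M305 (in simulation roughly 1–2% of lactations land
  on this degenerate branch). The box keeps fits on the biological
  branch; its limits are several genetic standard deviations beyond
  the simulated trait means.
* **Minimum data** — 5 test days (four free parameters) spanning at
  least 100 DIM; lactations below either limit are skipped with a
  logged reason, and unconverged fits are flagged and excluded
  downstream.

## 2. Relationship matrices

`a_matrix()` implements the tabular method (diagonals $1 + F$);
`inbreeding()` is its by-product. `g_matrix()` builds
$G = ZDZ'/\sum_i 2p_i(1-p_i)$ with $Z$ the dosage matrix centered by
$2p_i$ and $D$ positive SNP weights. Allele frequencies are computed
from the observed genotyped sample — base-population frequencies are
unavailable in practice, and this matches common single-step usage.
SNP with MAF below 5% (sample frequency) are excluded; markers exactly
at the threshold are retained.

`tune_and_blend()` solves the $2\times2$ system making the mean
diagonal and mean off-diagonal of $\alpha + \beta G$ equal those of
$A_{22}$, then returns
$G^* = (1-w)\,G_{\text{tuned}} + w\,A_{22}$ with $w = 0.05$ by
default. Blending is a guard against singular $G$ (more animals than
markers, duplicated genotypes); $w = 0$ is allowed, and
`h_inverse()` refuses a $G^*$ whose condition number exceeds
$10^{12}$ with a message suggesting a larger blend. With no genotyped
animals, or $G^* = A_{22}$ exactly, $H^{-1}$ reduces to $A^{-1}$
(asserted in tests to $10^{-8}$).

All algebra is dense base-R linear algebra; the intended scale is a
few tens of thousands of animals at most, and the test/acceptance
populations use 700–2,200.

## 3. AI-REML

`build_mme()` assembles Henderson's equations with the additive block
penalized by $H^{-1}\sigma_e^2/\sigma_a^2$ and, for repeated records,
an identity-structured permanent-environment block. The incidence of
records on animals is held as an index vector, never a dense $Z$.
Aliased fixed-effect columns are dropped by QR so the system is full
rank; an animal with records but absent from $H$ is an error naming
the ids.

`aireml()` maximizes the restricted likelihood with:

* **Gradients and likelihood from the MME factorization** — the trace
  identities $\sigma_a^2\,\mathrm{tr}(PZHZ') = q -
  \mathrm{tr}(H^{-1}C^{aa})/\sigma_a^2$ (and analogues) make every
  derivative available from one Cholesky factorization and inverse of
  the coefficient matrix per iteration; the same inverse later yields
  prediction error variances.
* **AI updates** — the average-information matrix is
  $\tfrac{1}{2}F'PF$ with $F$'s columns $Z\hat a/\sigma_a^2$,
  $W\hat p/\sigma_p^2$, $\hat e/\sigma_e^2$; each $Pf$ column comes
  from re-solving the MME with $f$ as data. Step-halving (up to 12
  halvings) rejects steps that leave the parameter space or decrease
  the likelihood; if no AI step is accepted the iteration falls back
  to an EM-REML update, which cannot decrease the likelihood. The
  trace keeps every accepted iterate, and a test asserts monotonicity.
* **Constraints and convergence** — components are floored at
  $10^{-8}\times$ the phenotypic variance; convergence requires
  relative parameter change $< 10^{-8}$ and the scaled gradient norm
  $\lVert g_i\theta_i\rVert < 10^{-6}$, with a 200-iteration cap.
  Starting values split the phenotypic variance 50/50 (20% to the PE
  term when present).

Correctness anchors: exact agreement with direct GLS/BLUP (via
$V^{-1}$) on small systems; exact agreement with the closed-form
ANOVA/intraclass solution on a balanced one-way design; $h^2 \to 1$ on
near-noise-free additive data and $\approx 0$ when the
pedigree–phenotype link is destroyed. Under the null the
positivity-constrained estimate is biased upward by $O(SE)$, so the
null check runs at a population size (~700) where that bias sits well
below the 0.05 bound.

**Bivariate REML** (`bivariate_reml()`) exists for genetic-correlation
recovery. It maximizes the same MME-based restricted likelihood over
Cholesky factors of the $2\times2$ genetic and residual covariance
matrices (log-diagonal parameterization, nlminb). This is a deliberate
departure from literal AI iterations: the Cholesky parameterization
makes both matrices positive semidefinite by construction, so the
correlation always lies in $[-1, 1]$ without ad-hoc projection, and at
the two-trait scale the optimizer's extra likelihood evaluations are
cheap. The headline pipeline path is single-trait throughout, matching
the stated evaluation model; how the original genetic correlations
were obtained (and their very small reported SDs) is not derivable
from the source, so the bivariate route is provided as a capability,
not as a reproduction.

## 4. Weighted single-step GWAS

`iterate_weights()` runs the canonical loop: $D = I$; build $G$ from
the current $D$, tune and blend; solve ssGBLUP for all animals;
back-solve $\hat u = \lambda D Z' G^{*-1}\hat a_g$; set
$d_i = \hat u_i^2\,2p_i(1-p_i)$; normalize $\sum d_i = M$; repeat.
Three iterations are run by default and iteration 2 is reported — the
iteration at which genomic evaluation accuracy peaked in the study
this pipeline follows; all iterations are retained so the choice is a
report-time parameter, not a refit. Accuracy is reported in both
conventions — $\sqrt{\max(0, 1 - \mathrm{PEV}/\sigma_a^2)}$ (default)
and the unrooted reliability — because the printed accuracy formula in
the source omits the conventional square root.

`window_variance()` tiles each chromosome into non-overlapping runs of
50 consecutive SNP (the last window may be shorter) and reports
$100\times\mathrm{Var}(\sum_{j\in w} Z_j\hat u_j)/\sigma_a^2$, the
variance taken across genotyped individuals with denominator $n-1$.
Tiling (rather than sliding) was chosen because it makes "every SNP in
exactly one window" true and window percentages comparable; a sliding
mode is available behind a flag. Because window scores are correlated
through linkage disequilibrium, the window percentages do not in
general sum to $100\times\mathrm{Var}(Z\hat u)/\sigma_a^2$; the test
suite asserts the per-window brute-force identity always, and the
exact partition on a constructed orthogonal case. Windows explaining
strictly more than 0.50% of $\sigma_a^2$ are candidates.

## 5. LD and annotation

`pairwise_r2()` computes genotypic $r^2$ (squared Pearson correlation
of dosages) for same-chromosome pairs within 200 kb; no phasing stage
exists in the pipeline, so haplotype $r^2$ is out of reach by design.
`find_blocks()` defines a block as a maximal run of consecutive
markers whose every adjacent pair has $r^2 \ge 0.7$ (configurable),
reported at length $\ge 2$. The block-calling algorithm behind the
published block counts is unstated, and confidence-interval methods
need phased haplotypes, so the adjacent-pair rule — simple, testable,
and deterministic — was adopted.

`genes_in_windows()` treats windows as half-open $[start, end)$ and
genes as 1-based inclusive intervals (GFF3 convention; BED input is
shifted on read), overlaps by $\ge 1$ bp, strand ignored.
`enrichment()` is a one-sided hypergeometric upper tail with BH
adjustment across all tested terms and a reporting filter of at least
4 candidate genes per term; the background universe is a required
explicit argument because the universe behind the original enrichment
is unstated. The test suite checks the p-values' null uniformity after
exact atom-smearing (the statistic is discrete, so a raw KS test
against $U(0,1)$ is miscalibrated).

## 6. The synthetic-data generator

`simulate_population()` emulates the structure of a multi-country
dairy data set: a random-mating pedigree with a sire team
(`simulate_pedigree`), biallelic SNP dropped through it with
recombination by Haldane's map function at 1 cM/Mb
(`drop_genotypes`), herds nested in countries, herd-year-season
contemporary groups (season = calendar quarter, 4 levels — the
conventional definition, since none is given in the source), age at
calving with linear and quadratic effects, and a parity distribution
giving roughly half primiparous records. Trait means and additive
variances of (scale, ramp, decay) default to the published
primiparous values (35.57 kg/d, 30.60 d, 0.00142 /d; variances 7.58,
0.0056, 2.228e-8); the offset $c$ is unreported there and is treated
as a nuisance parameter with small variance around 0. Environmental
effects act on the scale parameter (kg/day units) — a management
shift of the whole curve level. Test-day yields are the true curve
plus iid noise (default SD 2 kg/day, a typical test-day fit residual);
negative yields are truncated at 0 and counted.

Genetic architecture: a configurable number of markers act as QTL with
jointly normal effects rescaled so the realized QTL-score variance is
a set fraction of each trait's $\sigma_a^2$; the remainder is an
infinitesimal polygene dropped through the pedigree with
Mendelian-sampling variance $\tfrac12(1-\bar F)$ times the polygenic
covariance. The two halves matter: a purely infinitesimal trait is
statistically independent of the marker panel, so genomic
relationships deviate from the trait's true covariance as pure noise
and single-step REML mildly underestimates $\sigma_a^2$; a purely
marker-borne trait slightly overestimates it (the QTL sit inside the
panel). The heritability-recovery study therefore uses the mixed
architecture — 400 marker QTL carrying half of $\sigma_a^2$ plus an
infinitesimal remainder — which is also the standard working picture
of dairy yield traits (a handful of large regions plus a polygenic
background).

Founders are drawn in linkage equilibrium by default; setting
`n_founder_haplotypes` to a small number makes every founder gamete a
recombinant mosaic of an ancestral haplotype pool, creating baseline
LD that decays with map distance (used by the demo analysis). The
planted-block generator (`simulate_block_genotypes`) defines a block
as descent from two complementary ancestral haplotypes — within-block
adjacent $r^2$ is then 1 and blocks are unambiguous; with three or
more ancestral haplotypes adjacent $r^2$ routinely drops below 0.7
and blocks legitimately fragment, which is why the planted-block
recovery study uses two.

What the generator does **not** emulate: selection (matings are
random, so no Bulmer effect), genotyping error or missingness (no
imputation stage), recombination hotspots or interference, seasonal
calving patterns, heterogeneous herd sizes, and culling (every cow
completes her lactations). Passing tests therefore demonstrate
correctness of the estimators under a well-specified generative model,
not robustness to the messiness of field data.

## 7. Problem sizes and study conditions

Chosen once as desk-scale stand-ins for the real cohort (~21k
lactations, 566k SNP), and stated here as the package's own choices:

* Heritability recovery: 200 founders + 3×500 offspring (~1,500
  phenotyped, 800 genotyped), 2,000 SNP on 5 chromosomes of 100 Mb,
  $\sigma_a^2 = 526{,}630$, $\sigma_e^2 = 892{,}670$ (true
  $h^2 = 0.371$), HYS SD 400 kg, country SD 300 kg, age effects 30
  and −0.5 kg/month; mean $\hat h^2$ over ≥5 seeds within ±0.05.
* Planted-QTL power: ~1,550 fully genotyped animals, 1,000 SNP on 2
  chromosomes, one QTL at 10% of $\sigma_a^2$ over a 400-QTL
  background at 90%, $h^2 = 0.3$. Smaller cohorts leave the window
  estimates noise-dominated.
* Demo analysis (`analysis/`): 720 animals, 1,000 SNP, founder
  haplotype pool of 6 for visible LD.

## 8. Known limitations

Dense algebra caps the practical scale well below national
evaluations (no sparse $A^{-1}$, no APY). Missing dosages are
mean-imputed with a logged count rather than properly imputed.
Unknown-parent groups and metafounders are not implemented. The
repeatability model assumes a constant permanent-environment
covariance across parities, and age-at-calving covariates are refit in
the multiparous model rather than carried over. Single-trait REML is
the only fully hardened path; the bivariate module is for correlation
recovery at moderate scale.
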