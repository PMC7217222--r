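# lactgwas

Genetic dissection of milk lactation curves in dairy cattle: a
desk-scale, fully tested R implementation of the single-step genomic
analysis chain

    test-day records -> lactation-curve fits -> variance components
    -> weighted single-step GWAS -> LD blocks -> gene annotation

The package is aimed at quantitative geneticists who want a transparent,
hackable version of this pipeline — every matrix and estimator is
ordinary dense R code with unit tests against independent oracles — and
it ships a pedigree/gene-dropping simulator so the whole chain runs and
is testable without any proprietary data.

## The models

**Lactation curve.** Daily milk yield at *t* days in milk follows the
four-parameter MilkBot model

    y(t) = a (1 - exp((c - t)/b) / 2) e^(-d t)

with scale *a* (kg/day), ramp *b* (days), offset *c* (days) and decay
*d* (1/day). Derived traits used as GWAS phenotypes: cumulative 305-day
yield M305 (closed-form integral), peak time
t_peak = -b log(2db/(db+1)) + c, and peak yield y(t_peak). Curves are
fitted per lactation by bounded Levenberg–Marquardt least squares with
an analytic Jacobian.

**Variance components.** Single-trait animal model
y = Xb + Za + e (primiparous) or repeatability model with a
permanent-environment term (multiparous), with Var(a) = H σ²ₐ where H
merges the pedigree relationship matrix A with the VanRaden genomic
matrix G = ZDZ′ / Σ 2pᵢ(1−pᵢ) via

    H⁻¹ = A⁻¹ + [0 0; 0 G*⁻¹ − A₂₂⁻¹],

G being tuned to A₂₂'s diagonal/off-diagonal means and blended
(default 5% A₂₂). Estimation is average-information REML with
step-halving and an EM fallback; h² = σ²ₐ/σ²ₚₕₑₙ and repeatability
follow from the components.

**Weighted single-step GWAS.** SNP effects are back-solved from the
genotyped animals' GEBVs, û = λDZ′G*⁻¹â_g; weights dᵢ = ûᵢ²2pᵢ(1−pᵢ)
are renormalized and the loop repeated (three iterations, iteration 2
reported). Non-overlapping windows of 50 consecutive SNP are scored by
the percentage of additive variance their genomic score explains;
windows above 0.50% are candidate QTL regions, which are then examined
for LD blocks (adjacent-pair r² runs) and overlapping genes
(hypergeometric enrichment with BH adjustment).

## Worked example

```r
library(lactgwas)

# one lactation: true curve + noise, fit, derived traits
p <- milkbot_params(scale_a = 35.57, ramp_b = 30.60, offset_c = 0,
                    decay_d = 0.00142)
t <- seq(5, 305, by = 30)
set.seed(1)
fit <- fit_milkbot(t, milkbot_yield(p, t) + rnorm(11, 0, 1.5))
unlist(fit$params)
#>      scale_a       ramp_b     offset_c      decay_d
#> 35.000702430 28.024802576  1.572301466  0.001223606
fit$derived
#>       m305   t_peak peak_yield
#> 1 8407.987 77.61571   30.77432
```

M305 ≈ 8,408 kg is the area under the fitted curve to day 305; the cow
peaks at ~78 days in milk at ~30.8 kg/day; all three are within
sampling error of the true values (8,283 kg, 76.1 d, 30.6 kg/day).

The numbered scripts under `analysis/` run the full study on a
simulated population (720 animals, 1,000 SNP, 20 QTL) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # population + genotypes
Rscript analysis/02_fit_curves.R          # MilkBot fits, Table-1-style stats
Rscript analysis/03_variance_components.R # A/G/H + AI-REML
Rscript analysis/04_wssgwas.R             # window scan + candidates
Rscript analysis/05_ld_annotate.R         # LD blocks + genes + enrichment
```

Stage 3 prints, for this seed:

```
primiparous m305       h2 = 0.030
primiparous peak_yield h2 = 0.029
primiparous scale_a    h2 = 0.039
multiparous m305: h2 = 0.132, repeatability = 0.292
```

(at this demo scale the curve-fit noise dominates the parameter traits,
so their heritabilities are small — the repeatability of multiparous
M305 shows the permanent-environment structure is recovered), and stage
4 flags the windows harbouring the simulated QTL, e.g.

```
 chrom snp_from snp_to start_bp   end_bp n_snp pct_variance candidate
     1        1     50    49900  3193613    50    10.421883      TRUE
     1      101    150  6586826  9780439    50     5.226143      TRUE
simulated QTL inside the flagged windows: 4, 1, ...
```

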