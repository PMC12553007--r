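---
title: "Triangulated Mendelian randomisation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulated Mendelian randomisation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriad)
```

## The scientific problem

Coronary heart disease (CHD) risk is shaped by altered metabolism, and
circulating proteins are the most actionable entry points for
intervention.  `mrtriad` implements a three-layer triangulation strategy
that links plasma proteins to CHD *through* urinary metabolism breakdown
products, using Mendelian randomisation (MR) on GWAS summary statistics:

1. **metabolite → CHD** — genome-wide MR identifies breakdown products
   whose genetically predicted values alter CHD risk;
2. **protein → metabolite** — cis-MR (instruments restricted to a 200 kb
   window around the protein-encoding gene) identifies proteins that
   shift those breakdown products;
3. **protein → CHD** — cis-MR estimates each protein's own effect on CHD.

A protein is *triangulated* when all three layers are significant at
their own multiplicity thresholds and the effect signs are
**directionally concordant**: the sign of the protein→CHD effect equals
the product of the signs of the protein→metabolite and metabolite→CHD
effects.  Because horizontal pleiotropy enters the three layers through
different routes, sign-consistent triples are much harder to produce by
pleiotropy alone.  Triangulated proteins are then validated in
atherosclerotic-plaque tissue (association with a plaque vulnerability
index, single-cell cell-type enrichment) and annotated with pathway
over-representation and druggability status.

## The GLS estimators

Each MR layer fits the variant-level model

$$\hat\beta_{Y} = X\,\theta + \varepsilon,\qquad
\operatorname{cov}(\varepsilon) = \Omega = S\,C\,S,$$

where, for $m$ instruments, $X = \hat\beta_X$ (IVW, slope through the
origin) or $X = [\mathbf 1, \hat\beta_X]$ (MR-Egger, free intercept
absorbing directional pleiotropy), $S = \operatorname{diag}(se_Y)$ and
$C$ is the LD correlation among the instruments.  Generalised least
squares gives

$$\hat\theta = (X^\top\Omega^{-1}X)^{-1}X^\top\Omega^{-1}\hat\beta_Y,$$

with heterogeneity $Q = (\hat\beta_Y - X\hat\theta)^\top \Omega^{-1}
(\hat\beta_Y - X\hat\theta)$ on $m - p$ degrees of freedom.  Weighting by
the full $\Omega$ rather than its diagonal is what corrects for residual
LD after clumping.  Implementation notes:

* the fit is computed by Cholesky whitening, not explicit inverses; the
  test suite cross-checks it against a brute-force matrix-inverse oracle;
* $\Omega$ carries outcome-side standard errors only (first-order IVW
  weighting; no second-order exposure term);
* Egger fits first flip every variant so $\hat\beta_X \ge 0$ (the
  conventional orientation); LD correlations flip signs accordingly;
* the reported standard error is the fixed-effect GLS standard error
  inflated by $\sqrt{\max(1, Q/df)}$ — a multiplicative random-effects
  allowance for unexplained heterogeneity; the uninflated value is also
  stored.  Confidence intervals are $\hat\theta \pm 1.96\,se$;
* a near-singular $C$ (e.g. duplicate variants) is shrunk towards the
  identity by the smallest $\lambda$ bringing its condition number below
  $10^8$; the applied $\lambda$ is recorded on the fit.

Disease-outcome slopes are log-odds per SD of exposure and are also
reported as odds ratios $e^{\hat\theta}$.

## Instrument selection and diagnostics

Per exposure, in order: cis-window restriction (protein exposures only;
closed interval, gene ± 200 kb), minor-allele-frequency filter
($\min(\text{eaf}, 1-\text{eaf}) \ge 0.01$), instrument-strength filter
$F = (\hat\beta/se)^2 \ge 24$ (boundary retained), and greedy LD clumping
at $r^2 \le 0.30$ (best remaining p-value kept, ties broken by variant
id).  Outcome alleles are then harmonised to the exposure's effect
alleles; palindromic variants are aligned by allele labels only and
logged so the decision can be audited.  Every removal is logged with a
stage and reason.

After the initial fits, variants with leverage above three times the mean
leverage or with a $\chi^2$ contribution to $Q$ above 10.83 (the 1-df
critical value at two-sided $p = 0.001$) are excluded — the union of
variants flagged by the IVW and Egger fits is removed so both models are
refit on the same set — and the fit is repeated once.  Analyses with
fewer than six variants at any fitting stage are discarded with a reason
rather than reported.

**Model selection.** Egger's extra parameter is accepted only when it
buys a significant drop in heterogeneity: Egger is selected iff
$Q_{IVW} - Q_{Egger} > \chi^2_{1,\,0.95} = 3.84$; otherwise the more
parsimonious IVW fit is kept.  This goodness-of-fit-versus-parsimony
rule is an assumption (the cut-off is configurable): under strong
*balanced* pleiotropy the unscaled $Q$-difference over-selects Egger
because overdispersion inflates both $Q$s, and conditioning inference on
the selected model costs coverage (see *Calibration* below).

## Multiplicity and triangulation

Layer-wise thresholds are Bonferroni corrections $\alpha/n_\text{eff}$:

* **metabolite → CHD** uses a PCA-based effective test count — the
  smallest $k$ such that the top-$k$ eigenvalues of the metabolite
  correlation matrix explain 90% of total variance (365 components for
  954 breakdown products in the motivating study, hence
  $0.05/365 = 1.37\times10^{-4}$);
* **protein → metabolite** uses the full product of proteins and
  surviving metabolites ($0.05/(1562\times29) = 1.10\times10^{-6}$),
  regardless of how many tests were actually estimable;
* **protein → CHD** uses the number of proteins tested.

Screens use a strict inequality ($p <$ threshold).  Survivors are joined
into protein–metabolite–CHD triangles; concordance is the sign rule
above, indeterminate (zero) effects are excluded and logged.  Proteins
measured in more than one study are replicated against the secondary
study at a nominal $p \le 0.05$ with matching direction, and at the
stricter $0.05/n_\text{overlap}$ (the overlap count is an input, not a
constant; an overlap of 72 reproduces the threshold
$6.94\times10^{-4}$).  When a protein is measured by several GWAS the
largest sample size wins, ties broken lexicographically.

## Tissue validation and annotation

Plaque expression (protein and mRNA families, analysed separately) is
regressed on the plaque vulnerability index (PVI) by OLS — expression is
the response, so slopes are mean differences in normalised count per
unit PVI; the primary model is unadjusted (covariate adjustment is
optional because the motivating analysis states none).  P-values are
Benjamini–Hochberg adjusted within each family at FDR 0.1.  Subgroup
analyses stratify by sex, age (< 65 vs ≥ 65 years) and diabetes, with a
formal PVI×group interaction test in the pooled model.

Cell-type enrichment uses the one-vs-rest Wilcoxon rank-sum test per
gene across the thirteen plaque cell types and the three broad clusters
(structural, innate immune, adaptive immune; the type→cluster map ships
as an editable table).  The normal approximation with mid-ranks,
tie-corrected variance and continuity correction is used at all sizes;
an exact-enumeration mode exists for validation.  For group sizes of at
least five the normal approximation stays within 0.02 of the exact
two-sided p for *every* attainable statistic; at sizes 3–4 the
worst-case deviation grows to about 0.037 (measured exhaustively in the
test suite), which is why the equivalence checks use sizes 5–8.

Pathway/metabolite-set enrichment is an upper-tail hypergeometric
over-representation test $P(X \ge k)$ (no mid-p), BH-corrected across
sets at FDR 0.05, against a fixed background universe (the 1562 GWAS
proteins in the motivating design).  Druggability is a static
table join (drugged > druggable > not-yet-druggable, duplicates merged),
so tests never call external services.

## The synthetic-data generator

All inputs can be simulated with known ground truth, directly at the
summary level — the pipeline consumes only summary data, and
summary-level generation is the standard way to test MR methods:

* **LD** is block compound symmetry (within-block correlation $r$,
  default 0.3, blocks of 5), positive semi-definite by construction,
  minimally diagonal-inflated otherwise.
* **Effect sizes.** Cis protein effects are drawn uniform on
  $[0.05, 0.15]$ SD per allele, oriented to the protein-increasing
  allele; genome-wide metabolite instruments uniform on $[0.15, 0.30]$
  with random sign.  The metabolite inherits $\theta_{pm}$ times the
  protein effect plus optional per-variant pleiotropy; the disease
  inherits $\theta_{mc}$ times the metabolite effect plus a direct
  $\theta_{pc}$ path.
* **Noise.** Standard errors follow
  $1/\sqrt{2\,\text{eaf}(1-\text{eaf})\,n}$ (unit-variance traits), which
  reproduces the F-statistic/sample-size relationship the filters depend
  on; estimation noise is multivariate normal with covariance $SCS$,
  independent between exposure and outcome samples (two-sample MR).
  Default sample sizes mirror the motivating study's scale: protein GWAS
  35,559, metabolite GWAS 5,023, disease GWAS 500,000 effective.
* **Pleiotropy.** `balanced` draws per-variant direct effects from
  $N(0, \sigma)$; `directional` from $N(\sigma, \sigma/2)$.  The
  directional study condition uses $\sigma = 0.1$ (comparable to the
  median per-variant instrument effect), a regime in which directional
  pleiotropy is genuinely detectable.
* **Plaque tables** draw the PVI uniform on $[0, 4]$ (a continuous
  composite score; the index construction itself is out of scope and the
  index is consumed as a numeric column), expression linear in PVI with
  Gaussian noise, and covariates at endarterectomy-cohort prevalences
  (75% male, age $N(69, 8.7)$, 22% diabetes).
* **Single-cell matrices** are negative-binomial counts (size 2, base
  mean 2) over the thirteen cell types, with enriched genes' means
  multiplied by a fold factor in their target type.

What the generator does **not** emulate: realistic allele-frequency
spectra, genotype-level sampling, non-linear exposure–outcome relations,
shared samples between GWAS (no sample-overlap bias), cell-type-specific
library sizes, or covariate-confounded plaque expression.  Passing tests
therefore demonstrate internal correctness and calibration of the
estimators under the stated generating model, not robustness to every
failure mode of real data.

## Calibration results the test suite verifies

Computed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` at run time (500 replicates for recovery, fewer
for the costlier branches; problem sizes — 20 cis variants, 10-trait
null layers of 6 + 12 variants, 150 null replicates — are the package's
chosen study sizes):

* GLS-IVW equals the closed-form weighted IVW under identity LD to
  machine precision, and matches brute-force matrix-inverse oracles
  under block LD.
* With $\theta_{pm} = 0.3$, no pleiotropy and large samples (exposure
  GWAS $10^5$, metabolite GWAS $2\times10^4$), the IVW fit's mean bias is
  within 5% and its 95% CI covers at 95% ± 3 points.  The IVW fit is the
  evaluation target because it is the correctly specified model under
  this generating process; the *selected-model* interval covers at about
  92–94%, since falsely selected Egger fits rarely cover — an inherent
  post-model-selection property of the $Q$-difference rule that users
  should keep in mind when quoting selected-model intervals.  At the
  default (study-scale) GWAS sizes the cascade's bias grows to about
  −3% through winner's-curse selection at the $F \ge 24$ boundary.
* Under directional pleiotropy ($\sigma = 0.1$), Egger is selected in a
  clear majority of replicates (~60–70%).
* An all-null metabolite layer screened at $\alpha/n$ keeps the
  family-wise error at the nominal level within Monte-Carlo slack.
* The default pipeline run plants one concordant, one discordant and one
  sub-threshold chain ($\theta$ values $\{0.6, 0.3, 0\}$,
  $\{-0.6, 0.3, 0.48\}$, $\{0.6, 5\times10^{-4}, 0\}$, chosen by
  design-time power analysis so each layer's verdict is determined by
  the design rather than the draw) and recovers exactly the concordant
  chain.

## Numerical and degenerate-input conventions

Coordinates are 1-based with closed cis intervals.  Clumping ties break
by ascending variant id.  Constant expression features are reported as
`not_detected`, all-tied Wilcoxon data as $p = 1$ with undefined
direction, zero effects as indeterminate concordance.  Egger designs
with constant $\hat\beta_X$ (intercept and slope unidentifiable) are
treated as Egger-unfit and fall back to IVW with a flag.  Empty
harmonisation overlap is a logged discard, not an error.  All pipeline
stages derive their seeds deterministically from the master seed, so a
run is reproducible byte-for-byte from its manifest.

## Known limitations

Single-pass pruning (not iterated to convergence); no median/mode/
MR-PRESSO estimators, multivariable MR, Steiger filtering or
colocalisation; no proxy-variant lookup or liftover; ORA ignores pathway
topology; the replication layer models only measurement-independent
noise, not platform differences.  The $Q$-difference selection rule is
anti-conservative under strong balanced pleiotropy, and selected-model
intervals undercover as quantified above.
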