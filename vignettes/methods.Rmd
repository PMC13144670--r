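---
title: "Zygosity-free heritability estimation from register data: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zygosity-free heritability estimation from register data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regherit)
```

## The problem

Classical twin studies estimate narrow-sense heritability by contrasting
phenotypic concordance of monozygotic (MZ) and dizygotic (DZ) twins. In
population health registers zygosity is rarely recorded, but sex is. Because
opposite-sex twin pairs are certainly DZ while same-sex pairs are an MZ/DZ
mixture, sex composition can proxy zygosity at population scale. `regherit`
implements this design end-to-end: pair identification from person records,
diagnosis-to-phecode mapping, a variance-component model for within-pair
correlation of binary outcomes, conversion to the liability scale, the
modified Falconer estimator, and uncertainty quantification. A synthetic
registry generator with a known liability-threshold ACE structure makes
every stage testable without access to any real registry, which is also how
the package validates itself: real national-registry data of this kind are
not publicly available.

## The estimator

For a binary phenotype with prevalence $K$, each individual carries a latent
standard-normal liability; the phenotype is present when the liability
exceeds $T = \Phi^{-1}(1-K)$. Within-pair correlations on the liability
scale, $r_{SS}$ for same-sex twin pairs and $r_{OS}$ for the reference
group, combine into

$$\hat h^2 = \frac{2}{p}\,(r_{SS} - r_{OS}),$$

where $p$ is the probability that a same-sex pair is monozygotic. With known
zygosity ($p = 1$, $r_{SS} = r_{MZ}$, $r_{OS} = r_{DZ}$) this is the classic
Falconer estimator. Under Weinberg's rule — DZ pairs are same-sex with
probability one half — $p$ is identified from pair counts alone:
$p(\mathrm{MZ}) = 1 - 2 N_{OS}/N_{all}$, $p(\mathrm{SS}) = N_{SS}/N_{all}$,
and $p = p(\mathrm{MZ})/p(\mathrm{SS})$ (`mz_probability()`).

In the sibling design the reference group additionally contains every
non-twin full-sibling pair regardless of sex, because full siblings share
the same expected half of segregating variation as DZ twins. The same-sex
group is unchanged, and $p$ continues to come from the twin pair counts.

### Within-group correlations

`fit_variance_components()` fits the linear mixed model

$$y = X\beta + u_{pair} + u_{onlySS} + e$$

by REML, with $y \in \{0,1\}$ modelled linearly (a linear probability
model), fixed effects sex and birth year, a random intercept per pair, and a
second random intercept shared only within same-sex twin pairs. We take
$u_{onlySS}$ to be independent across individuals of reference-group pairs
rather than absent, so every individual carries the same total variance
$V_{total} = V_{pair} + V_{onlySS} + V_e$ while the within-pair covariance
is $V_{SS} = V_{pair} + V_{onlySS}$ for same-sex pairs and
$V_{OS} = V_{pair}$ otherwise. Observed-scale correlations are the ratios
$V_{SS}/V_{total}$ and $V_{OS}/V_{total}$.

Because every random-effect block is a $2\times 2$ pair, transforming each
pair into its sum and difference components diagonalises the covariance:
the eigenvalues are constant within four strata (SS-sum, SS-diff, REF-sum,
REF-diff). All REML quantities then reduce to weighted stratum
cross-products, so one likelihood evaluation costs $O(1)$ after a single
$O(n)$ pass, and the whole fit is a two-parameter bounded optimisation
(`nlminb` on the variance ratios, with a projected finite-difference Newton
polish). This is what makes a pair bootstrap with hundreds of replicates
per phenotype practical on one CPU: resampling pairs with replacement is
algebraically identical to reweighting the cross-products with multinomial
counts, so a bootstrap replicate costs one weighted cross-product pass.
The suite verifies the fast path against a brute-force dense per-pair
implementation (agreement to $10^{-6}$ on the variance ratios over random
small instances) and against `lme4::lmer` on the same model.

Variance components are constrained nonnegative; a component estimated at
the boundary is reported as 0. A constant outcome yields a flagged
degenerate result rather than an error from the optimiser.

### Observed to liability scale

Observed 0/1 covariances understate latent liability correlations. Given a
within-pair covariance $c$ and prevalence $K$, the recurrence risk in the
co-member of an affected individual is $q_R = K + c/K$, the group threshold
is $T_G = \Phi^{-1}(1-q_R)$, and the liability correlation follows the
Reich–James–Morris approximation with $i = \phi(T)/K$:

$$r = \frac{T - T_G\sqrt{1-(T^2-T_G^2)(1-T/i)}}{i + T_G^2\,(i-T)}.$$

Two algebraic variants of this formula circulate in the applied literature:
one with the plus sign inside the group-threshold argument
($\Phi^{-1}(1-K+c/K)$) and the square root attached to the threshold
difference. As implemented here the transform uses the minus sign and the
square root on $T_G$, which is the standard recurrence-risk construction:
it is strictly increasing in the covariance, maps 0 to 0 for every $K$, and
round-trips thresholded bivariate-normal simulations to within 0.01 across
$\rho \in \{0.1, \dots, 0.8\}$ and $K \in \{0.01, \dots, 0.2\}$ (verified
against exact quadrant probabilities and $10^7$-pair Monte Carlo in the
suite). The other arrangement is retained behind
`liability_correlation(..., variant = "printed")` for audit; it is not
monotone in the required direction and does not recover the generating
correlation, which is why it is not the default.

### A known, quantified bias of the design

The same-sex group's observed covariance is a mixture of MZ and DZ
covariances. The liability transform is convex in the covariance, so the
transform of the mixed covariance exceeds the corresponding mixture of
liability correlations, and $\hat h^2$ inherits a positive bias that does
not vanish with sample size. Under the package's reference simulation
conditions ($h^2 = 0.5$, $c^2 = 0.2$, $K = 0.1$, MZ fraction 0.28) the
bias is about $+0.05$; it grows with the MZ/DZ correlation gap and with
smaller $K$. This is a property of the zygosity-free design itself, not of
the implementation — it affects any method that transforms a pooled
same-sex covariance — and it is one reason the recovery tests use a
3-standard-error band rather than an equality.

## Uncertainty, multiple testing, aggregation

- **Bootstrap** (`bootstrap_estimate()`): pairs are resampled with
  replacement, stratified by analysis group so SS and REF keep their sizes
  (unstratified resampling is available); the full model-to-estimator
  pipeline is re-run each replicate. The standard error is the replicate
  standard deviation.
- **Confidence interval**: the reported `ci95` is the normal-approximation
  interval $\hat h^2 \pm 1.96\,\widehat{se}$; the percentile interval is
  retained as `ci95_percentile`. This choice comes from a calibration
  study run while validating the package: over 500 simulated registries
  (10,000 twin-pair families, $B = 200$), the percentile interval covered
  the generating $h^2 = 0.5$ in 92.8% of repetitions while the normal
  interval covered in 93.8%. With the convexity bias described above
  shifting the estimator's centre, the slightly wider normal interval is
  the better-calibrated summary at practical replicate counts.
- **Testing**: two-tailed z-test $p = 2(1-\Phi(|\hat h^2/\widehat{se}|))$,
  Benjamini–Hochberg step-up q-values across all phenotypes of one
  cohort-by-design run, and a significance flag at FDR < 0.05. Negative raw
  estimates are reported as computed; "non-zero heritability" is decided
  solely by the FDR flag.
- **Aggregation**: inverse-variance-weighted means with weights
  $1/se^2$ per functional domain (`ivw_mean()`), and weighted
  least-squares comparison fits between estimate sets matched on phecode
  with weights $1/(se_x^2 + se_y^2)$ (`compare_estimate_sets()`). Because
  sex imbalance biases the estimator, phenotypes whose case sex ratios
  differ between the two compared sets by more than a configurable factor
  (default 1.5) are excluded from comparison fits; the registry study this
  package follows reports example ratio pairs such as 3.76 vs 3.02 but no
  numeric cutoff, so the threshold is an explicit configuration knob.

## Cohort construction rules

- **Twin pairs**: two children of the same mother and father, born at most
  one calendar day apart at the identical birthplace, on or after
  1955-01-01; one pair per parent couple (the earliest). Same-sex pairs form
  the SS group.
- **Non-twin sibling pairs**: same parent couple, born between 11 months
  (334 days) and 4 years (1461 days) apart; when more than two children
  qualify, the pair born closest together (ties: earliest first-born, then
  lexicographic id — deterministic output). Individuals already in a twin
  pair are never re-used. The sibling cohort is the union of twin and
  non-twin pairs.
- **Follow-up**: a pair is followed until the first member's death or
  emigration, or the study end (2021-12-31). A person scores $y = 1$ for a
  phecode only if an event falls inside `[registry start, follow-up end]`.
- **Birth cohorts**: the 1955 cohort keeps pairs with both members born
  1955–2021 and alive on 1977-01-01 (the registry's first day of diagnostic
  coverage); the 1977 cohort keeps pairs with both members born 1977–2021,
  who are observed from birth. Contrasting the two quantifies left
  truncation.
- **Code mapping**: ICD-8 events map to ICD-10, then ICD-10 to phecodes
  (mapping tables are user-supplied files); events propagate to all
  hierarchical ancestors by decimal truncation (751.11 → 751.1 → 751).
  Unmapped codes are counted and reported, never fatal.
- **Eligibility filters** (`filter_config()`): prevalence ≥ 0.5%; for
  twin-cohort analyses at least 400 cases; at least 5 concordant pairs in
  the SS and in the REF group; case sex ratio ≤ 5, with a sex-ratio
  exclusion removing all hierarchical ancestors of the failing phecode
  (an aggregate of two single-sex subcodes can look balanced). The
  exclusion ledger records the first failing rule per phecode. The 400-case
  floor is treated as a twin-analysis rule and not applied to
  sibling-cohort runs, where the prevalence rule alone governs.
- **Onset classification**: early-onset iff at least 10% of cases have
  their first event by age 18. The denominator is cases (not the population
  at risk); this is one admissible reading of a "cumulative incidence of
  10% by 18" rule, and the computed fraction is always reported alongside
  the label so the choice is auditable.

## The synthetic registry

`simulate_registry()` generates families that each contribute either a twin
pair (probability `twin_fraction`, monozygotic with probability `p_mz`) or
a non-twin sibling pair. Liabilities are $l = g + c + e$ with
$\mathrm{Var}(g) = h^2$ and genetic correlation 1 (MZ) or 0.5 (DZ and
siblings), a pair-shared environment with variance `c2_twin` (twins) or
`c2_sib` (siblings), and independent residuals scaling the total to 1.
Sexes follow Weinberg's rule exactly (i.i.d. fair Bernoulli per member, MZ
pairs copying one draw; no sex-ratio-at-birth adjustment). An optional male
liability shift generates sex-imbalanced phenotypes for testing the
sex-ratio filter. Age at onset is log-normal; a diagnosis is recorded only
if the onset date falls on or after the registry opening and before the
person's censoring date, with death and emigration as independent constant
hazards — this is deliberately the simplest mechanism that exercises the
follow-up and left-truncation logic.

Defaults describe a registry-era birth cohort observed from birth: births
1977–2000, registry opening 1977, study end 2021, annual mortality and
emigration hazards of 0.001 each, onset ages averaging 8 years (childhood
onset, so most onsets are observable within follow-up), twin fraction 0.06
and MZ fraction 0.28 — values typical of a Northern-European register
population. The generator does not attempt realistic demography:
no assortative mating, no dominance or epistasis, no age-varying hazards,
no secular trends in fertility or diagnosis. Passing recovery tests on
these data therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to the many ways real
registry data violate them (diagnostic drift, dependent censoring,
sex-differential ascertainment).

The sibling-shared environment `c2_sib` deserves a note: the register study
this package follows does not state a generative model for it, so it is a
free simulation knob constrained to `c2_sib <= c2_twin`. Its role is
directional: with `c2_sib < c2_twin`, sibling-design estimates exceed
twin-design estimates on the same truth by
$(2/p)\,w_{sib}\,(c^2_{twin} - c^2_{sib})$ in expectation (with $w_{sib}$
the non-twin share of the reference group), which the suite verifies both
algebraically and by simulation.

## Numerical and design choices

- **Age fixed effect**: "age" in the mixed model is implemented as birth
  year (standardised internally); attained age is collinear with follow-up
  for ever/never outcomes. The design matrix drops aliased columns
  automatically (e.g. when all pairs share a birth year).
- **Optimisation**: variance ratios are optimised with box constraints at
  0; starting values come from method-of-moments covariances of OLS
  residuals computed from the same stratum cross-products. Degenerate
  inputs (constant outcome, missing group) produce flagged results or
  named errors, never silent zeros.
- **Problem sizes in the suite**: parameter-recovery runs use 200,000
  twin-pair families; the bootstrap calibration study uses 500 repetitions
  of 10,000 families at 200 replicates; the round-trip oracle uses $10^7$
  Monte-Carlo pairs per cell; the REML oracle uses 50 instances of at most
  200 pairs. These sizes keep every check well inside Monte-Carlo
  resolution while remaining runnable on a laptop core.
- **Determinism**: every stochastic routine takes an explicit seed;
  identical seeds and parameters reproduce simulated registries
  byte-for-byte and bootstrap replicate vectors exactly, independent of
  pair row order.
- **Pipeline**: the four stages (`run_simulate()`, `run_build()`,
  `run_estimate()`, `run_aggregate()`) exchange plain TSV files and write
  a JSON manifest (config, seed, input/output checksums) per stage, so a
  serialized `run_config()` reproduces a run and the manifests chain
  provenance. A thin command-line wrapper over these functions ships in
  `inst/cli/regherit.R`.

## Known limitations

- The design cannot estimate sex-specific phenotypes (the SS/REF contrast
  degenerates), and sex-imbalanced phenotypes are filtered rather than
  modelled.
- The mixture-convexity bias described above inflates estimates when the
  MZ/DZ correlation gap is large and prevalence is low; contrasts between
  designs or cohorts are more trustworthy than absolute values in that
  regime.
- The linear probability model ignores the binomial mean-variance
  relationship; the liability transform corrects the scale post hoc but
  not the within-fit heteroscedasticity induced by covariates.
- Sibling-design estimates are systematically inflated when siblings share
  less environment than twins; this is a feature of the contrast (it
  signals twin-specific shared environment), not an estimation error.
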