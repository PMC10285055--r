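---
title: "Multi-country pedigree BLUP: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-country pedigree BLUP: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

herdlink evaluates dairy cattle breeding values from pedigree and
first-lactation performance data, within one country and on data pooled
across countries connected by common sires, and translates the resulting
accuracies into predicted genetic gain under top-k sire selection. This
vignette is the package's own account of the statistics: the model and its
assumptions, what the simulator does and does not emulate, the numerical
choices, and the limits of what the tests demonstrate.

## The animal model

For trait t of cow i, the observation is

$$y = H_j + HYS_k + b\,(\mathrm{age} - \overline{\mathrm{age}}) + a_i + e$$

* `H_j` — fixed effect of the *birth* herd.
* `HYS_k` — fixed herd-year-season contemporary group of production
  (label `herd|year|season`; season defaults to calendar quarters,
  configurable to halves or months). Cows can produce in a herd other than
  their birth herd, which is what keeps the two factors separable.
* age regression — calving age in months, centred at the dataset mean;
  never fitted for AFC, whose observation is itself the calving age.
* `a_i` — additive genetic effect; across animals and traits
  `Var(a) = A \otimes G_0` with `A` the numerator relationship matrix.
* `e` — residual; the traits of one record are correlated through `R_0`,
  records are independent.

The pooled across-country model adds a fixed country effect and nests the
age regression within country (own slope per country, centred at the
country mean). Nesting is the package's choice where the source analysis is
ambiguous: production systems differ enough that a shared slope is hard to
defend, and it gives the orchestration a clean invariant — pooling two
countries with *no* genetic links reproduces each within-country evaluation
exactly, which the tests exercise. HYS groups are country-nested
automatically because a herd exists in exactly one country.

Unknown parents are draws from a single unselected base population; there
are no genetic groups. Missing traits are handled record-wise: each record
contributes through the inverse of the `R_0` submatrix of its observed
traits (the standard multi-trait treatment).

### Rank deficiency and constraints

Herd, HYS and country indicators are nested (HYS columns sum to herds,
herds to countries), so the fixed part is structurally rank-deficient. The
constraint set is combinatorial and deterministic:

1. drop the last country level;
2. drop the last herd within every country except the last;
3. per trait, drop the last HYS level within every connected component of
   the herd–HYS bipartite record graph.

For partition-structured factors this is exactly the deficiency count
(the rank of two stacked indicator blocks is `n_A + n_B − #components`), so
the reduced system is full rank without any numerical rank detection: when
no cow ever changes herd, rule 3 automatically absorbs the entire herd
factor into HYS, and with movement it drops a single level per connected
block. Constrained levels are reported with estimate 0; estimable contrasts
and EBVs do not depend on the choice.

### Solving and reliabilities

`A^{-1}` is assembled directly by Henderson's rules with
Mendelian-sampling variances `d_i` adjusted for parental inbreeding;
inbreeding coefficients come from the Meuwissen–Luo algorithm (no dense
`A` is ever formed; the recursive tabular `A` exists only as a desk-scale
oracle for the tests). The mixed-model equations are solved by sparse
Cholesky (CHOLMOD) by default, or by Jacobi-preconditioned conjugate
gradients; both are deterministic and the direct factor is cached.
Prediction-error variances are exact diagonal entries of `C^{-1}`, obtained
by solving against unit vectors in chunks — a few hundred sires on a
10^5-equation system cost seconds — rather than approximations from
iteration counts. Reliability is `r² = 1 − PEV/σ²_a` (clamped to `[0, 1)`)
and accuracy `ρ = √r²`.

## Variance components

`em_reml()` implements EM-REML for the same model. The M-steps are the
classical ones — `G_0` from animal-solution cross-products plus the
`tr(A^{-1} C^{aa})` correction, `R_0` from conditional residual
cross-products with the `W C^{-1} W'` correction; missing traits enter via
the conditional distribution of their unobserved residuals. Two practical
layers sit on top:

* **Starting values** default to a between/within sire-family
  method-of-moments split per trait, clipped to `[0.02, 0.7]` of the
  phenotypic variance. EM then only has to travel a short distance.
* **Acceleration.** Plain EM crawls when `σ²_a/σ²_p` is small; steps are
  extrapolated with a squared-extrapolation (SQUAREM-style) update that is
  accepted only if it stays positive definite and does not decrease the
  restricted likelihood, so the reported likelihood trace is still
  monotone. The likelihood itself is cheap through the identity
  `log|V| + log|X'V^{-1}X| = log|R| + log|A\otimes G_0| + log|C|`, with
  `log|A| = \sum \log d_i` falling out of the A-inverse construction.

The trace corrections need the full inverse of the coefficient matrix, so
the estimator is deliberately desk-scale (default refusal above 8,000
equations). Convergence is declared when no parameter moves more than
`tol` relative to its own magnitude in one EM step. There are no silent
default variances anywhere: evaluation refuses to run unless components
are supplied or estimated.

## Selection and gain tables

Selection intensity uses the infinite-population truncated-normal formula
`i = φ(z)/p`, `p = k/n`; `i = 0` when everything is kept, and the tests
check it against Monte-Carlo means of top-k normal order statistics
(finite-sample bias at small n is accepted and documented). The accuracy
`ρ` entering `R = i·ρ·σ_g` is by default the arithmetic mean of EBV
accuracies over *all* candidate sires (`mean_top_k` is available) — the
source tables do not state the aggregation, and the mean over the candidate
list is the least informative assumption. The pooled candidate count
defaults to the *sum* of the national sire lists without deduplicating
shared sires (e.g. 103 + 505 = 608): that convention, not the deduplicated
568, reproduces the published pooled intensities; a flag selects the
deduplicated union. Gains are held at full precision (`pgg = i·ρ·σ_g`
bit-for-bit); rounding to 2 decimals happens only in the TSV presentation
columns. Scenarios larger than a candidate list select everyone (`i = 0`,
zero predicted gain); if that happens to the pooled reference list itself
the percentage column is `NA` rather than an error, since a share of a
zero gain is undefined. Only the sire pathway is modelled — dam selection and gene-flow
discounting are out of scope, so realised progress would differ by the
usual pathway factors.

## The simulator

`simulate_study()` generates, per country, founder sires (a configurable
subset shared across countries — the only genetic connection; dams never
overlap), founder dams, and daughter cows with one first-lactation record
each. Founder breeding values are multivariate normal with covariance
`G_0`; offspring get the parent average plus a Mendelian deviation with
covariance `0.5(1 − (F_s+F_d)/2)\,G_0`. Phenotypes add a country mean,
birth-herd and HYS effects, the age regression (except AFC), and a residual
from `R_0`, thinned by per-trait missingness. Sire usage is skewed
(geometric-like daughter counts, mimicking AI), every sire is guaranteed at
least one recorded daughter, herds record calvings in contiguous year
windows, and cows move herds with probability `p_move` (default 0.15).
Identical seeds give byte-identical output.

The full-scale preset reproduces the pilot setting exactly in its
*structure*: 2,333 and 25,208 records, 103 and 505 sires with recorded
daughters, 40 common sires, calvings 1979–2014 and 1997–2014. All
*magnitudes* are declared assumptions, because the source datasets are
private and publish no means, variances or fixed-effect sizes. Defaults:
genetic SDs 528 kg (MY305), 61.2 (AFC) and 20.3 months (CI1) — taken from
the published pooled-evaluation genetic SDs as plausible scales;
heritabilities 0.25 / 0.15 / 0.08; genetic correlations −0.2 (MY305–AFC),
0.2 (MY305–CI1), 0.1 (AFC–CI1); residual correlations zero; herd and HYS
effect SDs 0.30 and 0.15 of the phenotypic SD; age slopes 15 kg/mo and
0.05 mo/mo for MY305 and CI1; missingness 0 / 5% / 20%. Each is a single
`sim_config()` argument and the simulation manifest flags them all as
assumptions.

What the simulator does **not** emulate — and therefore what passing tests
cannot show about real data: selection over time (no drift or truncation
across generations), genotype-by-environment differences between countries
(a common `G_0` with genetic correlation 1 across countries is assumed,
exactly as in the pilot), dam-side cross-country links, preferential
treatment of bull dams, heterogeneous variances across herds, and the
dependence between the AFC phenotype and the calving-age covariate of the
other traits (simulated independently). Results on simulated data validate
the *machinery*, not the magnitudes of any real population's parameters.

## Problem sizes in the tests

The suite runs every oracle comparison at desk scale (pedigrees ≤ 200 for
dense `A` identities; ≤ 20-animal toys against a dense GLS oracle), the
within-versus-pooled accuracy comparison on 20 seeded replicates of a
600-cow two-country study, EM-REML recovery as the mean of three seeded
replicates of a 3,200-cow / 160-sire single-country study per trait, the
EBV–TBV calibration on ten replicates of a 3,000-cow / 60-sire study, and
one full-scale (27,541-record) pooled solve. The calibration replicates use
*uniform* sire usage: a group correlation between EBVs and true values
equals the mean individual accuracy only when candidates carry comparable
information — under skewed usage the correlation tracks `sqrt(mean r²)`,
which Jensen's inequality places above the mean accuracy, and the check
would measure usage skew rather than model calibration. The replicate-mean design for
REML recovery is deliberate: a single REML estimate of a low-heritability
variance (CI1, h² = 0.08) from 160 sire families has a sampling spread of
roughly ±20–35%, so a single-replicate check against a 30% band would be a
coin flip for reasons unrelated to correctness. Averaging three seeded
replicates brings the spread inside the band while keeping the check
honest — the truth values are never used anywhere in the estimation path.

## Known limitations

* EM-REML is desk-scale by construction (dense `C^{-1}`); national-scale
  variance estimation would need AI-REML with sparse-inverse machinery.
* No genetic groups for unknown parents; pedigrees with strong base-
  population stratification will absorb that structure into EBVs.
* The gain comparison treats `σ_g` as known per source; uncertainty in the
  variance components is not propagated into `%PGG`.
* Selection intensity ignores finite-sample order-statistic corrections
  and correlated EBVs among half-sib candidates; at n ≥ 100 the error is
  below 0.01 standard deviations, at very small n it is visible.
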