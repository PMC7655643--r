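---
title: "Scoring low-input dairy production: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring low-input dairy production: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liprod)
```

## The problem

Low-input and organic dairy systems rely on grazing and keep concentrate
feeding and veterinary intervention low. Under that management, raw milk
yield is a poor yardstick for choosing among breeds: udder health, treatment
burden and the nutritional quality of the milk-fat matter as much as output.
`liprod` implements a composite **low-input-production (LI-P)** score that
folds thirteen routinely measurable variables into a single number per cow
record, plus the surrounding pipeline needed to compare breed groups
fairly: breed-code canonicalisation, cohort inclusion rules, per-date PCA
ordination, and a mixed-effects breed comparison.

The package works on long-format records: one row per cow per sampling
date, carrying production (milk yield in L/day, fat+protein solids in
kg/day), health (somatic cell count, SCC, in 10^3 cells/ml; treatment count
since the previous sampling), feeding (concentrate and conserved forage
offered, kg/day) and nine fatty-acid (FA) variables expressed as a
percentage of the total FA profile: oleic acid (OA), cis-9 trans-11 CLA
(CLA9), total omega-3, EPA+DPA+DHA, lauric (C12:0), myristic (C14:0) and
palmitic (C16:0) acids, total omega-6, and the omega-6/omega-3 ratio.

## The LI-P score

Variables have incompatible units, so each is converted to a rank-based
quintile score. For one variable, the `n` records are sorted ascending
(ties broken by the record key `(cow_id, date_code)` so the allocation is
deterministic); the record at ordinal position `r` (0-based) falls in group
`floor(5 r / n) + 1`, which makes the five group sizes differ by at most
one. Desirable variables (yield, solids, OA, CLA9, omega-3, EPA+DPA+DHA)
score the group number, 5 best; undesirable variables (SCC, C12:0, C14:0,
C16:0, omega-6, omega-6/omega-3) score `6 - group`, so 5 again means best.
Quintile scoring is invariant under any strictly increasing transformation
of a variable, which is exactly why it is used: no distributional
assumption is needed and extreme SCC values cannot dominate.

Components are then summed:

* **production** = yield quintile + solids quintile (2–10);
* **health** = reversed SCC quintile + an untreated indicator that is 1
  only for cows with zero treatments since the previous sampling (1–6);
* **fatty acids** = sum of the nine FA quintile scores (9–45).

Two convex weightings collapse the components to a score with maximum 1:

* health-emphasis: `0.3 (production/10) + 0.5 (health/6) + 0.2 (FA/45)`;
* production-emphasis: `0.6 (production/10) + 0.3 (health/6) + 0.1 (FA/45)`.

Breed groups are ranked by mean composite, computed over records (a cow
sampled on three dates contributes three records). Means are compared at
two decimal places — the precision at which such tables are reported — and
equal rounded means are separated by the smaller standard deviation;
any remaining tie breaks alphabetically so ranks are always a permutation.

**Quintile scope.** Quintiles can be allocated over the pooled cohort (all
dates, the default) or within each date (`scope = "per_date"`). Pooling
uses one scheme per variable and matches the single summary-table framing
of the score; per-date allocation removes seasonal level shifts but makes
scores incomparable across dates. Both are implemented because survey data
of this kind does not dictate the choice; the default is pooled.

## Breed codes and inclusion

Pedigree labels are canonicalised to be symmetric in sire and dam: a
purebred pair gives the pure label (`JE`), a cross of two purebreds gives a
two-breed label ordered by a fixed precedence list (`HFJE`, never `JEHF`),
and parents that share a single majority breed give that breed plus a
trailing `X` (`JEX`), flagged as a majority/backcross label. Crosses with
no dominant component collapse to `XX`. The precedence list (HF, NZF, BF,
JE, SR, SH, AYR, MO, BS, MRI, XX) makes the rule total; for
multi-generation, three-breed backcrosses no field convention exists, so a
majority label such as `JEX` is parsed as 3/4 named breed and 1/4 unknown —
a documented package choice, not an external standard.

A breed group enters comparative analysis only if, on at least one
sampling date, complete records exist for **at least six distinct cows on
at least three different farms**. Counting cows (not records) prevents one
repeatedly-sampled animal from qualifying a group, and the three-farm floor
keeps a single farm's management from masquerading as a breed effect.

## The synthetic herd generator

Real herd surveys of this kind are rarely deposited, so the package ships a
generator whose defaults encode a reference population: 1,070 cows on 17
organic and low-input farms in England and Wales, sampled on four dates
(autumn 2011, spring, summer and autumn 2012), with eight analysis breed
groups — Ayrshire cross (AYRX), Holstein/Friesian (HF), HF×Jersey (HFJE),
HF×Scandinavian Red (HFSR), Jersey cross (JEX), New Zealand Friesian cross
(NZFX), Dairy Shorthorn (SH) and Scandinavian Red cross (SRX) — at group
sizes 100, 325, 184, 274, 121, 90, 80 and 140 records.

Each breed × trait cell is a mean and SD, reproduced by a moment-matched
distribution:

* **Most traits**: a normal truncated below at zero whose *parent*
  parameters are solved numerically so the **realized** (post-truncation)
  mean and SD equal the targets. Naive truncation of `N(mean, sd)` inflates
  the mean (for NZFX yield, 20.1 ± 7.08 L/day, by ≈ 0.05 L/day); solving
  the truncated moments removes that bias so calibration checks can be
  exact. A zero-truncated normal cannot reach a coefficient of variation of
  1, so traits with CV ≥ 0.95 (conserved forage in several groups) fall
  back to a moment-matched lognormal.
* **SCC**: moment-matched lognormal, `σ² = log(1 + CV²)`,
  `μ = log(mean) − σ²/2`. SCC distributions are strongly right-skewed
  (means 170–293, SDs 400–945 ×10³ cells/ml), and the lognormal reproduces
  both the skew and the low medians (for NZFX, analytic median
  `exp(μ) ≈ 55.3` ×10³ cells/ml against a mean of 232).
* **Treatment counts**: moment-matched negative binomial,
  `size = mean²/(var − mean)`, reflecting overdispersion (0.41 ± 0.818 for
  AYRX); when `var ≤ mean` the family degrades gracefully to Poisson.
* **The omega-6/omega-3 ratio is never sampled**: it is computed as
  `n6_pct / n3_pct` on every record, so the ratio identity holds exactly
  by construction, and EPA+DPA+DHA is clipped to total omega-3 (long-chain
  omega-3s are a subset).

Cows are allocated to farms following the farm roster; a breed group can
only be placed on farms whose breed list contains its constituent breeds,
and global group totals follow the configured group sizes by
largest-remainder rounding. Farm intercepts and season shifts (both
mean-zero normal, per trait) create the crossed structure the mixed model
is designed for; defaults are 25% and 10% of the trait's median SD. Because
the calibrated SDs are *marginal* (they already contain farm and season
variation), default herds are slightly overdispersed relative to the
calibration targets — calibration experiments therefore disable the
variance components, and the moment-recovery tests sample the marginal
distributions directly. Per-date missingness defaults reproduce the
reference cohort attrition (299, 757, 772 and 613 complete records on the
four dates out of 1,070 cows).

Traits default to independence because trait covariances are rarely
published; a Gaussian-copula hook (`correlation_spec`) lets simulations
probe sensitivity to dependence (the copula feeds correlated uniforms
through each trait's quantile function, so the matched margins are
preserved). The generation mix defaults to 20% purebred, 40% F1 and 40%
later generations; the generation field is sampled independently of the
breed label and is bookkeeping only — no heterosis or lactation-curve model
is attempted. All randomness flows from the single config seed, and the
same seed yields a byte-identical herd CSV.

What passing tests on synthetic herds do **not** show: real FA variables
are strongly correlated through diet (fresh-forage intake raises omega-3
and CLA9 together), real farms differ in trait-specific, not proportional,
ways, and days-in-milk follows calving pattern rather than an independent
draw per date. Synthetic results validate the machinery and the rank
logic under the calibrated margins, not farm-level biology.

## Ordination

For each sampling date with at least three complete records, the thirteen
LI-P variables are standardized to mean zero and unit sample SD (n−1
denominator) — mandatory, since the variables' units differ by orders of
magnitude — and decomposed by PCA on the correlation matrix (SVD of the
standardized matrix). Variance fractions are `λ_i / Σλ`; eigenvector signs
are fixed by making each loading vector's largest-magnitude entry positive,
so results are reproducible across platforms. Treatment counts enter raw by
default (`treatments = "binary"` switches to the untreated indicator). Two
figure families are emitted per date: record scores coloured by farm
(management clustering) and variable loadings (trait co-occurrence).

## Breed comparison

`fit_breed_model()` fits `response ~ breed + (1 | farm) + (1 | season)` by
REML. Farms are observed on all four dates, so records are not independent;
the crossed random intercepts absorb farm management and seasonal level
shifts, leaving the breed contrast to the fixed effect. The omnibus breed
test is a Satterthwaite-approximated F test; its operating characteristic —
type-I error close to the nominal 5% under a null simulation — is part of
the test suite (300 null replicates of 120 records across 6 farms and 4
seasons). With zero random-effect variance the fit collapses to ordinary
least squares, which the tests assert to 1e−6; a variance component
estimated at the boundary is reported as 0 with a warning. **No post-hoc
pairwise tests are produced, deliberately**: with eight groups of uneven
size, 28 pairwise comparisons would either inflate the family-wise
false-positive rate or, after correction, be underpowered and misleading;
only the omnibus test and the descriptive means are reported. Feeding
variables are summarised but never modelled, because rations are set per
farm and date — not per cow — so a cow-level model has no valid error term
for them. SCC summaries always carry the median next to the mean; with 12%
of individual recordings far above the mean, the median is the
representative udder-health statistic.

## Numerical choices and degenerate inputs

* Quintile allocation requires ≥ 5 complete records and refuses missing
  values (filtering is an explicit upstream step, never implicit).
* Tie-break everywhere is the stable record key, so permuting input order
  never changes any score, rank or PCA result (tested).
* `rank_breeds()` requires ≥ 2 records per group (an SD must exist).
* `standardize()` names the offending column when one is constant; PCA
  needs ≥ 3 records; dates below that are skipped with a warning, not an
  error.
* Truncated-normal parent parameters are solved by Nelder–Mead on
  `(μ, log σ)` against closed-form truncated moments (relative tolerance
  1e−4 on both moments) and cached per target.
* The pipeline aborts with a stage-named error on an empty scoring cohort;
  the run manifest records counts at every stage so attrition is auditable.

## Simulation sizes

The packaged experiments use: 200 replicates for the rank-recovery
experiment (eight groups at their configured sizes, 1,314 records per
replicate); 10^5 draws for moment-recovery checks (tolerance three standard
errors); 300 replicates for the type-I-error simulation. These sizes put
Monte-Carlo error well below every tolerance asserted while keeping a full
run in the order of a minute.

## Known limitations

Scores are relative to the cohort scored: a quintile score of 5 means "top
fifth of this population", so composites are not comparable across
independently scored datasets. The weightings are fixed judgments (health-
vs production-emphasis), not fitted quantities, and no economic index is
attempted. Breed labels beyond two components rest on the package's
majority-labelling convention. The generator reproduces margins, roster and
missingness — not trait covariance, lactation curves, or
genotype-by-environment structure.
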