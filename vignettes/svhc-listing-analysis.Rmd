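---
title: "Methods: modelling the drivers of SVHC listing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the drivers of SVHC listing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the design

Under REACH, a substance of very high concern (SVHC) is regulated only after
it is placed on the Candidate List, from which a subset is prioritized onto
the Authorization List. This package asks what predicts those listing
decisions: the hazard profile of the substance, the economic footprint of its
production and import in the EEA, or the amount of scientific knowledge about
it. The analysis is observational and correlational by construction — the
logistic models below quantify association, not causality, and nothing in the
pipeline attempts to model the political process that produces a listing.

Each analysis is a *comparison sample*: members of a focal list (Candidate or
Authorization List) contrasted against a reference population. Against REACH,
the sample is every registered substance and the outcome is the focal-list
flag. Against the expert lists (SIN, PRIO) the reference population is not
stated unambiguously by the design, so we adopt the union convention: the
sample is the union of the two lists, focal members absent from the expert
list count as positives, expert-list members absent from the focal list as
negatives. This matches the question "which of the expert-flagged substances
made it onto the Candidate List" and keeps both classes interpretable.
Substances with any missing covariate are dropped per sample (listwise
deletion) and the dropped count is reported; missingness here is structural —
no classification-and-labelling entry, or only confidential tonnages — not a
measurement artifact.

## Hazard scores

The raw material is, per substance, the fraction of notifying firms that
label it with GHS codes for each CMR property (carcinogenicity, mutagenicity,
reproductive toxicity) crossed with the signal word, plus acute and chronic
aquatic-hazard fractions. The CMR score sums the six fractions with danger
weighted twice (danger marks the more severe GHS categories) and divides by
the attainable maximum:

$$\mathrm{CMR} = \frac{\sum_{p \in \{C,M,R\}} f_{p,w} + 2 f_{p,d}}{6}, \qquad
\mathrm{Env} = \frac{f_{acute} + f_{chronic}}{2}.$$

Two choices deserve comment. First, the divisor: we normalize by the
*theoretical* maximum (6 for CMR — three properties times a maximal weighted
contribution of 2; 2 for Env), which makes scores comparable across datasets
and puts the stated hand examples (all-danger profile scores 1; a 0.5 danger
plus 0.5 warning profile scores 0.25) on exact footing. An empirical
normalizer (divide by the largest observed weighted sum) is available behind
`normalizer = "empirical"` for sensitivity analysis. The theoretical maximum
of 6 presumes that, per property, a firm files either a warning or a danger
notification, so $f_{p,w} + f_{p,d} \le 1$; we do not *enforce* that
constraint on input data (the inventory aggregates notifications, not firms),
but profiles violating it can exceed 1 and the bounds guarantee applies to
profiles satisfying it. Second, missingness: a substance absent from the
classification-and-labelling inventory gets a *missing* score, never zero —
absence of notification is absence of information, not evidence of safety.

The disaggregated model replaces the two scores by the eight individual
variables (C/M/R × warning/danger, acute/chronic environmental), which are
pass-throughs of the fractions with per-variable missingness.

## Economic and knowledge covariates

**Tonnage.** Registry entries carry an upper tonnage bound or a sentinel.
Confidential entries are discarded first; the covariate is log10 of the
largest remaining upper bound (band 10–100 t ⇒ 2). A substance with only
no-production/intermediate-use entries scores 0; one with only confidential
entries has no data (missing). Dropping confidential entries *before* the
largest-entry rule is our reading of an ambiguous rule; it only matters for
substances mixing confidential and numeric entries, where the numeric
information still identifies a produced volume.

**Countries.** A country counts when it has at least one active or inactive
registrant; the covariate is the square root of the count (variance
stabilization for a right-skewed count). The count is validated against a
configurable EEA maximum (default 30, since EEA membership varied over the
study window).

**Publication rank.** Substance names (a preferred name plus synonyms) are
matched against a literature corpus; a publication counts once regardless of
how many names or occurrences it contains. The count is binned to a grouped
rank: 0 = no publications, 1 = 1–10, 2 = 11–100, 3 = 101–1000, 4 = >1000,
boundaries inclusive on the upper end as printed (exactly 1000 ⇒ rank 3).
Matching is case-insensitive and word-boundary-delimited: text and names are
lowercased, every run of non-alphanumeric characters becomes a single space,
and a name matches when its token sequence occurs contiguously — so "tin"
never matches "tinted", and punctuation variants of a name ("lead(II) oxide",
"lead ii oxide") coincide. Two implementations exist deliberately: a naive
per-substance scan (`count_publications`) and an n-gram-indexed whole-table
matcher (`match_corpus`); the test suite asserts they agree on random
corpora. Live literature retrieval and journal selection are out of scope —
the corpus is an input.

**Normalization.** Before fitting, covariates are mapped to [0, 1]: hazard
scores pass through (they are already unit-range), the publication rank is
divided by its fixed maximum of 4, and `tonnage_log` / `countries_sqrt` are
min-max scaled *over the comparison sample* (they have no theoretical range).
The constants are recorded in the run manifest; re-normalizing a normalized
table is a no-op. A zero-range variable is an error naming the variable, not
a silent constant column.

## Models and inference

`fit_logistic` fits the binomial GLM by iteratively reweighted least squares
(convergence tolerance 1e-8 on the relative log-likelihood change, at most
100 iterations; the fit is deterministic, no seed involved). Odds ratios are
`exp(β)` with Wald 95% intervals `exp(β ± 1.96·SE)` — the standard choice for
forest plots; with [0, 1] covariates an odds ratio is the fold-change from a
covariate's minimum to its maximum. Degenerate designs fail loudly: constant
covariates, rank-deficient designs, and complete separation (which names the
offending covariate) are errors; quasi-separation (fitted probabilities
numerically 0/1) and non-convergence are flagged on the result.

Model fit is the adjusted McFadden pseudo-R²,
$1 - (\ell_{model} - k)/\ell_{null}$ with $k$ the number of covariates
*excluding* the intercept (the penalty convention is not universal; excluding
the intercept makes the null model score exactly 0). Variable significance is
a likelihood-ratio test of the single-variable model against the null:
deviance $2(\ell_1 - \ell_0)$ against χ²(1). Raw p-values are reported with
significance stars at 0.1/0.05/0.01; no multiple-testing correction is
applied, matching the reporting style of the original analyses.

Before fitting, `correlation_screen` removes covariates from pairs with
|Pearson r| above 0.8 (threshold configurable), greedily dropping from the
worst pair the variable with the larger mean absolute correlation,
alphabetical tie-break — deterministic by construction. Per-variable list
comparisons use two-sided Welch t-tests (unequal variances; group sizes
differ by orders of magnitude across lists); the degenerate zero-variance,
equal-means case returns p = 1 by convention. List samples overlap (the
Candidate List is part of the REACH column), as in the tabulations this
mirrors.

## The synthetic registry generator

`simulate_registry` draws a full input bundle — registry entries,
notification fractions, memberships, substance dictionary, publication
corpus — whose defaults *are* the study conditions: 22,425 substances;
Candidate List prevalence 303/22425 with true log-odds over the normalized
covariates set to the headline effect sizes (odds ratios 184 for CMR, 1/520
for countries, 46 for publication rank, with moderate positive tonnage and
environmental effects); SIN and PRIO drawn from hazard-driven logistic rules
calibrated to 999/22425 and 1938/22425; the Authorization List subsampled
from the Candidate List at rate 86/303. Intercepts are calibrated by
root-finding so the *expected* prevalence hits the target given the drawn
covariates.

Marginal families are our choice, since only qualitative shape is documented:
per-property CMR notification totals are zero-inflated Beta(0.5, 2) with a
uniform danger/warning split (so the two signal-word fractions partition the
notifying firms and never exceed 1 jointly); environmental fractions are
driven by a generator-internal GHS aquatic classification (lognormal minimum
effect concentrations against the 0.01/0.1/1 mg/L threshold ladder for
rapidly-degradable / non-degradable / non-degradable-and-bioaccumulative
compounds — the rapidly-degradable-and-bioaccumulative cell is not specified
by the rule as stated and receives the strictest threshold); country counts
are zero-inflated (35% no production) shifted Poisson truncated at the EEA
maximum; tonnage bands are categorical over upper bounds 1–100,000 t with 2%
confidential entries; publication counts are negative binomial (size 0.12,
mean 2.5, capped at 2000 — far above the rank-4 boundary), giving the
strongly right-skewed counts the rank transform exists for. Defaults were
fixed once against the reported order-of-magnitude means (REACH-wide CMR
score ≈ 0.03, log-tonnage ≈ 1.6, √countries ≈ 1.4) and are not tuning knobs.
The corpus is constructed so that name matching recovers each substance's
drawn count exactly, with ~10% decoy records mentioning no substance.

Two wiring details matter for parameter recovery. Membership is drawn from
features normalized with min-max constants computed over the complete-case
substances — exactly the scale on which the pipeline refits the CL-vs-REACH
sample — so recovered coefficients are comparable to the configured truth
without rescaling. Substances with missing features receive mean-imputed
covariates for the draw only; the pipeline's listwise deletion removes them,
and because missingness is independent of everything else this costs
efficiency, not bias. An optional Gaussian-copula knob couples latent
hazardousness to the tonnage draw (default 0 = independent; the true
dependence in real registries is unknown but likely positive).

What the generator does **not** emulate: identity resolution across
identifier systems and grouped list entries (one list row covering many EC
numbers); correlation between hazard notification *completeness* and
economic importance; the nested expert-judgment process that makes real CL,
SIN and PRIO memberships far more mutually consistent than independent
hazard-driven draws (our four-way intersection is correspondingly small);
real corpus language, synonym ambiguity and name collisions. Passing recovery
tests on synthetic data therefore validates the estimator and the plumbing,
not the substantive conclusions on the deposited study data, which can be
re-run by supplying the real tables in the documented schemas.

## Problem sizes and test calibration

The test suite validates inference calibration with problem sizes chosen to
make Monte-Carlo error negligible relative to the tolerances: null-model
calibration uses 1,000 replicates at n = 1,000 (LR p-values tested for
uniformity by Kolmogorov–Smirnov at α = 0.01; Wald CI coverage required
within 95% ± 2%), and parameter recovery uses one draw of the study-condition
scenario at n = 20,000 with every true coefficient required within 3 standard
errors and the qualitative sign pattern (hazard and knowledge odds ratios
above 1, countries below 1) reproduced. Tiny-sample likelihoods are checked
against an independent grid-refinement maximizer to 1e-4, and the 2×2 design
against the closed-form cross-product ratio to 1e-6.

## Known limitations

- Wald intervals can be optimistic near separation; profile-likelihood
  intervals are not implemented (flagged on the fit via `quasi_separation`).
- The adjusted-McFadden penalty convention (k without intercept) is one of
  several in use; comparisons across software should check the convention.
- The union convention for expert-list comparisons is a documented choice,
  not the only defensible one; rerunning with a different sample definition
  only requires a different `build_sample` call.
- Tonnage and country covariates are structurally coupled (both zero for
  non-produced substances); their correlation (~0.65 under defaults) sits
  below the screening threshold but inflates each coefficient's SE.
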