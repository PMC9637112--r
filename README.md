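# svhcdrivers

What drives the listing of substances of very high concern (SVHCs) under the
EU REACH Authorization program? Regulation starts when a substance is placed
on the **Candidate List**, and from there a subset moves to the
**Authorization List**. This package implements a reproducible pipeline for
analysing the relative weight of three kinds of drivers in those listing
decisions:

- **toxicological hazard** — scores aggregated from GHS
  classification-and-labelling notifications (carcinogenicity, mutagenicity,
  reproductive toxicity; acute and chronic aquatic hazard),
- **economic interests** — production/import tonnage bands and the number of
  EEA countries with active or inactive registrants,
- **scientific knowledge** — a grouped rank of how often a substance is
  mentioned in a toxicological literature corpus.

It is aimed at regulatory-toxicology and environmental-economics researchers
who want to re-run, stress-test, or extend this style of analysis. Because the
real inputs (ECHA registry extracts, the C&L inventory, list snapshots, a
PubMed-derived corpus) cannot be redistributed here, the package ships a
seeded synthetic registry generator with the same statistical structure, so
every stage — including parameter recovery — runs offline.

## The model

For a comparison sample (e.g. Candidate List vs all of REACH), membership of
the focal list is a binary outcome `y` modelled by logistic regression on
covariates normalized to [0, 1]:

    logit P(y = 1) = β₀ + β₁·CMR + β₂·Env + β₃·tonnage + β₄·countries + β₅·pubrank

- `CMR = [Σ_{p∈{C,M,R}} (f_p,warning + 2·f_p,danger)] / 6` — notification
  fractions per property, with "danger" weighted twice, scaled by the
  attainable maximum;
- `Env = (f_acute + f_chronic) / 2`;
- `tonnage = log10(largest upper tonnage band)`, with zero for
  no-production/intermediate-use substances and missing when only
  confidential entries exist;
- `countries = √(active + inactive registrant countries)`;
- `pubrank ∈ {0,…,4}` for 0, 1–10, 11–100, 101–1000, >1000 matched
  publications.

Because each covariate spans [0, 1], `exp(βⱼ)` is the odds fold-change from
that covariate's minimum to its maximum — the quantity plotted in a forest
plot. Model fit is summarised by the adjusted McFadden pseudo-R²
`1 − (ℓ_model − k)/ℓ_null`, and each variable's significance by a
likelihood-ratio test of its single-variable model against the null.
Covariate pairs with |r| > 0.8 are screened before fitting, and per-variable
Welch t-tests compare list means.

## Worked example

```r
library(svhcdrivers)

# synthetic universe under the study conditions (22,425 substances,
# Candidate List prevalence 303/22425, strong hazard/knowledge effects,
# strong negative country effect)
bundle <- simulate_registry(study_scenario(n_substances = 22425, seed = 1))

res <- run_analysis(bundle, focal = "cl", reference = "reach")
print(res$fit)
```

```
Logistic fit [CL_vs_REACH]: n = 16884, k = 5, adjusted McFadden R2 = 0.1858
                 estimate     se odds_ratio  ci_low  ci_high
(Intercept)       -4.5030 0.1333     0.0111  0.0085   0.0144
cmr_score          4.6876 1.0618   108.5965 13.5512 870.2697
env_score          0.7800 0.3007     2.1814  1.2101   3.9324
tonnage_log        0.5350 0.6311     1.7075  0.4956   5.8823
countries_sqrt    -5.6402 0.7937     0.0036  0.0007   0.0168
publication_rank   4.4406 0.3764    84.8257 40.5667 177.3724
```

Reading: of the 22,425 simulated substances, 16,884 have complete covariates
(substances missing from the C&L inventory or with only confidential tonnage
are dropped). A substance whose CMR score goes from 0 to 1 multiplies its
odds of Candidate-List inclusion by ≈109 (true simulated value 184, within
the Wald interval); moving from no producing country to the sample maximum
*divides* the odds by ≈280 (true value 520); publication rank raises odds by
≈85 (true value 46). The signs and magnitudes reproduce the simulated truth
within sampling error — the pattern where economic presence dominates
hazard in the listing odds.

The numbered scripts under `analysis/` run the complete workflow (simulate →
features → models → overlap report) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_features.R
Rscript analysis/03_models.R
Rscript analysis/04_report.R
```

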