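# wealthineq

Quantify and decompose household-wealth inequality in under-five deaths
(U5D) from child-level survey microdata.

Large multi-country survey programmes record, for every live birth,
whether the child died before 60 months, the household's asset-based
wealth quintile, a sampling weight, the sampling cluster
("neighbourhood") and a set of individual and household covariates.
`wealthineq` implements the full analysis chain used to study the
poor/non-poor mortality gap in such collections:

1. **Harmonization** — the poor/non-poor dichotomy (wealth quintiles 1–2
   vs 3–5), a neighbourhood socioeconomic composite (first principal
   component of cluster-level no-education, no-media-access and
   unemployment rates), and iterative variance-inflation-factor
   screening (`VIF_j = 1/(1-R²_j)`, threshold 2.5).
2. **Summary measures of inequality** — weighted quintile prevalences and
   the WHO HEAT-style measures, for an adverse indicator with reference
   subgroup Q5 (richest):
   `D = r(Q1) − r(Q5)`, `R = r(Q1)/r(Q5)`, `PAR = r(Q5) − μ` (truncated
   at 0), `PAF = PAR/μ × 100`, with confidence intervals.
3. **Meta-analysis** — per-country poor-minus-non-poor risk differences
   (per 1000 live births), DerSimonian–Laird random-effects pooling with
   Cochran's `Q`, `τ²` and `I²`, the Mantel–Haenszel pooled odds ratio
   `OR_MH = Σ(aᵢdᵢ/nᵢ)/Σ(bᵢcᵢ/nᵢ)` with the Robins–Breslow–Greenland
   variance, and a burden-by-inequality country typology.
4. **Fairlie nonlinear decomposition** — the poor/non-poor gap in death
   probability is split into per-covariate compositional contributions:
   a pooled weighted logit supplies common coefficients β\*, groups are
   rank-matched on predicted probability, covariates are switched one
   block at a time from poor to non-poor values, and the path dependence
   of the sequential substitution is averaged out over random covariate
   orderings and subsample draws.
5. **Synthetic data** — a multi-country clustered survey generator with
   known ground truth (logistic outcome model, cluster random
   intercepts, per-country deviations of the poor effect, log-normal
   weights), so the whole pipeline is testable without restricted
   microdata.

## Worked example

```r
library(wealthineq)

cfg     <- pop_config(n_countries = 8, clusters_per_country = 40,
                      births_per_cluster = 30)
surveys <- generate_multicountry(cfg, seed = 2026)
records <- bind_surveys(surveys)
frame   <- build_analysis_frame(records)

compute_heat(estimate_subgroups(surveys[["C03"]]))
#> Inequality measures (adverse, reference Q5, scale per100)
#>   D  : 1.48 (-1.99 to 4.96)
#>   R  : 1.52 (0.56 to 4.15)
#>   PAR: -1.41 (-3.94 to 1.12)
#>   PAF: -33.28 (-89.19 to 22.63)

rds <- lapply(surveys, country_risk_difference)
dl_random_effects(vapply(rds, `[[`, numeric(1), "rd"),
                  vapply(rds, `[[`, numeric(1), "se"))
#> Random-effects meta-analysis (DerSimonian-Laird), k = 8
#>   fixed : 21.591 (11.814 to 31.367)
#>   random: 23.517 (7.343 to 39.691)
#>   Q = 19.000 on 7 df, tau2 = 342.49501, I2 = 63.2%

mh_pooled_or(lapply(surveys, wealth_death_table))
#> Mantel-Haenszel pooled OR = 1.565 (1.309 to 1.871), z = 4.91, p = 9.1e-07
#> Homogeneity X2 = 19.64 on 7 df (p = 0.0064), I2 = 64.4%

fairlie_decompose(frame, n_orderings = 20, n_subsamples = 5, seed = 11)
#> Fairlie decomposition of the poor/non-poor gap
#>   total gap  : 0.0247
#>   explained  : 0.0146 (59.3% of gap)
#>   unexplained: 0.0100
#>   replications: 20 orderings x 5 subsample draws
#>             covariate contribution replication_sd pct_of_gap pct_of_explained
#> 1  maternal_education       0.0046       1.24e-04       18.8             31.7
#> 2           residence       0.0050       1.12e-04       20.2             34.1
#> 3        water_source       0.0020       5.49e-05        8.2             13.8
#> 4           sex_child       0.0001       8.49e-05        0.3              0.5
#> 5        media_access       0.0030       1.07e-04       12.1             20.3
#> 6 maternal_employment      -0.0001       2.23e-05       -0.3             -0.5
```

Reading: the random-effects pooled risk difference is 23.5 per 1000
(pro-non-poor: poor children die more), with I² = 63% between-country
heterogeneity; the Mantel–Haenszel odds of dying before five are 1.57
times higher for poor children controlling for country; and 59% of the
raw 2.5-percentage-point gap is explained by covariate composition,
mostly maternal education, residence and media access — the expected
picture, since the generator's default world puts most of the gap into
those compositional gradients.

`run_pipeline(run_config(synthesis = cfg, seed = 2026))` runs all the
stages and writes CSV/JSON outputs plus a manifest;
`inst/cli/wealthineq.R` exposes the same stages as `simulate`,
`harmonize`, `heat`, `meta`, `decompose` and `all` subcommands.

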