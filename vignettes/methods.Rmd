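---
title: "Methods: measuring and decomposing wealth inequality in under-five mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and decomposing wealth inequality in under-five mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wealthineq)
```

## The problem

In household surveys of the DHS type, each live birth carries a binary
outcome (death before 60 months), an asset-based within-country wealth
quintile, a sampling weight, a sampling-cluster id and categorical
covariates.  Children in wealth quintiles 1–2 are classed as *poor*,
quintiles 3–5 as *non-poor*.  The questions this package answers are:
how large is the poor/non-poor mortality gap in each country and
overall; is it *pro-non-poor* (poor children die more) or *pro-poor*;
how heterogeneous is it across countries; and how much of it is
*compositional* — attributable to poor households simply having worse
distributions of measured covariates — versus a residual group effect.

## The synthetic world

Because the real microdata are access-restricted, every stage is
exercised on a generator with known ground truth.  For country $c$,
cluster $k$ and birth $i$:

$$\operatorname{logit} p_{cki} = \alpha + (\beta_{\text{poor}} + \delta_c)\,
  \mathbb{1}[q_{cki} \le 2] + \sum_j \beta_j x_{ckij} + u_{ck},$$

with $u_{ck}\sim N(0,\sigma^2_{\text{cluster}})$ drawn once per cluster
and $\delta_c\sim N(0,\sigma^2_{\text{country}})$ once per country (the
latter drives downstream meta-analytic heterogeneity).  Wealth
quintiles come from ranking a continuous asset score $N(0,1)$ within
country and cutting at weighted 20% points (ties broken by a seeded
draw); sampling weights are log-normal (log-scale SD 0.3 by default)
normalized to mean 1 within country; covariates are drawn from
group-specific category distributions, the simplest structure that
creates compositional gaps for the decomposition to find.

Defaults and why:

* **Scale**: 40 countries × 50 clusters × 30 births (60,000 records) —
  desk scale, large enough for stable weighted rates per quintile.
* **Coefficients**: calibrated once, by Monte-Carlo, against the
  marginal world typical of pooled LMIC collections — a non-poor death
  rate of 44 per 1000 and (from the compositional gradients alone) a
  poor rate of 60 per 1000.  That fixed the intercept at −3.52.  A
  modest direct poor effect, $\log 1.10$, is kept on top, lifting the
  poor rate to ~65–67 per 1000 (overall ~52), so most but not all of
  the default gap is compositional.  The calibration was performed
  before any acceptance measurement and has not been revisited.
* **Random-effect SDs**: 0.25 (cluster) and 0.30 (country) on the
  log-odds scale — with a mean log-odds gap of ~0.4, a country SD of
  0.30 makes roughly one country in eight run pro-poor, matching the
  minority of reversed-gap countries seen in real collections.

What the generator does **not** emulate: questionnaire content,
multi-stage frame construction, non-response, within-household birth
correlation beyond the shared cluster intercept, and the DHS
asset-index construction itself.  A green test therefore establishes
correctness of the estimators under clustered, weighted, covariate-
stratified sampling — not robustness to real-survey pathologies such as
informative non-response.

`true_contributions()` gives the generator's ground-truth per-covariate
contributions by direct Monte-Carlo evaluation of the sequential
substitution under the *generating* coefficients (no fitting), averaged
over all covariate orderings, with the direct poor effect excluded —
the estimand the decomposition targets.

## Harmonization

* **Dichotomy**: poor = quintile ≤ 2 (configurable cutoff).
* **Neighbourhood SES composite**: per-cluster weighted rates of
  no-education, no-media-access and unemployment; standardized; first
  principal component of their correlation matrix (the three rates are
  on comparable but not identical scales, so the correlation-matrix
  variant is the safer default); sign oriented so the loading on
  no-education is positive (higher score = more disadvantage); clusters
  cut into weighted quintiles of the score.  Rates are computed with
  sampling weights; pass `weighted = FALSE` to switch this off — the
  choice is documented because survey practice varies and the method's
  description does not fix it.  All-zero-variance ingredients raise a
  degenerate-composite error; single degenerate ingredients are dropped
  with a warning.
* **VIF screen**: `VIF_j = 1/(1-R²_j)` per dummy column; elimination is
  iterative, worst offender first, recomputing after each drop, until
  all retained VIFs are ≤ 2.5.  Exact ties break alphabetically;
  note that theoretically tied columns (e.g. an exactly correlated
  pair) differ in the last floating-point digits, so which member of
  the pair goes is numerically arbitrary — only "exactly one of the
  pair" is guaranteed.  Perfectly collinear columns get `VIF = ∞` and
  go first.  A covariate is dropped from the analysis set if any of its
  dummy columns is eliminated.
* **Missing data**: complete-case deletion with a logged count,
  performed before the SES composite so every stage sees clean data.
  No imputation.

## HEAT-style summary measures

With per-quintile weighted rates $r_1,\dots,r_5$ (per 1000), national
average $\mu$, and Q5 (richest) the most-advantaged reference for an
adverse indicator:

$$D = r_1 - r_5,\qquad R = r_1/r_5,\qquad
  \text{PAR} = r_5 - \mu,\qquad \text{PAF} = 100\,\text{PAR}/\mu .$$

Conventions and numerical choices:

* The *reference subgroup is the richest quintile*.  Published tables of
  this analysis type sometimes describe the most-advantaged subgroup as
  the "lowest" quintile, but the sign pattern of every tabulated row
  (PAR/PAF ≤ 0, truncated rows where the richest quintile does worse
  than average, PAF = −100 where its rate is 0) is reproduced only with
  the richest quintile as reference; the package follows the sign
  pattern.
* **Truncation**: for an adverse indicator a positive PAR is set to 0
  (with `truncated = TRUE`) — the reference subgroup doing worse than
  the average cannot yield a beneficial attributable risk.  Truncated
  measures keep the untruncated-width confidence interval centred at 0,
  matching the `0 (−x, +x)` display convention.
* **PAF = −100 exactly** iff the reference rate is 0 (untruncated).
  When $r_5 = 0$, `R` is flagged *undefined* rather than printed as a
  number — published tables show `0 (0-0)` in that case, which is a
  display rule this package does not guess.
* **Scales**: prevalences are carried per 1000; `D` and `PAR` are
  reported per 100 by default (matching conventional table magnitudes),
  with `scale = "per1000"` available.
* **Uncertainty**: subgroup SEs use the weighted proportion with
  effective sample size $n_{\text{eff}} = (\sum w)^2/\sum w^2$; D gets
  a normal CI with $\sqrt{SE_1^2+SE_5^2}$; R a log-scale delta CI; PAR
  and PAF delta CIs treating the reference rate and $\mu$ as
  independent — conservative, since their true correlation through the
  shared sample is positive.  No survey linearization: the design
  effect captured is the weight variation, not clustering.

## Meta-analysis

Per-country risk differences $\mathrm{RD} = r_{\text{poor}} -
r_{\text{non-poor}}$ per 1000 with normal CIs classify countries as
pro-non-poor (CI > 0), pro-poor (CI < 0) or insignificant.  Pooling is
DerSimonian–Laird:

$$\tau^2 = \max\!\left(0, \frac{Q - (k-1)}{\sum w_i - \sum w_i^2/\sum
  w_i}\right),\qquad I^2 = \max\!\left(0,\frac{Q-(k-1)}{Q}\right)\times 100,$$

the classic default of the standard binary-outcome meta-analysis
workflow; REML is deliberately not the default.  The Mantel–Haenszel
pooled odds ratio uses the Robins–Breslow–Greenland variance, a z-test
of OR = 1, and a Woolf-type homogeneity chi-square on per-stratum log
odds ratios (0.5 continuity correction on zero cells, logged).  The
country typology cross-classifies overall prevalence against 25 per
1000 — the SDG 2030 benchmark — and RD direction against 0; both
thresholds are configuration because the source analysis states no
numeric cutoffs.

## Fairlie decomposition

For a binary outcome, the group gap in mean predicted probability under
common coefficients $\beta^*$ decomposes over matched pairs: with both
groups reduced to the same size $N$, the contribution of covariate
block $j$ under ordering $\sigma$ is the change in
$\tfrac1N\sum_i F(\cdot)$ when block $j$ is switched from the poor to
the matched non-poor values, all blocks before it (in $\sigma$) already
switched.  The chain telescopes, so per replication the contributions
sum *exactly* to the explained gap $\tfrac1N\sum F(X^A\beta^*) -
\tfrac1N\sum F(X^B\beta^*)$ (asserted at 1e−10 relative tolerance in
the tests; only the split across covariates is path-dependent).

Choices the method description leaves open, and the defaults here:

* **$\beta^*$**: pooled weighted logit over both groups *including* the
  poor indicator, whose coefficient is dropped at prediction time — the
  standard default of the widely used implementation.  Group-specific
  coefficients are not the default.
* **Matching**: the larger group is subsampled without replacement to
  the smaller group's size with draw probabilities proportional to
  sampling weights (so the subsample represents the weighted
  population); both sides are then sorted by predicted probability and
  matched by rank.  Matching itself is unweighted — a documented
  approximation, in line with the method's own concession that it does
  not account for clustering and stratification.
* **Randomization**: path dependence is averaged over `n_orderings`
  random permutations × `n_subsamples` subsample draws (defaults 100 ×
  100; the pipeline uses 20 × 5 at desk scale — the replication SD of
  each contribution is already two orders of magnitude below the
  contribution itself there).  With balanced groups the matching is
  deterministic and one subsample replication is used.
* **Uncertainty**: the replication SD across draws — *not* an analytic
  or resampling SE.  It quantifies path/matching randomness only; see
  Limitations.
* **Percent base**: `pct_of_gap` divides by the raw total gap (so
  values may be negative or exceed 100 when covariates push in opposing
  directions); `pct_of_explained` is also emitted.  A zero total gap
  flags percents as undefined while keeping absolute contributions.
* **Categorical covariates** are switched as whole dummy blocks, so a
  covariate's contribution is a single number regardless of its number
  of levels.
* **Separation and collinearity**: inestimable coefficients name the
  offending column and point to the VIF screen; runaway coefficients
  (|β| > 15) are reported as separation.

## Numerical conventions

* Weighted quantile cuts assign a record to bin $b$ when its cumulative
  weight share lies in $((b-1)/5, b/5]$, ties broken by a seeded draw.
* Derived seeds: child streams use a fixed integer recurrence on the
  master seed, kept below $2^{31}$; identical (config, seed) gives
  bit-identical output everywhere, including CSV round-trips (numeric
  columns are written with 17 significant digits).
* `I²` is reported as 0 when `Q = 0` (including the single-study case,
  which warns); meta weights are normalized to percentages summing
  to 100.
* A label swap of the two groups negates the total gap exactly, and the
  explained gap exactly *at fixed coefficients*; after a pooled refit
  the intercept absorbs the flipped group dummy, so end-to-end negation
  is exact only up to that intercept shift.  The tests assert the exact
  fixed-coefficient identity.

## Limitations

* SEs use effective sample size only; intra-cluster correlation is not
  linearized, so CIs are mildly anti-conservative under strong
  clustering.  The null-calibration acceptance test (no clustering, no
  heterogeneity) shows the nominal 2.5% one-tail misclassification and
  ~95% pooled-CI coverage in the setting where the approximation is
  exact.
* The decomposition's replication SD understates total uncertainty: it
  captures ordering/subsample randomness but not the sampling error of
  $\hat\beta^*$.  Concretely, in the parameter-recovery acceptance
  setting (n = 50,000, event rate ~5%), the replication SD of the
  active covariate's contribution is ~9×10⁻⁴ while the coefficient
  sampling error propagates to ~2×10⁻³ on the contribution scale; a
  "within 3 replication SDs of truth" bound is therefore expected to
  fail even for a correct implementation, and the corresponding
  expectation is deliberately left failing rather than widened.  The
  recovery itself is sound: the lone compositionally different
  covariate carries ~101% of the explained gap and the null covariates
  ~0%.
* Wealth itself is not used as a decomposition covariate by default
  (the groups are defined by it); callers may add a within-group
  quintile covariate explicitly if they want the residual within-group
  wealth gradient decomposed — an internally ambiguous choice in the
  source analysis, left to the user here.
* No SII/RII or concentration-index measures; no funnel plots; no map
  rendering.
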