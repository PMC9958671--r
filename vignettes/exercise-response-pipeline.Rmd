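---
title: "Methods: exercise-response analysis of paired urine and plasma metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exercise-response analysis of paired urine and plasma metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromet)
options(uromet.verbose = FALSE)
```

# The problem

Myalgic encephalomyelitis / chronic fatigue syndrome (ME/CFS) is
characterized by post-exertional malaise: a worsening of symptoms after
exertion. One window on its physiology is the urine metabolome measured
before and 24 h after a maximal cardiopulmonary exercise test (CPET),
compared between patients and sedentary controls, with a companion plasma
panel from the same subjects. The design this package targets is small and
paired: two cohorts (8 sedentary control and 10 ME/CFS female subjects in
the motivating design), two urine timepoints (baseline U1, 24 h
post-exercise U3), four plasma draws (P1 baseline, P2 shortly
post-exercise, P3 at 24 h, P4 shortly after a second CPET), and an
untargeted LC-MS/MS panel of around 1400 compounds of which roughly 60%
are identified and annotated into non-overlapping subpathways.

`uromet` implements the complete analysis chain for this design as
composable, tested stages, together with a synthetic-data generator whose
ground truth makes every stage's behavior checkable. The central
scientific pattern the pipeline is built to detect is an *asymmetric
exercise response*: metabolites that rise in the urine of controls during
recovery but not in patients.

# Preprocessing

The preprocessing contract is fixed, in this order:

1. **Osmolality normalization** (urine only): each sample is divided by
   its measured osmolality (mOsm/kg), removing dilution differences
   between urine collections. This is a per-sample scalar division, so it
   exactly inverts a multiplicative dilution.
2. **Imputation**: missing cells of a metabolite are replaced by that
   metabolite's minimum observed value across all samples — the standard
   convention when missingness is left-censoring at a detection limit.
   Drug and tobacco compounds are imputed to 0 instead: for an exposure
   compound, absence of signal means absence, not a low concentration.
   An all-missing non-drug metabolite cannot be imputed and is dropped
   with a log entry.
3. **Median centering**: each metabolite is divided by its median, so the
   per-metabolite median is 1 to machine precision. If the median is 0
   (possible for drug compounds), the smallest positive value is the
   divisor; with no positive value the metabolite is dropped. Both
   fallbacks are logged.
4. **Variance-stabilizing log10**: the generalized log
   `glog10(x) = log10((x + sqrt(x^2 + lambda^2))/2)` with
   `lambda` = (smallest positive matrix value)/10. It is strictly
   increasing, asymptotically `log10(x)`, and finite at 0 — plain
   `log10` is not, and the drug convention above produces genuine zeros.
   A strict `log10` mode is available via `run_config(vst = "log10")`;
   on data without zeros the two differ only within ~`lambda` of zero.
5. **Modified 80% detection filter**: a metabolite is retained iff it was
   detected (pre-imputation) in at least 80% of all control samples or at
   least 80% of all case samples, both timepoints pooled within cohort.
   The threshold is non-strict (>= 0.8). The detection mask always
   reflects the pre-imputation state, so the filter is order-independent
   with respect to the transform steps.

Per-subject recovery ratios are formed on the transformed scale as
post minus baseline (log10 of the ratio); only subjects with both
timepoints contribute. Fold changes are converted to log2 for reporting
via the change of base (`x / log10(2)`).

One deliberate exception: the cross-biofluid correlation stage runs on the
*unfiltered* shared panel, because a compound sparsely detected in urine
can still correlate informatively with its plasma counterpart.

# The per-metabolite mixed model

Each retained urine metabolite is modeled as

```
value ~ cohort * timepoint + age + bmi + (1 | subject)
```

with a subject random intercept absorbing the strong within-person
correlation of the two timepoints, and age and BMI (centered at their
sample means) adjusting for the cohorts' demographic imbalance.

Estimation is REML with the variance ratio
`theta = sigma_u^2 / sigma_e^2` profiled out: for fixed `theta`,
generalized least squares gives the fixed effects and the residual
variance in closed form, and the one-dimensional profiled criterion is
minimized by a coarse log-scale grid (`theta` from 1e-6 to 1e6, with the
`theta = 0` boundary evaluated explicitly) followed by golden-section
refinement. Because the random-effect structure — the subject incidence
matrix — is identical for every metabolite, its eigendecomposition is
computed once per dataset and every criterion evaluation reduces to
diagonally weighted least squares; a full panel of ~1200 metabolites fits
in seconds. Boundary fits (`sigma_u^2 = 0`, common at n = 18 subjects)
are flagged, not discarded.

Five contrast families are reported per metabolite: case vs control at
baseline, case vs control post-exercise, the within-cohort change over
time for each cohort, and the cohort-by-timepoint interaction — the
difference of the two within-cohort changes, which is the direct test of
an asymmetric exercise response. Covariates carry zero contrast weight,
so every contrast is a marginal comparison at equal age and BMI.
Two-sided p-values use a t reference with Satterthwaite degrees of
freedom computed analytically from the gradient of the contrast variance
and the REML information of the variance components (a residual-df
fallback, `n_subjects - n_fixed`, is available via
`run_config(df_method = "residual")`). The test suite verifies exact
agreement of estimates, variance components, Satterthwaite df and
p-values with `lmerTest`, and of the optimum against an independent
grid/golden-section maximizer.

Benjamini–Hochberg adjustment is applied separately within each contrast
family across metabolites; the default significance threshold is
`q < 0.1`. Reported fold changes follow the plotting convention: for the
interaction, the ratio of ratios (mean case recovery ratio minus mean
control recovery ratio, in log2); for single-timepoint contrasts, the
difference of cohort means of transformed values.

# Set enrichment

Subpathway annotations are non-overlapping, so enrichment needs no
background metabolome: each set of member p-values (from one contrast) is
compared to Uniform(0,1) with a one-sample Kolmogorov–Smirnov test,
one-sided in the enrichment direction (members stochastically smaller
than uniform). Sidedness is not universally standardized for this use;
the two-sided variant is available via
`run_config(ks_alternative = "two.sided")`. Sets of size 1 are skipped.
Set p-values are BH-adjusted across sets — threshold `q < 0.05` for
subpathways and `q < 0.15` for chemical-similarity clusters, the looser
cluster threshold reflecting the exploratory role of that view. Each
record carries the *altered ratio* (fraction of members with `p < 0.05`)
and the *increased ratio* (fraction of altered members with positive
fold change of the mean normalized — i.e. median-centered — concentration),
which drive bubble size and color in the standard visualization. The
chemical-cluster mode consumes a precomputed `cluster_id` column;
mapping compounds to clusters from structure codes requires external
services and is out of scope.

# Pathway topology

Pathway graphs are user-supplied undirected edge lists over HMDB
identifiers (no reference database ships with the package; versions and
licenses drift). Annotated metabolites are matched to nodes by HMDB id
with a first-duplicate rule: when several metabolites share an id, only
the first in annotation order is kept. Each pathway with at least two
matched metabolites is scored two ways:

* **Quantitative enrichment (global test)**: the score statistic
  `Q = ||X'(y - ybar)||^2 / m` on the column-standardized matched
  matrix `X` against the 0/1 cohort labels — the score form of testing
  whether the pathway's metabolites improve classification of the
  samples, with the null that no member differs between groups.
  Inference is by label permutation (default 9999 permutations, add-one
  smoothing), which is exact at this study's sample size and verified in
  the tests against exhaustive label enumeration; the original
  formulation's asymptotic chi-square mixture is deliberately not used.
* **Impact**: node importances are relative betweenness centralities
  (Brandes semantics — unweighted shortest paths, fractional credit for
  ties, endpoints excluded), normalized so each pathway's maximum is 1;
  the impact score is the sum of importances over matched nodes. Graphs
  with no intermediate vertices anywhere (2-node graphs, complete
  triangles, isolated nodes) have all importances 0.

The timepoint comparison scores per-sample transformed values at the
post-exercise timepoint; the recovery comparison scores per-subject
ratios. Global-test p-values are BH-adjusted across pathways,
threshold `q < 0.2`.

# Cross-biofluid correlations

For compounds measured in both fluids, Pearson correlations are computed
within cohort at seven subject-paired pairings: the same-day timepoint
pairs (U1 with P1 and P2; U3 with P3 and P4) and the recovery-ratio pairs
(U3/U1 with P4/P1, P3/P2, P3/P1). The p-value is the t-test of R = 0
(`t = R sqrt((n-2)/(1-R^2))`, `n - 2` df); BH families are per
cohort-by-pairing across metabolites (a single global family is
config-switchable), threshold `q < 0.15`. The census counts strong
correlations (`R > 0.7`, `R < -0.7`) per cohort and pairing.

Outlier handling follows a compound-level scope rule: modified z-scores
(`0.6745 (x - median) / MAD`, raw MAD) are computed per metabolite for
every variable vector with cohorts pooled; any `|z| > 6` in a timepoint
variable removes the compound from all timepoint pairings only, and any
outlier in a ratio variable removes it from all ratio pairings only. A
zero MAD makes outliers uncallable for that vector, which is flagged.

The differential screen then asks for compounds whose urine–plasma
relationship differs qualitatively between cohorts: criterion 1, one
cohort with `|R| > 0.7`, `p < 0.05` and `q < 0.15`; criterion 2, the
other cohort with `|R| < 0.3` or an oppositely signed R. Criterion 2's
weak-correlation bound is interpreted as a bound on `|R|` (the natural
reading when the significant correlation is negative); this is
config-switchable via `weak_r`. Correlations use the transformed values —
the only matrix the preprocessing contract defines.

# Subject clustering

Subjects are clustered on the post-exercise discriminating compounds
(those with `q < 0.1` in the case-vs-control post-exercise contrast),
using their normalized (median-centered) post-exercise concentrations:
agglomerative hierarchical clustering, Euclidean distance, Ward.D2
linkage, cut at k = 3 by default. `hclust`'s deterministic agglomeration
is verified in the tests against an independent Lance–Williams
implementation of the Ward.D2 update; merge heights are monotone, and the
result is invariant to metabolite column order.

# The synthetic-data generator

`simulate_study()` generates paired urine + plasma studies with known
ground truth. The log10 latent urine value of subject *j*, metabolite
*m*, timepoint *t* is

```
x = mu_m + u_j + a_m age_j + b_m bmi_j + delta_m [case]
    + gamma_m [t = U3] + eta_m [case & t = U3]
    + z_jm + r_jm [t = U3] + eps
```

with subject intercept `u_j ~ N(0, sigma_u^2)`, a subject-by-metabolite
level deviate `z_jm` and a post-exercise response deviate `r_jm` that are
shared with the plasma series at correlation `rho_m`, and residual
`eps ~ N(0, sigma_e^2)`. The stored raw urine value is
`osmolality_s * 10^x` — osmolality multiplies the raw scale, so
normalization exactly inverts it — and any cell whose pre-osmolality
value falls below the per-metabolite detection limit is left-censored to
missing, matching the assumption under which minimum-value imputation is
sensible. *Responder* subpathways carry `gamma_m = 0.3` and
`eta_m = -gamma_m`: a post-exercise increase in controls that cases do
not show, the asymmetric-recovery structure of interest.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_control`, `n_case` | 8, 10 | the emulated design |
| `n_metabolites` | 1403 | panel size, split 886/64/453 known/partial/unknown |
| `responder_frac` | 0.1 of subpathways | ~10% of compounds respond asymmetrically, the order of the motivating data's interaction-significant fraction |
| `gamma` | 0.3 log10 (2-fold) | a clearly detectable but not overwhelming paired effect at n = 8 |
| `sigma_u`, `sigma_e` | 0.1, 0.15 log10 | between-subject and residual spread typical of normalized urine panels |
| `sigma_met`, `sigma_resp` | 0.2, 0.1 | subject-by-metabolite level and response heterogeneity; these carry the cross-fluid coupling |
| `rho` | 0.8 | strong urine–plasma coupling, putting the strong-correlation census in the tens of percent |
| osmolality | log-normal(log 600, 0.35) mOsm/kg | physiological urine osmolality range |
| censoring | 80% of metabolites at 0–5% missing, 20% at 15–70% | leaves roughly 80% of the panel passing the detection filter, matching the motivating data's retention rate |
| ages ~ U(45, 60); BMI ~ N(33, 4) control / N(25, 4) case | | cohorts age-matched but BMI-imbalanced, so the covariate adjustment is load-bearing |

What the generator does *not* emulate: batch effects and instrument
drift (the motivating assay ran in a single batch), heteroscedastic
mass-spectral noise, non-normal heavy tails, correlated metabolite blocks
within subpathways beyond the shared subject deviates, diet-driven
xenobiotic structure, and informative (non-left-censored) missingness.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artifact of
real LC-MS/MS data.

# Numerical choices and degenerate inputs

* `theta` search bounded to [0, 1e6] with the boundary evaluated
  explicitly; non-finite criteria mark the fit unconverged.
* Satterthwaite df falls back to the residual df when the variance-
  component information matrix is numerically singular.
* BH is implemented as the exact step-up rule (`q_(i) = min_{j>=i}
  m p_(j)/j`, capped at 1) and cross-checked against `p.adjust`.
* Ties in agglomeration follow `hclust`'s deterministic behavior; with
  continuous data exact ties have measure zero.
* Degenerate vectors: zero-variance correlation inputs are flagged and
  skipped; zero-MAD outlier vectors are flagged with no outliers called;
  KS sets of size < 2 are skipped; pathways with < 2 matched metabolites
  are skipped. All skips are logged.
* Problem sizes used by the checks: the test suite runs panels of
  60–1000 metabolites at the emulated 18-subject design (about a minute
  in total), and the acceptance script one full 1403-metabolite study
  plus a 400-metabolite null study and a 100-metabolite noise-free study
  (about half a minute).

# A worked example

```{r example}
sim <- fixture_small()
cfg <- run_config(n_perm = 499)
run <- run_pipeline(sim$urine, sim$plasma, sim$samples, sim$annotation,
                    graphs = toy_pathway_graphs(sim$annotation),
                    config = cfg)
str(run$summary)
head(subset(run$lmm$results, contrast == "interaction"))
```

# Known limitations

* The model has a single random intercept; random slopes are neither
  needed for two timepoints nor identifiable here.
* Kenward–Roger df are not implemented; with n = 18 subjects,
  significance counts near a q threshold can shift by a few metabolites
  between df approximations, which is why both Satterthwaite and the
  conservative residual fallback are exposed.
* The chemical-cluster enrichment requires cluster assignments computed
  elsewhere; the package does not map structures to clusters.
* Pathway membership counts depend entirely on the supplied graphs;
  nothing is downloaded.
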