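---
title: "Methods: comparative heavy-metal tolerance in butterflies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative heavy-metal tolerance in butterflies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

metaltol tests two explanations for why some butterfly species carry —
and presumably tolerate — higher heavy-metal burdens than others: the
*toxin coevolution hypothesis* (an evolutionary history with mutagenic
host-plant chemistry preadapts a species to novel toxins) and the
*range-size–tolerance hypothesis* (large geographic ranges select for
broad stressor tolerance). The package turns each hypothesis into a
quantitative species-level predictor, turns field tissue concentrations
into species-level tolerance proxies, and relates the two with
phylogenetic regression. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## 1. Mutagenicity of host-plant families (Ames scoring)

The raw material is a table of literature Ames tests: one row per assay
of a plant extract, with the plant's family and order, methodology
covariates (extraction solvent class, bacterial strain, S9 metabolic
activation), and a binary outcome — mutagenic if revertant colonies at
least doubled over control.

Raw per-family positive proportions confound biology with methodology:
some families happen to have been screened mostly with high-sensitivity
strains or activating conditions. `fit_methodology_model()` therefore
fits a binomial (logistic) regression of outcome on family plus the
methodology covariates, and `family_scores()` converts it to a
per-family probability by **marginal standardization**: the mean
predicted positive probability for that family, averaged over the
empirical joint covariate distribution of the *whole* dataset. This
construction has two properties we rely on:

* when the covariates are constant (or dropped as inert) it reduces
  *exactly* to the raw per-family proportion, and
* under covariate–family confounding it estimates the proportion the
  family *would* show under the pooled mix of methodologies, which is
  the comparable quantity across families.

The additive correction is on the logit scale, the natural scale of the
logistic model. Perfect separation (families with all-positive or
all-negative outcomes under some covariate pattern) is detected from the
fitted probabilities and handled by refitting with a small ridge penalty
(`penalty`, default 0.5) on the non-intercept coefficients, keeping
scores finite; the penalty is never applied when the model is well
identified, so it cannot bias the ordinary case.

Families with fewer than `min_tests` (default 8) assays are too sparse
for a family-level estimate; they inherit the corrected score of their
plant *order*, computed the same way from all records of that order, and
are flagged `order_fallback`. The rule is exact: `level ==
"order_fallback"` iff `n_tests < min_tests`.

`family_effect_test()` asks whether family matters at all, as a partial
F test for the family factor in a linear probability model of the 0/1
outcome on covariates plus family, restricted to families meeting the
replicate threshold. An F on 0/1 outcomes is an approximation, but a
well-behaved one at these group sizes, and a null simulation (in the
test suite) confirms near-nominal rejection. Because published analyses
of this kind have reported numerator degrees of freedom equal to the
*number* of families rather than families − 1 — parameterizations
differ across software — the function reports both the standard partial
F and the cell-means joint test.

## 2. The species mutagenicity index

A butterfly's exposure to mutagenic chemistry over evolutionary time is
summarized by the host-use-weighted mean of its host families' scores:
weights are the fractions of its listed larval host taxa per family
(`weights_from_host_lists()`), and the index is the convex combination
`sum(w_f * score_f)` (`species_mutagenicity_index()`). Listing counts
are the default usage measure because quantitative feeding frequencies
are rarely available; externally derived proportions can be supplied
directly. Hosts whose family cannot be resolved are reported and the
remaining weights renormalized — never silently zeroed. The index always
lies within the range of the contributing scores, and any reliance on an
order-level fallback score is propagated as `any_fallback`.

## 3. Tolerance proxies from censored concentrations (Tobit ML)

Tissue concentrations from ICP-MS come with per-run detection limits;
readings below the LOD — or returned negative by the instrument — carry
only the information that the true value lies below a bound. Deleting or
zero-substituting such values biases species means, especially for
metals with 10–20% nondetects, so the package treats them as
**left-censored** observations of a normal model on the
`log10(concentration + 1)` scale (the +1 offset keeps transformed values
nonnegative; configurable via `log_offset`).

After technical replicates are averaged (`average_replicates()`),
`encode_censored()` marks a measurement censored iff its averaged raw
value is below its run's LOD or negative, and codes the censor bound
from the *mean* LOD across runs per metal (the run-specific bound is an
option, `lod_averaging = "run"`).

`fit_censored_species_model()` maximizes, per metal, the censored-normal
likelihood with one mean per species and a shared standard deviation:

$$\ell(\mu, \sigma) = \sum_{\text{uncensored}} \log
\frac{1}{\sigma}\phi\!\left(\frac{y_i - \mu_{s(i)}}{\sigma}\right) +
\sum_{\text{censored}} \log \Phi\!\left(\frac{b_i -
\mu_{s(i)}}{\sigma}\right)$$

A shared sigma matches a single generalized regression per metal with a
species factor; it borrows strength across species and keeps every
species' mean identified from modest samples. Optimization is L-BFGS-B
on `(mu_1..mu_S, log sigma)` with analytic gradients, three fixed starts
(naive estimates with sigma, 2 sigma, sigma/2) to guard against flat
regions, and a 1e-4-scaled `factr` (about 1e-12 relative) tolerance;
standard errors come from the analytic observed information. When no
value is censored the likelihood collapses exactly to the ordinary
normal ML solution — a property the tests assert, not just assume.
Species with *no* uncensored observation have a mean on the likelihood
boundary; they are flagged and excluded from the fit and the contrast,
never silently scored.

Two proxies summarize each species × metal: the ML species mean
(`predicted_mean_log`) and the maximum *uncensored* observation
(`max_observed_log`; a censored value can never be a maximum). The
species-effect test is a Wald test of equal means. Its raw chi-square
statistic (reported, with df = S − 1) uses the plug-in ML covariance,
which is biased low in finite samples because the ML scale divides by n
rather than the residual degrees of freedom; at the study scale (26
species × 28 specimens) the chi-square calibration rejects a true null
about 7.8% of the time at the 5% level. The reported `p.value` therefore
rescales the statistic by `(n − S − 1)/n` and refers `W/(S − 1)` to
`F(S − 1, n − S − 1)` — the censored-likelihood analogue of the
classical ANOVA F calibration, which restores the nominal level (5.8%
in a 1000-replicate null at study scale). The asymptotic chi-square p is
kept as `p_chisq`. A likelihood-ratio pseudo-R² (Cox–Snell with its
Nagelkerke normalization) is reported for comparability with generalized
regression software; its exact proprietary counterpart is unspecified,
so it should be read as an effect-size indicator only.

## 4. Geographic range area

Range size comes from habitat-suitability rasters on a longitude/
latitude grid. Cells with suitability strictly below the threshold
(default 0.2) or flagged nodata are excluded — nodata means *no
information*, never zero suitability. Retained cells are summed with the
exact spherical cell area

$$A = R^2\,\Delta\lambda\,(\sin\varphi_N - \sin\varphi_S),$$

with R the authalic Earth radius 6371.0088 km (configurable), so a
1-degree cell at 60°N correctly contributes about half the area of an
equatorial one. Summing a global grid reproduces the sphere's surface to
well under 0.1%. Only geographic rasters are supported — a projected
grid would silently distort areas, so it is rejected with an explicit
error — and input is the plain-text ESRI ASCII grid format. When two
named taxa are analysed as one (e.g. a species pair inseparable in the
field), `merge_taxa()` assigns the lumped name the arithmetic mean of
the members' areas.

## 5. Phylogenetic generalized least squares

Species are not independent data points. The model for a tolerance proxy
`y` is GLS with residual covariance proportional to `V(lambda)`, where
`V[i,j]` is the branch length shared by tips i and j (root-to-MRCA) and
Pagel's lambda multiplies the off-diagonal: lambda = 0 is ordinary least
squares, lambda = 1 Brownian motion. Both predictors — range area and
mutagenicity index — are standardized (mean 0, sample SD 1) so their
coefficients are directly comparable effect sizes.

Lambda is estimated by maximum likelihood: the profile log-likelihood is
evaluated on a grid over [0, 1] (`grid_points`, default 101) and refined
by local optimization between the best grid point's neighbours, with the
boundary values always candidates — boundary estimates (lambda exactly 0
or 1) are legitimate and common at n = 26. ML rather than REML is used
so that fixed-effects models with different predictors remain comparable
and boundary estimates are reported as such. At the ML lambda the fit
reports coefficient t tests on n − k residual df (k columns including
the intercept: n = 26, k = 3 gives df 23), an overall F for the
non-intercept terms against the intercept-only model *under the same
transformed covariance* with df (k − 1, n − k), and the GLS analogues of
R² and adjusted R² computed from the transformed residual sums of
squares. The numerics go through the Cholesky factor of V — no explicit
inverse — and a dense-matrix textbook oracle plus `nlme::gls` with
`ape::corPagel` verify the implementation in the tests.

A species missing from the phylogeny but with a sister present can be
substituted: the default relabels the sister tip (topology and branch
lengths untouched); a graft option instead adds the species as a
zero-length sister, giving it exactly the sister's covariances while
keeping both tips.

## 6. The synthetic study and what it does (and does not) show

`simulate_bundle()` generates every input with known truth, at the scale
of the motivating field study: 26 species on a unit-height pure-birth
tree, ~28 specimens per species (~730 per metal), 4 metals over 3
instrument runs, and a literature-style Ames database with at least 56
families reaching the 8-test threshold plus a few data-poor families
that exercise the order fallback.

Species mean log concentrations follow the same PGLS model the pipeline
fits — intercept 1.5, standardized true range area and true mutagenicity
index with effects 0.3 and 0.15, phylogenetic residuals with lambda 0.5
and variance 0.09. The effect sizes sit in the range of standardized
slopes such field studies report, and at n = 26 they give the pipeline
comfortable (>80%) power — the package's calibrated reference condition.
The grand mean is kept well above zero on the log scale so negative
instrument readings are rare, which is what real ICP-MS data at these
concentrations look like and what makes a ~0% censoring target
attainable for one metal. Detection limits are placed at the target
censor-fraction quantiles of the realized concentrations (defaults 0,
0.3, 13 and 21 percent across the four metals, bracketing the emulated
study's 0–21%), spread ×0.9/1.0/1.1 across runs, and by default capped
just below every species' peak value (`ensure_detectable`) because in
the emulated study no species fell entirely below detection; disabling
the cap allows degenerate all-censored scenarios.

What passing tests on this generator establish: correct likelihoods and
estimators under the *assumed* models (normal within-species variation,
additive logit methodology effects, Pagel-lambda residuals), correct
censoring bookkeeping, exact geometry, and end-to-end plumbing with
power at the stated effect size. What they cannot establish: robustness
to real-data violations — heavy-tailed or skewed concentration
distributions, methodology effects that interact with family, host-list
errors, spatial structure in exposure, or phylogenetic error. The
generator deliberately matches the fitted models so that estimator
properties are testable; it is a verification tool, not evidence about
field data.

Problem sizes used by the test suite and acceptance script (lambda
recovery on 200-tip trees, 50 or 20 replicates per lambda; censored-ML
recovery at n = 1000; a 1000- or 400-replicate Wald null at study scale;
200-replicate power runs) were chosen as the smallest designs whose
Monte-Carlo error is comfortably inside the asserted tolerances.

## 7. Numerical and degenerate-input choices

* Censored likelihood: censored terms use `pnorm(..., log.p = TRUE)` and
  the inverse Mills ratio is computed on the log scale, so deep-tail
  bounds do not underflow.
* The ames F test computes the partial F explicitly from residual sums
  of squares with the difference clamped at zero — `anova()` returns NA
  when floating-point cancellation makes the improvement ≈ −1e-16, which
  happens whenever group means coincide exactly.
* All-identical Ames outcomes: the F test returns a `zero_variance`
  flag rather than 0/0.
* Constant predictors refuse to standardize; rank-deficient designs and
  non-positive-definite covariances are hard errors, not warnings.
* Ties in the lambda profile resolve to the grid/boundary candidate with
  the highest likelihood; equal likelihoods at 0 and an interior point
  return the interior optimum only if it is strictly better.
* Every generator function takes an explicit seed and is deterministic
  given it (R's default Mersenne-Twister); bundle stage seeds are
  derived from the master seed.

## 8. Known limitations

* The methodology correction assumes additive logit effects; strong
  family-by-strain interactions would require a richer model than the
  data plausibly support.
* One shared sigma per metal is an approximation; a per-species scale is
  deliberately not offered by default because several species would have
  too few uncensored values to identify it.
* The spherical Earth model differs from ellipsoidal area tools by up to
  a few tenths of a percent depending on latitude; the radius is
  configurable but the geometry is spherical.
* Raster input is the ESRI ASCII dialect only; georeferenced TIFFs must
  be converted upstream.
* PGLS assumes the tree is known without error and residuals are
  Gaussian; n = 26 gives limited power to distinguish intermediate
  lambda values, which is why boundary estimates are frequent.
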