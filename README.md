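# metaltol

Why do some butterfly species carry high heavy-metal burdens in polluted
landscapes while others do not? Two candidate explanations are an
evolutionary history with mutagenic host-plant chemistry (toxin
coevolution: pathways evolved against natural toxins are co-opted for
novel ones) and geographic range size (large ranges select for broad
stressor tolerance). **metaltol** is an R package for running that
comparative analysis end to end, for ecologists and evolutionary
biologists working with field-collected tissue concentrations:

* **Ames scoring** — turns a table of literature Ames-test records into
  methodology-corrected mutagenicity scores per plant family. A logistic
  regression of the binary outcome on family + methodology covariates
  (solvent class, strain, S9 activation) is converted to adjusted
  proportions by marginal standardization; families with fewer than 8
  tests inherit their plant order's score (flagged as a fallback).
* **Host index** — each butterfly species' mutagenicity index is the
  host-use-weighted average of its host families' scores,
  `sum(w_f * score_f)`.
* **Censored metals (Tobit ML)** — ICP-MS readings below the detection
  limit (or negative) are left-censored, not zero. Per metal, species
  means `mu_s` and a shared `sigma` maximize
  `sum_unc log phi((y - mu_s)/sigma)/sigma + sum_cens log Phi((b - mu_s)/sigma)`
  on the `log10(x + 1)` scale, with a Wald test for the species effect.
  Tolerance proxies per species: the ML mean and the maximum uncensored
  observation.
* **Range area** — habitat-suitability rasters are thresholded
  (suitability < 0.2 excluded) and retained cells summed with exact
  spherical areas `R^2 * dlon * (sin lat_N - sin lat_S)`,
  R = 6371.0088 km.
* **PGLS** — each tolerance proxy is regressed on standardized range
  size and mutagenicity index under phylogenetic covariance with
  maximum-likelihood Pagel's lambda, giving coefficient t tests
  (df n − k), an overall F (df k − 1, n − k) and adjusted R².
* **Synthetic data** — every input (tree, Ames records, host lists,
  specimens + LODs, rasters) can be simulated with known ground truth at
  the scale of the motivating study (26 species, ~730 specimens per
  metal), so the whole pipeline is testable offline.

## Worked example

```r
library(metaltol)

b   <- simulate_bundle(synth_config(), seed = 1)  # all five inputs + truth
run <- run_all(b)                                 # full pipeline
run
#> metaltol pipeline run: 26 species, 8 PGLS models ( As, Cd, Mn, Pb )
#>
#>          model  n lambda range_estimate range_t  range_p ... f_value f_df1 f_df2 adj_r_squared
#> 1       As_max 26  0.000          0.361    5.13 3.38e-05 ...    16.4     2    23         0.551
#> 2 As_predicted 26  0.498          0.399    6.01 3.95e-06 ...    21.9     2    23         0.625
#> ...
#> 7       Pb_max 26  0.568          0.343    6.50 1.24e-06 ...    24.0     2    23         0.648
#> 8 Pb_predicted 26  0.726          0.340    8.35 2.04e-08 ...    38.6     2    23         0.751

run$fits[["Pb_max"]]
#> PGLS fit: n = 26, lambda = 0.568 (ML), logLik = -0.920
#>                estimate       se       t         p
#> intercept      1.929528 0.116047 16.6271 2.595e-14 ***
#> range_z        0.343085 0.052769  6.5017 1.237e-06 ***
#> mutagenicity_z 0.151238 0.049053  3.0831  0.005253 **
#> F(2, 23) = 24.026, p = 2.327e-06;  R^2 = 0.676, adj. R^2 = 0.648
```

Reading the output: each of the 8 models (4 metals × {observed maximum,
censored-ML predicted mean}) reports the standardized effect of range
size and of the mutagenicity index on species metal burden, the ML
phylogenetic-signal estimate `lambda`, and the overall model F with its
(2, 23) degrees of freedom at n = 26 species. Here the bundle was
simulated with true standardized effects 0.3 (range) and 0.15
(mutagenicity) under lambda = 0.5, and the fitted slopes (0.28–0.40 and
0.06–0.24) recover them; `range_z = 0.343` in the `Pb_max` model means
one standard deviation of range area is associated with +0.34 in
log10(Pb + 1). With real data, `read_bundle()` loads the same file
layout (CSV tables, Newick tree, ESRI ASCII rasters) written by
`write_bundle()`, and `write_reports()` saves the tables and per-model
summaries as delimited text.

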