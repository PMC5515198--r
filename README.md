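# metachain

Markov chain modelling of metastatic breast cancer progression.

## The problem

Breast cancer spreads from the primary tumour through a sequence of
anatomical sites, and the identity of the *first* metastatic site carries
strong prognostic information. `metachain` is for biostatisticians and
modellers working with longitudinal registry data — one row per patient,
one dated row per metastatic event — who want to turn those event streams
into an interpretable progression model rather than a collection of
per-site incidence tables.

The core is a discrete-time Markov chain over a fixed taxonomy of ten
states: the breast (origin), eight metastatic locations (bone, chest wall,
mammary/distant lymph nodes, lung/pleura, liver, brain, other) and an
absorbing `deceased` state. The row-stochastic transition matrix *A*, with
entries *a(i, j)* = P(next event at site *j* | disease at site *i*), is
estimated by direct enumeration of progression events, and the state vector
evolves as *v(k+1) = v(k) A*. On top of the fitted chain the package
computes:

* **spreader/sponge classification** — a site whose outgoing two-step
  pathway mass (breast → s → j) exceeds its incoming mass (breast → i → s)
  is a net exporter of progression (amplification factor > 1, a
  "spreader"); the converse is a "sponge";
* **Kaplan–Meier survival** grouped by solitary first metastatic site,
  first-relapse multiplicity, or ER/HER2 subgroup, with rate-ratio and
  log-rank hazard ratios;
* **Weibull fits** (profile-likelihood MLE) to diagnosis-to-k-th-metastasis
  times, linking the chain's step index to calendar time;
* **ring (sunburst) diagrams** and chord-diagram exports of the pathway
  structure;
* a **seeded synthetic cohort generator** — timed random walks on a
  configured transition graph with Weibull waiting times, co-occurring
  first relapses and right-censoring — so the whole pipeline can be
  exercised and tested without access to registry data.

## Worked example

```r
library(metachain)

coh <- simulate_cohort(default_config(seed = 11))
coh
#> Metastatic cohort: 446 patients, 1495 metastatic events, 217 deceased
#> Subgroups: ER+/HER2- 288, ER-/HER2- 95, HER2+ 63, unknown 0

fit <- metachain_fit(coh)          # 10-year window, all subgroups
fit
#> Markov chain model of metastatic progression
#>   subgroup: all   eligible pathways: 388  (of 446 patients)
#>   distinct pathways: 256
#>   leading first-metastasis probabilities: bone 0.296, ln_distant 0.157, chest_wall 0.125

summary(fit)$classification
#> Spreader/sponge classification (two_step flows)
#>         site outgoing incoming factor    label
#>         bone    0.296    0.093  3.185 spreader
#>   chest_wall    0.125    0.031  4.021 spreader
#>   ln_mammary    0.091    0.028  3.260 spreader
#>   ln_distant    0.157    0.164  0.956   sponge
#>  lung_pleura    0.115    0.150  0.765   sponge
#>        liver    0.099    0.175  0.564   sponge
#>        brain    0.054    0.064  0.843   sponge
#>        other    0.064    0.087  0.738   sponge

km <- km_estimate(group_cohort(coh, "first_site_solitary")$bone)
survival_at(km, 10)
#> [1] 0.6075949

weibull_mle(sample_met_times(default_config(), ordinal = 1,
                             n = 5000, seed = 30))
#> Weibull fit (n = 5000): shape 1.515, scale 5.926 y, implied mean 5.344 y (sample mean 5.346 y)
```

Reading the output: of 446 synthetic patients, 388 have fully observed
10-year pathways; the estimated chain puts about 30 % of first relapses at
bone, and the two-step flow analysis labels bone (factor 3.2) a spreader
and liver (factor 0.56) a sponge — bone re-exports three times the
progression mass it receives, liver absorbs roughly twice what it passes
on. Estimated 10-year survival for patients whose first relapse is
solitary bone is about 61 %, and the fitted Weibull to the
diagnosis-to-first-metastasis times has an implied mean of ~5.3 years.

`predict(fit, k = 0:10)` propagates the state vector, `simulate(fit, ...)`
draws new cohorts from the fitted chain, and `plot(fit)` draws the state
occupancy against the model step. See the vignette
(`vignettes/metastatic-progression.Rmd`) for the model, the calibration of
the synthetic generator, and the numerical conventions.

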