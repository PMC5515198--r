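---
title: "Modelling metastatic breast cancer progression as a Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metastatic breast cancer progression as a Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metachain)
```

## The model

Metastatic breast cancer progresses from the primary tumour through a
sequence of anatomical sites. `metachain` models this progression as a
discrete-time Markov chain: the state space is a fixed taxonomy of ten
states — the breast (unique origin), eight metastatic locations (bone,
chest wall, mammary and distant lymph nodes, lung/pleura, liver, brain, and
a catch-all "other"), and an absorbing `deceased` state. One model step is
one progression event, not a unit of calendar time; calendar time enters
separately through the temporal fits below.

The chain is driven by a row-stochastic transition matrix $A$ whose entry
$a_{ij}$ is the probability that the next event after disease at site $i$
occurs at site $j$. Starting from the state vector
$v_0 = (1, 0, \ldots, 0)$ (all mass on the breast), the distribution after
$k$ steps is $v_k = v_0 A^k$. The Markov assumption — no history dependence
beyond the current site — is a deliberate simplification: it ignores
treatment, tumour burden and host factors, but it turns a heterogeneous
registry into a single interpretable flow network.

$A$ is estimated by direct enumeration: every observed progression from one
site to the next contributes a count, and rows are normalised. In a cohort
of 100 tracked patients of whom 36 relapse first in bone, the breast-to-bone
entry is simply $36/100 = 0.36$.

```{r worked}
sites <- setdiff(met_sites(), c("breast", "bone", "deceased"))
pw <- c(replicate(36, pathway(list("breast", "bone")), simplify = FALSE),
        lapply(rep(sites, length.out = 64), function(s) pathway(list("breast", s))))
A <- suppressWarnings(estimate_transition_matrix(pw))
A$probs["breast", "bone"]
```

## From patient records to pathways

The data model is longitudinal: one row per patient (receptor status, vital
status, follow-up), one row per dated metastatic event. `extract_pathways()`
reduces these to ordered site-set sequences under two rules.

**Eligibility window.** A patient enters the analysis only if their
progression over the window (default 10 years) is fully known: either they
were followed alive for at least the window, or they died within it (their
pathway is then complete and ends in `deceased`). Events after the window
are truncated. This avoids the bias of partially observed pathways at the
price of discarding short-follow-up survivors.

**Co-occurrence tolerance.** Metastases are detected at discrete clinical
visits, so events reported within a short interval are best treated as one
multi-site presentation. Events within 14 days (~0.038 y) of the first
event of a group share a site-set; the tolerance is a parameter, and
setting it to zero splits every distinct pair of times. Fourteen days was
chosen because surveillance exams in such registries typically occur at
one-to-three-month intervals, so a shorter gap is below the detection
resolution; no merging rule can be read off the data themselves.

When a transition leaves or enters a multi-site set, each destination site
contributes one unit of count split equally over the source sites. This
fractional-count convention preserves total transition mass and is our
declared convention — event-level data cannot say which of two co-occurring
tumours seeded the next one. Repeat events at an already-affected site are
kept as self-transitions: progression networks observed in practice show
return flow (e.g. lung back to bone), and discarding repeats would
underestimate it.

## The synthetic cohort generator

Registry data of this kind are not publicly deposited, so the package ships
a generator (`simulate_cohort()`) that emulates the study conditions and
makes every downstream stage testable. Each synthetic patient draws a
receptor subgroup, then performs a timed random walk on the subgroup's
transition graph: Weibull waiting times between events, an optional
multi-site first relapse, absorption at death, and administrative
right-censoring.

The packaged calibration (`default_config()`) encodes the study conditions:

* 446 patients; subgroup proportions 218 : 70 : 62 for ER+/HER2−,
  ER−/HER2−, HER2+.
* Breast-row (first-relapse) probabilities with bone leading at 0.40 /
  0.27 / 0.33 per subgroup (0.36 pooled), distant lymph nodes second for
  the ER subgroups and lung/pleura second for HER2+.
* Diagnosis-to-first-metastasis waiting time Weibull with shape 1.5 and
  mean 5.30 years; subsequent inter-event gaps Weibull shape 1.5, mean
  2.28 years, so the diagnosis-to-second-event time has mean 7.58 years.
  Shape 1.5 gives the right-skewed, unimodal event-time histograms typical
  of relapse data; only the means are externally anchored, the shape is a
  calibration choice.
* Administrative follow-up uniform on 8–20 years, so both eligibility
  branches (long follow-up, early death) occur.
* First-relapse multiplicity 0.7 / 0.2 / 0.1 for 1 / 2 / 3 sites.

Every matrix entry beyond the leading ones is a **calibration constant, not
a published value**: the downstream rows were chosen once so that the
pooled chain reproduces the qualitative flow structure (spreader/sponge
labels and exit orderings, below) and then frozen. The generator is seeded
and bit-reproducible; with a fixed seed the same configuration always
yields the same cohort.

What the generator does *not* emulate: treatment effects on transition
rates, non-Markov history dependence, site-specific waiting times (one
shared gap distribution by default, per-edge overrides supported), and
detection-interval artefacts. Passing tests on synthetic cohorts therefore
validate the estimators and the pipeline, not the biological fidelity of
any particular matrix entry.

```{r simulate}
coh <- simulate_cohort(default_config(seed = 11))
coh
fit <- metachain_fit(coh)
fit
```

## Spreaders and sponges

For every two-step pathway breast → $i$ → $j$ the probability is
$a(\text{breast}, i)\, a(i, j)$. Summing these masses per site gives, for
each metastatic site $s$,

* outgoing mass: $\sum_j a(\text{breast}, s)\, a(s, j)$ — flow through $s$
  as an intermediate;
* incoming mass: $\sum_i a(\text{breast}, i)\, a(i, s)$ — flow into $s$ as
  a terminal.

A site whose outgoing/incoming ratio (amplification factor) exceeds one is
a **spreader** — a net exporter of progression; a ratio below one marks a
**sponge** that absorbs more flow than it re-exports. Breast and deceased
sit outside the dichotomy by construction. The neutral band is exact
($|f-1| \le 10^{-12}$): estimated factors are generically different from
one, so a fuzzy band would only hide information. A site with zero
incoming mass has an undefined factor and is flagged rather than labelled.

The two-step definition is the default because it weights each site's flow
by how reachable it is from the primary; a plain one-step variant
(off-diagonal row vs column sums) is provided for sensitivity analysis,
and the two can disagree — which definition a given published factor used
is often ambiguous, so both are exposed.

```{r classify}
summary(fit)$classification
site_exit_distribution(fit$transition, "bone", top_k = 3)
```

On the default calibration the pooled chain labels bone, chest wall and
mammary lymph nodes spreaders, with lung/pleura, distant nodes, liver and
brain sponges, and lung/pleura is the most probable metastatic destination
when exiting bone — the qualitative structure the calibration targets.

## Survival analysis

Survival runs from initial diagnosis (not first relapse; an
`eligible_only`/grouping layer controls who enters). `km_estimate()` wraps
the standard product-limit estimator: at each death time $t$ with $d$
deaths among $r$ at risk, $\hat S$ multiplies by $(1 - d/r)$; ties between
deaths and censorings process deaths first. `group_cohort()` produces the
prognostic splits: solitary first metastatic site, number of first-relapse
metastases (1 / 2 / >2), and receptor subgroup.

The hazard ratio defaults to the incidence-rate ratio
(events per person-year in A over B), which is the literal reading of
"group A dies at twice the rate of group B" and is exact under exponential
hazards; a log-rank $O/E$ variant is available. Cox regression is
deliberately omitted — nothing in this pipeline requires covariate
adjustment.

```{r survival}
groups <- group_cohort(coh, "first_site_solitary")
km_bone <- km_estimate(groups$bone)
survival_at(km_bone, 10)
```

## Temporal fits

The chain's step index is calibrated to calendar time by fitting
two-parameter Weibull distributions to realised time-to-event samples:
diagnosis to $k$-th metastasis, or diagnosis to first event at a named
site. These are observed-event samples — patients without the event are
excluded and no censored likelihood is used, matching the practice of
fitting the realised-time histograms; a censored MLE is a different
estimand and out of scope.

`weibull_mle()` maximises the likelihood by profiling: for fixed shape $k$
the scale MLE is $\hat\lambda(k) = (\tfrac1n\sum t_i^k)^{1/k}$, leaving a
one-dimensional search started from the method-of-moments shape and solved
to $10^{-8}$. The fit is deterministic, reports the implied mean
$\hat\lambda\,\Gamma(1 + 1/\hat k)$ alongside the sample mean (the two can
differ when the Weibull is misspecified, e.g. for a sum of Weibull gaps),
and flags non-convergence instead of failing.

```{r weibull}
t1 <- sample_met_times(default_config(), ordinal = 1, n = 5000, seed = 30)
weibull_mle(t1)
```

## Ring diagrams

`build_ring_diagram()` aggregates pathways into the nested sunburst
("ring") representation: ring 0 is the primary, ring $k$ the $k$-th
site-set, each sector sized by the fraction of the full eligible cohort
passing through that prefix — cohort normalisation, so sectors shrink
outward as patients stop progressing, with equality in ring 1 exactly when
every patient relapsed. Co-occurring sets become a single canonical sector
(`"bone+liver"`). The tree exports to JSON (sunburst renderers) and CSV and
round-trips losslessly.

## Numerical choices and degenerate inputs

* Row-stochasticity is enforced to $10^{-9}$; the deceased row is always
  forced absorbing.
* A non-deceased state with no observed exits cannot be normalised; by
  default it becomes self-absorbing with a warning (no invented mass), and
  add-one smoothing is available as an explicit opt-in.
* Tie-breaks are deterministic everywhere: two-step pathways sort by
  probability then taxonomy order; ring children by count then label.
* Death on the same date as a metastatic event orders the death last, so a
  pathway never continues past `deceased`.
* Unknown site labels collapse into `other` with a warning, keeping the
  state space closed; unknown receptor status excludes a patient from
  subgroup analyses but not from the pooled cohort.
* Empty inputs are errors for estimation (no pathway beyond the primary)
  but not for conditioning (`conditional_next_distribution()` returns an
  empty distribution with a match count of zero).

## Problem sizes and what the checks show

The test-suite simulations use cohorts of a few hundred patients for
pipeline checks and 5 000 patients (or draws) for statistical-recovery
checks — the scale at which binomial/Weibull sampling error is a few
percent, so 3-standard-error envelopes and 2–3 % tolerances are
discriminating without being brittle. Parameter-recovery tests switch
multiplicity off and censoring effectively off, because those features
deliberately decouple the *observed* event stream from the *generating*
row (co-occurring extras are drawn from the breast row excluding the
principal site; censoring preferentially hides late transitions). This is
a property of the data-generating design, not an estimator defect, and it
is why recovery is asserted for the estimator under clean sampling rather
than for the full observational process.

## Known limitations

* The registry-dependent headline statistics of any particular published
  cohort (per-site amplification factors, subgroup survival percentages,
  conditional transition values, the distinct-pathway count) are not
  reproducible from synthetic data; the package reproduces the *operations*
  and the qualitative structure, not those numbers.
* Under the default calibration deceased patients accumulate on average
  about 2.5 distinct metastatic sites before death — early deaths are
  biased toward short pathways — whereas registry reports put this near 4;
  matching it would require site-specific death hazards that the
  calibration deliberately keeps simple.
* The estimator treats the event ordinal as the time step; semi-Markov or
  continuous-time estimation, covariate adjustment, and treatment effects
  are out of scope.
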