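---
title: "Partitioning subterranean species diversity across drips, caves and regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning subterranean species diversity across drips, caves and regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(epidiv)
library(dplyr)
```

## The problem and the data model

Epikarst — the fissured zone between soil and cave ceiling — drains through
discrete drips, each the outlet of a miniature (roughly 0.1–300 m²)
drainage basin. Filtering drip water for a year yields quantitative,
replicable samples of the obligate subterranean copepod fauna, and because
several drips are sampled per cave and several caves per karst region, the
data fall naturally onto a three-level hierarchy: sample (drip) within
site (cave, a ~1 km² quadrat) within region (~1000 km²).

`epidiv` represents such data as a long tibble of `(species, sample, site,
region, count)` records — the `occurrence` class. Two modelling choices are
load-bearing:

* **Empty samples are data.** Roughly a third of surveyed drips yield no
  copepods at all. They are kept as placeholder rows, count in per-drip
  means when those are reported, and are *excluded* from multiple-site
  dissimilarity (Sorensen dissimilarity against an empty set is
  undefined). `multi_site_beta(drop_empty = )` and
  `additive_partition(include_empty_samples = )` expose both conventions.
* **Pooling is summation.** A cave's assemblage is the column sum of its
  drips, a region's the sum of its caves; `pool()` and `occ_matrix(level =)`
  implement this, and total counts are conserved exactly.

The Slovenian survey tables (30 stygobiotic copepod species, 81 drips, 13
caves, 3 regions) ship as plain-text fixtures; `load_fixture()` documents
them, and the extdata `MANIFEST.md` records the printed tables' internal
inconsistencies, which we preserve rather than reconcile. Two fixtures are
*reconstructions*: per-drip composition inside Snežna jama and Jama pod
Babjim zobom was never printed, but the per-cave richness histograms
together with the species occupancy table force (Snežna) or strongly
constrain (Jama pod Babjim zobom) the assemblage sets; their files are
flagged `_reconstructed` and their help pages state which table each
trusts.

## Nonparametric richness estimation

Observed richness under-counts when rare species are missed. The Chao
family corrects with the frequencies of the rarest classes:

$$\hat S_{\mathrm{Chao1}} = S_{obs} + \frac{F_1^2}{2F_2}
\quad\text{(classic)},\qquad
\hat S_{\mathrm{Chao1}} = S_{obs} + \frac{n-1}{n}\,\frac{F_1^2}{2F_2}
\quad\text{(bias-corrected)},$$

with $F_1$ singletons and $F_2$ doubletons; when $F_2 = 0$ the
bias-corrected form substitutes $F_1(F_1-1)/(2(F_2+1))$ (the classic form
would divide by zero; with no doubletons at all the substitution is the
standard Chao correction). Chao2 is the incidence analogue with uniques
$Q_1$, duplicates $Q_2$ and the $(T-1)/T$ factor over $T$ units. Note the
convention implemented here keeps the $F_1^2/2F_2$ ratio in the
bias-corrected form whenever $F_2 > 0$ — this is the published formula for
these data, and it is the only reading under which the Isolated region's
bias-corrected Chao2 of 7.0 (4 observed species, $Q_1 = 4$, $Q_2 = 0$,
$T = 2$) reproduces:

```{r}
m <- rbind(sp1 = c(1, 0), sp2 = c(1, 0), sp3 = c(0, 1), sp4 = c(0, 1))
chao2(m, variant = "bias_corrected")
```

ACE and ICE instead scale the rare/infrequent group (at most 10
individuals resp. units, the bound of the printed formula, exposed as a
parameter) by estimated sample coverage, with a squared-CV heterogeneity
term. Both fall back to the matching Chao estimator when coverage is zero,
flagged `variant = "fallback"`; the ICE fallback uses the *bias-corrected*
Chao2 because that is the value the published regional table prints for
the all-unique Isolated case (the classic fallback would give 10, not 7).

`variant = "auto"` implements the EstimateS-style selection rule: the
classic form only when the coefficient of variation of the frequencies
exceeds 0.5 ("greater than 50%" read strictly), and
`select_regional_estimate()` then returns the larger of the Chao and
coverage candidates, both recorded. SD columns use the standard
Chao-family variance expressions; the survey printed SDs without formulas,
so ours are reference-formula values, deliberately not tuned to any
printed SD.

Rarefaction is *sample-based* and exact: the expected richness among $t$
of $T$ units is $\sum_k 1 - \binom{T-T_k}{t}/\binom{T}{t}$, with the exact
subset-richness SD from pairwise joint-absence probabilities. The
published methods name the Mao tau estimator "individual based", but the
curves are drawn over drips and caves — sampling units — so the
sample-based form is the one implemented; the tests pin it to exhaustive
subset enumeration for all matrices with $T \le 6$.

```{r}
caves <- load_fixture("cave_incidence")
cmp <- accumulation_compare(caves, n_common = 3)
cmp$at_common
```

Regions with fewer units than the comparison point are dropped with a
message by default (`drop_short = FALSE` to make that an error), matching
how the two-cave Isolated region is handled in the source analysis.

## Turnover versus nestedness

Baselga's decomposition splits Sorensen dissimilarity into species
*replacement* (Simpson dissimilarity) and a *nestedness* remainder:
$\beta_{sor} = \beta_{sim} + \beta_{sne}$ with, for a pair,
$\beta_{sor} = (b+c)/(2a+b+c)$ and $\beta_{sim} = b/(b+a)$ ($a$ shared,
$b \le c$ the exclusives). The multiple-site form sums
$\min(b_{ij}, b_{ji})$ and $\max(b_{ij}, b_{ji})$ over unit pairs against
$K = \sum_i S_i - S_{tot}$. Additivity holds to $10^{-12}$ by
construction and is property-tested on random matrices, as is the
reduction of the multiple-site form to the pairwise one for $T = 2$ and
agreement with `vegan::nestedbetasor()`.

When the poorer member of a pair is empty the turnover share is taken as
0 (pure nestedness); both members empty is an error, and empty units are
excluded from multiple-site computation by default.

```{r}
beta_by_level(caves, "within_region")
```

The Isolated region's two caves share no species — total dissimilarity
1.00, all of it turnover. The multiple-site convention over cave-pooled
assemblages recovers the published regional values well: Alpine 0.571 →
0.57 with 87.5% → 88% turnover, Dinaric 0.758 → 0.76 (its turnover share
recomputes to 89.5% against a printed 88). The Isolated row is exact
under every candidate convention, which is why it anchors the package's
acceptance checks.

## Additive hierarchical partition and its null

`additive_partition()` decomposes γ richness as
$\gamma = \alpha_1 + \beta_1 + \beta_2 + \beta_3$: mean sample richness,
plus increments to mean site richness, mean region richness, and γ. Means
are **unweighted** across units at each level — with cave-level data this
yields the published rounded components (6 among caves, 18 among regions):

```{r}
additive_partition(caves)
```

Two design points discovered while building this:

* Mean sample richness uses non-empty samples by default (163 occurrences
  over 56 occupied drips ≈ 2.9 ≈ "three species within a drip");
  `include_empty_samples = TRUE` switches to all-sample means.
* Unweighted level means are *not* guaranteed to produce non-negative β
  components on strongly unbalanced hierarchies (a rich, densely sampled
  site can pull the sample mean above the unweighted site mean). The
  `weights = "samples"` option weights each site/region mean by its number
  of contributing samples, which provably keeps every component
  non-negative; it is not the default because only the unweighted form
  reproduces the published partition.

The null model (`randomization_null()`) reallocates every individual
independently to a sample with probability proportional to that sample's
total — species totals preserved exactly, sample effort in expectation —
and recomputes the partition per replicate (1000 by default, seeded).
p-values are two-sided empirical with the $(r+1)/(n+1)$ correction to
avoid zero p-values. Counts are treated as individuals; presence/absence
data are shuffled occurrence-wise, since nothing distinguishes sparse
counts from incidence. Calibration is itself tested: on communities built
with no spatial structure the observed α falls inside the central 95% of
its null in ≥ 90% of seeded trials, and on strongly structured
communities observed α drops below the null mean.

## Auxiliary statistics

`kruskal_wallis()` is the tie-corrected rank statistic with a χ²
approximation (exact small-sample tables are unnecessary at these group
sizes), pinned against `stats::kruskal.test` on random tied data. On
per-cave richness by region it gives H = 8.95, df = 2, p ≈ 0.011.
`ols_fit()` wraps `stats::lm` and reports
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-2)$; the maximum per-drip richness predicts
cave totals with $R^2_{adj} = 0.92$ over the 13 caves, while the mean
per-drip predictor recomputes to ≈ 0.81 from the printed summary table
(the 0.75 printed alongside it does not recompute from the same table,
one of that table's documented internal inconsistencies — only the
maximum-predictor value is asserted anywhere).

## The synthetic generator

`synthetic_config()` + `generate_community()` produce three-level
communities with known truth, used to validate every stage without any
external data. The generative chain is occupancy-then-abundance: regional
pools with a shared core (`pool_overlap`), Bernoulli thinning to sites
(`site_occupancy`) and to samples, geometric-series relative abundances
(`abundance_k`; one parameter, singleton-heavy frequency counts like the
real occupancy table's 8 single-drip species), then Poisson detection
summed over `n_events` monthly visits, so rare true members can be missed.
A latent per-species uniform shared across a site's samples, mixed with a
per-sample redraw by `nestedness_weight`, spans perfectly nested
(`1`, provably zero turnover) to independent (`0`, turnover-dominated)
assemblages. `hotspot_fraction`/`hotspot_multiplier` inflate occupancy for
a few samples, reproducing the survey's hotspot drips, and
`empty_sample_rate` forces dry drips.

Defaults are fixed at the survey's scale: 3 regions with 8/3/2 sites of 6
samples (~80 drips), pools of 25/8/8 species with 10% overlap, 31% empty
samples, 10% hotspots, 8 events of ~12 expected detections. What the
generator does *not* emulate: environmental covariates (ceiling thickness,
drip chemistry), temporal dynamics across months, and dispersal — so
passing recovery tests demonstrate estimator correctness under the assumed
sampling model, not robustness to those processes.

`recovery_experiment()` wraps the loop: under deep sampling
(detections ≫ pool size) Chao1's mean over 200 replicates sits within 5%
of true richness; under shallow sampling it stays an over-estimate of
$S_{obs}$ and its bias shrinks monotonically with depth (within
Monte-Carlo error). Replicate counts of 60–200 keep the whole suite under
a minute while leaving the Monte-Carlo error well inside the asserted
tolerances.

## Reproducing the survey tables

`reproduce()` runs the full pipeline on the fixtures — per-cave and
per-region richness estimates, the dissimilarity decompositions at all
three scales, the partition with its null, the regional rank test and both
cave-richness regressions — returning tibbles and optionally writing TSVs
plus a seed-deterministic `summary.json` (no timestamps inside, so two
runs with one seed are byte-identical). Per-cave Chao1 columns of the
published richness table are *not* reproduced: they require the per-drip
abundance supplements that were never machine-published. Of the regional
estimates, ICE over Dinaric cave-level incidence recomputes to 41.43 →
exactly the printed 41.4, while the printed Dinaric Chao2 of 40.4 does
not recompute from cave-level occupancy (classic Chao2 gives ≈ 32.6; the
original run evidently used finer sampling units for that column), and
the Alpine ICE recomputes to 10.4 against a printed 10.9 — consistent
with the one-species discrepancy between the occupancy table's Alpine
pool (5 species) and the regional table's printed 6. The package's
shell-free interface is deliberate: every published subcommand-style
operation maps onto one exported function.

## Numerical conventions

* CV thresholds strict (`> 0.5`); rounding to integers happens only in
  report columns, never internally.
* Estimates are floored at $S_{obs}$; `F_1 = 0` (or `Q_1 = 0`) returns
  $S_{obs}$ with SD 0.
* Rarefaction uses `lchoose` throughout; no Monte Carlo anywhere outside
  the null model and the generator.
* All randomness flows through explicit integer seeds (`set.seed` in
  `randomization_null()`, `generate_community()`,
  `recovery_experiment()`), so every stochastic result in the package is
  replayable.
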