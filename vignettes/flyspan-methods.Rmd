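---
title: "Methods behind flyspan: survival statistics, expression-weighted pathway scoring and activity profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind flyspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyspan)
```

flyspan implements the quantitative core of a *Drosophila melanogaster*
longevity study design in which the catalytic subunit of
glutamate-cysteine ligase (*Gclc*, the rate-limiting enzyme of
glutathione synthesis) is overexpressed in neurons and compared with a
control line across four read-outs: lifespan, age-dependent stress
resistance, head-transcriptome pathway changes, and locomotor/circadian
activity. This vignette explains the models and conventions behind each
module, the tunable parameters, and the choices made where the design
was genuinely open.

## Survival data on a census grid

All survival assays record deaths at discrete censuses: daily for
lifespan (census interval 1 day) and twice daily for acute stress assays
(interval 12 h). A death observed at a census is known only to have
occurred since the previous census, so the package treats every recorded
death time as a grid value and the synthetic generators round latent
continuous death times *up* to the next grid multiple. `survival_cohort()`
enforces the grid: off-grid or missing times are rejected loudly.
Censoring is deliberately unsupported — the assay protocols follow every
fly to death, and accepting censored rows silently would corrupt every
downstream statistic.

`summarize_cohort()` reports the mean with its standard error, the
median survival time M and the time of 90% mortality (t90, the study's
operational "maximum lifespan"). Both quantiles are *step-function*
quantiles: the smallest grid time at which the cumulative death fraction
reaches 0.5 or 0.9, with no interpolation. This is the convention under
which every published M and t90 of this design is a multiple of the
census interval, and it makes the quantiles permutation-invariant and
monotone under pointwise increases of the death times (both are tested
properties).

### Comparing two cohorts

`compare_lifespan()` reports percent differences of M and t90 with the
*experimental* (overexpression) group's value in the denominator,
`dM = 100 (M_exp - M_ctrl) / M_exp`. The convention is not universal,
but it is the one that reproduces all four published percent cells of
this design (+23.1%, +5.3%, +30.3%, +18.2%) from the printed medians
and t90s, so it is adopted as the package convention.

Survival-curve differences are tested with a hand-implemented weighted
log-rank over the union of distinct death times. At each distinct time
$t_j$ with $d_j$ pooled deaths, $n_j$ at risk and $n_{1j}$ at risk in
group 1, the statistic accumulates
$w_j\,(d_{1j} - d_j n_{1j}/n_j)$ with hypergeometric variance
$w_j^2\, d_j \frac{n_{1j}}{n_j}\left(1-\frac{n_{1j}}{n_j}\right)\frac{n_j-d_j}{n_j-1}$,
and the squared total over the variance is $\chi^2_1$. Weight
$w_j = 1$ is the Mantel-Cox test; $w_j = n_j$ is the
Gehan-Breslow-Wilcoxon test. Both are always computed and reported,
because the literature of this design names both without stating which
produced a given p-value; neither is privileged. The implementation is
hand-written rather than delegated because the number-at-risk Gehan
weight is not what `survival::survdiff(rho = 1)` computes (that is the
Peto-Peto variant with Kaplan-Meier weights); `survdiff` instead serves
as an independent oracle for the Mantel-Cox case in the test suite,
alongside a brute-force risk-set implementation for both weightings.

Maximum-lifespan differences use the Wang-Allison construction: the
pooled 90th-percentile death time (step-function quantile again) defines
a threshold, flies are cross-classified as group × (died after vs at/by
the threshold), and the 2×2 table is tested with the two-sided Fisher
exact test — the sum of all hypergeometric table probabilities not
exceeding the observed one, which is exactly `stats::fisher.test`'s
two-sided rule and is verified against full enumeration in the tests.
A table with a zero margin (e.g. identical cohorts) yields p = 1 with a
warning flag rather than an error.

Cox proportional-hazards modelling is intentionally absent: it is a
standard routine available in the survival package and not part of what
this package contributes.

## Age-dependent stress resistance

The study design assays stress survival (paraquat, CuSO4, CdCl2, NaCl)
in cohorts collected at ten ages (7 to 70 days, weekly). The decline of
resistance with age is quantified by the Pearson correlation between
assay age and the cohort's *mean* survival time
(`age_survival_correlation()`), with the usual two-sided t test on
$t = r\sqrt{(n-2)/(1-r^2)}$. Correlation on 3 or more pairs with
non-constant values is required; degenerate inputs are errors, not NAs.

Whether the overexpression genotype *changes the dynamics* of that
decline is tested by comparing the two genotypes' correlation
coefficients with the Fisher z machinery
(`compare_correlations()`): $z_i = \operatorname{atanh} r_i$,
$SE = \sqrt{1/(n_1-3) + 1/(n_2-3)}$, and a **one-sided** normal p-value
on $|z_1 - z_2|/SE$, so equal correlations give exactly p = 0.5. The
source design never printed its formula; this choice is the one that
reproduces the published male paraquat (0.30) and CdCl2 (0.46) cells
from the published 3-decimal correlations, and those are the only cells
the package claims. The remaining published cells are not recoverable
from rounded correlations under any standard two-correlation test we
tried, presumably because unrounded values were used; the package does
not guess further.

The fecundity/fertility read-out needs only a Pearson chi-square on
count tables (`chi_square_counts()`, no continuity correction); the
underlying counts are user-supplied since none are published.

## Expression-weighted KEGG node aggregation

The package's core transcriptomic computation addresses a real defect of
naive pathway coloring: a KEGG node frequently represents several
genes/isoforms, and summing their log2 fold-changes lets a trace-level
isoform dominate. The canonical two-isoform example is succinate
dehydrogenase subunit A: the major isoform is down-regulated with age
(logFC −2.1) while a minor isoform at ~100-fold lower absolute
expression is up-regulated (logFC +5.2). Summation scores the node
+3.1 — the wrong sign for what the tissue is actually doing.
`aggregate_node(method = "weighted")` instead computes the
expression-weighted mean

$$\mathrm{logFC}_{\mathrm{node}} =
\frac{\sum_i \mathrm{logFC}_i \cdot w_i}{\sum_i w_i},$$

with absolute expression (CPM or FPKM) as weight $w_i$, scoring the
example node −2.0277. The weighted score is a convex combination of the
member logFCs (always inside their range), is invariant to rescaling all
weights in a node, and converges to the dominant member's logFC as its
weight grows — all tested as properties. The `"sum"` method is retained
for comparison.

Open choices resolved here: weights default to the mean CPM across all
samples of the comparison (direction-neutral; condition-specific means
can be supplied by passing a different `cpm` column — the aggregation is
agnostic to how the weight was averaged). Genes mapping to several nodes
contribute independently to each (mirroring KEGG's many-to-many
reality). Nodes with no measured member, or zero total weight, are
reported *unscored* and drawn grey — never 0, because 0 means "no
change". Identifier matching is exact-string; nothing is ever looked up
online.

Pathways enter either as a KGML subset (entries of type `gene` carry a
whitespace-separated member list; relations become edges; graphics
coordinates are ignored) via `read_kgml()`, or as a simple node-map TSV
via `read_node_map()`. Both have writers and are round-trip lossless.
Scores export as TSV or as a DOT graph colored on a symmetric
blue-white-red scale clipped at |logFC| = 2 by default (a conventional
saturation point for fold-change heat scales).

## Activity monitoring

`read_dam()` parses TriKinetics-style monitor files (one line per
acquisition interval: index, date, time, status, six reserved fields, 32
channel counts) and insists on constant intervals and strictly
increasing timestamps. Records with a non-valid status are *flagged and
excluded*, not zeroed, and any day containing one is dropped from
profiles — conservative, but it never deflates a day's activity.

Binned series (`bin_series()`) aggregate by **sum** within bins (beam
breaks are events), while `daily_profile()` aggregates across flies and
complete days by **mean** — reading "average activity in 10-min bins" as
the mean across flies of per-bin event sums. Profiles are aligned to
zeitgeber time (ZT 0 = lights-on); during constant darkness circadian
time simply continues the prior light-dark phase, the standard anchoring
when no free-running period estimate is attempted. Total activity is
conserved: raw sums, bin sums and actogram row sums agree over complete
days (tested). `actogram_matrix()` produces the days × bins raster,
optionally double-plotted (day d beside day d + 1, last row padded with
the final day). Period estimation and rhythmicity statistics are out of
scope — rhythm analysis belongs to dedicated periodogram tools.

## The synthetic-data generators

Every input the pipeline consumes can be generated with explicit seeds
(`gen_stress_cohorts()`, `gen_lifespan_cohorts()`, `gen_gene_stats()`,
`gen_toy_pathway()`, `gen_dam_file()`). No global RNG state is touched;
identical scenario + seed is byte-identical output.

The generators' defaults are the study conditions they emulate, chosen
once:

* **Stress survival**: exponential latent death times (Weibull
  available) with mean
  $80\,\mathrm{h} \times g^{[\mathrm{overexp.}]} \times
  s^{[\mathrm{female}]} \times (1-\delta)^{\mathrm{age}-\mathrm{age}_{\min}}$,
  rounded up to the 12-h grid and capped at 240 h. The 3%/day default
  decline $\delta$ and the 80-h young-age scale match the magnitude of
  published paraquat assays (mean survival falling from ~77 h at 7 days
  to ~13 h at 63 days); genotype factor 1.1 and female factor 0.9 are
  modest, in line with the published direction of those effects. Ten
  weekly ages from day 7 and 150 flies per cohort are the assay's
  stated design.
* **Lifespan**: Gompertz hazard $a e^{bt}$ sampled by inverse CDF
  ($t = \log(1 - (b/a)\log U)/b$, exponential when $b=0$), defaults
  $a = 1.05\times10^{-3}$/day, $b = 0.08$/day (median ≈ 50 days, the
  published control median) and a protective hazard factor 0.3 for the
  overexpression group (median ≈ 65 days, the published overexpression
  median), 400 flies per group on a daily grid. No parametric model is
  claimed for the real data; Gompertz is the standard minimal choice
  for adult fly mortality and is exposed as configuration.
* **Expression**: 9400 genes (the filtered head-transcriptome size in
  this design), 65% exactly null (allocation exact, not binomial), unit
  spread of true logFCs, lognormal CPM weights spanning orders of
  magnitude.
* **Activity**: 2 LD days + 6 DD days at 1-min acquisition, expected
  counts $\mathrm{mesor} + \mathrm{amplitude}\cos(2\pi(\mathrm{ZT} -
  \mathrm{peak})/\mathrm{period})$ per minute with negative-binomial
  noise (variance $\mu + \phi\mu^2$, $\phi = 0.5$ by default; Poisson
  at 0); peak at ZT 12 where the fly's evening activity peak falls.

What the generators deliberately do **not** emulate: bimodal
morning/evening activity peaks and lights-on startle artifacts (the
sinusoid has a single peak); vial-level clustering and shared-environment
correlation between flies; age-dependent changes of the *shape* (not
just scale) of stress-survival distributions; and mortality-driven
dropout of activity channels. Passing tests therefore demonstrate the
statistical machinery on data with the right grid structure, marginal
distributions and effect directions — not that real assay data satisfy
the generators' parametric forms.

### A calibration caveat worth knowing

The parameter-recovery property (the measured age-survival correlation
strengthens with the generator's decline rate) holds in the
noise-limited regime — small cohorts, mild decline — and is tested there
(single-vial cohorts of 30 flies at 1/2/3 %/day). It is *not* monotone
over a wide decline range: by 6%/day the exponential decay of mean
survival is so convex (and the 12-h grid floor so close) that the
*linear* Pearson correlation weakens again even as the decline gets
steeper. At the full assay size (150 flies/cohort) the mean correlation
across 100 replicates is −0.94, −0.97, −0.97, −0.94, −0.88 at
1, 2, 3, 4, 6 %/day. This is a property of Pearson correlation on
curved trends, not of the generator; it is also a reason the published
analysis pairs the correlation with regression scatterplots rather than
relying on r alone.

## Numerical conventions and degenerate inputs

* Grid quantiles use `sort(x)[ceiling(q n)]` with a $10^{-9}$ guard
  against floating error in $q n$.
* Rounding-up to the grid uses a $10^{-12}$ relative guard so values
  already on the grid are not pushed a whole interval up.
* Log-rank with zero variance (all death times identical) returns
  statistic 0, p 1 — a defined result, not an error; the same applies
  to a degenerate Wang-Allison table (p 1 plus a warning flag).
* Fisher-z comparison requires $n \ge 4$ (finite SE) and $|r| < 1$
  (finite transform); violations are errors.
* `aggregate_node` distinguishes *unscored* (`NA` + `scored = FALSE`)
  from 0; NaN logFCs are errors.
* All TSV/DOT/DAM writers emit plain LF text deterministically, so
  pipeline reruns with one configuration are byte-identical (the
  manifest records seed, config hash and package version).

## Problem sizes used in the shipped checks

The test suite and the reference battery are sized for a desk machine:
log-rank and Fisher enumeration oracles run on cohorts of ≤ 30 flies per
group; the Wang-Allison type-I-error simulation uses 1000 replicates of
100 flies per group under a null genotype effect (rejection rate at
$\alpha = 0.05$ expected in [0.02, 0.08] — Fisher exact is
conservative); decline-rate recovery uses 100 replicates per level of
ten 30-fly cohorts; the full pipeline demonstration runs a few hundred
flies, hundreds of genes and a handful of monitor channels. These sizes
are the package's own verification choices; all scale linearly if
increased.
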