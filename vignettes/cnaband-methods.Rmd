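---
title: "Copy-number calling from low-coverage WGS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling from low-coverage WGS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaband)
```

cnaband turns per-bin read counts from shallow whole-genome sequencing
(~10 M reads per library, 500-kb autosomal bins) into cytoband- and
arm-level copy-number calls and cohort statistics. This vignette is the
package's own account of the underlying models, the tunable parameters,
and the places where the design was genuinely open.

## The signal model

A tumour sample is a mixture of tumour cells (fraction $\rho$, the
purity) and normal diploid cells. A genomic bin whose tumour copy number
is $c$ contributes read mass proportional to

$$\mu_b \propto w_b \,\bigl[\rho\, c_b + 2(1-\rho)\bigr],$$

with $w_b$ the bin width. After width normalization and scaling to a
width-weighted mean of 1, a segment at tumour copy number $c$ sits at
relative level

$$r = \frac{\rho c + 2(1-\rho)}{\rho \psi + 2(1-\rho)},$$

where $\psi$ is the genome-average tumour copy number (the ploidy).
Inverting this gives the continuous absolute copy number used
throughout:

$$\mathrm{cn}(r, \rho) \;=\;
\frac{r\,[\rho\psi + 2(1-\rho)] - 2(1-\rho)}{\rho},$$

floored at zero. Ploidy is fixed at $\psi = 2$: hyperdiploidy is rare in
follicular lymphoma, and at this coverage a free ploidy is poorly
identified against purity. Note an assumption hiding in the mean-1
normalization: the *sample average* tumour copy number must be close to
$\psi$. Heavily imbalanced genomes (say, gains only, covering a large
fraction of the genome) shift the normalization anchor and bias the fit;
near-diploid lymphoma genomes satisfy the assumption, and the
synthetic-data generator draws balanced gain/loss events for the same
reason (below).

## Segmentation

Bins are segmented per chromosome by circular binary segmentation: the
arc $(i, j]$ whose mean differs most from its complement — scaled by
$\sqrt{m(n-m)/n}$ for an arc of $m$ of $n$ bins — is split off when a
permutation test on the same statistic gives $p < \alpha$, and the
pieces are segmented recursively. The arc form matters: a plain
single-split statistic dilutes an event in the middle of a chromosome
across two half-contrasts and loses it. Defaults: $\alpha = 0.01$,
1000 permutations, minimum segment width 2 bins.

Numerical choices:

* Segmentation operates on $\log_2(r + 10^{-3})$ (variance
  stabilization); segment means are reported in linear space as the
  plain mean of the bins' relative values.
* Bins are winsorized at the median $\pm 4$ MAD (log scale) before
  segmentation only — outliers cannot seed splits, but segment means
  are computed from the unwinsorized values.
* The permutation p-value is $(1 + \#\{T^{(b)} \ge T\})/(1 + B)$, valid
  at any $B$; the permutation loop stops early once exceedances
  guarantee $p \ge \alpha$. Permutations use R's RNG, so a seed makes
  segmentation reproducible.
* After the recursion, each boundary is repositioned between its
  neighbours by exhaustive residual-sum-of-squares minimization
  (segment count held fixed, deterministic). Accepted arcs occasionally
  drag one or two flanking bins along; this sweep returns them.
* The scan and the permutation test are compiled (Rcpp): the arc scan
  is $O(n^2)$ per evaluation and runs a thousand times per accepted
  split.

Under the null the split test inherits the permutation guarantee, so the
per-chromosome false-split rate is at most $\alpha$ — this is checked
by simulation in the test suite.

## The purity fit

For every candidate purity on a grid (default 0.20–1.00, step 0.01) the
fit error is

$$E(\rho) = \sum_{s \in \mathcal{C}} n_s\,
\bigl(\mathrm{cn}(r_s, \rho) - \mathrm{round}(\mathrm{cn}(r_s, \rho))\bigr)^2,$$

summing over candidate segments $\mathcal{C}$ and weighting by segment
bin counts $n_s$; rounding is half-up to the nearest *non-negative*
integer, so solutions that push segments far below zero are penalized
rather than clipped silently. Interior grid points where $E$ is lower
than both neighbours are local minima; the minimum with the smallest
error is selected, exact ties going to the *higher* purity (the more
conservative solution: smaller absolute deviations). A sample with no
local minimum — typically a flat profile — falls back to $\rho = 0.2$,
the most sensitive setting of the search range, with a flag recorded.

Candidate segments must satisfy two conditions:

* $|r_s - 1| > 0.05$ (the flatness threshold): flat segments carry no
  purity information, only noise.
* $n_s \ge 5$ bins (`min_fit_bins`): the mean of a very short segment is
  noisy enough that its rounding residual is essentially uniform, and
  such segments systematically favour harmonic solutions (half or double
  the true purity) where their residuals happen to shrink. Requiring a
  stable mean removes this failure mode; the value 5 is a numerical
  hygiene choice, not a biological one.

Two identifiability facts worth knowing. First, a profile whose only
alterations are two-copy steps (CN 0/4) is exactly scale-ambiguous with
one at doubled purity and single-copy steps; real tumours escape the
degeneracy through their single-copy changes, and under noise the true
solution has the smaller error because residual sensitivity scales as
$1/\rho$. Second, at exact purity 1.0 the error zero sits on the grid
boundary, which cannot be a *local* minimum; the selected interior
minimum (0.5, where every integer maps to another integer) yields
identical alteration states, so calls are unaffected.

The optional subclonal pass recomputes the profile at fixed
$\rho = 0.1$ — a deterministic, sensitive re-read used for serially
sampled patients in place of any manual inspection step.

## Region calls and burden

A cytoband or arm is called altered in a direction only when strictly
more than 50% of its assigned bases (its intersection with usable bins)
lie in bins of that state; exactly 50% never calls. The two directions
share a denominator, so both cannot exceed 50% simultaneously. Regions
with zero assigned bases (e.g. acrocentric p arms under a mappability
blacklist) are retained but never callable, avoiding a zero
denominator. *Focal* is defined as band-altered without a
same-direction arm call — the field's focal-versus-arm-level
dichotomy made reproducible. PGA uses usable autosomal bases as its
denominator (sex chromosomes are excluded at grid construction), and
the CNA count merges adjacent same-state altered bins across
segmentation boundaries: two abutting segments at the same integer copy
number are one biological alteration.

## Cohort statistics

The enrichment screen runs one two-sided Fisher exact test per
(cytoband, direction) with no multiple-testing correction — matching
the screening convention of the analyses this package reproduces — and
emits a Benjamini–Hochberg column as supplementary output only.
Discreteness makes the exact test conservative under the null, which
the suite checks by empirical-CDF domination. Burden comparisons use
the exact rank-sum distribution when the two groups total at most 20
untied observations and the normal approximation with tie correction
otherwise. FISH is always the reference standard for concordance;
predictive values with a zero denominator are NA, never 0. Survival
uses the product-limit estimator and the two-group log-rank test (via
the survival package), with event-free survival encoded by the
metadata's time/event pair.

## The synthetic-data generator

`simulate_sample_counts()` draws negative-binomial counts with mean
given by the mixture model and variance $\mu + d\mu^2$; $d = 0$ is the noiseless limit and returns
the expected counts themselves. Defaults emulate the targeted
assay: $10^7$ reads per library, dispersion $d = 0.02$ (at which a
500-kb bin has ~14% CV — FFPE-grade noise), optional multiplicative
quadratic GC bias. The assay-scale genome is the true GRCh38 autosome
tiling (5,760 bins); replicated simulation studies use
`sim_chrom_sizes()`, twenty-two 80-Mb chromosomes (3,520 bins), chosen
so that tumours carry many independent events (what conditions the
purity fit), events stay a modest fraction of their chromosome (so the
permutation null is not dominated by the signal itself), and replicated
runs stay fast.

`simulate_truth_profile()` draws alteration events in gain/loss pairs
of matched width and step so the genome-average tumour copy number
stays at 2 — the regime the ploidy-2 inversion assumes — with the
first pair always single-copy to break the purity scale degeneracy.
Defaults: altered fraction 0.20–0.35, events 35–60 bins, two-copy
events with probability 0.15. `simulate_cohort()` draws band-level
events independently per (band, direction) by group frequency, plus
exponential event times with region-conditional hazard ratios and
uniform censoring for the survival layer.

What the generator does *not* emulate: sequence-level FFPE artifacts,
wavy GC residuals, mappability structure, subclonal mixtures, or
linkage between neighbouring bands beyond whole-band events. Passing
tests therefore demonstrate the correctness of the algorithms under
the stated noise model, not robustness to every property of real FFPE
libraries.

The synthetic cytoband map (`synthetic_cytoband_grch38()`) is likewise
synthetic: real GRCh38 autosome lengths, approximate centromeres, a
curated set of anchor bands carrying real names at approximately real
positions (18q21.33, 9p21.3, 2p15, …), and filler bands numbered from
51 so they can never collide with a real band name. Analyses of real
data should load the UCSC table with `read_cytoband_table()`.

## Problem sizes used by the checks

The recovery study runs 100 samples on the simulation genome (purity
uniform 0.3–0.9, dispersion 0.02) and asserts purity within
$\pm 0.05$ and integer CN correct on altered bins, each at the 95%
level. Null calibration uses 200 call-level cohorts for the Fisher
screen and 400 flat 100-bin profiles for the segmentation
false-positive rate. The noiseless round trip uses eight full-purity
samples on seven real-size autosomes. These sizes are the package's
choices, balancing Monte-Carlo resolution against replicated-run cost.

## Known limitations

* Ploidy is fixed at 2; genuinely hyperdiploid tumours will be
  mis-scaled (by design, out of scope).
* The purity fit needs non-neutral segments; its fallback (0.2) is a
  sensitivity device, not an estimate, and is flagged as such.
* Very small focal events (a few bins) at low purity sit below the
  detection frontier of any segmentation method at this coverage and
  dispersion; the recovery guarantees are stated for the generator's
  event-size regime.
* p-values from the screen are reported uncorrected by design; use the
  supplementary BH column for modern error control.
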