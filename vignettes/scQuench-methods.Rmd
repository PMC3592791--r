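---
title: "Single-cell dose-response profiling from fluorescence-quench imaging"
author: "scQuench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell dose-response profiling from fluorescence-quench imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scQuench)
```

## The assay and its model

Ligand-gated chloride channels such as glycine receptors (GlyRs) can be
profiled functionally in live cells by co-expressing a halide-sensitive YFP
variant: when the channel opens, anion influx quenches the reporter's
fluorescence. Imaging one well of a 384-well plate once in agonist-free
solution and then after each of ten increasing agonist injections turns
every fluorescent cell into an 11-point dose-response — fluorescence
decreasing sigmoidally with agonist concentration. Because hundreds of
cells are imaged in parallel, a single well yields a distribution of
per-cell functional parameters rather than one bulk readout, which is what
makes receptor phenotypes of individual cells (e.g. homomeric vs
heteromeric subunit composition) separable within one heterogeneous
culture.

Each cell's trace is fitted with the four-parameter Hill model

$$F(c) \;=\; F_{max} + \frac{F_{min} - F_{max}}{1 + (EC_{50}/c)^{n_H}},$$

where $F_{max}$ is the fluorescence plateau at the lowest agonist
concentration (the unquenched state), $F_{min}$ the plateau at the highest
concentration, $EC_{50}$ the half-maximal activation concentration in µM
and $n_H$ (the Hill slope) the steepness at the midpoint. $F(0)$ is defined
as $F_{max}$, the mathematical limit, so the agonist-free control frame
participates in the fit. Because the reporter is quenched, the curve is
monotone non-increasing in concentration. The per-cell dynamic range is
$\Delta F = 100\,(F_{max}-F_{min})/F_{max}$ percent. This is the unique
four-parameter form consistent with plateau-at-extremes, half-maximal
midpoint and midpoint steepness semantics; we use it both as the fitting
model and as the generative model of the synthetic data.

## Pipeline stages and their parameters

**Segmentation** (`segmentReference`) runs on the control frame only — it
is the brightest, since the reporter is unquenched in chloride solution —
and the resulting pixel sets are held fixed across all frames
(`measureSeries` takes the mean of all pixel values inside each object per
frame). Cells are adherent and stationary over the few minutes of a
protocol, so tracking adds nothing; cells that detach mid-series are
removed later by the quality filters rather than followed. The segmenter
itself is an iterative size- and intensity-based threshold sweep: starting
at a high intensity quantile (default the 99.5th percentile), 8-connected
components with area inside [`minArea`, `maxArea`] (defaults 20 and 800 px
at the 2×2-binned 10× scale of a 696×520 field) are accepted and masked
out together with a one-pixel guard ring, then the threshold is lowered
(by default in 10 even steps) down to a floor just above background
(median + 5 robust SDs, but never the median itself so that noise-free
frames keep a strictly positive margin). Two consistency rules resolve
ambiguity: an object accepted at a higher threshold wins any overlap with
later candidates, and an accepted object whose 8-connected component at
the floor threshold exceeds `maxArea` is discarded — it is the bright core
of an over-sized structure (typically a large debris clump whose pixels
straddle one threshold level because of noise), not a cell. A configurable
central-field crop (`cropFrac`, default 1) can restrict analysis to cells
near the well centre; the protocol's optics make the periphery less
reliable, but no principled default radius exists, so the whole frame is
kept unless the user says otherwise.

**Fitting** (`fitDoseResponse`) is nonlinear least squares by
Levenberg-Marquardt (`minpack.lm::nls.lm`), with EC50 optimized as log10
for conditioning. The primary start is data-derived ($F_{max}$ ← max,
$F_{min}$ ← min, EC50 ← concentration nearest the half-range crossing,
slope ← 1) and is supplemented by a small multi-start set over (EC50,
slope): single-start LM can stall in a shallow local minimum when the true
EC50 sits near the top of the ladder, and the multi-start recovers the
global optimum at negligible cost. Box bounds — EC50 in [1e-3, 1e6] µM,
slope in [0.05, 20], plateaus in [0, 2·max(F)] — keep debris traces from
diverging; they are wide enough never to bind for plausible cells. Failed
optimizations are recorded (`converged = FALSE`), not raised, because in a
screen a failed fit is data (it will be filtered), not an error. Fits use
raw fluorescence without pre-normalization, unweighted by default; both
the inclusion of the c = 0 control point and per-point weights are exposed
as arguments since reasonable protocols differ on them.

**Filtering** (`applyFilters`) applies four empirically motivated closed
windows per cell: $R^2 \ge 0.9$ (the curve must actually describe the
points), $\Delta F$ in [20, 100]% (a real responder co-expresses reporter
and channel; reporter-only cells are flat), slope in [0.5, 5]
(physiologically plausible cooperativity) and EC50 in [0.3, 3000] µM
(inside the range the ladder and drug shifts can probe). Endpoints are
inclusive, the combined flag is the AND of all four, and non-converged
fits fail everything. On realistic wells roughly half the segmented
objects survive, which matches the intuition that debris, reporter-only
cells and detached cells make up a large minority of segmented objects.

**Summaries** (`wellSummary`, `plateMap`, `compareGroups`) report per-well
EC50 as median ± SEM (per-cell EC50s are approximately log-normal, so the
median is the robust location; SEM = sd/√n) plus 5/25/75/95% quantiles for
box plots, and assemble wells into a plate matrix for color-map reporting.
Two-group comparison is an unpaired Student's t-test on per-cell EC50s
with significance at p < 0.05; Welch correction and log-scale testing are
available as flags but off by default — the plain equal-variance test on
raw values mirrors how such screens conventionally report, and the
log-scale option exists precisely because the raw-scale convention is
statistically questionable for log-normal data. Plate color maps default
to cold = low EC50, warm = high (i.e. warm marks inhibition in an
antagonist screen); the orientation is a flag because both conventions
appear in practice.

**Phenotyping** (`trainClassifier`, `classifyCells`) trains an
axis-aligned decision tree on (log10 EC50, slope) of filter-accepted cells
from pure populations and classifies mixed wells, reporting per-class
fractions. The tree (via `rpart`) uses entropy/information-gain splits
with minimum leaf size 5 — on two numeric features this is behaviorally a
C4.5-equivalent, and the decision surface is insensitive to the choice of
pruning scheme at these sample sizes. Cross-validation is stratified
k-fold (default 10) with a fixed fold-assignment seed; per-class held-out
accuracy and the summed confusion matrix are stored on the model. log10 on
EC50 is a monotone transform, so it cannot change an axis-aligned tree's
decisions; it only makes reported thresholds readable. ΔF can be appended
as a feature but is off by default: it separates responders from debris,
which the filter has already done, and adds nothing between genuine
phenotypes.

## What the synthetic generator emulates — and what it does not

The generator is the package's ground-truth instrument, not a fixture:
every downstream stage is validated against it. A `PopulationSpec` draws
per-cell log10(EC50) from a normal around the population median (the
median is therefore preserved exactly), slope and ΔF uniform within
ranges, baseline fluorescence log-normal, and a Bernoulli responder flag.
A `WellSpec` mixes populations, fixes the 11-point ladder (default: 0 plus
0.1–3000 µM in half-log steps — protocols list twelve stock
concentrations but inject ten, and which ten is protocol-specific, so the
ladder is configurable), and adds the failure modes the quality filter
exists for: non-responders (reporter without functional channel, emulating
the 20–60% co-transfection efficiency), abrupt detachment (a cell drops to
background from a uniformly drawn frame onward — detachment during
perfusion is listed as a debris source in this kind of assay without any
finer model, so abrupt is the honest choice), and additive Gaussian noise
with sd proportional to the cell's baseline (default 2%). At image level,
cells are non-overlapping uniform discs placed by rejection sampling on a
constant background (5% of mean baseline), and debris appears as small or
large irregular blobs (half below, half above the cell-area gates) whose
intensity varies arbitrarily frame to frame; pixel values are rounded and
clipped to 16 bits.

Deliberate simplifications: Gaussian rather than Poisson noise (at 16-bit
scale with thousands of counts the difference is immaterial), no optics or
PSF simulation, no photobleaching, no within-frame quench kinetics, no
touching cells (so the segmenter's watershed-free design is never
stressed), and dilution bookkeeping is not simulated — the ladder lists
final concentrations. Passing tests therefore demonstrate the analysis
logic is correct on data satisfying the assay's own assumptions; they do
not demonstrate robustness to focus drift, uneven illumination or
confluent cultures, which real instruments produce and which are out of
scope here.

Default calibrations chosen once: `ec50LogSd = 0.15` reproduces the
visual width of per-well EC50/slope scatter in single-cell screens of
this type (published work shows the dispersion only graphically, so this
is a calibration choice, not a measured value); `fractionResponders`
defaults to 1 for clean recovery studies, with 0.55 used in the standard
mixed-well condition of the acceptance script to emulate a realistic
transfection; radius 4–8 px and baseline CV 0.2 give 100–500 resolvable
cells per field at realistic brightness spread.

## Numerical choices and degenerate inputs

Reproducibility is absolute: every stochastic step draws from a sub-stream
derived by `deriveSeed()` from one global seed plus named tags (stage,
well, purpose), so no stage's randomness can perturb another's and two
runs of `runPipeline` with the same configuration are bit-identical (the
manifest records md5 hashes of every artifact). Optimizer tolerances
(`ftol = ptol = 1e-15`, 500 iterations) are set so that noiseless model
data is recovered to machine precision. Zero-variance traces make $R^2$
undefined; an `NA` sentinel is returned and treated as failure by the
filters. A well with no accepted cells summarizes to `NA` statistics with
a `degenerate` flag rather than an error; a single accepted cell reports
SEM 0, flagged likewise. Empty images segment to an empty object table.
Ties between overlapping segmentation candidates go to the
higher-threshold acceptance, deterministically.

## Problem sizes used in validation

The test suite and acceptance script run entirely on generated data at
the scale of one typical well: 200 cells per isoform for recovery (medians
10.1 / 49 / 186 µM, 2% noise), a full 696×520 field with 300 cells and
100 debris objects for segmentation, 400 training cells for the
classifier with a 500-cell 1:1 mixture, and 40–320-cell wells in
triplicate for the SEM scaling check. These sizes match the regime the
assay reports (about 10² responsive cells per well) while keeping a full
validation run in the low minutes on one core.

## Known limitations

The segmenter assumes bright objects on a darker, roughly uniform
background and will not split touching cells. The fitter assumes a
monotone single-site quench; biphasic or two-site responses are out of
scope. The classifier is supervised — it cannot discover an unknown
number of subpopulations, and its accuracy on real cultures depends on
how well pure-population training wells represent the mixture. EC50s
outside the ladder span are extrapolations and are largely excluded by the
filter window by design.
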