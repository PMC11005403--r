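---
title: "Quantifying replication-origin usage by marker frequency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication-origin usage by marker frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfakit)
```

## The measurement

In a population of cells that is actively replicating its DNA, loci that
have already been duplicated are present in more copies than loci that
have not. Bulk sequencing therefore over-represents sequences near active
replication origins, and the normalized read-depth profile along the
chromosome — the marker frequency — carries a peak at an active origin.
Polyploid Thermococcales are an instructive case: each cell holds on the
order of ten copies of one circular ~2 Mb chromosome, and initiation can
occur at the canonical origin *oriC* or through recombination-dependent
replication (RDR), which starts at dispersed homologous-recombination
intermediates and produces no localized peak. The balance between the two
modes shifts with growth phase, genetic background (origin deletion,
recombinase knockdown) and hydrostatic pressure, and the *oriC* peak
height and area are the readout of that balance.

`mfakit` implements the full quantification chain plus a generative model
of the underlying population, so that every step can be validated against
a closed form.

## The population model

Each of N chromosomes is independently mid-replication with probability
r. A replicating chromosome initiated at *oriC* with probability f,
otherwise at a site drawn uniformly on the circle; replication proceeds
bidirectionally, so a chromosome at progress p (the fraction of the
genome already copied) carries a duplicated arc of length pL centred on
its initiation site. Progress is Uniform(0, 1): in an asynchronous
steady-state population a chromosome is equally likely to be at any stage
of its replication. Copy number is 2 inside the arc and 1 outside. Read
counts per bin are Poisson with mean proportional to the summed copy
number of the pool.

Averaging over initiation site and progress gives the expected
per-chromosome copy number at circular distance d from the origin,

$$E[c(x)] = 1 + r\left[\frac{1-f}{2} + f\left(1 - \frac{2d(x)}{L}\right)\right],$$

a tent with apex 1 + r(1+f)/2 at the origin, trough 1 + r(1−f)/2 at the
antipode, and genome-wide mean 1 + r/2. The uniform mode contributes the
constant 1/2 because a uniformly placed arc of Uniform(0, 1) relative
length covers any fixed point with probability 1/2 — which is exactly why
dispersed initiation is invisible to MFA: it raises the whole profile
without shaping it.

Deliberate simplifications: one initiation per chromosome (no
re-initiation or multiple concurrent forks — adequate for a single-peak
profile, not for fast multi-fork growth); RDR sites uniform on the genome
(any sequence bias, e.g. toward lesions or highly transcribed loci, is an
assumption we do not model); Poisson read sampling with no GC or
mappability bias; no fork-speed or time-resolved dynamics.

## From depth to profile

* **Binning** (`bin_coverage`): length-weighted mean depth per fixed bin,
  default 1,000 bp. At 1 kb a ~2 Mb chromosome resolves into ~2,000
  bins, fine enough to localize the origin to a gene-scale interval and
  coarse enough that per-bin Poisson noise is small at routine depth.
* **Normalization** (`normalize_profile`): division by the genome-wide
  mean bin depth; the output mean is exactly 1 (enforced to 1e−9 in
  tests) and the operation is idempotent. Each sample is normalized
  independently; no stationary-phase control track is subtracted.
  Zero-coverage bins participate in the mean (no masking by default).
* **Smoothing** (`gaussian_smooth`): discrete Gaussian kernel, truncated
  at ±4σ and renormalized to sum 1, applied as a *circular* convolution by
  default — the chromosome is circular and one reference species has its
  origin at coordinate 0, where a linear filter would be most distorted.
  Circular smoothing preserves the mean to machine precision and is
  shift-equivariant; the linear variant renormalizes the kernel at the
  track ends and is flagged with a warning. The default bandwidth σ = 10
  bins (10 kb) suppresses bin-level noise while broadening the apex only
  slightly; it is exposed as a parameter everywhere. Kernels wider than
  the profile wrap correctly (modular indexing).

## Peak calling and the origin-usage estimator

The apex is the maximum bin within a window (default L/10) of the
annotated origin, ties broken toward the origin and then the lower
coordinate. The baseline is the **median of the far half** of the genome
(circular distance > L/4 from the origin): a far-field median is robust
both to the peak's own leakage and to a handful of aberrant bins. An
explicit `baseline` argument allows pinning the baseline instead, as
interactive peak-analyzer tools do. Height is apex − baseline; the peak
is "detected" when height ≥ `min_height` (default 0.05 relative units,
set so that origin-less simulations at typical depth essentially never
trigger a call — 0/10 seeds in the shipped checks). Support bounds are
the first bins on either side where the baseline-subtracted profile
touches zero, clipped at the antipode; area is trapezoidal integration of
the positive excess between the bounds (for a genome-spanning tent of
height h this is exactly hL/2). Undetected peaks report height and area
0, not NA, so time courses plot continuously. Absolute areas depend on
these baseline/bounds conventions; across-sample comparisons within one
convention are the meaningful quantity.

Inverting the tent: with contrast k = apex/trough − 1, where the trough
is the profile minimum within L/10 of the apex antipode,

$$\hat f = \frac{k\,(1 + r/2)}{r\,(1 + k/2)},$$

exact on noiseless profiles. Profiles generated by any (f, r) with equal
k are bin-wise identical after normalization, so f and r are **not
jointly identifiable** from shape; r must come from an independent
measurement (e.g. fraction of replicating cells). Under the shipped
simulation conditions (N = 2000, r = 0.6, λ = 10 reads/bin/copy, 1 kb
bins, σ = 10) the estimator recovers f with RMSE ≈ 0.02–0.04 across the
full range.

## qPCR ploidy, growth and densitometry

The standard curve is the least-squares line of Cq on log10(copies) over
a 10-fold dilution series spanning 10^3–10^9 copies; the amplification
efficiency E = 10^(−1/slope) − 1 is an exact bijection on slope < 0
(E = 0.90 corresponds to slope −3.5873). Replicate Cq values are averaged
**before** inversion — inverting first and averaging is upward-biased
because the transform is convex. Copies per mL divided by the microscopy
cell count gives chromosomes per cell; the replicate SD propagates to
first order (relative SD = ln 10/|slope| × SE of the mean Cq), cell
counts are treated as error-free unless an SD is supplied, and sub-unity
ploidies are reported but flagged, since incomplete cell recovery at
early time points genuinely produces them. No correction is applied for
DNA-extraction efficiency.

Doubling time is ln 2 divided by the slope of ln(density) on time,
reported in minutes with a delta-method SE; it is invariant to density
units and time origin. The automatic window is the contiguous span of
≥ 4 points maximizing R² with positive slope — a deliberately simple
exponential-phase selector that lands inside the log phase of
lag/log/stationary test curves but is not a lag-time estimator.

Blot quantitation is pure arithmetic: normalization factor = reference
total protein / lane total protein; normalized volume = band volume ×
factor; percent of reference = 100 × normalized / reference normalized.
It is invariant to lane loading. Replicate blots are summarized as mean ±
SD per lane across experiments; background subtraction is assumed done by
the imager, and significance testing is out of scope.

## Numerical and statistical choices

* Coordinates are 0-based with half-open bins; all circular arithmetic is
  modulo L. Genome-browser 1-based positions must be shifted by one.
* Simulated bin membership of a replicated arc is evaluated at the bin
  midpoint; with 1 kb bins on a 2 Mb genome the induced discretization is
  far below sampling noise.
* One integer seed drives one deterministic generator per simulation; the
  caller's RNG state is restored afterwards, and the seed is recorded in
  the truth sidecar so any run can be reproduced bit-for-bit.
* Validation of the simulator against the closed form uses per-bin
  z-scores with the exact variance λ²Nq(1−q) + λNE[c]. Because all bins
  of one simulation share the same chromosome draws, exceedances beyond
  3 SE clump; the shipped check therefore pools the ~18,000 per-bin
  comparisons across nine independent (f, r) settings and requires ≥ 99%
  within 3 SE (99.7% expected marginally) with none beyond 6 SE, rather
  than asserting every bin of every run individually.
* Shipped problem sizes — N = 2000 chromosomes, λ = 10, 20 replicates per
  f level, 100 noisy qPCR runs — were chosen as the smallest sizes at
  which the Monte-Carlo error of each check is comfortably below the
  quantity it verifies.
* Degenerate inputs fail loudly: all-zero coverage, constant dilution
  series, non-positive growth slopes, zero cell densities, overlapping
  depth intervals and out-of-range coordinates are errors, not silent
  NAs. Peak calling on an unsmoothed profile is allowed but warned.

## What passing the simulations does and does not show

The generator reproduces the features MFA itself relies on — circularity,
a mixture of localized and dispersed initiation, asynchronous progress,
depth-proportional sampling — so green checks demonstrate that the chain
is numerically correct and that the estimator inverts the model it
assumes. Real libraries additionally carry GC and mappability bias,
uneven fragmentation, replication restart and possible sequence-biased
RDR; none of these are emulated, so agreement here does not certify
accuracy on real data beyond the model's assumptions. The known
limitations worth repeating: f requires an external r; absolute peak
areas are convention-dependent; multi-origin chromosomes and de novo
origin discovery are out of scope; and an inverted (convex) profile at
the origin, as occasionally seen under high pressure, is flagged as
undetected rather than modeled.
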