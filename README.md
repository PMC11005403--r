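# mfakit

Marker frequency analysis (MFA) of DNA replication initiation in polyploid
archaea, from deep-sequencing coverage of a circular chromosome.

Thermococcales such as *Thermococcus barophilus* carry many copies of one
circular chromosome and can initiate replication two ways: by firing the
canonical origin *oriC*, or by recombination-dependent replication (RDR),
which starts from dispersed, origin-independent sites and leaves no single
detectable peak. In an actively replicating population, loci near an active
origin are over-represented in bulk DNA, so the normalized read-depth
profile shows a peak at *oriC* whose height and area quantify origin usage.
`mfakit` is for microbiologists and genome scientists who want to turn raw
depth tracks from such experiments into calibrated origin-usage numbers
across a growth curve, together with the companion measurements those
studies rely on: qPCR ploidy, doubling times, and western-blot
densitometry.

## The model

A population of N chromosomes has a fraction *r* mid-replication. A
replicating chromosome fired at *oriC* with probability *f*, or at a
uniformly random site with probability 1 − *f* (the RDR mode); replication
is bidirectional and progress is Uniform(0, 1) (asynchronous steady
state). The expected per-chromosome copy number at a position with
circular distance *d* from *oriC* is

    E[c(x)] = 1 + r [ (1 − f)/2 + f (1 − 2d/L) ]

maximal at *oriC*, minimal at the antipode, with genome-wide mean
1 + r/2. Reads are Poisson with mean proportional to local copy number.
The analysis chain — binning, mean-normalization (profile mean exactly 1),
circular Gaussian smoothing, far-half-median baseline, peak height/area —
inverts this model: the peak-to-trough contrast k = apex/trough − 1 gives

    f̂ = k (1 + r/2) / ( r (1 + k/2) )

*f* and *r* are not jointly identifiable from profile shape alone, so the
estimator takes *r* as input.

The qPCR module fits the standard curve Cq = slope·log10(copies) +
intercept, with amplification efficiency E = 10^(−1/slope) − 1, and
reports chromosomes per cell; the growth module fits ln(density) vs time
(doubling time τ = ln 2/slope); the densitometry module applies
total-protein lane normalization and percent-of-reference scaling.

## Worked example

Simulate a *T. barophilus*-scale population (2,010,000 bp, *oriC* at
1,671,000 bp) with 60% of chromosomes replicating and 80% of firings at
the origin, then quantify the peak:

```r
library(mfakit)
tbar <- genome_def(2010000, ori_position = 1671000, name = "Tbar")
params <- sim_params(tbar, n_chromosomes = 2000, replicating_fraction = 0.6,
                     ori_fraction = 0.8, mean_depth_per_copy = 10,
                     bin_size = 1000, seed = 101)
sim <- simulate_population(params)
mfa <- gaussian_smooth(normalize_profile(sim$coverage), sigma = 10)
peak <- detect_ori_peak(mfa)
peak
#> <peak_call> detected: apex 1.1764 at 1,663,000 bp, baseline 0.9119, height 0.2645, area 2.007e+05
estimate_ori_fraction(mfa, peak, r = 0.6)
#> [1] 0.7634958
```

The apex lands within a few bins of the annotated origin (smoothing and
sampling noise move it slightly); the relative copy number there is 1.18
times the genome average, 0.26 units above the far-half baseline, and the
inversion recovers the simulated origin-usage fraction 0.8 to within
\~0.04. A knockdown of the recombinase (less RDR, higher effective *f*)
raises this peak; deleting *oriC* (f = 0) flattens it below the 0.05
detection threshold.

Doubling-time comparison of two strains from their fitted means:

```r
doubling_ratio(list(tau = 215.3, se = 35.7), list(tau = 90.6, se = 7.5))
#> $ratio  2.376...  -> rounds to a 2.4-fold slow-down
#> $se     0.440...
```

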