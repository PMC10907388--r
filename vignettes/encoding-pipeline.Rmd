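---
title: "From calcium movies to the bipolar-cell encoding space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium movies to the bipolar-cell encoding space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BipolarCoding)
```

This vignette documents the models, parameter choices and numerical
decisions behind `BipolarCoding`: what each stage assumes, why the defaults
are what they are, and what the synthetic-data generator does and does not
emulate.

## The scientific setting

Retinal ON bipolar cells relay photoreceptor signals to ganglion cells
through axon terminals that stratify at type-specific depths of the inner
plexiform layer (IPL, normalized 0 at the outer border to 1 at the inner
border). Seven ON cone bipolar types form two laminar blocks: an upper
block (BC5o, BC5i, BC5t, XBC) above the ON ChAT band and a lower block
(BC6, BC7, BC8/9) below it. Two-photon calcium imaging of GCaMP6f in these
axons, under spot, sinusoidal, checkerboard and naturalistic movie
stimulation, gives access to the functional organization of this mosaic:
which types carry temporal contrast, which spatial contrast, which motion
information, and whether single axon arbors act as one computational unit.

## The synthetic-data generator

Because every downstream stage needs inputs with known ground truth, the
package ships a generator rather than fixtures.

**Stimuli.** `generateSpotStimulus()` renders the seven-spot protocol (20,
50, 100, 200, 400, 600, 800 µm diameters; 1.5 s ON, 1.5 s OFF, five
ON-OFF cycles in a row per size, sizes in a seeded pseudorandom order with
1.5 s background gaps). Contrast units span [-0.5, 0.5] with 0 the adapted
background; the OFF phase is a dark disk, not a dark field, mirroring a
projector that only modulates the spot aperture.
`generateFreqStimulus()` modulates 150 and 800 µm spots sinusoidally over
the full contrast range for 2 s per epoch at 0.5–16 Hz;
`generateCheckerboard()` draws binary squares (ON with probability 0.5)
and repeats the unique-frame sequence twice; and
`generateNaturalisticSurrogate()` builds a spatially correlated random
field with a power-law spectrum (power ~ f^-2 by default, the
natural-image slope; exponent 0 gives white noise) that is translated
rigidly during motion segments by exact Fourier phase shifts, so
sub-pixel velocities are rendered faithfully. Pseudorandom orderings are
uniform seeded shuffles; all generators are pure functions of their seeds.

**Model cell.** `simulateCellResponse()` applies, in order: a linear
center-surround drive (Gaussian center with SD = `centerRadius`/2 minus
`surroundWeight` times a uniform annulus from `centerRadius` to
`surroundRadius`), a first-order adaptation stage (the low-pass state with
time constant `transienceTau` is subtracted from the drive; `Inf` means no
adaptation, i.e. a fully sustained cell), half-wave rectification, the
GCaMP6f kernel, box-average resampling to the acquisition rate, and
additive AR(1) noise with lag-1 coefficient `noisePhi` and marginal SD
`noiseSd`. The default `centerRadius` is 25 µm: bipolar-cell receptive
field centers are ~50 µm across, and — decisive for the surround
statistic — 50 and 100 µm spots must drive the center to near saturation
for S = (r_c - r_s)/r_c to track the surround weight cleanly. An optional
`motionGain` adds a motion-energy drive (mean absolute temporal gradient
in the center), a deliberately cheap proxy that makes responses
motion-sensitive without simulating flow.

**The seven default types** (`defaultCellTypes()`) encode the two-block
organization as generator set-points: the upper-block types share
`surroundWeight = 0.7` (which yields large-spot responses near ~30% of
the 150 µm response, i.e. strong, uniform surround suppression) while
their adaptation constants span 0.15 s (XBC, most transient) to 4 s
(BC5t, most sustained); the lower-block types share sustained kinetics
(2.5 s) while their surround weights span 0.2 (BC8/9, weak) through 0.4
(BC6) to 1.1 (BC7, strong enough to invert large-spot responses, S > 1).
IPL depths ascend from 0.50 to 0.90. These numbers were chosen once to
reproduce the qualitative organization; they are not fits.

**Arbors.** `generateArbor()` samples skeleton nodes uniformly in a disk
of the requested equivalent diameter, connects them by their Euclidean
minimum spanning tree, and places ROIs on nodes. Per-ROI signals are a
Cholesky mixture whose pairwise correlations decay with tree path
distance d as exp(-d/(2λ)). The factor 2 is deliberate: the
length-constant estimator works on the paired-consistency scale, where
the observed consistency k equals the squared signal correlation times
the expected consistency q (k is a product of two cross-repeat
correlations), so signal correlations exp(-d/(2λ)) make k = exp(-d/λ)·q
and the estimator consistent for the generator's λ. Defining the
generator's λ directly on signal correlations would make every recovered
length constant half the nominal one. `lengthConstant = Inf` gives a
perfectly homogeneous arbor.

**What the generator does not emulate.** Photoreceptor adaptation,
frequency-dependent suppressive baseline (F0) shifts — whose mechanism is
an open question and which we deliberately do not invent —, rod input,
chromatic opponency, optical blur and scan artifacts, nonstationary
noise, and z-drift. Tests passing on this generator therefore demonstrate
that the analysis recovers the statistical structure it assumes, not that
real recordings satisfy those assumptions.

## Imaging

Registration estimates integer-pixel translations by Fourier
cross-correlation against a reference frame; at ~18 pixels/µm² sampling,
sub-pixel refinement adds nothing the downstream ROI averages would see.
Shifts estimated on one channel can be applied to a paired channel
(`applyShifts()`). Axial drift cannot be corrected in-plane;
`registrationQc()` flags series whose frames decorrelate from the
reference below a configurable floor (default 0.5), replacing a visual
rejection step with a recorded criterion.

The 3×3×3 median filter (reflect padding, compiled code) suppresses
shot-noise impulses; pixels are then masked in when their temporal SD is
in the top 75%. Segmentation finds strict local maxima of the SD image
above a threshold (default its 75th percentile, exposed as a parameter —
the manual fine-tuning loop of an interactive workflow is intentionally
not emulated), snaps optional manual seeds to the peak among their 12
nearest pixels, and grows ROIs by synchronized multi-source BFS so that
each above-threshold pixel joins the peak nearest by geodesic
(within-mask, 4-connected) distance — guaranteeing every ROI is connected
— with simultaneous arrivals resolved to the lower peak index for
determinism.

Epoching cuts ROI traces per stimulus-log entry and subtracts the mean of
the 0.5 s before onset. Repeat reliability is the median squared
correlation between half-split averages over all balanced splits (one
split for two trials). ROI consolidation runs k-means on row-z-scored
traces (whose squared Euclidean metric is proportional to correlation
distance) with k-means++ style restarts under a fixed seed, choosing k by
BIC = n·ln(RSS/n) + k·ln(n) where RSS sums correlation distances to
cluster centroids; k equal to the ROI count is handled as the trivial
one-ROI-per-cluster solution.

## Temporal-frequency analysis

The GCaMP6f kernel is (1 - e^(-t/τr))·e^(-t/τd) with τr = 49.5 ms and
τd = 156 ms, peak-normalized; a temperature adjustment factor is exposed
but defaults to 1 since no published factor exists for these conditions.
F1 power resamples the trace to 189.4 Hz by Fourier zero-padding — exact
band-limited interpolation for epoched (quasi-periodic) data, which is
why no polyphase filter dependency is needed — and reads |FFT(X)/N|² at
the stimulus frequency: one bin when f1 times the epoch duration is an
integer, else the sum of the two nearest bins. A full-contrast sine
(amplitude 0.5 in contrast units) thus has F1 power (0.5/2)² = 0.0625.
The kinetics correction simulates the kernel's response to each
modulation (with 1 s pads at the 0.5 mid-level), pushes the simulation
through the *same* F1 code path, peak-normalizes, and subtracts; feeding
the simulation to itself yields exactly zero by construction.

F1 phase averages the complex F1 components (amplitude-weighted vector
sum) across trials and the one-or-two nearest bins. Weighting by
amplitude rather than converting to unit vectors keeps near-empty
neighbor bins from distorting the mean; in this convention a pure sine at
the stimulus frequency reports -90°.

The AR(1) model is fit by OLS of x_t on x_(t-1) with an intercept (the
coefficient is the slope), the innovation SD matching the residuals;
simulation reproduces the lag-1 correlation structure for
stimulus-independent surrogates.

## Spot features and typing

Surround strength and transience use the fixed windows 0.34–1.54 s
(S, over 50/100 vs 600/800 µm spots) and 0.23–0.67 s vs 1.21–1.65 s
(T, over 50/100/200 µm spots), all half-open [t0, t1) at the acquisition
rate. Traces are baseline-subtracted and normalized to the single peak
across the full epochs of all sizes (normalizing per size would erase the
very ratios S measures; taking the peak over the full epoch rather than
the ON phase only is the package's resolution of an ambiguity, flagged
here for review). Both statistics are invariant to positive rescaling.
The trial-based peak-amplitude analysis detects local maxima 0.1–1.5 s
after onset (prominence at least 3 pre-stimulus noise SDs) in trials
whose repeat reliability clears 0.5, and scores multimodality of the
pooled amplitudes by Gaussian-mixture BIC comparison (mclust, 1 vs up to
3 components) — a likelihood-based alternative to a dip statistic, chosen
because it also estimates the number of amplitude modes.

The classifier scores an unknown ROI against each type by the median
correlation distance to that type's reference exemplars (the pure
nearest-exemplar rule is available as an option; the median is robust to
a single atypical exemplar), converts distance to probability through
the survival function of a gamma distribution fitted by maximum
likelihood to the reference cells' nearest-type distances (distance 0
maps to probability 1), multiplies by a per-depth-normalized IPL-depth
prior (smoothed by a 21-point moving average), and assigns the arg-max
type with deterministic low-index tie-breaking. Outliers are ROIs whose
combined probability falls in the lower 5% tail of a gamma fit to all
combined probabilities — the analogue of a two-SD cut for a skewed
distribution.

One calibration fact worth knowing: leave-one-out validation with
permuted labels is biased *above* the nominal 1/7 chance level in small
references, because the held-out cell's own label always has the smallest
remaining group and the median-distance rule favors small groups (~20%
at 4 cells per type, ~17% at 8). The package's chance-level checks
therefore run at 8 cells per type — the augmented-population scale — and
the residual 2–3 point bias is a property of the procedure, not of the
classifier's information content.

## Encoding space

Pairwise correlation distances get a binary weight mask: any distance
deviating more than 3 SDs from the mean of all pairwise distances is
given zero weight and excluded from both the embedding and the explained
variance. Correlation distances need not satisfy the triangle inequality;
`triangleViolationRate()` reports how often they do not, and the
nonmetric formulation tolerates the violations.

The embedding is weighted nonmetric SMACOF written for this package
(no installed MDS accepts a weight matrix): alternating isotonic
regression of configuration distances on the rank-ordered dissimilarities
(`stats::isoreg` on the masked pairs) and Guttman-transform updates, with
stress-1 as the criterion, a classical-MDS start plus 4 random restarts
under a fixed seed, a 2000-iteration cap, and a 10^-6 relative stress
tolerance. Coordinates are reordered by single-coordinate explained
variance. On unmasked fixtures the final stress is cross-checked against
`MASS::isoMDS` in the test suite. A caveat at desk scale: with a few
dozen units, a 16-dimensional nonmetric embedding is nearly saturated and
admits degenerate monotone solutions whose raw-distance R² swings widely
even as stress stays near zero; analyses of the small synthetic
populations therefore embed at the structure dimension (3), where the
explained variance is stable (~0.96).

The batch-effect test compares the Jensen-Shannon divergence (natural
log; kernel densities on a shared grid, normal-reference bandwidths on
the pooled points) between batch-respecting splits of the first two
coordinates with random splits of the pooled points whose sizes mimic the
batch splits; p is the one-sided fraction of random-split JSDs at or
above the median batch-split JSD (the tail convention is the package's
choice and is what makes the null mean ~0.5). Feature axes implement the
mean over ordered unit pairs of (w_i - w_j)(v_i - v_j) — computed in
closed form but tested against the O(n²) loop — and angular robustness is
assessed over 1000 random 90-pair subsamples by default.

## Naturalistic features

The receptive-field weight mask is a bivariate normal with covariance
2πr·I µm² (r the mask radius), truncated at r and max-normalized; feature
values are weighted frame averages divided by the weight sum. The g
operator convolves with a 4 s kernel whose central component is the 2 s
GCaMP6f response function, area-normalized so steady-state gain is 1
(peak-normalizing instead would rescale steady luminance by the kernel
mass); a 200 ms shift aligns features with the delayed responses.
Features are computed at the movie frame rate and box-averaged into the
response sampling bins.

Temporal kernels f_b (Gaussians at 0.08 s/SD 0.05/weight 1 and
0.12 s/SD 0.12/weight -0.5) and f_l (0.24 s/SD 0.1/weight 1 and
0.3 s/SD 0.24/weight -0.001) are discretized on a 1 s window with
quadrature (1/rate) scaling, so their relative masses match the
continuous definitions.

Horn-Schunck optical flow uses the classic iterative scheme with
smoothness 3 and 100 iterations (convergence at these settings is
verified on translation fixtures rather than monitored online). Frame
pairs are rescaled to a 0–255 intensity range first: the smoothness
parameter's conventional meaning assumes 8-bit-like intensities, and on
[-0.5, 0.5] contrast units the same α would crush the data term. The
coherent-motion statistic is O_a - O_v inside a 200 µm disk, with O_v
taken as the magnitude of the *mean* flow vector so that it is
dimensionally commensurate with O_a (the raw vector-sum magnitude, which
scales with pixel count, is available behind a flag); the statistic then
vanishes for rigid coherent flow and grows with incoherent motion. The
in-center contrast S_cin splits the center disk into four quadrants
weighted by the Gaussian mask times a linear radial ramp and takes the SD
of the four quadrant contrasts per frame (alternatives the field has
tried — weighted pixel SD, finer subdivisions — behave equivalently); the
blend weight β maximizing Corr(β·g(S_cin) + (1-β)·g(S_c), R) is found by
an exhaustive 0.001-step grid (cross-checked against a continuous
optimizer) and reported as I = log10(β) with β floored at 10^-3 to keep
the logarithm finite.

Receptive-field mapping correlates responses with g-filtered 80 µm-disk
luminance at 441 positions (±40 µm, 4 µm steps) and refines the peak by
separable cubic-spline interpolation onto a 0.5 µm grid; peaks on the
grid border are returned unrefined and flagged, and maps whose best
squared correlation stays below 0.1 are flagged as unmappable.

## Arbor analysis

ROI centroids attach to the nearest skeleton point sampled every 0.1 µm
along edges; attachment points are chained in arclength order on their
host edges so that two ROIs on one edge are separated by their true
arclength gap, and path distances are exact shortest paths on the
weighted graph (igraph). Paired consistencies q and k are computed per
repeat pair and averaged when more than two repeats exist (the choice of
averaging over repeat pairs is the package's); per-movie-clip inputs are
computed per clip and averaged. The length constant maximizes
Corr(r_λ ⊙ q, k) over a 60-point log grid from 1 to 1000 µm plus Inf
(r ≡ 1); a profile whose range is below 10^-6 is reported as unbounded.
A λ* exceeding the arbor's equivalent diameter is the operational
verdict that the arbor responds homogeneously.

## Problem sizes and reproducibility

The test suite and the acceptance script run on deliberately small
instances chosen as the smallest sizes at which each statistical claim is
stable: populations of 4 cells per type (8 for the chance-level control),
stimulus movies at 10–20 µm/pixel, 400–900 checkerboard frames, arbors of
40–60 ROIs with 500-sample signals, 10–17 simulated arbors per length
constant, and 40–60 batch splits against 150–300 random resamples with
31-point KDE grids. Production analyses should use the full-scale
defaults built into the functions (5000 permutation iterations,
2000/20000 batch resamples, 16 embedding dimensions, 1000 angular
subsamples). Every stochastic step takes an explicit seed, and all
generators are pure functions of their arguments and seeds.

## Known limitations

Registration is integer-pixel and purely translational; spike inference
is out of scope (the indicator kernel is inverted only implicitly, via
the F1 correction); the anatomical classification tree that identifies
types morphologically is represented only by user-supplied feature
thresholds; the naturalistic surrogate has stationary statistics and
cannot stand in for real scene content; and the classifier's depth prior
assumes the synthetic stratification profiles' accuracy — with real
connectomic profiles its calibration should be revisited.
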