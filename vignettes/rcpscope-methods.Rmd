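---
title: "Digital RCP counting and in situ genotype scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital RCP counting and in situ genotype scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Rolling-circle amplification (RCA) turns a single circularized probe —
a padlock probe ligated in situ on a target transcript, or a restriction
fragment captured by a selector probe — into a micron-sized DNA coil
carrying hundreds of concatemeric repeats. After hybridization with
fluorescent detection oligonucleotides, each rolling-circle product (RCP)
appears as one diffraction-limited spot. Counting spots therefore counts
molecules, and the ratio of spots between two colour channels reads out an
allele ratio: in the in situ KRAS assay, one channel carries the
mutant-specific probe and the other the wild-type probe; in
sequencing-by-ligation (SBL), the interrogated base maps to a channel
(A on Cy5, T on FITC, G on Cy3, C on Texas red or, in two-channel
operation, the absence of signal).

On low-cost imagers — the motivating case is a phone camera behind an
external lens, with an object-plane pixel pitch of roughly 0.42 µm/px so a
1 µm spot covers an object of 2–8 px — three obstacles stand between raw
frames and reliable counts: high per-frame noise, auto-fluorescent tissue
structures that mimic spots, and small rigid shifts between the channels
acquired sequentially. `rcpscope` implements the full chain: frame
averaging, Gaussian denoising, phase-correlation co-registration, white
top-hat spot enhancement with size and intensity gates, a 14-feature
random-forest spot classifier, anchor gating, double-stain rejection, base
calling, genotype scoring and dilution-series regression — plus a
synthetic micrograph generator that provides per-object ground truth for
every stage.

# Preprocessing

**Frame averaging.** Each channel is acquired as N repeated frames
(default 5) of the same region of interest; averaging reduces independent
noise by √N. The average is then divided by the full 16-bit range, so all
downstream intensities live in [0, 1] and *absolute* thresholds (the
0.1–0.4 detection gate) keep their meaning across images — we deliberately
do not normalize per-image maxima.

**Gaussian denoising.** A normalized Gaussian kernel with default
σ = 1 px, chosen just below the spot σ (≈ 1.0–1.7 px), trades a factor
≈ 2 of peak amplitude for a further variance reduction of ≈ 4πσ² on white
noise. The convolution uses edge replication at the boundary.

**Co-registration.** Channels are aligned to the first signal channel by
phase correlation: the whitened cross-power spectrum is inverted, its peak
located on the pixel grid, and the location refined on a 0.05-px grid by
evaluating the inverse transform locally (upsampled-DFT refinement; a
single-bin parabolic fit is biased here because the whitened peak of a
half-integer shift splits across bins with alternating signs). Both images
are Hann-windowed first — the frames are not periodic, and without the
window the shared frame edges correlate spuriously at zero offset along
each axis. Translation can only be estimated from features the two
channels *share* (double-stained structures, an anchor stain, a
bright-field frame). When the correlation peak is below `min_peak_corr`
(default 0.01), or the estimated shift exceeds `max_shift_px`, the image
is passed through unshifted and flagged rather than shifted by a spurious
estimate. Estimation is per-acquisition; correction applies the
Fourier-shift theorem (sub-pixel, periodic boundary). Rotation and scale
are out of scope: the stage is rigid and the channels share one optical
path.

On rendered test scenes the mean absolute shift-recovery error over random
shifts in ±5 px is well under 0.1 px; the test suite asserts < 0.3 px.

# Detection

**Enhancement.** White top-hat with a disk of radius 4 px (configurable):
the morphological opening removes everything the disk fits inside —
flat background, slow auto-fluorescence gradients — and the subtraction
leaves compact structures smaller than the disk.

**Gating.** Pixels at or above the intensity threshold (default 0.1,
sensible range 0.1–0.4) form 8-connected components; 8-connectivity avoids
splitting 2-px diagonal objects. A component is kept when its equivalent
circular diameter `2*sqrt(area/pi)` lies within 2–8 px — the size window is
a *diameter*, consistent with 1-µm spots at 0.42 µm/px. Touching spots are
not declumped: the densities of interest are sparse and no watershed step
is defined for this assay. Output is sorted by centroid and fully
deterministic.

**Adaptive threshold.** Real samples differ in auto-fluorescence level, so
a fixed threshold inside 0.1–0.4 is a per-sample choice. The `adaptive`
mode makes that choice reproducible: threshold = median + k·MAD of the
enhanced image (k = 6), clipped into [0.1, 0.4]. This rule is our own
construction; nothing in the underlying assay prescribes it.

**Measurement.** Per object and channel: mean, max, min and integrated
intensity over the pixel set, plus the mean and s.d. of a local background
annulus — a 2-px-wide ring starting 2 px outside the object. Objects whose
annulus is clipped away at the image border fall back to the global image
median/MAD and are flagged.

# Classification

Fourteen per-object features feed a random forest (bagging over
bootstrapped samples, random feature subsets per split): six intensity
statistics (mean, max, min, integrated, s.d., median), four size/shape
descriptors (area, equivalent diameter, perimeter, eccentricity), two
regularity descriptors (solidity, compactness) and two local-context
descriptors (contrast over the annulus, peak SNR = max / annulus s.d.).
Only the first three are fixed by the original method description; the
remaining eleven are our choice of the standard intensity/shape/context
panel, picked so the classifier can act on exactly the axes on which
auto-fluorescent artifacts differ from RCPs — size, elongation,
irregularity and local contrast.

Forest defaults are canonical: 100 trees, ⌈√14⌉ = 4 features per split,
unlimited depth, bootstrap of size N. Training rows are sorted by a stable
key before seeding the bootstrap, so the fitted model does not depend on
row order. An exact vote tie resolves to `not_rcp`: spurious counts from
auto-fluorescence are the failure mode digital counting guards against.
Accuracy is reported as per-object classification accuracy under
stratified k-fold cross-validation (the alternative reading — detection
sensitivity against a benchtop gold standard — is not what this module
measures, and we say so explicitly).

# Base calling and artifact rejection

Per-channel signals are background-subtracted (annulus mean) and floored
at zero, which makes calls invariant to multiplicative intensity rescaling
and insensitive to channel-specific background offsets. The decision rule
per object:

1. all coded channels below `min_signal` → the blank base if the coding
   declares one (disabled by default), else `no_call`;
2. double-stain ratio (second-highest / highest signal) strictly above
   0.3 → rejected as auto-fluorescent (a ratio of exactly 0.3 is kept);
3. otherwise the base coded by the dominant channel.

`min_signal` defaults to 3× the median annulus s.d. per channel — the
assay description gives no value for "no signal", so this three-sigma rule
is our choice and is surfaced as a parameter. The coding map treats the
Texas-red/blank code as C; the published coding sentence assigns G twice,
an evident typo given that four bases need four codes and G is already
Cy3. An anchor stain (Alexa750), when measured, gates objects first:
background-subtracted anchor signal below 3× the median anchor annulus
s.d. → rejected as non-RCP. Two-channel (Cy3/Cy5) operation without an
anchor is the default, matching a two-laser imager; the gate is then
skipped with a warning. Single-cycle calls only — consensus filtering over
multiple sequencing cycles is out of scope.

# Genotype scoring and quantification

ROI counts are pooled by summation; fewer than six ROIs raise a flag
(six randomly chosen fields are the practical minimum to accumulate
mutant RCPs in tissue). The headline ratio is pooled MT/WT — not the mean
of per-ROI ratios — and a sample scores **Mutant** when the *unrounded*
ratio exceeds 8%, wild type at or below. The reported percentage is
rounded to one decimal, half away from zero, matching how such tables are
printed, but scoring never depends on display rounding. The 8% default
stems from the highest mutant ratio observed on clinically wild-type
tissue; it is a configurable constant here.

Dilution series are fit by ordinary least squares of log10(mean count) on
log10(concentration). The linear dynamic range is the widest contiguous
concentration span whose restricted fit reaches R² ≥ 0.98; a saturating
top point (spot merging at high density) therefore drops out of the span
instead of corrupting the slope, and the reported slope/intercept/R²
describe that span.

# The synthetic scene generator

`render_scene()` emulates the acquisition: true RCPs are isotropic 2-D
Gaussians with σ = diameter/(2.355·pixel size) ≈ 1.01 px (the FWHM
convention for a 1 µm spot at 0.42 µm/px), placed uniformly at a Poisson
number per tile, each staining exactly one signal channel (its coding
base) plus, optionally, the anchor channel. Auto-fluorescent artifacts are
larger elliptical Gaussians (major-axis σ drawn U(1.8, 4.0) px,
eccentricity U(0.6, 0.92)) staining two signal channels with a
minor/major amplitude ratio U(0.35, 0.95) — above the 0.3 rejection
boundary — and never the anchor. Non-reference channels are rendered with
a configurable rigid shift. Each frame draws `gain · Poisson(expected/gain)`
shot noise plus Gaussian read noise, is rounded and clipped to [0, 65535].

Defaults were fixed once, before any acceptance measurement, at values a
microscopist would call realistic for this assay class:

* tile 1024×1024 px (≈ 0.18 mm² at 0.42 µm/px) rather than the full
  ≈ 0.8 mm² field of view — desk-scale test sizes;
* background 2% of full scale; spot peak amplitudes U(0.30, 0.55) of full
  scale, i.e. bright staining spanning the upper part of the 0.1–0.4
  detection gate *after* the ≈ 0.5× peak loss of denoising;
* `peak_snr` (default 12; the harder test condition is 5) is defined on a
  **single raw frame** as mean spot amplitude over background noise s.d.;
  the read-noise s.d. is derived from it as
  `sqrt(max(0, (amp/peak_snr)^2 - gain*background))` with gain
  2 DN/photon. Averaging five frames and denoising then recover the
  detection margin, which is precisely the pipeline's working principle.
  At low SNR the background tail clips at zero; the noise-model variance
  check therefore runs at high SNR where clipping is negligible.

Artifact density and brightness in tissue are not quantified anywhere we
could anchor to, so those defaults are free parameters of the generator,
not calibrated claims.

**What the generator does not emulate:** tissue morphology and nuclei,
raw Bayer/DNG sensor data, optical aberrations and vignetting, focus
drift, spot blinking/bleaching, and spatial clustering of RCPs within
cells (placement is uniform). Passing the synthetic checks therefore
demonstrates the correctness and calibration of the *algorithms* under a
controlled noise model, not end-to-end performance on real tissue images.

# Problem sizes in the bundled checks

The test suite and `scripts/acceptance.R` run at sizes chosen as the
package's own desk-scale study conditions: a dilution series of five
concentrations (1 fM–10 pM equivalents, densities 2→20,000 expected
spots per tile, 3 replicates, extra tiles at the two lowest densities);
a labelled set of 500 RCPs + 500 artifacts at peak SNR 5 for 5-fold
cross-validation; mixture scenes with ≥ 2,000 RCPs (50:50) and ≈ 7,500
RCPs (1:1000 spike-in); 50 random sub-pixel shifts for registration
recovery. At the top dilution density ≈ 2% of the tile is occupied and
nearby spots merge into single connected components, which is exactly the
saturation behaviour the restricted-span regression is designed to
tolerate.

# Known limitations

* Registration fails gracefully but cannot succeed when channels share no
  structure; scenes with disjoint single-stained populations and no
  anchor/bright-field reference are registered only by luck of shared
  artifacts.
* Detection counts connected components; at occupancies beyond a few
  percent, merging biases counts low (visible as slope compression at the
  top of a dilution series).
* The classifier is trained and evaluated on synthetic renderings; its
  reported accuracy is a property of the generator's artifact model, not
  of any particular real tissue.
* Genotype calls carry no confidence intervals; the 8% threshold is a
  fixed operating point, not an estimated decision boundary.
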