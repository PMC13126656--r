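---
title: "Quantifying endometrial vasculature from OR-PAM images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endometrial vasculature from OR-PAM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamvasc)
```

## The problem and the approach

Optical-resolution photoacoustic microscopy (OR-PAM) images subsurface
microvasculature label-free, at micron lateral resolution, by detecting
the ultrasound that hemoglobin emits under pulsed laser excitation.
Malignant and premalignant endometrium (endometrial cancer, EC, and
endometrial intraepithelial neoplasia, EIN) remodels its vascular bed:
vessels become enlarged, heterogeneous in caliber, and fragmented,
and the bulk photoacoustic spectrum shifts toward lower frequencies as
effective absorber dimensions grow. `pamvasc` turns these observations
into a quantitative separability analysis in three stages:

1. **Preprocessing.** Raw radiofrequency (RF) C-scan volumes are
   band-limited (default 30 kHz-50 MHz), envelope-detected with the
   analytic signal, and collapsed to en-face maximum intensity
   projections (MIPs). A 45-dB logarithmic display window is applied
   before structural analysis.
2. **Feature extraction.** Two parallel branches quantify each image.
   The *structural* branch segments the MIP (background subtraction by
   grayscale opening, CLAHE, Otsu thresholding, despeckling),
   skeletonizes it by Guo-Hall thinning, and measures (a) the
   distance-transform diameter map — at each centerline pixel the local
   diameter is twice the exact Euclidean distance to the vessel
   boundary — and (b) the skeleton graph: endpoints, branch nodes,
   segments, isolated components, with counts and lengths normalized by
   ROI area. The *spectral* branch computes a pixel-wise power spectral
   map (Hann periodograms averaged over a 5 x 5 sliding window of
   A-lines, with noise gating) and reduces it to the power-weighted mean
   frequency.
3. **Separability analysis.** Features are screened by Welch's t-test,
   de-correlated greedily (accept in order of ascending p while
   |Pearson r| with all accepted features stays below 0.5, default
   k = 5), turned into a cosine-similarity network of L2-normalized
   feature vectors, embedded in 2D by a similarity-weighted
   Fruchterman-Reingold layout with an in-sample logistic boundary for
   visualization, and classified by leave-one-out cross-validation
   (LOOCV): each fold summarizes every training sample by four
   attributes — mean and SD of similarity to each class cluster — fits a
   ridge-stabilized logistic regression on the (n-1) x 4 matrix, and
   scores the held-out sample from its similarities to the n-1 training
   samples only.

The five features the framework is designed around are the spectral
mean frequency, the mean and SD of vessel diameter, the area-normalized
isolated branch length (a fragmentation surrogate: centerline length in
components that contain no branch node, per unit ROI area), and the
branching interval (mean centerline length of segments joining two
branch nodes).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `pixel_size_um` | 3 | µm | lateral scanner step; calibrates all lengths |
| `band_hz` | 30 kHz – 50 MHz | Hz | analysis band of the RF signal |
| `dynamic_range_db` | 45 | dB | display window before segmentation |
| `spectral_window_px` | 5 | px | sliding-average window of the spectral map |
| `noise_floor_quantile` | 0.5 | — | envelope-maximum quantile gating signal A-lines |
| `ball_radius_px` | 25 | px | background-opening disc radius (&gt; vessel radius) |
| `min_area_px` | 10 | px | despeckle threshold after thresholding |
| `k` | 5 | — | number of features retained |
| `corr_threshold` | 0.5 | — | absolute-correlation bound during selection |

## Numerical choices

**Bandpass filtering.** The band edges span five decades, and a single
order-4 Butterworth bandpass is numerically ill-conditioned at a
normalized low edge of 2.4e-4; worse, the low-edge transient is longer
than a typical A-line record, so a forward-backward IIR high-pass alone
cannot reject DC on finite records. `bandpass_filter()` therefore
removes the per-A-line mean exactly, then applies zero-phase order-4
low-pass and high-pass filters in cascade. In-band tones are preserved
within 1%, out-of-band tones are attenuated by more than 40 dB, and a
constant A-line maps to zero.

**Envelope and spectra.** The analytic signal is built by the FFT
construction; the first and last ~1% of samples carry circular edge
artifacts and are excluded from envelope accuracy checks. Periodograms
use a Hann window (leakage control; configurable in principle, fixed in
this release). The transducer bandwidth is deliberately *not*
deconvolved from the spectra — it is constant across images, so it
cancels in between-class comparisons.

**Skeleton topology.** Centerline pixels are classified by their degree
on the *shortcut-pruned* pixel adjacency graph: a diagonal link between
two pixels that are already joined through an orthogonally adjacent
common neighbor is a triangle shortcut and is not counted, for degrees
or for lengths. Raw 8-neighbor counts would classify the chain pixels
diagonally adjacent to a junction as branch pixels, absorb them into
the junction cluster, and bias segment lengths; with pruning, an "H" of
two junctions joined by a 40-step crossbar yields exactly a 40-step
branching interval. Adjacent branch pixels are merged into one node by
connected-component labeling. Diagonal steps count sqrt(2) pixels.
Images with no branch-to-branch segment get a *missing* branching
interval and are excluded from analyses that use it — no imputation.

**Thinning.** No installed R package provides topology-preserving
thinning, so Guo-Hall two-subiteration thinning is implemented
directly (vectorized over the image). The parallel passes can leave a
fully set 2 x 2 square at the core of a multi-way junction; a cleanup
pass removes one pixel at a time, only when deletion provably preserves
connectivity (local connectivity number, falling back to an explicit
global check).

**Distance transform.** The exact Euclidean distance transform (from
EBImage) matches a brute-force nearest-background search bit-for-bit,
which the test suite and acceptance script verify on random phantoms.
All skeleton pixels enter the diameter statistics, including those near
junctions.

**Logistic fits.** LOOCV folds on well-separated classes are perfectly
separable, where the logistic MLE diverges. All logistic fits use a
ridge penalty of 1e-6 on the non-intercept coefficients (damped Newton
iterations with a backtracking line search), which leaves coefficients
finite and predictions effectively 0/1 in the separable case.

**Similarity and layout.** Feature vectors are L2-normalized on their
raw scales (no per-column standardization) — cosine similarity is then
invariant to per-sample positive scaling; a `scale = TRUE` switch
exposes the z-scored alternative. Because cosine similarities of
nonnegative vectors crowd into a narrow range near 1, the force layout
min-max rescales the off-diagonal similarities to [0, 1] before using
them as attraction weights; the rescaling is monotone, so the
stronger-similarity-stronger-attraction mechanism is untouched, and
layouts become reproducibly class-separated. The layout is
Fruchterman-Reingold with 500 iterations and a fixed seed.

**AUC and confusion.** The AUC is the Mann-Whitney rank statistic on
the pooled out-of-fold probabilities (ties count one half); the
confusion matrix calls a sample positive at probability >= 0.5.

## The synthetic-data module

Patient OR-PAM scans are not distributable, so the package generates
its own inputs with known ground truth; every downstream stage is
tested against these.

**Vascular phantoms** (`generate_vessel_phantom()`) grow trees by
stochastic directed walks: walkers step one pixel at a time with
Gaussian heading noise, branch with a fixed per-step probability
(children emerge at the parent's wall, one parent-radius off the
centerline), draw per-segment diameters from a truncated normal
(bounded below by two pixels so vessels stay resolvable), and stop at
the frame edge, on contact with rendered vasculature (anastomosis), or
when entering the exclusion zone that keeps non-branching vessels about
one diameter apart — without that spacing rule, parallel vessels merge
into wide slabs and the distance transform reads their joint width.
Segments shorter than their own diameter are not grown: they would
render as blobs with no observable centerline. Tubes are rendered by
stamping pixel-center-sampled disks of radius r - 0.25 px along the
centerline; the quarter-pixel shrink centers the distance-transform
readback on r, because the lattice distance that the transform returns
overshoots a continuous radius by about a quarter pixel on average.
Isolated fragments (short unbranched walks, at least 1.5 diameters
long) are placed with a clearance margin until they contribute the
requested fraction of total centerline length. Tree size is capped in
proportion to image area so that default phantoms keep a vessel area
fraction near 15-25%, which is what en-face OR-PAM MIPs of endometrium
look like; trees are regrown (up to 20 attempts) if they end up with
fewer than two branch nodes or less than two mean segment lengths of
extent.

Ground truth records the *realized* network: per-centerline-pixel
diameters as drawn, branch nodes that actually produced a child,
total centerline length measured from the rasterized centerline mask by
the same step-length accounting the topology module uses (a continuous
arc length would disagree with any pixel-chain measurement by up to
~8% digitization bias), and fragment length from the fragments' own
chains.

**RF phantoms** (`generate_rf_phantom()`) place Gaussian-modulated
cosine pulses (default carrier 40 MHz — the transducer center frequency
the package targets — and spectral SD 7.5 MHz, chosen so the pulse
spectrum sits inside the 50 MHz analysis band) on a random half of the
A-lines, plus white noise. Absorber size enters as a closed-form
spectral surrogate: a diameter d multiplies the pulse spectrum by a
Gaussian low-pass with cutoff c/(pi d) (c = 1540 m/s), and the product
of two Gaussians is again Gaussian with an analytically known, strictly
size-decreasing effective carrier. This gives the spectral pipeline an
exact oracle and the right direction of effect, while making no claim
to simulate acoustics (explicitly out of scope).

**Feature tables** (`generate_feature_table()`) draw per-class
multivariate normal vectors for the five selected features
(exchangeable correlation 0.2, rejection-sampled at zero since all
features are nonnegative). Effect directions follow the biology: the
EC/EIN class has lower mean frequency and higher diameter mean/SD,
isolated branch length, and branching interval. The default magnitudes
(e.g. 38 vs 33 MHz, 28 vs 42 µm) correspond to a 2-SD shift per
feature — clearly separated but overlapping classes; published
class-difference magnitudes for these features exist only as boxplot
figures, never as tabulated numbers, so these magnitudes are the
package's own choice, exposed through
`default_effect_spec(separation = ...)` with `separation = 0` giving an
exact null and `separation = 6` an essentially separable dataset.

**What the phantoms do not emulate.** No optical speckle, no surface
bleeding artifacts, no depth-dependent fluence, no real segmentation
ambiguity: phantom vessels are bright, in-focus, and noise is white.
Passing tests therefore demonstrate that the *measurement chain* is
correct — diameters, counts, lengths, centroids, and the classifier are
recovered from data whose truth is known — not that segmentation would
be artifact-free on clinical images. A note on the feature inventory:
there is no single canonical list of vascular descriptors for this
modality; `run_extract()` produces the five framework features plus a
documented set of standard morphometric and topological descriptors
(~22 in total), and the selection stage operates on whatever table it
is given.

## Problem sizes in the verification suite

The test-suite and acceptance-script problem sizes are chosen to
exercise each property at meaningful scale on a single core: 30-50
random phantoms (128-192 px frames, tens of thousands of centerline
pixels) for the exact distance-transform and topology-oracle
equivalences, 100-120 seeded runs for diameter recovery at 30 and
60 µm — with the frame scaled to vessel caliber (192 px at 30 µm,
320 px at 60 µm) so every phantom holds enough independent segments
for a stable mean, since the lattice skeleton sits up to half a pixel
off a continuous centerline depending on segment slope and that offset
only averages out across segments — 1000 replicates for Welch null
calibration, and 200 label permutations for the LOOCV null. The LOOCV itself always runs at the
study shape: 40 images, 10 normal/benign + 30 EC/EIN.

## Known limitations

* Depth information is deliberately ignored (MIP-based analysis only).
* The "robust multipixel sliding averaging" behind the spectral map is
  implemented as window averaging with quantile gating — explicit and
  testable, but a stand-in for an externally referenced procedure whose
  details are not available here.
* Interactive, per-image segmentation algorithm choice (as in
  DiameterJ) is replaced by one fixed, fully parameterized default;
  reproducibility is preferred over per-image tuning.
* The 2D embedding boundary is an in-sample visualization; only the
  LOOCV numbers are cross-validated.
* With a single strongly discriminative feature selected, cosine
  similarity degenerates (all vectors point the same way); the
  framework needs at least two retained features, which `run_full()`
  inherits as a practical requirement.

## A worked example

```{r example, eval = FALSE}
library(pamvasc)

# a labeled two-class feature table at the generator's default
# (moderate) separation: 10 normal/benign + 30 EC/EIN images
tab <- generate_feature_table(seed = 9)

report <- run_full(tab)
report
plot(report$embedding, boundary = report$boundary)
```
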