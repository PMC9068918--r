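---
title: "Depth-resolved cell mapping from single lensless acquisitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved cell mapping from single lensless acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging problem

A millimeter-scale lensless fluorescence imager has no focusing optics; its
point spread function (PSF) is narrow for emitters on the sensor surface and
widens with distance. A single acquisition of a labeled tissue stack is
therefore a *sum of differently blurred layers*, and the depth information
is encoded implicitly — in how blurred, and how attenuated in contrast, each
contribution is. `cellstack3d` builds the whole loop needed to study
recovery of that information: a phantom generator, a forward imaging model,
trainable reconstruction networks and pixel-level evaluation.

Everything in the package is a pure function of a configuration and an
integer seed; per-sample child seeds are derived as `seed + index`, so any
dataset, model or report can be regenerated bit-for-bit.

## Phantom synthesis

Tumor-cell images are drawn from classic lattice-gradient (Perlin) noise:
pseudorandom unit gradients on an integer lattice, smoothstep-interpolated
and min-max normalized to [0, 1]. Pixels above the 0.5 threshold form the
binary tumor mask; the coherent field makes the foreground smooth connected
foci rather than speckle. Intensities are then drawn per pixel from two
Gaussian populations (signal on mask pixels, background elsewhere), clipped
at zero.

Parameters, defaults and rationale:

* `grid_period = 10` px, `octaves = 1`, `persistence = 0.5` — one octave at
  a 10 px lattice yields foci of roughly 5–15 px, the visual scale of cell
  clusters in chip-scale fluorescence images. More octaves add fine texture
  if wanted.
* `threshold = 0.5` — symmetric split of the normalized field; occupancy is
  approximately half the frame. Exposed for sensitivity studies. The
  moving-cluster generator uses a sparser threshold (0.70, config
  `dynamics_threshold`) so that an inserted cluster can occupy a site empty
  in all four layers — that keeps the total cell count constant along a
  trajectory, which is what makes cluster tracking a well-posed readout.
* `snr_range = (2, 10)`, `background_mean_range = (50, 150)` arbitrary
  units, `cv = 0.15` — a wide band of signal-to-background ratios and gains,
  standing in for the spread observed in real chip acquisitions. These are
  tuning knobs, not claims about any particular dataset.

The per-pixel Gaussian intensity model is the simplest two-moment model; it
reproduces means and variances but not photon-counting statistics
(mean-variance coupling), spatial intensity gradients within a focus, or
autofluorescence texture. Tests passing on these phantoms therefore
demonstrate the *method*, not performance on real tissue.

## Forward imaging model

The PSF family is an isotropic Gaussian with width linear in depth,

\[ \sigma(z) = \sigma_0 + s \cdot z, \qquad \sigma_0 = 0.5\,\text{px},\;
   s = 4\,\text{px/mm}, \]

truncated at 3 sigma and renormalized to unit sum. The defaults make a
1 mm-deep layer heavily blurred (sigma of 4.5 px on a 51 px frame) while a
surface layer is essentially sharp, which is the qualitative regime of a
lensless chip. A `disc` kind (defocus pillbox) and a `measured` kind
(nearest-depth lookup in a kernel bank read from TIFF calibration files) are
drop-in replacements — the package works in pixel units throughout, and
`pixel_pitch_um` (default 55) is used only for axis labeling.

Design choices worth stating:

* **Flux conservation.** Kernels sum to one, so depth attenuation emerges
  purely from spreading (plus losses over the frame edge). Whether a real
  chip shows additional per-depth intensity loss is a calibration question;
  a measured kernel bank can encode it.
* **Boundary handling** is zero padding: the scene outside the frame is dark
  tissue. Reflective or circular boundaries would invent fluorescence that
  is not there.
* **No scattering, absorption or sensor noise** is modeled; layers combine
  strictly linearly. This is the idealization under which the networks are
  trained and evaluated.

The dual-sensor geometry places sensor A at depth 0 and sensor B at
`separation_um` (default 1000) facing it, so a layer at depth z is imaged by
B with effective depth `separation - z`; the two effective depths sum to the
separation exactly. Convolution is carried out by FFT (`EBImage::filter2`);
the test suite checks it against a direct double-sum convolution at 1e-6
relative tolerance.

## Task datasets

* **Depth classification** — one phantom layer blurred at one of 20 depths,
  50 µm to 1.95 mm in 100 µm steps; class k is at `50 + 100k` µm. Train and
  test use disjoint seed streams.
* **Deblurring** — (blurred, sharp) pairs at continuous uniform depths in
  [0, 1 mm].
* **Two-layer, non-overlapping** — two layers at least 500 µm apart;
  overlapping cell regions are removed from both masks and refilled with
  background (`subtract_overlap()`), so each cell pixel belongs to exactly
  one layer. The label is a per-pixel map of normalized depth (`d/1000`,
  background 0).
* **Four-layer, overlapping** — four independent layers in [0, 1 mm], one
  per 250 µm bin with adjacent gaps of at least 200 µm (the bin structure
  and the gap constraint reconcile the two ways the sampling is naturally
  described; both are enforced and re-validated on every sample). Overlaps
  are kept. Labels are the four binary masks ordered by distance from
  sensor A — the sorted-layer convention, chosen over fixed depth bins
  because the detector's output planes then always carry comparable
  signal statistics.
* **Moving cluster** — a fixed four-layer background scene plus one
  connected Perlin focus that hops from layer 1 to layer 4 across four
  steps, emulating a cell cluster migrating from sensor A towards B. The
  cluster is inserted additively at a lateral site empty in all layers (see
  above); insertion rather than replacement keeps the background scene
  identical across steps, so step-to-step differences are exactly the
  cluster's plane change.

Training sizes default to 20,000 samples with 1,000 test samples and 100
trajectories; the `fast` profile (2,000 / 200 / 10, detector training
1,200) is the desk-scale configuration used by the test-suite and the
acceptance script so that every experiment fits comfortably on one CPU.

## Networks and training

No deep-learning framework is assumed: the package carries a compact seeded
engine (RcppArmadillo) with conv2d, transposed conv2d, fully connected,
residual-block, batch-norm, dropout and global-average-pooling layers,
ReLU/sigmoid/abs/log activations, and Adam on cross-entropy, MSE or
logit-BCE losses. Gradients of every layer type are verified against finite
differences in the test suite (on smooth configurations: ReLU kinks and
sigmoid saturation are subgradient questions, not backward-pass bugs).
Training is deterministic given the seed: initialization, batch order and
dropout masks all derive from it.

* **Depth classifier** — conv 9×9/stride 2 (16 ch), then three 3×3 stages
  (32, 64, 64), global average pooling, a 96-unit FC layer with dropout 0.5
  and a 20-way softmax. Two design points matter and were chosen on the
  scaled task: the network sees the view normalized *relative to its mean*
  (`v/mean(v) - 1`) rather than min-max scaled — flux-conserving blur leaves
  the mean untouched while shrinking spatial variance, so absolute contrast
  is the strongest physical depth cue and min-max scaling would discard it;
  and global average pooling replaces a wide flattening FC layer, removing
  the positional degrees of freedom that a small training set would
  otherwise memorize. `train_depth_classifier(n_members = k)` optionally
  averages an ensemble of independently initialized members.
* **Deblurring / depth map / detector** — the 6-layer encoder-decoder of
  the task family: three strided 3×3 convolutions, three transposed
  convolutions back to 51×51 (output padding restores the odd sizes), with
  1 output channel (identity output, MSE) for deblurring and the two-layer
  depth map, and 4 logistic output planes (logit-BCE) for the detector.
  Channel widths are (24, 48, 96) for deblurring and (16, 32, 64) for the
  detector — the smallest widths that pass the capacity checks and reach
  the desk-scale operating points; dense views are min-max normalized per
  view, which also makes detector outputs exactly invariant to gain and
  offset changes of the raw acquisition.
* **Residual detector** — a stride-1 residual trunk (first conv plus eight
  two-conv residual blocks, widths 8/16) followed by the 2-conv detection
  head. Stride 1 keeps the trunk at input resolution so the head can emit
  51×51 planes without an upsampling path. No pretrained weights are
  bundled; initialization is from scratch (He), which keeps the package
  self-contained.

Learning rate 1e-3 (3e-3 for the deblurring regression, whose MSE converges
slowly near its noise floor) with a step decay (×0.3 after two thirds of the
epochs, ×0.1 for the final twelfth), batch 32. Epochs per task in the fast
profile: 60 (depth), 20 (deblur), 12 (detector, depth map) — sized so each
training run completes in a few minutes on one CPU.

## Evaluation conventions

* Per-pixel error rate is the fraction of pixels whose thresholded
  prediction (at 0.5) disagrees with the binary truth; it equals
  1 − accuracy exactly.
* Sensitivity and specificity follow the pixel-level confusion definitions;
  planes without any true cell pixel are excluded from averaged sensitivity
  with a warning.
* Continuous outputs (deblurring, depth maps) are scored by mean normalized
  deviation: mean |pred − truth| divided by the dynamic range of the truth.
* Multi-sample reporting computes the metric per sample, then averages.
* ROC pools pixels across layers and samples, sweeps thresholds from high to
  low and integrates by the trapezoid rule; the suite cross-checks the AUC
  against the rank-statistic definition and against pROC.
* `reconstruct_3d()` places the four thresholded planes at their depths in a
  50 µm voxel grid between the two sensor markers and exports a CSV voxel
  list plus a TIFF stack; reading the CSV back reproduces the occupancy
  exactly.

## Numerical and degenerate cases

Zero-width PSFs return an identity kernel; constant views normalize to
zero; rejection sampling of the four-layer depths aborts after 1,000
attempts (the default constraints are feasible with large margin); the
moving-cluster generator retries scene and placement up to fixed bounds and
fails loudly rather than silently relaxing disjointness. ROC on
single-class truth raises a degenerate-curve error rather than returning an
arbitrary value.

## Known limitations

The phantom family and the linear, noise-free forward model are idealized;
no claim is made about scattering tissue, photon noise or real chip
calibration beyond what a measured kernel bank can express. Reported
operating points at the fast profile are tied to the stated training sizes;
accuracy at the 20,000-sample default profile is substantially higher but
takes hours on a single CPU. The residual detector mirrors the compound
architecture of the dynamics experiment but is trained from scratch;
with pretrained first-stage filters it would likely need fewer epochs.
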