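---
title: "Single-generator diatom classification by holographic phase imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-generator diatom classification by holographic phase imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
optical model, the reconstruction and autofocus procedures, the
wrap-preserving augmentation, the classifier protocol, and — just as
importantly — the numerical choices, the validity domains, and what the
synthetic test bed does and does not establish about real data.

## The recording model

A transmission off-axis holographic microscope interferes a tilted plane
reference wave with the object wave on the camera. Writing the object
wave as $O = |O|\,e^{i\psi_o}$ and the reference with carrier frequency
$f_R$ and phase offset $\varphi_R$, the recorded intensity is

$$H \;=\; |R+O|^2 \;=\; |R|^2 + |O|^2 +
  2|R||O|\cos\!\big(2\pi f_R (x+y) - \varphi_R + \psi_o\big).$$

`form_hologram()` evaluates this pointwise; the sign convention of the
reference phase is chosen so the cross term carries $+\psi_o$ (the
opposite choice reconstructs the conjugate object, an error the
forward–inverse tests would catch). Assumptions: scalar diffraction,
unit-amplitude reference, and a pure phase object — transmission 1
everywhere, all information in $\psi_o$. Real frustules also absorb;
that is deliberately not modeled, and the autofocus criterion below
depends on the pure-phase assumption.

The default optics are a 532 nm source, 5.5 µm pixels and a carrier of
$1/(4p)$ cycles/m on each axis ($p$ the pixel pitch). A quarter of the
sampling frequency per axis is the classic off-axis compromise: the +1
order, the −1 order and the DC autocorrelation stay separated, and the
carrier completes an integer number of cycles across any frame whose
side is divisible by 4, which makes the synthetic forward–inverse chain
exact rather than merely approximate. When a beam tilt angle is supplied
instead, the carrier magnitude is $\sin\vartheta/\lambda$ split equally
over both axes.

## Demodulation and propagation

`demodulate()` multiplies the intensity by the conjugate carrier wave and
applies a hard circular low-pass at the spectral origin. This is
algebraically the same operation as selecting a circular bandpass around
the +1 carrier peak and shifting it to baseband, but it remains exact for
carriers that do not sit on an integer Fourier bin. The default filter
radius is half the carrier magnitude — the largest radius that provably
cannot touch the DC peak while leaving headroom for the autocorrelation
skirt. The filter is the resolution bottleneck of the whole instrument
model: any spatial frequency of $e^{i\psi_o}$ beyond the radius is lost,
which bounds recoverable phase gradients at roughly
$2\pi \cdot 0.18$ rad/px with the default geometry. Everything
downstream inherits this band limit.

`propagate()` applies the angular spectrum transfer function
$\exp\!\big(i 2\pi\,\Delta z\sqrt{1/\lambda^2 - f_x^2 - f_y^2}\big)$,
the exact scalar-diffraction propagator. Evanescent components
($f_x^2+f_y^2 > 1/\lambda^2$) are zeroed — they decay within nanometres
physically, and keeping them would blow up for backward propagation. On
the propagating band the operator is unitary, so energy is conserved,
propagation distances compose additively, and a forward–backward round
trip restores the field to ~1e−10 relative error (both are tested as
properties).

FFT conventions: forward transform with negative exponent (R's
`stats::fft`), frequency grids in cycles/metre derived from the pixel
pitch, no `fftshift` in stored spectra. Coordinates are row-major with
pixel (1,1) at the top left, $x$ growing along columns and $y$ along
rows.

## Autofocus

For a pure phase object the reconstructed amplitude is flattest at best
focus, so focus is found by *minimizing* an amplitude-contrast metric
over propagation distance. The package uses the Tamura coefficient
$T = \sqrt{\sigma/\mu}$ of the amplitude image (population standard
deviation over mean) — the standard form in the digital-holography
autofocus literature; the metric is dimensionless and invariant to
amplitude rescaling.

`autofocus()` evaluates $T(|P_z u|)$ on a uniform coarse grid (default
21 points) and refines by successive step halving (default 3 levels):
each level evaluates the two midpoints flanking the running minimum at
half the previous step, so the final bracket half-width is
$(z_{max}-z_{min})/(n_{coarse}-1)/2^{levels}$. A minimum on the search
boundary warns rather than fails, since it usually means the object lies
outside the range. The scan history is kept and plotable
(`autoplot()` on the result).

**Validity domain.** Amplitude-contrast minimization is exact in the
weakly scattering regime, where the demodulation filter passes
essentially all of the object's spectral content. For compact objects
with peak phase near $3\pi$, the hard bandpass truncates the field; the
truncation residue adds amplitude structure whose minimum is displaced
from true focus by a fraction of the depth of field (~0.1 mm at the
default geometry, against a ~1 mm depth of field). That displacement is
irrelevant for refocused *classification* — the image at the found plane
is visually indistinguishable from the true focal plane — but it means
bracket-level focus *metrology* should only be claimed for smooth,
moderate-phase objects. Accordingly, the focus-recovery test suites use
spatially smooth objects with peak phase 0.5–1.5 rad and radii 40–60 px,
and the recovery claim (focus error within the final bracket width,
~19 µm, in ≥95% of draws) is made for that regime.

## The phantom slide

`make_phantom_slide()` emulates a commercial test slide: $n$ disjoint
pure-phase objects on a zero-phase background, one per class. Five
parametric families rotate across classes — elliptic with longitudinal
striae, pennate-like superellipse with transverse striae, centric with
radial arms, annular, and a ringed dome — with per-class texture
frequency, aspect ratio, arm count, orientation and peak phase drawn
deterministically from the class index and the slide seed. Defaults:
radii 22–38 px, peak phase $2.2\pi$–$3.2\pi$ (so wrapped phase images
genuinely wrap, the regime the augmentation's modulation operator
exists for), raised-cosine edge over 35% of the radius, and ≥12 px
clearance between objects.

Two renderer choices are deliberate. Striae are *additive* with fixed
sub-radian amplitude rather than multiplicative on the peak: texture
phase gradients then stay within the demodulation passband regardless of
the object's peak phase, mirroring real microscope images where the
optics resolve the frustule texture. And profiles taper smoothly to
zero, since a discontinuous phase step at the object edge is neither
physical nor recoverable through the bandpass.

Placement is rejection sampling of centres under a minimum-distance
constraint with a bounded number of attempts per object; failure raises
an error rather than silently overlapping objects.

**Wet fixtures.** `simulate_wet_object()` renders a *fresh instance* of a
class — same deterministic morphology parameters, new orientation and
±8% size jitter around the radius that class has on the training slide
(live specimens of a species share the fixed specimen's scale; letting
the size drift beyond the ±20% augmentation span would test
extrapolation, not the method) — then records it defocused (uniform in a
configurable range, default 0.5–2.5 mm), with additive Gaussian
intensity noise (default sd 0.02 on a ~0–4 intensity scale) and a
residual phase offset drawn from $[0,\pi]$. The offset enters physically
through the reference phase, so the demodulated field is globally
shifted — exactly the error the phase-bias augmentation models.

## Reconstruction-side compensation and segmentation

Before segmentation the pipeline removes the constant phase offset:
`compensate_offset()` takes the mode of the 256-bin phase histogram
(the flat background concentrates there) and refines it with a circular
mean over pixels within 0.3 rad of the mode. Constant-offset
compensation is the only aberration handling implemented; higher-order
aberration compensation is out of scope, and its residuals are precisely
what the bias augmentation teaches the classifier to tolerate.

`segment_slide()` thresholds the *absolute* wrapped phase with Otsu's
criterion (256-bin histogram, between-class variance maximized with
exact per-edge class statistics), closes the binary map with a small
disc (default diameter 5 px), fills interior holes, labels 8-connected
components, discards components under 100 px, and crops each survivor
with 8 px of zero-phase padding. Thresholding |phase| makes both
positive and wrap-negative object values bright against the zero
background. The closing and the filling are two faces of the same
wrapping phenomenon: wherever $\psi_o$ crosses a multiple of $2\pi$ the
wrapped map dips to zero, producing interior rings (holes — filled) and,
when a wrap contour crosses the entire object, open bands that split the
mask (bridged by the closing). The closing diameter must stay below the
smallest gap between distinct objects — hence the 12 px phantom
placement margin. Connectivity, minimum area, padding and closing are
package defaults, exposed as parameters, not values inherited from any
particular instrument.

Class identity: with ground truth available, segmented objects are
matched to true objects by greedy one-to-one nearest-centroid
assignment (tested to agree within 2 px on noise-free slides); without
ground truth, objects are numbered in reading order, the convention used
on physical test slides.

## Wrap-preserving augmentation

Each class's single segmented WQPI is the *generator* of its training
set. Three nested transformations expand it: anisotropic resize by
$(1+s_x, 1+s_y)$ with $s$ on a 21-point grid from −20% to +20% per axis
(2% steps — the only reading of "21 × 21" consistent with anisotropy),
rotation in 10° steps (36 angles), and a constant phase bias from 11
values evenly spaced on $[0,\pi]$. The lattice therefore has
$21 \cdot 21 \cdot 36 \cdot 11 = 174{,}636$ tuples per class. Evenly
spaced biases were chosen over random draws for reproducibility; a
random-draw mode exists behind a flag.

After *every* step the $2\pi$-modulation operator
$\psi \mapsto ((\psi+\pi) \bmod 2\pi) - \pi$ restores the $[-\pi,\pi)$
range (half-open; $\pi$ maps to $-\pi$). Interpolation acts on the
wrapped values directly; pixels straddling a wrap discontinuity produce
localized artifacts, which is intentional — the classifier must tolerate
exactly those artifacts at test time. An alternative complex-domain mode
(interpolate $e^{i\psi}$, take the argument) is available but off by
default. Transform order is fixed: resize → rotate → bias. Identity
parameters reproduce the generator bit-exactly (the resize and rotation
are skipped at identity, and re-wrapping already-wrapped values is not
numerically a no-op for values near zero).

Datasets are *planned* before they are materialized: `plan_dataset()`
samples, per class, a fixed number of tuples uniformly **without
replacement** (the natural choice when the sample is a small fraction of
the lattice) and returns a manifest tibble; images are realized lazily
(`realize_augmentation()`) or written to disk (`generate_dataset()`).
This keeps the full-scale arithmetic — 21,000 sampled per class,
stratified 80/20 split into exactly 16,800/4,200 — checkable in
milliseconds without creating a million images. The split rounds
per class and partitions the manifest exactly. The augmentation canvas
defaults to 256 × 256 (configurable); images are centre-placed on a
zero-phase background.

## The classifier and the ensemble

The training protocol is fixed: minibatch SGD with learning rate 0.001,
momentum 0.9 and weight decay 0.001 on cross-entropy loss; validation
loss computed each epoch; early stopping after 5 epochs without a new
validation-loss minimum, at most 200 epochs; and the checkpoint with the
minimum validation loss is the model retained. All randomness
(initialization, epoch shuffles) flows from one seed, so training is
bit-reproducible.

The built-in architectures are small one-hidden-layer tanh/softmax
networks (registry `mlp32`/`mlp64`/`mlp128` by hidden width). Inputs
are centre-cropped (default 224 px), bilinearly resampled to a small
square (default 32 px) and encoded as the **cosine and sine channels**
of the wrapped phase. The cos/sin pair is continuous across the wrap
seam — downsampling cannot manufacture spurious edges there — and a
residual phase bias acts on it as a smooth rotation rather than a
discontinuous gray-level shift; for networks this small, the encoding is
the difference between learning the task and underfitting it. The
conventional 8-bit gray mapping of $[-\pi,\pi)$ to 0–255 remains
available (`encoding = "gray"`) and is the on-disk export convention.

Predictions from several models are fused by max voting: per sample the
modal label wins; ties break by the highest mean confidence among tied
labels, then by the lowest class id — a fully deterministic rule (the
tie-break is the package's choice; the voting itself is verified against
brute-force mode computation). `select_ensemble()` retains models
strictly above an accuracy threshold (default 0.90) before fusion.
Confusion matrices are kept over the full trained class set and can be
projected onto a class subset; predictions escaping the subset collapse
into an explicit `other` column so counts are conserved.

## Orchestration, seeds and problem sizes

`run_config()` bundles every stage's parameters; its defaults are the
full-scale study conditions (50 classes, 2048 × 2048 sensor, the full
lattice, 21,000 images per class). One global seed fans out to stage
seeds by fixed offsets; reports contain no timestamps, so identical
configurations produce byte-identical reports.

The shipped test suite and the acceptance script run at desk scale,
chosen so the whole suite completes in minutes on one CPU while
exercising every stage at full fidelity: the 50-object slide is
reconstructed and segmented at 1024 × 1024; propagation and autofocus
properties use 256 × 256 fields; the end-to-end run trains three
independently seeded `mlp64` networks on 500 augmented images per class
for 5 classes (512 × 512 slide, 160 × 160 augmentation canvas) and
tests on 100 simulated wet objects.

## What the synthetic test bed does and does not show

The generator reproduces the *structure* of the problem: off-axis
carrier fringes, phase wrapping above $2\pi$, per-object defocus in a
volume, global phase offsets, additive intensity noise, disjoint objects
of distinct parametric morphologies, and the single-generator training
regime. Passing tests therefore demonstrate that the chain — formation,
demodulation, refocusing, segmentation, wrap-preserving augmentation,
protocol-faithful training, max-voting fusion — is internally correct
and that the single-generator strategy can recover held-out instances
under those distortions.

It does not show performance on real diatoms. Real frustules absorb as
well as shift phase; real recordings carry speckle, camera noise and
higher-order aberrations rather than clean Gaussian intensity noise and
constant offsets; real within-species variability is biological, not a
parametric jitter; and the five synthetic families are far better
separated than 50 morphologically similar species photographed through
real optics. The desk-scale networks are also not ImageNet-pretrained
convolutional families; plugging such models into the same manifests and
protocol is the intended path for real data, not a packaged capability.

## Known limitations

* Phase unwrapping is deliberately absent; the method operates on
  wrapped phase throughout.
* Aberration compensation beyond a constant offset is not implemented.
* Touching objects are not split (no watershed); the slide layout
  guarantees separation, and the segmentation closing assumes a minimum
  gap between objects.
* The Tamura autofocus is accurate to its final bracket only for
  weakly-scattering smooth objects (see above); for strong-phase compact
  objects it is accurate to a fraction of the depth of field.
* Training at the full 21,000-images-per-class scale is supported by the
  manifest machinery but is not exercised in the shipped tests.
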