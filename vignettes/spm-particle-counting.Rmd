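---
title: "Counting nanoparticles in surface plasmon microscopy images: model, data generation and classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nanoparticles in surface plasmon microscopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Surface plasmon microscopy (SPM) images nano-objects bound to a metal film
label-free: a surface plasmon (SP) wave propagating along the film is
scattered by each particle, and the camera records the interference between
the propagating wave and the scattered waves. A single particle therefore
does not appear as a spot but as a parabolic-tailed fringe pattern whose
tails extend over many micrometers. When several particles sit in one field
of view, their patterns overlap and counting them by eye — or by finding
intensity peaks in a reconstructed image — becomes unreliable, especially
under noise. `spmcount` implements the full computational pipeline for
training and evaluating an image classifier that predicts the number of
particles in an SPM image directly, using physics-simulated and composited
training data.

## Image formation model

The clean image is the squared modulus of a coherent sum

$$I(\mathbf r) \;=\; \Bigl|\, E_0\, e^{i k_{sp}\, \mathbf r\cdot \hat{\mathbf d}}
\;+\; \sum_j A_j\, \frac{e^{i\left(k_{sp}\rho_j + \varphi_j\right)}\,
e^{-\rho_j/L}}{\sqrt{\rho_j}} \,\Bigr|^2 ,
\qquad \rho_j = \max\bigl(\lVert \mathbf r - \mathbf r_j \rVert,\; \rho_{\min}\bigr),$$

where $k_{sp} = 2\pi/\lambda_{sp}$ is the SP wavenumber, $\hat{\mathbf d}$
the propagation direction, $E_0$ the background field amplitude, and each
particle $j$ contributes a decaying in-plane wave with amplitude $A_j$,
phase $\varphi_j$ and 1/e decay length $L$.

Two modelling choices deserve comment:

* **Scattered-wave form.** The scattered field of a small particle on the
  film is treated as an in-plane cylindrical wave with a $1/\sqrt\rho$
  geometric envelope and an exponential propagation loss $e^{-\rho/L}$.
  This is the simplest form that reproduces the characteristic parabolic
  fringes: the relative phase $k_{sp}(\rho - \mathbf r\cdot\hat{\mathbf d})$
  is constant on parabolas with focus at the particle, which the test suite
  verifies to $10^{-9}$ on pixels lying exactly on such a parabola. A full
  vectorial treatment (pupil functions, Fresnel stack of the metal film,
  leakage-radiation point spread functions) is out of scope.
* **Singularity clamp.** The envelope diverges at the particle position, so
  all distances are clamped at `min_distance` (default: one pixel pitch,
  never less than half a pixel). Inside the clamp disk the clamped distance
  is used in both the envelope and the propagating phase, making the field
  constant there.

### Default optical parameters

The study that motivates this package reports no numerical optics values, so
defaults were chosen once at plausible visible-light SPM scales and all
results are functions of them:

| parameter | default | unit | rationale |
|---|---|---|---|
| `sp_wavelength` | 0.6 | µm | visible-light SP spatial period |
| `decay_length` | 10 | µm | long tails spanning the field of view |
| `pixel_pitch` | 0.1 | µm | sub-fringe sampling (6 px per period) |
| `image_shape` | 64 × 64 | px | desk-scale simulation grid |
| `background_amplitude` | 1 | – | intensity normalized to the background |
| `min_distance` | `pixel_pitch` | µm | singularity clamp |
| amplitude range | [0.2, 1] | – | polydisperse scattering strengths |

Scenes place particles uniformly in a margin-inset rectangle (margin 4 px)
with i.i.d. uniform amplitudes and phases; `sample_scene()` is reproducible
from a single seed and scenes round-trip losslessly through JSON.

## Degradation pipeline

Real SPM images are blurred and noisy. The pipeline applies, in this order:

1. **Disk blur**: correlation with a radius-1 disk kernel whose entries are
   the overlap areas between the disk and each pixel square (computed by
   256× sub-pixel supersampling, normalized to sum exactly 1), under
   replicate boundary handling, so constant images are exactly invariant.
2. **Additive Gaussian noise at a target SNR (dB)**:
   $\sigma^2 = P_s / 10^{\mathrm{SNR}/10}$ with
   $P_s = \operatorname{var}(\text{clean image})$.

Two policies are deliberate and recorded in every dataset manifest:

* **Signal power is the variance of the clean image about its mean**, not
  its mean square. SPM images sit on a large flat background ($E_0^2$);
  defining SNR against mean-square signal would let the background inflate
  the SNR and make "15 dB" images look nearly clean. The variance definition
  matches the visual severity of the degraded examples the method is
  designed around. The flag `snr_signal_power` in the manifest records it.
* **Blur before noise**, so the stated SNR is exact with respect to the
  blurred signal; the test suite verifies the injected-noise variance
  against the blurred image and that the measured SNR of 100 independent
  realizations averages within ±0.1 dB of the target.

A corollary worth knowing: a blank scene (N = 0) is constant after
rendering, its variance is numerically zero, and the noise scale collapses
with it — blank images stay blank at every nominal SNR. This is inherent to
any per-image SNR definition and is why the classifier can recognize the
N = 0 class essentially perfectly at all noise levels.

## The hybrid dataset

Training data mixes three generation methods, mirroring the design in which
pure simulation is complemented with measured backgrounds and particle
crops:

* **Method 1 — pure simulation**: sampled scene → render → blur+noise.
  Default: 1000 images per class under each of seven conditions (no noise,
  30, 25, 20, 15, 8, 1 dB) = 7000.
* **Method 2 — simulated particles on a background**: the zero-mean
  interference term (`render` − $E_0^2$) is added to a background image,
  then degraded. Default 1000 per class, cycling the same noise grid. With
  a flat background this reduces bit-exactly to Method 1, which is tested.
* **Method 3 — patch compositing**: single-particle patches (rendered at
  30 dB and cropped around the particle) are pasted at random positions
  onto a background by adding `patch − border_mean(patch)`; overlapping
  pastes accumulate additively, consistent with the interference physics of
  the additive scattered-field term. Default 100 per class, no further
  degradation (the patches carry their own noise) — both switchable.

That yields 8100 images per class for 11 classes. Labels follow
`min(n, 10)`: classes 0–9 are exact counts and class 10 ("others") absorbs
every scene with more than nine particles; its generator draws counts
uniformly from 10–14 (configurable — the design only requires N > 9).

Backgrounds and patches are synthetic stand-ins with a documented
interface: `gen_background()` emulates the three dominant nuisance
structures of real SPM backgrounds — a planar illumination gradient
(non-uniform incident intensity), band-limited speckle with a configurable
autocorrelation length, and 1-D streaks (vibration-induced motion
artifacts). Real experimental crops can replace them without touching any
other module. What passing tests show, therefore, is that the pipeline is
correct and that the classifier learns the physics-simulated distribution;
they cannot show domain transfer to real microscope images, which requires
real backgrounds and patches in exactly these slots.

The manifest is a pure function of the configuration (including the master
seed): per-record seeds, background assignments and "others" counts are all
derived deterministically, so a rebuild is bit-identical and any single
record re-renders identically from the manifest alone. Images are written
as 224 × 224 PNGs (bilinear resize, per-image min–max 8-bit quantization,
grayscale replicated to three channels) with a CSV manifest and JSON config
sidecar. Images constant up to numerical ripple quantize to mid-gray 128.

## Classifier

Two architecture profiles share one training/inference code path:

* **`b0`** follows the EfficientNet-B0 topology: a 3×3 stem convolution,
  seven stages of mobile inverted bottleneck (MBConv) blocks alternating
  3×3 and 5×5 depthwise kernels with squeeze-excitation and batch
  normalization, and a 1×1 convolution + global average pooling + 11-way
  head — nine stages in total, for 224×224 3-channel input. With the
  canonical 1000-class head this topology counts ~5.3 M learnable
  parameters (checked in the tests); the 11-class head used here has
  ~4.0 M.
* **`desk`** is a reduced CNN (three 3×3 conv/ReLU/max-pool blocks of 8, 16
  and 32 channels, then a dense 11-way head; 64×64 single-channel input,
  ~28 k parameters). It exists because full B0 training on ~89 k images is
  a GPU-scale experiment; every experiment in this package runs under
  either profile unchanged.

The network layers (grouped/depthwise convolution via im2col + GEMM, batch
norm, squeeze-excitation, swish/ReLU, pooling, dense) are implemented in
the package with compiled kernels, and every layer's analytic gradient is
property-tested against central finite differences.

Training hyperparameters are not prescribed by the underlying study;
defaults are Adam (learning rate 10⁻³, cosine-decayed), batch 64, 10–12
epochs, cross-entropy loss, best-validation-epoch checkpointing, per-image
standardization to zero mean/unit variance after 8-bit quantization, no
augmentation and no pretraining. All are arguments. Training is
deterministic given the initialization and shuffling seeds.

## Evaluation

* `confusion_matrix()` — row-normalized 11 × 11 matrix with supports;
  per-class accuracy is its diagonal (`accuracy_by_class()`).
* `noise_sweep()` — fresh Method-1 test images per (class, condition) cell;
  per-condition accuracy-vs-count curves plus the mixed-condition curve.
* `peak_count_baseline()` — the non-learned reference: disk smoothing,
  median subtraction, threshold at 6 robust standard deviations (MAD), and
  greedy non-maximum suppression with a 5 px separation radius. Because
  scattering phases are uniform, particles appear as peaks *or* dips; the
  default detection image is therefore the absolute deviation from the
  median (`polarity = "abs"`), with `"bright"` available for positive-only
  detection. The full Fourier-space deconvolution reconstruction that
  inspired this baseline is intentionally not reproduced — it serves as
  context, not as a contribution.
* `bootstrap_accuracy_diff()` — seeded paired bootstrap (500 resamples) for
  all counter comparisons.
* Inference wall-time per image is reported by tooling around `predict()`
  but is hardware-dependent and not part of any acceptance check.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study at desk scale, a
package design choice so that every result is reproducible on a single CPU:
the reduced simulated dataset uses 500 images per class (72 per noise
condition × 7 conditions, totalling 504) on the 64 × 64 grid, an 8:1:1
stratified split (floor rounding to validation/test, remainder to train),
and 10 training epochs; the full-scale configuration (8100 per class,
224 × 224, B0 profile) is expressed by the same code and configuration
objects and is the intended cluster/GPU reproduction, including the
headline ~90% accuracy at N = 9, which is a full-scale quantity and is not
asserted at desk scale. Other numerical policies: argmax prediction breaks
ties toward the lower count; probabilities are computed with a
max-subtracted softmax; the quantizer treats ranges below 10⁻⁹ (relative)
as constant; batch-norm uses ε = 10⁻³ and momentum 0.1; Adam uses
β = (0.9, 0.999), ε = 10⁻⁸.

## Known limitations

* The scattered-wave model is scalar and two-dimensional; particle size
  enters only through the scattering amplitude, and near-field terms are
  absent.
* Synthetic backgrounds/patches emulate, but are not, experimental data;
  conclusions about real-microscope performance require dropping real crops
  into the documented interfaces.
* The desk profile trades accuracy for CPU feasibility; its absolute
  accuracies on crowded classes are well below what full-scale B0 training
  reaches, and only class structure, trends and the blank-scene accuracy
  are asserted at desk scale.
* Per-image SNR is undefined for blank scenes (see above); such images are
  effectively noise-free at every nominal SNR.
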