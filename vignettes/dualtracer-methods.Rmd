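---
title: "Simulating and directly reconstructing simultaneous dual-tracer dynamic PET"
author: "dualtracer package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and directly reconstructing simultaneous dual-tracer dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Positron emission tomography measures the distribution of a radiolabelled
tracer through coincident 511-keV photon pairs. When two tracers are
injected simultaneously, every detected event looks the same: the scanner
records the *sum* of the two tracers' projections, and any separation into
single-tracer images must exploit the tracers' different kinetics —
different plasma input functions, different exchange rates with tissue
compartments, possibly different half-lives.

This package implements a complete, self-contained 2D workflow for
studying that separation problem:

1. a **simulator** that produces dual-tracer dynamic sinograms together
   with matched single-tracer labels, and
2. a **multi-task convolutional network** that maps the dual-tracer
   dynamic sinogram directly to the two single-tracer dynamic image
   sequences, without an intermediate conventional reconstruction.

## The imaging model

A single-tracer acquisition is modelled as \(y(t) = G\,x(t) + n(t)\),
where \(x(t)\) is the activity image at frame time \(t\), \(G\) the
system matrix, and \(n(t)\) noise. The dual-tracer measurement is

\[
y^{I+II}(t) \;=\; G\,[x^{I}(t) + x^{II}(t)] \;+\; n^{I}(t) + n^{II}(t),
\]

i.e. the element-wise sum of two single-tracer sinograms
(`combineTracers()`). The direct-reconstruction task is to learn
\([\hat X^{I}, \hat X^{II}] = h_\theta(Y^{I+II})\) for dynamic sequences
\(Y = [y(t_1), \dots, y(t_F)]\).

### System matrix

`buildSystemMatrix()` constructs \(G\) by strip integrals on a
parallel-beam geometry: entry \((i, j)\) is the intersection area of
detector strip \(i\) with square pixel \(j\) divided by the strip width —
the strip-averaged intersection length in mm, computed in closed form
from the trapezoidal projection profile of a square. Defaults are 128
radial bins and 160 angles uniform over \([0^\circ, 180^\circ)\), with the
bins spanning the image-diagonal field of view so every pixel is seen at
every angle. Attenuation, scatter and detector-efficiency variations are
deliberately not modelled. The matrix is deterministic, sparse, and its
adjoint is exact by construction (`forwardProject()` / `backProject()`).

### Noise

`addNoise()` scales each frame so the expected true counts equal
`countLevel * (1 - randomsFraction)`, adds a spatially uniform randoms
background contributing `randomsFraction` (default 20%) of total expected
counts, Poisson-samples the sum, and returns the result on the original
intensity scale. Randoms are *not* subtracted afterwards. The count level
(default 5e5 per frame; 2e5 in the desk profile) is a modelling choice —
published experiments rarely state it — and nothing downstream depends on
its exact value. We interpret "a 20% randoms fraction" as a fraction of
total expected counts entering the Poisson sampler; a variance-scaling
interpretation would be an alternative reading.

## Kinetics

Single-tracer images are generated from the two-tissue compartment model

\[
\frac{dC_1}{dt} = K_1 C_P(t) - (k_2 + k_3) C_1 + k_4 C_2,\qquad
\frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,\qquad C_T = C_1 + C_2,
\]

with \(K_1\) in mL·min⁻¹·mL⁻¹ and \(k_2, k_3, k_4\) in min⁻¹.
`solve2TCM()` uses the closed-form biexponential impulse response
convolved exactly against a piecewise-linear plasma input on a 1-s grid;
the package's tests verify agreement with adaptive ODE integration
(deSolve's lsoda) to well below 1e-3 relative error over randomized
physiological parameter sweeps. Near-repeated eigenvalues (only possible
when \(k_3 = 0\) and \(k_2 = k_4\)) are handled by an infinitesimal nudge
of \(k_2\), far below the solver's verified tolerance.

Plasma inputs use a Feng-type multi-exponential bolus for all three
built-in tracers (FDG, FMZ, acetate), \(C_P(0) = 0\), decaying toward 0
at late times. The shipped coefficient and per-ROI kinetic tables
(`inst/extdata/tracer_defaults.yaml`) are documented stand-ins on the
scale of published human values — the literature values behind specific
studies are cited rather than printed in most papers — and everything is
overridable through configuration. No analysis in this package depends on
the exact defaults.

Frame values are *window averages* \(\int_{\text{frame}} C(t)\,dt /
\Delta t\) on the 1-s grid rather than point samples at the mid-frame
time: that is how a scanner accumulates counts, and it removes the
early-frame bias of point sampling (for a TAC linear in \(t\) the two
coincide exactly, which the tests exploit). Physical decay
\(e^{-\ln 2\, t / T_{1/2}}\) is applied to tissue activity before frame
averaging by default, since half-life differences are one of the
kinetic signatures separating tracer pairs such as FDG (F-18, 109.8 min)
and FMZ (C-11, 20.4 min); it can be disabled (`decay = FALSE`).

Individual variability is modelled by Gaussian randomization
(`sampleParameters()`): each kinetic and input-function parameter is
drawn with standard deviation `cv * mean`. Non-positive draws are
redrawn, not clipped — clipping would put a point mass at zero and bias
the realized cv.

## Phantoms

`makePhantom()` draws 2–5 region-of-interest phantoms — a head-like
outer boundary containing nested/overlapping ellipses and annuli — as a
stand-in for anatomical brain slices. Shapes are drawn largest-first and
later ROIs overwrite earlier ones, so the label map is always an exact
partition \(\{0, \dots, R\}\); candidates are redrawn (deterministically
under the seed) until every ROI has at least 4 pixels. Pixel geometry
defaults to 2.2 × 2.2 mm in-plane with 1.4 mm slice thickness. No attempt
is made to match any specific anatomical atlas; what matters downstream
is the ROI-wise kinetic structure, not anatomical realism.

## Labels: frame-wise OSEM

Training labels are reconstructed from each *noisy single-tracer*
sinogram by ordered-subsets expectation maximization (`osem()`, default
6 iterations × 5 subsets) with round-robin angle subsets processed in a
fixed order, a uniform positive initialization, guarded zero ratios, and
pixels of zero subset sensitivity frozen at zero. No corrections,
normalization or post-filtering. The EM fixed point (consistent data,
positive truth), monotone Poisson log-likelihood (one subset), and
sub-1% noiseless residual after 200 iterations are all covered by tests.

The choice of OSEM initialization and subset ordering is not critical:
the fixed-point and convergence properties hold for any positive
initialization, and the defaults are stated above for reproducibility.

## The multi-task network

`buildNetwork()` constructs a fully convolutional 3D encoder–decoder
(`frames × bins × angles` in, two `frames × H × W` sequences out):

* **encoder** (shared): three blocks of [3×3×3 conv, stride 1] →
  [3×3×3 conv, stride 2], channels 16, 32, 64, then a stride-1
  convolution to 128 bottleneck channels;
* **decoders** (two, structurally identical, independent weights): three
  blocks of [3×3×3 deconv, stride 2] → [3×3×3 conv, stride 1], channels
  64, 32, 16, then a 1×1×1 convolution to one channel.

Batch normalization and ReLU follow every (de)convolution except the
final 1×1×1 layer. Because activities are nonnegative, a clamp at zero
is applied to the outputs at inference (`finalClamp`, on by default).
The clamp deliberately lives *outside* the training graph: a ReLU as
the final training activation leaves roughly half of the output units
dead at initialization — the classic dead-ReLU pathology, which stalls
small-data optimization on a long plateau. Training on the raw
final-layer outputs and clamping only reconstructed images avoids this
without changing what the model ultimately emits.

Two shape problems need explicit policy decisions:

* **Angle axis vs image width.** A 160-angle sinogram must become a
  128-wide image through symmetric down/up-sampling. The default policy
  linearly resamples the angle axis to the image width before the
  encoder, so encoder and decoder operate on congruent grids. The
  alternative `"crop"` policy keeps the angle axis through the network
  and centrally crops the decoder output.
* **Odd sizes under stride 2.** The encoder records each block's input
  size per axis and the matching decoder deconvolution targets exactly
  that size (the transposed convolution is the exact adjoint of the
  corresponding strided convolution), so 18 → 9 → 5 → 3 → 5 → 9 → 18
  round-trips losslessly. Frame counts below 4 cannot survive three
  halvings and are rejected.

All convolution machinery (im2col/col2im with BLAS gemm, transposed
convolutions as exact adjoints, batch-norm, ReLU, Adam) is implemented
in the package with explicit forward and backward passes; every layer's
analytic gradient is verified against finite differences in the tests.
Weight initialization is a seeded fan-in ("He") scheme.

## Loss

The per-frame loss combines MSE with a structural-similarity term,

\[
L(\hat x, x) = \alpha\,\mathrm{MSE}(\hat x, x)
  - \beta \ln \frac{1 + \mathrm{SSIM}(\hat x, x)}{2},
\]

summed over the two tracers and averaged over frames. SSIM inside the
loss uses an 11×11 Gaussian window (σ = 1.5), stability constants
\((0.01 L)^2\) and \((0.03 L)^2\) with dynamic range \(L = 1\) on the
normalized label scale, and border-renormalized windows (so small frames
are handled without padding artifacts). Simulation defaults are
\(\alpha = 100\), \(\beta = 1\); the animal-study preset
(`animalConfig()`) switches to \(\alpha = 1\), \(\beta = 0.01\), weight
decay 0.01, learning rate 1e-4 and a 1e6 label scale.

## Metrics

`evaluatePair()` reports MSE, MS-SSIM and PSNR frame-wise plus their
unweighted frame average. MS-SSIM uses 5 scales with the standard
exponents (0.0448, 0.2856, 0.3001, 0.2363, 0.1333), dyadic 2×2
average-pool downsampling, the luminance term at the coarsest scale
only, and weights renormalized when fewer scales fit the image (a level
needs at least 8 pixels per side; an explicit over-deep request errors
with guidance). PSNR takes \(x_{\max}\) from the reference frame, and
identical images yield `Inf` with a warning rather than a silent number.
The package's MS-SSIM was cross-checked against an independent
NumPy/SciPy implementation of the same conventions to 1e-6; the frozen
reference values live in the test suite.

Metrics are computed against the OSEM labels by default — the quantity
the network was trained toward; evaluating against the noise-free truth
instead is a one-argument switch in `evaluatePair()` callers. Which
reference a given published table used is generally ambiguous; reporting
against labels is the conservative reading.

## Experiment pipeline

`buildDataset()` simulates every (phantom × parameter set) group:
per-tracer noise-free images → forward projection → per-tracer noise →
summed dual-tracer input sinogram; per-tracer OSEM labels. Groups are
split 8:1:1 (train/validation/test) at the group level with
`round(ratio * N)` test/validation sizes and the remainder training.
`normalizeDataset()` standardizes inputs by the global mean/sd of the
*training* inputs only and divides labels by a constant; normalization
statistics and model selection (lowest validation loss) depend only on
the train/validation partitions, so there is no test-set leakage —
asserted in tests by recomputing the statistics by hand.

Every stage derives a child seed from the master seed, so the full
pipeline is reproducible bit for bit: rebuilding a dataset reproduces
identical files, and retraining reproduces the epoch-1 loss exactly.

### Problem sizes

Two profiles ship with the package. The **full-scale profile**
(`experimentConfig()` defaults) — 40 phantoms × 30 parameter sets = 1200
groups of 18-frame 128×128 images and 128×160 sinograms, 100 epochs —
matches the full experimental design and is practical on GPU-class
resources or long CPU runs. The **desk profile** (`deskConfig()`) — 32×32
phantoms, 32 bins × 40 angles, a 6-frame 30-minute protocol, 4 phantoms
× 5 parameter sets = 20 groups, 20 epochs — is the configuration used by
the test suite and the acceptance script; it exercises every stage of
the pipeline end to end with the same code paths at sizes a single CPU
handles in minutes.

The desk protocol compresses the *frame count* (6 instead of 18) but
keeps the full 30-minute scan duration of dual C-11 imaging: the
kinetic divergence between an early-peaking, washing-out tracer (FMZ)
and an accumulating one (acetate) develops over tens of minutes, and a
shortened scan would remove the very signal that makes separation
learnable.

Desk-profile training hyperparameters differ from the full-scale
defaults in two documented ways. With only 16 training groups, an epoch
at batch size 4 is just 4 gradient steps (against 240 at full scale),
so the desk profile uses batch size 1 (16 steps per epoch) and a larger
learning rate (1e-3) to extract comparable progress from far fewer
updates. And the desk label-scale constant is 64 rather than 255: the
constant's role is to bring labels onto a \([0, 1]\)-ish scale where
the SSIM dynamic-range convention \(L = 1\) applies; desk-profile
activities top out well below 255, where dividing by 255 would leave
labels (and MSE gradients) several times too small.

### What the desk profile does and does not show

The synthetic data reproduce the structural features that make
dual-tracer separation hard and learnable: shared detector geometry,
summed indistinguishable projections, tracer-specific kinetics and input
functions, per-tracer Poisson noise, OSEM label texture. They do not
emulate attenuation, scatter, randoms structure, detector blur,
inter-frame motion, or anatomical realism — so passing desk-scale tests
demonstrates that the implementation is correct and that the multi-task
network extracts tracer identity from kinetics at small scale, not that
the trained desk model transfers to real scanner data.

## Numerical choices and degenerate inputs

* Strip/pixel intersection areas use the closed-form trapezoid CDF;
  axis-aligned angles take a rectangular special case (guarding a 0/0).
* OSEM guards \( (Gx)_i = 0 \) bins (ratio contribution 0, never NaN)
  and freezes zero-sensitivity pixels; an all-zero sinogram returns a
  zero image with a warning.
* `addNoise()` on an all-zero frame returns zeros (scaling undefined)
  unless a randoms background is requested.
* PSNR on identical images is `Inf` with a warning; a nonpositive
  reference maximum is an error.
* SSIM windows are renormalized at borders; MS-SSIM level means are
  clamped at 0 before exponentiation.
* Gaussian parameter draws at mean 0 stay exactly 0 (cv of nothing is
  nothing); positive means are redrawn until positive.

## Known limitations

* 2D only; no attenuation/scatter/efficiency modelling, no listmode or
  time-of-flight data, by design.
* The desk-scale network, trained for 20 epochs on 16 groups, learns a
  coarse separation — enough to beat the uninformed split-half baseline,
  far from the quality a 1200-group, 100-epoch training run attains.
* The compiled kernels are single-threaded per BLAS call; full-scale
  training is possible but slow on one CPU.
* Kinetic and input-function default tables are synthetic stand-ins, as
  documented above.
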