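---
title: "Multi-orientation MRI super-resolution with an unsupervised transformer prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-orientation MRI super-resolution with an unsupervised transformer prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

A single MRI acquisition trades off spatial resolution, signal-to-noise ratio
(SNR) and scan time. Acquiring a stack with high in-plane resolution but thick
slices is fast and has high SNR, at the cost of through-plane resolution.
`srmri` reconstructs an isotropic high-resolution (HR) volume $x$ from two or
three such thick-slice stacks $y_i$ acquired in different slice-select
orientations (e.g. axial + coronal), so that each stack contributes
high-frequency information along a different axis.

The acquisition of stack $i$ is modelled as

$$y_i = (b_i * (m_i \circ x))\downarrow_i + \; e,$$

where $m_i$ is a rigid (6-DOF) head-pose transform, $b_i$ a 1-D Gaussian
slice-profile blur along the slice-select axis whose FWHM equals the slice
thickness, $\downarrow_i$ decimation along that axis by the integer factor
(slice thickness / in-plane spacing), and $e$ additive Gaussian noise. The
decimation is performed in the frequency domain: a 1-D FFT along the slice
axis, retention of the central $1/f$ frequency band, and an inverse FFT on the
coarse grid, scaled so constants are preserved.

Two reconstruction routes are provided:

* **TV baseline** (`tv_reconstruct()`): minimizes
  $\sum_i \|y_i - A_i x\|_2^2 + \lambda\, \mathrm{TV}_\varepsilon(x)$ by
  monotone gradient descent with backtracking, where
  $\mathrm{TV}_\varepsilon(x) = \sum_v \sqrt{\|\nabla x(v)\|^2 + \varepsilon^2}$
  is smoothed isotropic total variation and $A_i$ the noise-free forward
  operator.
* **Unsupervised transformer reconstruction** (`dip_train()`): the package's
  core. A 3-D vision transformer $T_\theta$ is trained per subject — with no
  external training data — by minimizing the data-consistency loss
  $\sum_i \|y_i - (b_i * (m_i \circ T_\theta(z)))\downarrow_i\|_2^2$
  over the weights $\theta$ with Adam, where $z$ is the TV combination of the
  stacks resampled onto the HR lattice. The network parameterization acts as a
  deep image prior: no explicit regularizer is used, and the reconstruction is
  $x = T_\theta(z)$ after a fixed number of iterations.

## Network architecture

The encoder tokenizes the input volume into cubic patches of `patch_size`
voxels (default 16, i.e. $16^3$ voxels per token), projects each patch
linearly to an embedding of width `embed_dim` (default 768), and adds a
learnable position embedding. A stack of `num_blocks` (default 12) pre-norm
transformer blocks follows, each with `num_heads` (12) self-attention heads
and a GELU MLP of width `mlp_dim` (3072). Hidden states at the configured
`skip_taps` (default blocks 3/6/9/12) are projected to volumetric feature
maps on the token grid and fused into a cascade of $2\times$
transposed-convolution stages up to full resolution — the UNETR-style decoder
family. A full-resolution shallow skip feeds the input volume itself into the
last decoder stage through a $1{\times}1{\times}1$ convolution, and the head
is a $1{\times}1{\times}1$ convolution followed by a sigmoid, so the output
matches the input shape with intensities in $(0,1)$.

Design choices the source architecture leaves open, and how they were fixed:

* **Decoder widths and skip wiring**: the deepest tap starts the decoder at
  `decoder_channels` (32) channels, halving per stage with a floor of 8;
  remaining taps are merged additively after successive stages (deepest
  first). Patch sizes must be powers of two because each decoder stage
  doubles resolution; the supported sweep values 8/16/32 all are.
* **Initialization**: truncated-normal weights (sd 0.02), seeded; the
  skip/head pair is initialized so that the network output at iteration 0 is
  approximately `sigmoid(4 z - 2)`, i.e. the input passed through the
  sigmoid near-identically, with the transformer and decoder branches
  starting near zero and learning corrections. This removes several hundred
  iterations that would otherwise be spent re-deriving the input.
* **Input conditioning**: the sigmoid output requires a $[0,1]$ target
  scale. The TV combination that forms the network input is run with a
  deliberately strong weight ($\lambda = 0.1$, ten times the TV baseline's
  default) — the combination only conditions the input, and a smoother input
  slows the uptake of observation noise during training — then clamped to
  its 0.1/99.9 intensity percentiles (band-limitation ringing and noise
  spikes otherwise dominate the min/max) and min-max normalized; the
  recorded range denormalizes the output exactly.
* **Whole-volume training**: every iteration uses the full volume (no patch
  sampling), so the only randomness is the seeded initialization and training
  is bitwise reproducible.
* **No early stopping**: a fixed iteration count is used. The full-scale
  default is 4000 iterations at a constant learning rate of 0.01; the
  desk-scale reduced preset (`recon_config_reduced()`: 4 blocks, embedding
  96, 6 heads, MLP 192, patch 8) uses 300 iterations at 0.003 with a linear
  decay to a tenth — at this scale a constant 0.01 oscillates, and, as is
  typical for deep-image-prior training, very long schedules eventually fit
  observation noise, so the preset stops (and anneals) while the implicit
  prior still dominates.

## Forward model: numerical choices

* Operations compose in the model's order: transform, blur, decimate, then
  noise; with noise off the composite operator is linear, and its exact
  adjoint (transposed sparse warp, transposed banded blur matrix, analytic
  adjoint of the band-retention chain) drives both the TV solver and network
  training.
* The slice-profile Gaussian has $\sigma = \text{thickness}/(2\sqrt{2\ln 2})$
  mm on the HR lattice, truncated at $\pm4\sigma$ (odd length, renormalized).
  Spatial blurring uses mirror boundary handling to avoid the wrap-around
  ghosting a circular implementation would produce.
* Band retention keeps frequencies $k \in \{-(M/2-1), \dots, M/2\}$ for even
  output length $M$ (the positive Nyquist bin is kept at the tie); constants
  are preserved exactly. Axis extents not divisible by the factor are
  zero-padded symmetrically before the FFT and the padding is recorded.
* Non-integer thickness/in-plane ratios are rejected rather than rounded —
  every protocol the package models (1/1.5/2/2.5/3 mm at 0.5 mm in-plane,
  4 mm at 1 mm) is integer.
* Noise is zero-mean Gaussian with $\sigma$ a stated fraction (10% in the
  simulation protocol) of each stack's own maximum intensity.

## Registration

Stacks are aligned by maximizing mutual information (dense joint histogram,
32 bins by default) under a rigid transform, optimized with Powell's
direction-set method (Brent line searches; deterministic) over a
coarse-to-fine lattice schedule, with cubic B-spline interpolation (standard
recursive prefilter) during resampling. The first-listed stack defines the
reference frame; a simulated study can bypass registration entirely and use
its known ground-truth poses, which isolates reconstruction behaviour from
registration error. MI evaluations at fine levels subsample the lattice
deterministically (at most `max_voxels` samples) to bound runtime.

## TV solver choices

Smoothed isotropic TV with $\varepsilon = 10^{-3}$; gradient descent with
backtracking (step halving on any objective increase, mild regrowth after
acceptance), so the objective trace is non-increasing by construction. The
step is initialized at $1/L$ with $L$ estimated by deterministic power
iteration on the normal operator. `lambda_tv` is stated for unit-normalized
intensities (default $10^{-2}$) and rescaled internally by the stacks'
intensity range, since the data term is quadratic and the TV term linear in
intensity scale. Initialization is the adjoint back-projection average of the
stacks (each $f_i A_i^T y_i$, averaged). With `lambda_tv = 0` and a
row-space initialization, gradient descent converges to the minimum-norm
least-squares solution — the three-orientation operator has a genuine null
space (k-space corners attenuated along every axis), which is what makes the
prior necessary in the first place.

## Quality metrics

* **SSIM**: Gaussian window, $\sigma = 1.5$ voxels (radius
  $\mathrm{round}(3.5\sigma)$, edge-replicating padding), $K_1 = 0.01$,
  $K_2 = 0.03$, dynamic range from the reference, mean over the
  window-interior region. Verified to $10^{-6}$ against an independent
  reference implementation on frozen fixtures.
* **NMI**: $(H(x)+H(\mathrm{ref}))/H(x,\mathrm{ref})$ from a joint histogram
  (256 bins per image over each image's own range): 2 for identical images,
  $\to 1$ for independent ones.
* **JSD**: Jensen-Shannon divergence in bits between marginal intensity
  histograms over the shared range, using the standard bounded form
  $\tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)$, $m = (p+q)/2$ — symmetric, in
  $[0,1]$, zero iff the histograms agree. (The printed divergence formula in
  the source publication evaluates to $-2$ for $p=q$; the reported value
  ranges there are consistent with the standard convention, so the printed
  form is treated as a typo and the standard form implemented.)
* **Sharpness (AES)**: computed in 2-D slice-wise (the underlying measure is
  2-D; axis configurable): a Canny mask selects edge pixels, the Prewitt
  gradient is evaluated there, and the per-slice mean of the squared gradient
  norm is averaged over slices with edges. The squared-norm exponent follows
  the printed definition; a `power = "magnitude"` switch provides the
  gradient-magnitude variant common in the sharpness literature — relative
  comparisons, the only use made of AES here, are unaffected by this
  monotone transform. Normalized sharpness is the ratio against a reference
  image. Canny thresholds: high = Otsu of the non-maximum-suppressed
  gradient magnitudes, low = 0.4 high.
* **SNR / CNR**: $s/\sigma$ and $|s_{GM}-s_{WM}|/\sigma$ with $s$ the
  count-weighted gray+white mean and $\sigma$ the background standard
  deviation. The bundled `segment_simple()` (Otsu + largest-component head
  mask + 3-class k-means with deterministic quantile-initialized centers) is
  a stand-in whose only purpose is feeding these two numbers; it is not a
  morphometric tool.

## The synthetic phantom

`make_phantom()` builds a brain-like label image: nested ellipsoidal shells
(background, peripheral CSF, cortical gray-matter band, white-matter core,
ventricular CSF) whose radii are modulated by seeded low-frequency cosine
modes for lobular variation. Intensities are exactly the specified tissue
means (defaults, T2-like: CSF 200, GM 120, WM 80, background 0), so
label-conditional statistics are known in closed form. `simulate_study()`
degrades it through the forward model for every requested
thickness x plane combination — the full simulation protocol is thicknesses
$\{1, 1.5, 2, 2.5, 3\}$ mm in three orthogonal planes with 10% noise; the
clinical protocol is two stacks (axial + coronal) at factor 4.

A scale caveat worth stating explicitly: the advantage of the transformer
route over the TV baseline is a property of sufficiently ill-posed problems.
On the $64^3$ desk benchmark at upscale factors 2–4 the transformer
reconstruction dominates clearly; on very small grids ($32^3$) with the same
protocol the TV baseline is already near-optimal and the ordering can
invert. Conclusions about the method should be drawn at (or above) the desk
benchmark scale.

What the phantom does **not** emulate: cortical folding, partial-volume
mixtures, intensity nonuniformity (bias fields), Rician noise statistics, or
motion within a stack. Passing tests on this phantom therefore demonstrate
the correctness of the operators and the relative behaviour of the
reconstruction routes under the modelled degradation, not clinical image
quality.

## Problem sizes used in tests

The test suite and the acceptance script run at desk scale, chosen so the
full pipeline exercises every component in minutes: a $64^3$ phantom at a
nominal 0.5 mm (the clinical two-stack factor-4 protocol), $32^3$ studies for
smoke tests, $\le 16^3$ grids wherever a dense-matrix oracle is compared
against the matrix-free operators, and the reduced network preset for
training runs. The full-scale configuration (patch 16, embedding 768, 12
blocks, 4000 iterations) is the package default for real data.

## Known limitations

* Training the full-scale network on CPU in R is orders of magnitude slower
  than the GPU setting the method was designed for; the package is honest
  about this by providing the reduced preset for experimentation and testing.
* The stand-in segmenter assumes a brain-like three-tissue histogram with
  background near zero; it is not robust to bias fields.
* Slice-to-volume motion within a stack and deformable alignment are out of
  scope; registration is rigid and between-stack only.
* The set-valued network input of the problem statement (all stacks as
  separate channels) is realized, following the method's own pipeline
  description, as the single TV-combined volume; a multi-channel variant is
  left unimplemented.
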