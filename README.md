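# srmri — multi-orientation MRI super-resolution with an unsupervised transformer prior

`srmri` reconstructs an isotropic high-resolution 3-D MRI volume from two or
three fast, thick-slice 2-D acquisitions taken in different slice-select
orientations (for example a 2-minute axial and a 2-minute coronal T2 TSE
stack at 0.5 mm in-plane / 2 mm slices). It is aimed at researchers in MRI
reconstruction and quantitative neuroimaging who want a complete, inspectable
implementation of the forward acquisition model, a classical
total-variation (TV) baseline, and a per-subject *unsupervised* transformer
reconstruction — trained on nothing but the subject's own low-resolution
stacks — together with the image-quality metrics used to compare them.

## The model

Each low-resolution stack is modelled as

```
y_i = (b_i * (m_i ∘ x)) ↓_i  +  e ,        i = 1..N
```

with `m_i` a rigid head pose, `b_i` a 1-D Gaussian slice profile along the
slice-select axis (FWHM = slice thickness), `↓_i` frequency-domain decimation
by the integer factor slice-thickness / in-plane-spacing, and `e` Gaussian
noise. Two solvers invert the model:

* `tv_reconstruct()` — minimizes `Σ‖y_i − A_i x‖² + λ·TV_ε(x)` by monotone
  gradient descent (the baseline, and the generator of the network input);
* `dip_train()` — the core method: a 3-D vision transformer `T_θ`
  (patch tokenization, learnable position embedding, pre-norm multi-head
  self-attention blocks, a deconvolutional decoder fed by skip connections,
  a 1×1×1 convolution + sigmoid head) is trained with Adam to minimize the
  data-consistency loss `Σ‖y_i − (b_i * (m_i ∘ T_θ(z)))↓_i‖²`, where `z` is
  the TV combination of the stacks. The network parameterization acts as a
  deep image prior — no reference images, no pretraining, no external data —
  and the reconstruction is `x = T_θ(z)`.

Rigid alignment of the stacks (`register_rigid()`, `register_group()`) uses
mutual information with Powell's optimizer and cubic B-spline interpolation.
The metric suite implements SSIM, normalized mutual information (NMI),
Jensen–Shannon divergence (JSD), average edge strength (AES, Canny +
Prewitt), and tissue-based SNR/CNR with a bundled stand-in segmenter. A
procedural brain phantom (`make_phantom()`, `simulate_study()`) reproduces
the whole simulation protocol so every component is testable without
external data. Everything — including the transformer, its backpropagation
and the Adam loop — is implemented in R on BLAS primitives.

## Worked example

Simulate the two-stack clinical protocol at desk scale (64³ phantom at a
nominal 0.5 mm, axial + coronal stacks with 2 mm slices, 10% noise), then
reconstruct with both routes and compare:

```r
library(srmri)

ph    <- make_phantom(phantom_spec(seed = 1))
study <- simulate_study(ph$volume, ph$masks, thicknesses = 2,
                        planes = c("axial", "coronal"),
                        sigma_fraction = 0.1, seed = 2)
stacks <- lapply(study$stacks, `[[`, "volume")
geoms  <- lapply(study$stacks, `[[`, "geom")

tv  <- tv_reconstruct(stacks, geoms)
sr  <- dip_train(stacks, geoms, cfg = recon_config_reduced(seed = 1))

seg_tv <- segment_simple(tv$volume, "T2")
seg_sr <- segment_simple(sr$volume, "T2")
cat(sprintf("SSIM  tv %.4f  transformer %.4f\n",
            ssim_volume(tv$volume, ph$volume), ssim_volume(sr$volume, ph$volume)))
cat(sprintf("SNR   tv %.3f  transformer %.3f\n",
            snr(tv$volume, seg_tv), snr(sr$volume, seg_sr)))
cat(sprintf("CNR   tv %.3f  transformer %.3f\n",
            cnr(tv$volume, seg_tv), cnr(sr$volume, seg_sr)))
```

Output (about 9 minutes on one CPU; bitwise reproducible for fixed seeds):

```
SSIM  tv 0.4704  transformer 0.6356
SNR   tv 5.274  transformer 11.795
CNR   tv 2.037  transformer 4.621
```

The transformer reconstruction recovers more structure (SSIM), suppresses
more noise (SNR), and preserves more gray/white contrast per unit noise
(CNR) than the TV baseline — the method's central claim, reproduced at desk
scale. `recon_config()` holds the full-scale settings (16³-voxel patches,
768-wide embedding, 12 heads/blocks, 4000 Adam iterations at lr 0.01);
`recon_config_reduced()` is the desk preset used above.

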