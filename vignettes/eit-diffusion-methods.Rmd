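---
title: "Methods: simulation and conditional-diffusion reconstruction for time-difference EIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and conditional-diffusion reconstruction for time-difference EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eitdiff)
```

# The problem

Electrical impedance tomography (EIT) reconstructs the interior conductivity
of a domain from current/voltage measurements at boundary electrodes.
`eitdiff` implements the full desk-scale stack for time-difference EIT on the
unit disk: a finite-element forward solver under the complete electrode
model, the classical one-step regularized Gauss--Newton inversion, and a
multi-source conditional denoising diffusion model whose reverse process is
guided jointly by the measured boundary voltages and by the Gauss--Newton
reconstruction used as a spatial prior.

# Forward model

The potential $u$ satisfies $\nabla\!\cdot(\sigma\nabla u) = 0$ in the disk
$\Omega$.  The complete electrode model adds, for each electrode $e_\ell$
with contact impedance $z_\ell$,

$$u + z_\ell\,\sigma\frac{\partial u}{\partial n} = U_\ell \ \text{on}\ e_\ell,
\qquad \int_{e_\ell}\sigma\frac{\partial u}{\partial n}\,ds = I_\ell,$$

with zero current density off the electrodes.  Discretization uses
piecewise-linear triangular elements on a structured mesh of concentric
rings.  The angular resolution is graded towards the centre while staying a
multiple of the electrode count, so the mesh is exactly invariant under
rotation by one electrode spacing; homogeneous-disk frames are then
cyclically identical across injections, which the tests exploit as a strong
correctness check.  Grounding imposes $\sum_\ell U_\ell = 0$ through a
Lagrange multiplier, preserving the symmetry of the system and the
interchangeability of electrodes.  Defaults chosen where the problem leaves
them open: contact impedance $z_\ell = 10^{-2}\,\Omega\,\mathrm{m}^2$ for
every electrode, electrode coverage one half (equal metal and gap arcs).
Currents are supplied in mA and converted to A internally; voltages are
volts.

Measurements follow the adjacent protocol: current between each neighbouring
electrode pair $(\ell, \ell+1)$, differential voltages across every
neighbouring pair not touching the injectors, in cyclic order starting after
the current sink.  With $L = 16$ electrodes a frame has
$L(L-3) = 208$ values.

The sensitivity (Jacobian) matrix of the forward operator is computed with
the adjoint-field identity
$\partial V_{dm}/\partial\sigma_e = -A_e\,\nabla u_d\cdot\nabla u_m$, where
$u_d$ and $u_m$ are the drive and (reciprocal) measurement fields; under the
adjacent protocol the measurement patterns coincide with drive patterns, so
one batch of $L$ solves yields the whole matrix.  It is validated against
central finite differences (relative error below $10^{-3}$ on a
300-element mesh, dominated by the finite-difference step itself).

To avoid the inverse crime, data generation and inversion use different
meshes: a finer forward mesh (default ~2000 elements; ~500 in the
scaled-down study) and a coarser inverse mesh (~800 / ~300 elements) on
which the Jacobian and the Gauss--Newton prior live.

# Synthetic phantoms and measurement noise

Phantoms place 1--4 inclusions (circle, triangle, square, and the
non-convex pentagram, heart, crescent for the "Complex" subset) in the disk
of radius 0.9 with pairwise circumcircle separation at least 0.05, on a
1.0 S/m background.  Inclusion conductivities are 0.1 S/m (low phase) or
10 S/m (high phase) with probability one half each, times an amplitude
factor uniform in $[0.9, 1.1]$.  Where the shape family leaves details
open, the package fixes them once: pentagram as a ten-vertex star polygon
with inner/outer radius ratio $1/2.6$; heart as the classic closed sextic
curve scaled to a unit bounding box; crescent as the difference of two
discs with offset $0.45\,s$ and secondary radius $0.8\,s$; inclusion scales
uniform in $[0.15, 0.35]$.  Motion augmentation translates by a vector
uniform in a disc of radius 0.15 and rotates uniformly; "independent" mode
draws a transform per inclusion, "global" mode applies one rigid transform
to all inclusions (pairwise distances preserved exactly), with rejection
resampling to restore containment and separation.

Targets are rasterized at 256x256 (128x128 in the tiny study) by
point-in-shape tests at pixel centres and block-mean downsampled to the
network resolution; the conductivity change $\Delta\sigma$ is zero outside
the disk mask exactly.

Measurement noise is white Gaussian added to the absolute current-state
frame, with per-frame variance $P_\mathrm{signal}/10^{\mathrm{SNR}/10}$
($P_\mathrm{signal}$ the mean square of the clean frame); the network input
is the reference-subtracted difference, globally standardized by the
training-set mean and standard deviation (an exactly invertible affine
map whose statistics are stored with the dataset).

What the generator does *not* emulate: electrode drift or detachment,
non-Gaussian electronics noise, boundary-shape mismatch, 3-D current
spreading.  Passing the synthetic benchmarks therefore demonstrates
correctness of the algorithms under the stated model, not hardware-level
robustness.

# One-step Gauss--Newton (NOSER) inversion

The classical baseline and the diffusion prior share one implementation:

$$\hat{x} = (J^\top J + \lambda R)^{-1} J^\top \Delta v,$$

with $R = \operatorname{diag}(J^\top J)$ (the NOSER operator; exponent 1 on
the diagonal) and $\lambda = 0.05$ by default.  The reference state is the
homogeneous 1 S/m background, so the data residual is exactly the stored
voltage difference.  The normal matrix is factorized once (dense Cholesky;
inverse meshes stay below ~2000 elements) and reused across samples.
Element updates are mapped to pixel images by point-in-triangle lookup with
a nearest-element fallback for boundary slivers.

# The conditional diffusion model

The forward process corrupts the target image $x_0$ with
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\varepsilon$.  The
default schedule is linear in $\beta$; because the terminal signal fraction
depends on $\sum\beta_t$, shorter chains scale the DDPM range
$[10^{-4}, 0.02]$ by $1000/T$ (the tiny study uses $T = 200$, i.e.
$\beta \in [5\times10^{-4}, 0.1]$, giving $\bar\alpha_T \approx 5\times10^{-5}$).

Conditioning is multi-source: the standardized 208-vector passes through a
two-layer perceptron and is reshaped row-major into a spatial map; the
Gauss--Newton prior enters directly as an image channel.  Both maps are
concatenated with $x_t$ as network input channels and are additionally
average-pooled to each decoder resolution and injected into the skip
connections through gated fusion units
($g = \operatorname{sigmoid}(\mathrm{conv}[\mathrm{main},\mathrm{cond}])$,
output $\mathrm{main} + g \odot \mathrm{proj}(\mathrm{cond})$).  The
single-source ablations are pure configuration flags that zero one condition
channel everywhere (`mask_gn` for the data-constrained variant, `mask_vol`
for the physics-guided variant); the three variants differ in nothing else.

## Model units

The diffusion model operates on the log-conductivity contrast
$u = \log_{10}(1 + \Delta\sigma/\sigma_0)/1.05$, which maps the two phase
families symmetrically into $[-1, 1]$ (low phase $\to$ $-0.95$, high phase
$\to$ $+0.95$) and is exactly invertible.  A linear rescaling of
$\Delta\sigma$ would compress the low phase to $\approx -0.09$, an order of
magnitude below the diffusion noise floor, and the model would never
reconstruct low-conductivity inclusions; the logarithmic contrast is also
the natural parametrization of conductivity ratios.

## Denoising network

The denoiser is a U-Net whose shallow and intermediate stages use pairs of
window-attention blocks (regular then shifted windows, with learned relative
position biases and an additive mask that blocks cross-window pairs in the
shifted pass) and whose deepest stage and bottleneck use bidirectional
state-space blocks: a diagonal continuous-time system
$\dot h = A h + B x$, $y = C h + D x$ discretized by zero-order hold
($\bar A = e^{\Delta A}$, $\bar B = A^{-1}(\bar A - I)B$, with the series
limit at $A \to 0$), scanned forward and backward along the row-major token
sequence, concatenated and projected.  Downsampling is space-to-depth plus a
linear map; time steps enter through a sinusoidal embedding, an MLP, and a
per-block additive shift after the first layer normalization.  All residual
output projections start at zero, so the untrained network is an identity
plus a zero head -- a stable start for training.  Attention, scans and layer
normalization run in compiled code; every gradient was validated against
central finite differences.

The full-scale configuration is 64x64 input, widths 64/128/256/512 with
attention at resolutions 64/32/16 (window 8/8/4) and state-space blocks at
8; the package's tiny preset used by the scaled-down study is 32x32 with
widths 24/48/96 and window 4 at both attention stages, sized so the whole
study fits a single CPU.

## Training objective and parametrization

The composite objective is $L = L_\mathrm{denoise} + \gamma L_\mathrm{phys}$.
The physics term is the squared residual of the linearized forward operator,
$\|J_\mathrm{pix}\,\Delta\hat\sigma - y\|^2$, evaluated on the standardized
measurement scale so that $\gamma$ is dimensionless; $J_\mathrm{pix}$
composes the inverse-mesh Jacobian with the pixel-to-element averaging map.
A full nonlinear FEM mode exists for evaluation.  The clean-image estimate
entering the physics term is clamped to $[-1.2, 1.2]$; $\gamma = 0.1$ by
default with an optional linear ramp.  With $\gamma = 0$ the trainer is a
plain conditional diffusion trainer.

Internally the network predicts the clean image; the exposed model is the
noise predictor through the exact identity
$\hat\varepsilon = (x_t - \sqrt{\bar\alpha_t}\,\hat{x}_0^{net})/\sqrt{1-\bar\alpha_t}$,
so the sampler sees a standard $\varepsilon_\theta$.  The default
`denoise_space = "x0"` trains with the clean-image MSE, which equals the
noise MSE weighted by $(1-\bar\alpha_t)/\bar\alpha_t$ (an inverse-SNR
weighting); `"eps"` recovers the unweighted noise objective.  The reason is
budget: at a few hundred to a few thousand optimizer steps the unweighted
noise objective spends the model's capacity reproducing the noisy input
channel, because the conditional mean is attenuated by
$\sqrt{\bar\alpha_t}$ in the noise target and carries almost no gradient
at the steps where it matters most, whereas the clean-image loss weights the
conditional mean equally at every step.  At a production-scale budget of
hundreds of thousands of steps the two parametrizations are
interchangeable; at desk scale the clean-image space is the viable choice.

Optimization is Adam (learning rate $10^{-3}$, cosine decay, global
gradient-norm clipping at 1).  Training logs per-epoch losses, aborts on
non-finite or diverging losses, and checkpoints restore bit-exactly.

## Sampling

Inference uses the deterministic DDIM update
$x_{t-1} = \sqrt{\bar\alpha_{t-1}}\,\hat{x}_0 +
\sqrt{1-\bar\alpha_{t-1}}\,\hat\varepsilon$ over an evenly spaced decreasing
subsequence that always includes $T$ and 1, starting from standard normal
noise; 50 steps by default (200 also supported).  The clean-image estimate
is clamped to $[-1.2, 1.2]$ during sampling, which stabilizes the earliest
steps where $1/\sqrt{\bar\alpha_t}$ amplifies prediction error.  Given
weights, conditions and seed, sampling is bit-reproducible.  With an oracle
noise predictor the sampler reconstructs any target exactly for any step
count -- the strongest algebraic check of the implementation, and a frozen
test.

# Evaluation

Relative error and correlation are computed over in-disk pixels; SSIM uses
a 7x7 uniform sliding window with $C_1 = (0.01 L_r)^2$, $C_2 = (0.03 L_r)^2$
on the truth's dynamic range; Dice thresholds each image at half its
extreme value per conductivity phase (a phase is extracted only when the
extreme exceeds 5% of the phantom contrast scale), computes the overlap per
phase present in the truth, and averages.  Reference maps encode
background/low/high as 0/1/2 with a lossless decoder.  Reports aggregate
mean and sample standard deviation by (method, subset, SNR).

# The scaled-down benchmark study

`run_tiny_benchmark()` fixes the desk-scale study conditions: 300 samples
(60 per subset) at 40 dB SNR and 1.0 mA on a ~500-element forward /
~300-element inverse mesh pair at 32x32 resolution; five-fold split with
fold 1 held out; $T = 200$; 10 epochs at batch size 8; DDIM-50 sampling.
These sizes were chosen once so that the full study (dataset, two trained
models, sampling, and the SNR sweep) completes on a single CPU in well
under the package's test-suite runtime; they are deliberately far below the
50,000-sample, 300-epoch GPU scale of a full study, so absolute metric
values are not comparable -- only orderings (diffusion vs baseline,
degradation with noise) are meaningful at this scale.  The SNR sweep
(`noise_sweep()`) re-uses identical phantoms across levels and re-injects
noise at the measurement level only, so metric differences across levels are
attributable to noise alone.

```{r, eval = FALSE}
bm <- run_tiny_benchmark(seed = 7)
print(bm$report)
sweep <- noise_sweep(bm$models$MS, bm$dataset)
print(sweep)
```

# Known limitations

* 2-D circular domains only; no admittivity (complex-valued) EIT, no 3-D.
* The structured mesh trades element-quality uniformity for exact
  rotational symmetry; extreme refinement near the centre is wasteful.
* The linearized physics term shares the inverse-mesh Jacobian with the
  prior; it regularizes towards the same linear physics rather than the
  full nonlinear operator (the FEM mode is evaluation-only).
* At the tiny scale the diffusion model's advantage over the one-step
  baseline is modest and stochastic in sign for individual samples; the
  study reports group means.
* Real-hardware effects (contact-impedance drift, electrode placement
  error) are out of scope of the generator.
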