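# eitdiff

Simulation and reconstruction for **time-difference electrical impedance
tomography (EIT)** on a 2-D disk, in R.  The package is aimed at people who
want a self-contained, testable EIT stack: a complete-electrode-model (CEM)
finite-element forward solver, the classical one-step regularized
Gauss–Newton inversion, and a **multi-source conditional diffusion model**
that reconstructs conductivity-change images under the joint guidance of
the measured boundary voltages and the Gauss–Newton image used as a
physics-informed prior.

## The science in brief

The forward problem solves $\nabla\cdot(\sigma\nabla u)=0$ on the unit disk
with CEM boundary conditions ($L=16$ electrodes with contact impedances
$z_\ell$), discretized with linear triangular elements.  The adjacent
stimulation/measurement protocol produces $L(L-3)=208$ differential
voltages per frame; time-difference imaging targets
$\Delta\sigma = \sigma_2-\sigma_1$ from $\Delta v = F(\sigma_2)-F(\sigma_1)
\approx J(\sigma_1)\,\Delta\sigma$, with the sensitivity matrix $J$
computed by the adjoint-field identity.

Reconstruction methods:

* **TR** — one-step Gauss–Newton with the NOSER prior,
  $\hat{x} = (J^\top J + \lambda\,\mathrm{diag}(J^\top J))^{-1}J^\top\Delta v$,
  $\lambda = 0.05$;
* **MS** — a conditional denoising diffusion model: forward noising
  $x_t=\sqrt{\bar\alpha_t}x_0+\sqrt{1-\bar\alpha_t}\varepsilon$, a hybrid
  denoising U-Net (shifted-window attention in shallow stages,
  bidirectional state-space scans in deep stages, gated condition fusion)
  trained with the physics-enhanced objective
  $L = L_\text{denoise} + \gamma\,\|J_\text{pix}\Delta\hat\sigma - y\|^2$,
  and deterministic DDIM sampling (50 steps);
* **DC / PG** — single-source ablations of MS (voltage-only /
  prior-only), implemented as pure condition-masking flags.

A parametric phantom generator (five subsets of 1–4 inclusions, six shape
families, motion augmentation, SNR-controlled Gaussian measurement noise)
supplies fully reproducible synthetic datasets; metrics are relative error,
correlation, SSIM and per-phase Dice.  See the methods vignette
(`vignettes/eit-diffusion-methods.Rmd`) for the modelling choices.

## Worked example

Forward-simulate a phantom, reconstruct with one-step Gauss–Newton, and
score it:

```r
library(eitdiff)

mesh_f <- build_disk_mesh(2000, electrode_count = 16, coverage = 0.5)
mesh_i <- build_disk_mesh(800, 16, 0.5)       # separate inverse mesh
proto  <- build_adjacent_protocol(16, amplitude = 1.0)
elec   <- electrode_array(16)

ph    <- sample_phantom("Two", rng_seed = 21)
sigma <- phantom_to_mesh(ph, mesh_f)
dv    <- timediff_forward(mesh_f, rep(1, mesh_f$n_elements), sigma, elec, proto)

J   <- compute_jacobian(mesh_i, rep(1, mesh_i$n_elements), elec, proto)
reg <- build_regularizer(J, "noser", lambda = 0.05)
rec <- elements_to_grid(as.vector(gn_onestep(J, reg, dv$values)), mesh_i, 64)

truth <- rasterize(ph, 256, 64)
c(RE   = relative_error(truth$pixels, rec$pixels, truth$mask),
  CC   = corr_coeff(truth$pixels, rec$pixels, truth$mask),
  Dice = dice(truth$pixels, rec$pixels))
#>        RE        CC      Dice
#> 0.8568069 0.6232410 0.5827518
```

The one-step image localizes the inclusions (positive correlation, Dice
well above zero) but is blurred and overshoots amplitudes — the classical
behaviour this package's diffusion model is there to improve.  The whole
scaled-down study (dataset generation, diffusion training, DDIM sampling,
method comparison) is one call:

```r
bm <- run_tiny_benchmark(seed = 7)   # ~12 min on one CPU
print(bm$report)                     # TR vs DC vs MS, mean +/- sd
```

A thin command-line interface over the same functions is installed at
`inst/cli/eit.R` with verbs `simulate`, `reconstruct-tr`, `train`,
`sample`, `evaluate`.

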