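# mcfholo

Phase-only computer-generated holography for randomly distributed multi-core
fiber (MCF) phased arrays, as used in lensless holographic microendoscopy.

A multi-core fiber carries thousands of single-mode cores; with the
intrinsic optical path differences between cores compensated by digital
optical phase conjugation, the distal facet becomes a coherent phased array
that can synthesize an arbitrary intensity pattern in its far field
(here 700 um beyond the tip at 532 nm). The computational problem is the
inverse one: find the per-core piston phases whose far field matches a
target image. Because the cores are sparse and randomly placed, a hologram
computed for a regular pixel grid is spatially aliased into an
unrecognizable pattern when the fiber samples it — the method must respect
the core constraint.

The package implements the complete simulation stack in R (with C++
convolution kernels):

* **Band-limited angular spectrum propagation** — the scalar diffraction
  engine $U_o = F^{-1}\{H_\mathrm{lim} F\{U_i\}\}$ with
  $H_\mathrm{lim}(u,v) = \exp(i 2\pi z\sqrt{1/\lambda^2-u^2-v^2})\,
  \mathrm{rect}(u/2u_\mathrm{lim})\mathrm{rect}(v/2v_\mathrm{lim})$ and
  $u_\mathrm{lim} = [(2\Delta u z)^2+1]^{-1/2}\lambda^{-1}$; its adjoint
  (conjugate transfer) doubles as backward propagation and as the gradient
  path for training.
* **Fiber model** — synthetic core maps with guaranteed minimum spacing,
  nearest-pixel phase sampling, circular-mask rendering of piston-phase
  disk fields, and a simulated distortion/phase-conjugation pair that
  cancels bit-for-bit.
* **Iterative baselines** — plain Gerchberg-Saxton (GS) and the
  core-constrained Core-GS, which re-projects onto the fiber constraint
  every iteration.
* **An unsupervised phase-encoder network** — a dual-input residual U-Net
  that maps the real and imaginary parts of the back-propagated target
  field to a full-resolution phase hologram, trained end-to-end *through*
  the differentiable fiber + propagation model with the negative Pearson
  correlation (NPCC) loss. The network, its backward passes, and Adam are
  implemented in the package.
* **Evaluation harness** — the 2-D correlation coefficient
  $\mathrm{CC}(X,Y)$ between reconstruction and target, with every method
  reconstructed through the identical forward model.

See `vignettes/mcfholo-methods.Rmd` for the models, parameter choices and
the desk-scale study profile (64 x 64 grid, 85 um facet, 128-200 cores — a
proportionate miniature of a 10,000-core, 350 um instrument).

## Worked example

```r
library(mcfholo)

geom <- field_geometry(64, 64, pitch_x = 2, wavelength = 0.532)
cm   <- make_synthetic_core_map(200, facet_diameter = 85, seed = 1)
tg   <- generate_targets(1, 64, "glyphs", seed = 7)[[1]]

# core-constrained iterative retrieval
r <- core_gs_retrieve(tg, cm, z = 700, geom, iters = 100)
r
#> <retrieval_result> core hologram, 100 iterations, final CC = 0.5953

# naive GS, sampled through the cores afterwards: strong aliasing
g  <- gs_retrieve(tg, z = 700, geom, iters = 100, trace = FALSE)
gh <- sample_core_phases(g$hologram, cm, geom)
I  <- reconstruct_intensity(render_core_field(gh, cm, geom), z = 700)
correlation_coefficient(I, tg)
#> [1] 0.3727306
```

The Core-GS hologram reaches a correlation of about 0.60 with the target on
this 200-core desk geometry, while the same iteration budget spent on plain
GS drops to about 0.37 once the fiber samples the hologram — the spatial
aliasing that motivates core-aware methods (milder here than at full scale,
where the hologram carries far finer structure relative to the core
spacing).

Training the phase encoder (a few minutes on one CPU at desk scale):

```r
train <- generate_targets(2000, 64, "glyphs", seed = 2)
model <- build_corenet(corenet_config(64, depth = 3, base_width = 4, seed = 1))
model <- train_corenet(model, train, cm, geom, z = 700,
                       epochs = 5, batch_size = 8, lr = 3e-3, seed = 1)
holo  <- infer_hologram(model, tg, z = 700, geom)   # one forward pass
```

A command-line front end over the same functions lives in
`inst/cli/mcfholo-cli.R` (subcommands `retrieve-gs`, `infer`, `train`,
`make-dataset`).

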