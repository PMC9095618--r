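---
title: "Holograms for random phased arrays: models and methods in mcfholo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holograms for random phased arrays: models and methods in mcfholo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A multi-core fiber (MCF) microendoscope carries thousands of single-mode
cores, each transmitting one piston phase. Driving the proximal facet with a
phase-only spatial light modulator turns the distal facet into a coherent
phased array: by choosing the per-core phases one can synthesize an arbitrary
intensity pattern a few hundred micrometres beyond the fiber tip. The
computational task is the inverse problem — given a target intensity, find
the per-core phases — under two obstacles:

1. the cores are randomly and sparsely distributed, so a hologram computed
   for a regular pixel grid is aliased into an unrecognizable far field when
   it is spatially sampled by the cores;
2. iterative projection methods that respect the core constraint are too slow
   for video-rate hologram streams.

`mcfholo` implements the full simulation stack for this problem: a
differentiable scalar-diffraction engine, the fiber facet model, two
iterative baselines (Gerchberg-Saxton and its core-constrained variant), an
unsupervised convolutional phase encoder trained *through* the physical
model, and a correlation-based evaluation harness.

## Diffraction model

Propagation between the facet plane and the target plane uses the
band-limited angular spectrum method:

$$U_o = F^{-1}\{ H_\mathrm{lim}(u,v) \cdot F\{U_i\}\},\qquad
H_\mathrm{lim}(u,v) = e^{\,i 2\pi z\sqrt{1/\lambda^2 - u^2 - v^2}}\,
\mathrm{rect}\!\Big(\frac{u}{2u_\mathrm{lim}}\Big)
\mathrm{rect}\!\Big(\frac{v}{2v_\mathrm{lim}}\Big),$$

with $u_\mathrm{lim} = [(2\Delta u\, z)^2+1]^{-1/2}\lambda^{-1}$ and
$\Delta u = 1/(N_x\,\mathrm{pitch}_x)$ the frequency sample interval. The
window removes the frequencies whose sampled transfer-function phase would
alias at distance $z$, which is what makes the method accurate in the
far-field regime this package targets ($z = 700\,\mu m$ at
$\lambda = 532$ nm).

Numerical choices:

* **Evanescent components** ($1/\lambda^2 - u^2 - v^2 < 0$) are set to zero
  rather than attenuated. At the working distances these components are
  physically negligible, and zeroing avoids exponential overflow when the
  same transfer function is conjugated for backward propagation.
* **Backward propagation is the adjoint**, i.e. multiplication by
  $\overline{H}$, not a naive $z \to -z$ substitution. Because $|H| = 1$
  inside the window, the forward/backward pair is exactly unitary on the
  passband: round trips are identities in band, and in-band energy is
  conserved to machine precision. The same adjoint is what back-propagates
  loss gradients during network training, so the physics engine and the
  autodiff engine are literally the same code path.
* **Frequency grid**: DC-centred sampling in unshifted FFT order, with all
  derived quantities ($\Delta u$, band limits) recomputed from the geometry
  on every call; nothing is cached where it could go stale. Iterative
  callers may pass a precomputed transfer function explicitly.
* **Amplitude convention**: intensity targets enter as $\sqrt{I}$ with zero
  phase; reconstructions are $|U|^2$, max-normalized only for display and
  reporting (the fidelity metric is scale-invariant either way).

A caveat that matters for interpretation: at $z = 700\,\mu m$ on the
desk-scale grid the window passes only part of the sampled band, so forward
propagation is a projection, not a unitary map. Properties that rely on
strict unitarity (e.g. the classical monotone error of Gerchberg-Saxton) are
therefore exercised in the package's tests at distances where the window
covers the full band; the far-field working distance keeps the band limit,
which is the point of the band-limited method.

## Fiber model

A core map holds physical centre coordinates (micrometres), a common core
radius, the facet diameter, and the guaranteed minimum centre spacing.
Defaults mirror a high-count imaging bundle (10,000 cores, 350 um facet,
3.3 um spacing, 1 um core radius); everything is configurable.

* **Synthetic maps.** At low packing density, centres are drawn by random
  darts with rejection — the irregular distribution typical of drawn fiber
  bundles. A rejection sampler, however, saturates near 55% of the
  hexagonal packing limit, while a real 10,000-core, 350 um bundle sits at
  ~98% of that limit: such bundles are jammed, locally ordered arrays, not
  sparse random ones. Above 45% of the limit the generator therefore
  switches to a randomly rotated, jittered triangular lattice, which reaches
  the physical density while keeping the spacing guarantee exact.
* **Rendering.** Each core is painted as a hard-edged disk (pixel centre
  within one core radius) of unit amplitude and uniform phase; cladding has
  zero amplitude. Sub-pixel anti-aliasing is deliberately not applied —
  binary circular masks keep sample-after-render an exact identity. A core whose disk covers no pixel
  centre paints its single nearest pixel, so every core always has support.
* **Sampling.** A hologram is sampled at the pixel nearest each core centre
  (no interpolation). The desk profile keeps the minimum spacing above
  $\sqrt{2}\times$ the pitch so distinct cores always read distinct pixels,
  which makes `sample(render(h)) = h` exact up to phase wrap.
* **OPD and phase conjugation.** Intrinsic optical path differences are
  modelled as a per-core phase layer; digital optical phase conjugation is
  its negation. Layers accumulate in a dedicated slot of the hologram and
  are summed *before* being added to the hologram phase — the same way a
  real system stacks the conjugation layer and the fiber distortion — so an
  exact conjugate cancels the distortion bit-for-bit, and the compensated
  transmission is literally identical to the undistorted one. In-situ
  guide-star calibration of a physical fiber is out of scope; the
  distort/compensate pair is its simulated analogue.

## Iterative baselines

Plain Gerchberg-Saxton alternates between unit source amplitude and target
amplitude through the propagation engine, with a uniform zero-phase start by
default (a seeded random start is available). Stopping is a fixed iteration
budget; there is no tolerance-based early exit, which keeps method
comparisons budget-for-budget fair. The core-constrained variant (Core-GS)
additionally projects the source plane onto the fiber constraint every
iteration: sample the back-propagated phase at the core centres, re-render
the piston-phase disk field. This is the minimal constraint-projection
reading of a core-tailored GS; per-core piston phase (not per-pixel freedom
inside a disk) is the implemented constraint. Each iteration records the
reconstruction correlation; a constant reconstruction (e.g. the very first
iterate from a uniform start) has no defined correlation and is recorded as
`NA`.

## The phase encoder network

The encoder maps a target to a full-resolution hologram in a single forward
pass. Its input is not the raw image: the target amplitude is first
back-propagated to the facet plane, and the real and imaginary parts of that
complex field form the two input planes, so input and output live at the
same plane and the map the network must learn is near-local. The
architecture is a modified U-Net: the downsampling path is duplicated per
input plane; each down/up block is two pre-activation residual sub-blocks
(BatchNorm, ReLU, convolution, twice per sub-block) with the first
convolution — or transposed convolution on the upsampling path — strided
(2, 2); the two paths join at the bottleneck by channel concatenation; the
upsampling path receives skip connections from *both* downsampling paths,
concatenated (the exact skip wiring is not fixed by the source design; this
is the package's documented choice). The head is BN-ReLU-conv to a single
plane read as unwrapped phase; the wrap to $[0, 2\pi)$ happens downstream
through $e^{i\varphi}$ inside the rendering stage, which keeps gradients
smooth across the wrap.

Training is unsupervised: the forward pass continues through core sampling,
disk rendering and propagation, and the loss is the negative Pearson
correlation (NPCC) between the reconstructed intensity and the input target
itself. No precomputed hologram enters the loop at any point. Gradients flow
through every stage analytically: the adjoint of propagation is conjugate
propagation; rendering routes each disk's aggregated field gradient into its
core phase via $\partial L/\partial\varphi_c =
\mathrm{Im}(\overline{v_c}\sum_{p\in\mathrm{disk}_c} g_p)$, and sampling
scatters those into the phase image. The whole chain is verified against
central finite differences in the test suite.

The network, its layer-wise backward passes, and the Adam optimizer are
implemented in the package itself (R with C++ convolution kernels via Rcpp);
convolutions use batched im2col + BLAS GEMM with the forward column matrices
cached for the backward pass.

## Desk-scale study profile

All tests and the acceptance script run at a desk scale chosen to be a
proportionate miniature of the full instrument, not just a smaller grid:

| quantity | full scale | desk profile |
|---|---|---|
| grid | 1920 x 1080 (512 x 512 work area) | 64 x 64 (48 x 48 work area) |
| cores | 10,000 | 128 (200 for baseline comparisons) |
| facet | 350 um | 85 um |
| z, lambda | 700 um, 532 nm | unchanged |
| pixel pitch | ~0.4 um (demagnified SLM pixel) | 2 um |

The facet diameter is the one genuinely free parameter, and it is fixed by a
scaling argument rather than convenience: the far-field speckle grain of a
facet of diameter $D$ is $\lambda z/D$, so the number of independent
resolution cells across the working area divided by the number of cores
measures how over- or under-determined the synthesis problem is. The full
instrument works at roughly 4 cells per core; $D = 85\,\mu m$ reproduces
that ratio for 128 cores on the desk grid (about 540 cells over the 96 um
working area). A desk model with the full 350 um facet would put ~60 cells
per core and make every method look bad for reasons that have nothing to do
with the methods.

Network defaults at desk scale are depth 3 and base width 4 (channel widths
4/8/16, ~50k parameters), batch size 8, Adam at learning rate 3e-3 for the
prescribed 5 epochs. Capacity is not the binding constraint at this training
scale: doubling the base width to 8 changes held-out fidelity by less than
0.01 while doubling the training cost, and depth 4 / width 32 — a closer
match to full-scale practice — trains an order of magnitude slower for no
change in the qualitative conclusions. The learning rate was selected once
from {1e-3, 3e-3, 1e-2} by held-out fidelity on the standard run (3e-3 and
1e-2 are indistinguishable; the smaller value is kept); batch size follows
the stated default.

A consequence worth stating plainly: at this training scale the encoder
converges to a solution close to per-core phase conjugation of its input
field — the best near-local map — which on the desk geometry yields mean
correlations around 0.4, below the ~0.55 that 100 Core-GS iterations reach
by global refinement. The full-scale ordering (network above Core-GS)
emerges only with orders of magnitude more training data and optimization
than a desk CPU run performs; the package's tests therefore verify the
training contract (unsupervised loss decreases, the network beats a
random-phase baseline, it can overfit a single target to the physical
ceiling) and report the method comparison honestly rather than asserting
the full-scale ordering at desk scale.

## What the synthetic data does and does not emulate

`generate_targets()` renders character-like glyphs (2-4 random thick
polylines and arcs), binary patterns (rectangles, disks, rings, dot
clusters), and filled disks, lightly Gaussian-smoothed and max-normalized,
each guaranteed at least 1% support. The glyph family emulates the stroke
statistics of handwritten-character corpora used for training at full scale;
the binary patterns emulate the custom letter/pattern test sets. They do not
emulate: grayscale natural images, class structure (no label balance, since
nothing is supervised), or the 131,600-image corpus size. Consequently,
passing desk-scale tests demonstrates that the architecture, the
differentiable physics, and the training contract work as specified — it
does not certify full-scale fidelity numbers, which depend on GPU-scale
training and a physical fiber.

No public handwritten-character corpus is a dependency: every input is
generated programmatically, and a user who wants to train on real
handwritten characters (e.g. an EMNIST download) can pass any list of
matrices to `train_corenet()`.

## Evaluation

Fidelity is the 2-D Pearson correlation coefficient between the numerically
reconstructed intensity and the target,

$$\mathrm{CC} = \frac{\sum_i (X_i-\bar X)(Y_i - \bar Y)}
{\{\sum_i (X_i-\bar X)^2 \sum_i (Y_i-\bar Y)^2\}^{1/2}},$$

computed over all pixels; the training loss is its negation. The evaluation
harness reconstructs *every* method — iterative or learned — through the
identical sample-render-propagate model before scoring, so no method is
advantaged by its own forward model. Reports carry per-target values plus
box-plot summaries (median, quartiles, 1.5 IQR whiskers — the whisker
convention is the package's choice).

## Known limitations

* Scalar diffraction on uniform grids only; no vectorial effects, no
  inter-core coupling, no multimode cores, no bending dynamics.
* Per-core transmission is uniform; real bundles have amplitude variation.
* The desk-scale fidelity ceiling is set by 128-200 phase degrees of
  freedom; absolute correlation values are not comparable to full-scale
  instruments and are read as method orderings, not specifications.
* Checkpoints use RDS, and field containers use two-plane float TIFF with a
  JSON sidecar; holograms additionally ship as 8-bit PNG for display with
  floor quantization (error < $2\pi/256$ per pixel).
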