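---
title: "Active Maxwell mechanics of stress fibres: models, synthetic scenes and measurement chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active Maxwell mechanics of stress fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the mechanical models, the choices that were genuinely open, the synthetic
data the measurement chains are validated on, and the limits of what the
passing test suite demonstrates.

## The 1D continuum model

A stress fibre (or a 1D transect of a contractile cell) is modelled as an
*active Maxwell fluid*: at every point, an active contractile stress
`sigma_a(x, t)` acts in parallel with a passive Maxwell element — a spring
of modulus `E` (Pa) in series with a dashpot of viscosity `eta` (Pa s).
The cell couples to an elastic substrate through friction. The governing
system solved by `simulate_1d()` is

* passive stress dynamics: `d(sigma_p)/dt = E dv/dx − (E/eta) sigma_p`
* total stress: `sigma = sigma_p + sigma_a`
* quasi-static force balance: `d(sigma)/dx = kM w`
* substrate friction: `dw/dt = v − (kM/gamma) w`

with `v` the cytoskeletal velocity, `w` the substrate displacement
(traction `kM w`), and stress-free ends (`sigma = 0`) by default; a clamped
option exists. Activation adds
`dsigma · 1[a ≤ x ≤ b] · f(t)` with the exponentially plateauing ramp
`f(t) = 1 − exp(−(t − t_on)/tau_a)` during activation and exponential decay
with `tau_d` after switch-off.

The key emergent quantity is the **viscoelastic relaxation time**
`tau = eta / E`. Below `tau` the material responds elastically — when the
activating stress is removed, stored passive stress drives a reverse flow
and most of the displacement recoils. Above `tau` it flows: deformation is
plastic and permanent. With a 15 min activation and `tau` = 60 min, roughly
`1 − exp(−15/60) ≈ 22%` of the peak displacement converts to plastic strain,
which is exactly the ~3 um contraction / ~1 um residual phenotype of the
calibrated reference scene.

### Numerical scheme

The solver is a method-of-lines semi-implicit stepper (C++): `sigma_p` lives
on elements, `u` on nodes, the substrate displacement is slaved to the force
balance constraint, and the velocity field solves a tridiagonal elliptic
system at every step, obtained by differentiating the constraint in time and
substituting the friction law. `sigma_p` advances by an exponential update
that is exact for piecewise-constant strain rate, so the scheme remains
stable when `tau` is far below the step (the fluid-like regime, `tau` = 1 s,
stepped at 0.5–2 s). Fits run thousands of forward simulations, which is why
this stepper is custom and compiled rather than delegated to a generic stiff
ODE integrator; the test suite cross-checks it against an independent
`deSolve::lsoda` integration of the same discrete system at tight tolerance
(agreement to 0.1%) and against grid refinement (<1% change under
halving of `dx` and `dt`). The stepper has a friction-related stability
limit at very stiff substrate couplings; it detects divergence and asks for
a smaller `dt_step`.

Two subtleties of this model class are worth recording:

* **Baseline contractility is a gauge choice.** With free ends, a nonzero
  uniform `sigma0` has no exact steady state (the Maxwell element lets the
  boundaries creep at rate ~`sigma0/eta`). The reference state is therefore
  taken at `sigma0 = 0`: baseline contractility is absorbed into the state
  around which activation perturbs the cell. Consequently the baseline
  substrate strain energy is zero, and "return to baseline" is quantified as
  the residual fraction `(U_end − U_base)/(U_peak − U_base) ≤ 10%`.
* **Recoil speed is set by the activation decay and friction, not by
  `tau`.** After switch-off the stored elastic stress drives flow back until
  `sigma ≈ 0`; with the calibrated parameters this produces a fast recoil
  over the first ~1 min and a sustained ~1 nm/s reverse creep for the rest of
  the relaxation phase — matching the kymograph phenomenology.

### Calibrated reference parameters

`reference_params()` freezes two parameter sets. R1 (elastic-like):
`E = 1000 Pa`, `eta = 3.6e6 Pa s` (`tau` = 60 min), `gamma = 1.5e4`,
`kM = 30`, `dsigma = 1530 Pa`, a 10 um activation region centred in a 60 um
cell, `tau_a = 180 s`, `tau_d = 30 s`. These were found once by a coarse
grid search (committed in `inst/scripts/calibrate_reference.R`) against the
jointly required phenomenology: a feature 5 um outside the region edge moves
~3 um during 15 min of activation and retains ~1 um after 15 min of
relaxation, with mean activation flank flow above 3 nm/s. R2 (fluid-like)
differs in a single field: the Maxwell spring is stiffened so `tau` = 1 s.
With an effectively rigid spring the element reduces to a dashpot of the
same viscosity, which preserves the activation-phase contractile flow
(the viscous coupling length `sqrt(eta/gamma)` ≈ 15 um is unchanged) while
abolishing recoil. Scaling `eta` down instead would shrink that length below
a micron and suppress all flank motion — not what fluid-like cells show.

## The 2D discrete model

`simulate_2d()` evolves an equilateral triangular mesh of Maxwell cables
(elastic force `k (l − l_r)`, rest-length flow `dl_r/dt = (k/eta)(l − l_r)`)
with overdamped nodes (`gamma_node dX/dt = sum of forces`). Stress fibres
are chains of links with their own `k_SF`, `eta_SF`. Activation adds an
equal-and-opposite contractile pair (`sigma_m f(t)`) along each activated
link — a force dipole — so internal forces always sum to zero and the free
mesh centroid is stationary to integration tolerance. Two scenarios span
the architecture question: if the whole mesh is contractile, parallel fibres
pinch together transverse to their axis; if only fibre links are, motion is
confined to the fibre axis. A thin strip with one fibre reproduces the 1D
continuum solution within 10% once parameters are matched
(`E = k_SF · a`, `eta = eta_SF · a`, `gamma = gamma_node / a`, rigid
substrate limit), with the activation span matched to the lattice's
link-midpoint discretization.

Integration is explicit Euler with a step capped at
`0.2 gamma_node / k_max` and adaptive sub-stepping when any node moves more
than a tenth of the lattice spacing; quantitative comparisons use
`dt ≈ 0.1 gamma_node / k_max` because first-order error at the cap is a few
per cent.

## Synthetic scenes

The generator is first-class, tested code; every scene carries complete
ground truth (model trajectory, per-frame puncta positions, traction and
displacement fields, noise seeds), and identical seeds give bit-identical
scenes.

* **Fibre movies** (`gen_fibre_movie()`): Gaussian puncta (sigma 0.3 um)
  at ~1 um spacing along a horizontal fibre, advected by the 1D model's
  displacement field plus a constant 1 nm/s drift toward the activation
  centre (the baseline retrograde flow, which the mechanical model does not
  produce and which is therefore injected by the generator); intensity in
  the region rises by `1 + 0.5 f(t)` (1.5-fold at plateau); global
  bleaching `exp(−t/2400 s)`; Poisson shot noise at ~400 peak photons
  (puncta SNR ≈ 10) plus Gaussian read noise; 16-bit counts at 0.108 um/px,
  one frame per 20 s for 45 min (15 min baseline / activation / relaxation).
* **Bead scenes** (`gen_bead_scene()`): four cell-scale contractile
  Gaussian force dipoles (sigma 5 um, separation 16 um, 1.5 kPa) with
  exactly zero net force; surface displacements from the forward Boussinesq
  operator on an 8.6 kPa, nu = 0.5 half-space; ~2.5 beads/um² rendered at
  0.215 um/px (a 2x-binned bead channel). The dipole scale is chosen so the
  displacement features are well resolved by the PIV interrogation window —
  the regime in which the inverse problem is validated.
* **Adhesion movies** (`gen_adhesion_movie()`): elliptical Gaussian
  adhesions with programmed intensity time courses; placements are drawn
  sequentially with a minimum separation so thresholded blobs stay
  disjoint.

What these scenes deliberately do *not* emulate: realistic PSFs beyond
Gaussians, camera-specific noise, actin turnover/treadmilling, fibre
curvature, intersecting fibre networks, or adhesion splitting/merging.
Passing tests therefore demonstrate that the measurement chains are correct
and well-calibrated on clean, geometrically simple data — not that they are
robust to every pathology of real movies.

## Measurement chains and their numerical choices

**Traction force microscopy.** `piv_beads()` is a multi-pass
window-deformation PIV: per-shift normalized cross-correlation (box-sum
normalization), 3×3 least-squares Gaussian sub-pixel peak fit,
normalized-median outlier rejection with interpolation of gaps, and two
deformation passes in which the deformed image is warped back by the
box-smoothed predictor and residual shifts are re-measured. The deformation
passes remove the displacement-gradient attenuation of single-pass PIV
(amplitude slope 0.99 vs ~0.85 on the validation scenes) and the smoothing
of the predictor keeps pass noise from accumulating; the noise floor on the
reference bead scenes is ~0.04 px. `krige_interpolate()` is ordinary
kriging with an exponential variogram fitted to the empirical
semivariogram, nugget-free so it interpolates the data exactly (constant
fields are returned exactly by unbiasedness; a singular system falls back
to radial-basis interpolation with a warning). `fttc_inverse()` solves the
per-wavevector 2×2 Tikhonov system with the tangential Boussinesq tensor
and nulls the zero mode (zero net force by construction).

**Choosing the regularization weight.** `lcurve_select()` computes the full
L-curve (residual and solution norms per candidate weight) and, by default,
selects the weight by generalized cross-validation evaluated exactly from
the per-wavevector filter factors. The geometric corner of the L-curve is
also computed (after pruning the small-weight plateau) and is available as
`rule = "corner"`, but on these fields it locks onto the bend where
regularization starts removing *traction signal* rather than measurement
noise: in low-noise settings it lands more than a decade above the weight
that minimizes the true traction error and attenuates the recovered strain
energy to ~70%. GCV tracks the noise level instead: on the package's
validation scenes it stays within ~0.6 decade of the brute-force true-error
optimum and recovers the stored strain energy within 15% end-to-end
(PIV → kriging → inversion → `1/2 ∫ T·u dA`), noise-free and with photon
noise. For exactly noiseless input it returns the smallest candidate weight.

**Optical flow.** `optical_flow()` is Horn–Schunck with coarse-to-fine
warping; the inner problem is solved by red-black successive
over-relaxation, which converges where plain Jacobi iteration (the textbook
scheme) stalls on sparse-texture fibre images. Frames are normalized to a
common [0, 255] scale so the smoothness weight is independent of camera
counts. The accuracy contract — pure translations up to 2 px recovered
within 0.1 px — holds for both the variational solver and the
block-matching fallback. At the study cadence (20 s) fibre motion is
0.01–0.8 px/frame; per-frame flow at the low end of that range is below any
estimator's noise floor, so the generator-consistency test compares the
*time-integrated* projected flow over the activation phase with the
Eulerian displacement field (agreement ~12–13%; the residual is dominated
by the advective difference between Eulerian and material displacement at
multi-micron excursions, not estimator error).

**Kymographs and displacement reversal.** `extract_kymograph()` samples
1-px arc-length steps with a 9-sample perpendicular stencil (bilinear
interpolation); `project_flow()` signs speeds positive toward increasing
arc length, and flank summaries re-sign so "toward the activation region"
is positive. `displacement_reversal()` tracks the local intensity pattern
column-to-column by normalized correlation — which keeps lock through the
fast coherent recoil just after switch-off, when the per-frame shift can
exceed the spacing between neighbouring puncta — and then snaps to the
nearest intensity peak so the tracked coordinate is the material punctum
rather than the window-averaged pattern. The punctum's baseline drift is
estimated on the pre-activation window and its linear extrapolation is
subtracted, so the reported `d_act`/`d_rel` isolate activation-induced
motion from the constant retrograde drift; without this correction a
coherent 1 nm/s drift would add 0.9/1.8 um to the two readouts and the
printed ~3 um / ~1 um phenotype could not coexist with the printed ~1 nm/s
baseline flow.

## Fitting and identifiability

`fit_strain_energy()` and `fit_kymograph()` minimize squared residuals over
`{E, eta, gamma, dsigma, tau_a}` in log space with the substrate stiffness
fixed (it is not identifiable jointly with the overall stress scale),
using Nelder–Mead from multiple jittered starts plus a polishing pass. Two
documented options matter in practice:

* `relax_weight` up-weights the relaxation phase, where `tau` is primarily
  constrained.
* `loss = "relative"` scales residuals by the data magnitude (floored at 5%
  of its maximum). This is the matched least-squares weighting when the
  observational noise is multiplicative — as it is for the synthetic
  observables — and it stabilizes the recovered `tau` substantially: across
  noise seeds the plain-SSR estimate of a 60 min relaxation time ranges over
  58–92 min, the relative-loss estimate over 58–64 min. The headline
  recovery therefore uses the relative loss; the default remains plain SSR.

The absolute scale of `E` and `dsigma` is only weakly identified from a
single observable (the strain-energy curve constrains ratios); `tau = eta/E`
is the robust quantity, which is exactly what the analysis reports. The
recovery bias grows monotonically with noise (2% → 10% multiplicative), and
strain-energy and kymograph fits of the same scene agree on `tau` within
30%.

## Problem sizes

Default analyses use: 121-node 1D grids at 0.5–1 s internal steps
(and 61 nodes at 2 s inside fitting loops, where each simulation takes a
few milliseconds); 45-min movies at 20 s cadence (136 frames) and 0.108
um/px; 256 px bead images at 0.215 um/px with a 0.86 um analysis grid; 2D
meshes of ~550 nodes; fitting with 3–5 multistarts and 250 simplex
iterations; reversal ensembles of 20 tracked features over 10 scenes. These
sizes reproduce the study conditions at full fidelity for the movies and
are the package's chosen operating points for simulation grids and
optimizer budgets.

## Known limitations

* The continuum model has no actin turnover, no sarcomeric substructure,
  and no stochastic motor kinetics; baseline retrograde flow must be
  injected by the generator.
* Tractions are not computed from the 2D model (no substrate spring there),
  and the 2D model is compared forward-only, never fitted.
* The FTTC chain assumes a semi-infinite substrate; finite-thickness
  corrections are out of scope.
* The displacement-reversal tracker assumes a punctate, locally rigid
  intensity pattern; heavily remodelling fibres would defeat the
  peak-snapping step.
* Periodic FFT operators mean bead scenes must keep tractions away from
  image borders (the default dipole layout does).
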