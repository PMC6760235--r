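---
title: "Snapshot quantitative phase imaging with a coded wavefront sensor: models, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot quantitative phase imaging with a coded wavefront sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(specklephase)
```

## The sensing principle

A coded wavefront sensor is an ordinary intensity sensor with a random
binary phase mask (features of 12.9 um, etched to a 0 or pi phase step)
mounted a short distance `z` (about 1.5 mm) in front of the pixels. Under
collimated illumination the mask casts a high-contrast diffraction speckle
pattern onto the sensor: the *reference image* `I0`, captured once. A thin,
mostly transparent sample placed at a plane conjugate to the mask distorts
the incoming wavefront `phi`, and to first order in ray optics the speckle
pattern translates locally by

    u(r) = (lambda z / 2 pi) * grad phi(r) = z * grad OPD(r),

where `OPD = (lambda / 2 pi) phi` is the optical path difference in
micrometres. Because both the displacement and everything else we estimate
depend on the wavefront only through the OPD, the method works under
broadband (temporally incoherent) illumination: a nominal wavelength
(532.8 nm throughout) is needed only to exchange OPD and phase in radians.

Conservation of energy along the displaced ray bundles adds an intensity
modulation: where the wavefront converges, intensity piles up. To first
order in the local curvature, a sample with amplitude `A(r)` satisfies

    I(r + z grad OPD) = |A(r)|^2 * (1 - z lap OPD) * I0(r),

the product `v = |A~|^2 = |A|^2 (1 - z lap OPD)` being the *modulated
intensity*. The *curvature (caustic) factor* `1 - z lap OPD` is exposed as
`curvature_factor()`; `geometric_forward()` implements the full warp model;
`correct_amplitude()` undoes the caustic modulation after reconstruction
(`A = A~ sqrt(1 + z lap OPD)`). The model is valid only while
`|lap OPD| << 1/z`; `curvature_upper_bound(z_um)` returns that bound
(about 700 / m at the calibrated `z` = 1.43 mm) and
`h_upper_bound(z_um, omega)` translates it to a sinusoid amplitude bound
`1 / (z omega^2)`.

Taylor-expanding the warp model in `z` yields the transport-of-intensity
relation between an in-focus and a defocused image; `tie_predict()` (the
forward linearization) and `tie_solve()` (the classical two-Poisson-solve
inversion) implement that limit and serve as an independent cross-check on
the geometric model: their discrepancy shrinks quadratically in `z`, which
the test suite verifies by Richardson extrapolation.

## What the simulator emulates — and what it does not

`make_mask()`, `simulate_reference()` and `simulate_measurement()` form a
physical-optics simulator: the binary mask is drawn i.i.d. at the feature
pitch, upsampled to a grid that oversamples the sensor pitch 4x, multiplied
by the sample field, propagated by the exact band-limited angular-spectrum
kernel over `z`, and box-integrated onto sensor pixels. A raised-cosine
illumination taper occupies half of a 32-pixel guard border (cropped from
all outputs) so the spectral propagator's periodic wrap-around never touches
the image; the same taper is applied to the reference and the measurement,
so a flat sample reproduces the reference exactly.

Two modelling choices deserve emphasis:

* **Mask edge rounding.** An ideal sharp-edged 0/pi mask scatters roughly a
  third of its speckle power beyond the sensor Nyquist frequency. The
  fabricated mask is designed so that the speckle stays within the pixel
  sampling cutoff, which a lithographic mask achieves through its finite
  edge transition (and broadband illumination smooths further). We model
  this as a Gaussian rounding of the complex mask transmission
  (`edge_sigma_um`, default 2 um), which brings the beyond-Nyquist power
  under 10% while keeping speckle contrast near 0.8.
* **Monochromatic light.** The simulation runs at the nominal wavelength.
  This is adequate for OPD-level questions (the encoded displacement is
  wavelength-free), but it does not reproduce the additional speckle
  smoothing of a broadband source, so the simulated phase transfer function
  (below) is if anything pessimistic at high spatial frequencies. Additive
  Gaussian read noise and Poisson shot noise can be toggled on with
  `add_sensor_noise()`; fill-factor effects and fixed-pattern nonuniformity
  are not modelled. Passing tests demonstrate correctness of the algorithms
  under the stated physics, not robustness to every camera artefact.

Phantoms with stored analytic ground truth cover the validation experiments:
`microlens_phantom()` (spherical-sag plano-convex lenslet arrays; 150 um
pitch, 6.7 mm back focal length, n = 1.46 by default, with an optional
imaging `magnification` that stretches the pattern laterally as a conjugate
objective would while leaving OPD untouched), `sinusoid_phantom()` and
`curvature_phantom()` for transfer analysis, `cell_phantom()` (a torus-
shaped OPD with an optional central amplitude dip, emulating the bowl-like
indentation of a red blood cell tangled with absorption; its ~0.4 um peak
OPD is a fixture choice, not a measured quantity), and `tilt_phantom()` for
calibration. Lenslet junction cusps genuinely fold the ray model (the
curvature factor crosses zero on a thin set); the wave simulator handles
them physically, while `geometric_forward()` clamps the factor there with a
diagnostic warning.

## The joint reconstruction problem

`solve_joint()` estimates the wavefront and the modulated intensity from a
single image pair by minimizing

    || I(r + c grad phi) - v I0 ||_2^2
      + alpha ||grad phi||_1 + beta (||grad phi||_2^2 + ||lap phi||_2^2)
      + gamma (||grad v||_1 + ||lap v||_1) + tau (||grad v||_2^2 + ||lap v||_2^2)

with images normalized to the 0–255 gray scale, on which the default
weights `alpha = 0.1, beta = 0.1, gamma = 100, tau = 5` are calibrated
(`solver_params()`). The two unknowns alternate (3 outer steps by default):
the phase subproblem is Gauss–Newton-linearized around the current warp and
solved by scaled-form ADMM (soft-thresholding for the L1 terms, duals
zero-initialized, a DCT-preconditioned conjugate-gradient inner solve for
the quadratic normal equations); the intensity subproblem is a per-pixel
quadratic data fit under its own L1/L2 priors, solved by the same
machinery. The ADMM penalty is 1.0 for the phase block and `max(1, gamma)`
for the intensity block — with a penalty of 1 the L1 duals of the strongly
weighted intensity prior would take thousands of iterations to activate,
whereas `rho ~ gamma` puts the threshold `gamma / rho` at order one on the
normalized scale. After the alternation, the affine plane is removed from
the wavefront (`remove_tilt()`, the standard step that isolates the sample
from coverslip or alignment tilt) and the amplitude is caustic-corrected.

### Why speckle data needs more than textbook Gauss–Newton

The sensor samples its speckle close to the Nyquist rate, which breaks two
silent assumptions of standard warping optimization. The solver therefore
adds four safeguards, each of which was found necessary:

1. **Sinc-upsampled warping.** Interpolating near-Nyquist speckle with a
   polynomial kernel corrupts the data term enough that the true wavefront
   no longer comes close to minimizing it. All warps therefore sample a 4x
   Fourier (sinc) upsampled copy of the measurement; the forward model uses
   the same resampling.
2. **Increment smoothing.** Pointwise, a speckle pattern can be re-matched
   by many small displacement fields: the unregularized linearized step is
   dominated by a non-physical pixel-scale "zigzag" solution that fits the
   data *better* than the truth (the published prior weights are far too
   small to prevent this; they shape the solution, they do not select the
   basin). Each Gauss–Newton increment therefore carries a smoothness
   penalty proportional to the mean data-term curvature
   (`increment_smooth`, default 0.5, decaying geometrically over the pass
   schedule). Because the penalty acts on the increment rather than the
   accumulated phase, it vanishes at convergence and does not shrink the
   final wavefront.
3. **A data pre-filter floor.** Gauss–Newton passes run over a decreasing
   Gaussian pre-filter schedule (graduated non-convexity), but the schedule
   floors at `data_smooth_px = 0.7` px rather than 0: pre-filtering
   commutes with the displacement, so it leaves the encoded slopes
   unbiased, while passes on the raw Nyquist speckle demonstrably shrink
   the recovered wavefront by ~15% (a regression-dilution-type bias of the
   linearized matching). The solver's objective — including the reported
   trace — is defined at this smoothing level; `eval_objective()` exposes
   the unsmoothed textbook objective for reference.
4. **Tracking initialization and a monotonicity safeguard.** The phase is
   initialized from windowed cross-correlation tracking integrated by a
   Poisson solve (`init = "track"`; `init = "zero"` is available), and
   every accepted update must not increase the objective — a backtracking
   safeguard makes the outer objective trace non-increasing by
   construction. A coarse-to-fine pyramid engages automatically when the
   expected displacement exceeds 3 px.

`curl_free_flow()` is the phase-only ablation (amplitude and caustic factor
not modelled) and `track_slopes()` + `integrate_slopes()` the classical
sequential baseline; all three share formats so paired comparisons are
one-liners. On synthetic absorbing cells the expected ordering — joint
error at or below both baselines, with the pure-flow methods missing the
central indentation — reproduces, which is the computational heart of the
method's claim.

### Problem sizes and accuracy

The test suite and the bundled validation scripts run at desk scale: 96–192
px sensor images (384–768 px simulation grids), chosen so the full suite
completes in minutes while every claim remains sharp. At these sizes the
solver recovers smooth pure-phase wavefronts pushed through the wave
simulator to ~1–3% RMS of range, magnified lenslet arrays to <5% of the
sag, and the modulated intensity to <2% RMS; identical input images recover
a flat transparent sample to machine precision.

## Calibration, refocusing, and the phase transfer function

`calibrate_sensor_distance()` closes the loop on the distance calibration:
known tilts spanning 0.5–3 px of speckle shift are simulated, tracked by
upsampled-DFT cross-correlation, and inverted through the tilt-to-shift
scaling; the mean implied distance recovers the simulated 1.43 mm to well
within 2%.

`refocus_field()` propagates the recovered complex field (OPD converted to
phase at the nominal wavelength) by the angular-spectrum method, and
`find_best_focus()` sweeps a defocus range. Its metric is the peak
intensity *compensated by the geometric spreading factor* `(delta f)^2`:
the on-axis irradiance of a converging beam is a symmetric function of
`(1/z - 1/f)` divided by `z^2`, so for lenslets whose Fresnel number
`a^2 / (lambda f)` is of order one (1.6 for the 150 um / 6.7 mm lenslet)
the raw intensity peak is focal-shifted toward the aperture by 20–25%,
while the compensated peak sits at the paraxial focus. With this metric the
simulated lenslet refocuses to its design back focal length within 1%, and
the phase cross-sections evolve from converging through flat to diverging
across the focus.

`measure_phase_transfer()` quantifies wavefront resolution: sinusoidal OPD
phantoms `H cos(omega x)` are pushed through the wave simulator and
reconstructed, and the `valid` score `1 - relative RMS error` (clipped to
[0, 1]) is tabulated over `(H, omega)`. Recovery degrades monotonically
with the curvature `H omega^2` and collapses well before the geometric
bound `1/z` — reproducing the qualitative shape of the measured transfer
function, whose exact failure onset is a property of the physical
prototype. In the monochromatic simulation the recovery is additionally
attenuated at higher `omega` by speckle diffusion over the propagation
distance, an effect intrinsic to the sensing physics rather than to the
solver (ray-model data at the same frequencies reconstructs to ~1%).

## Degenerate inputs and numerical conventions

All lengths are micrometres; images are `rows = y`, `columns = x` with a
pixel-centred origin at the grid centre. Derivatives are forward
differences with replicate (Neumann) boundaries, the Laplacian is the
5-point stencil `-(Dx'Dx + Dy'Dy)` — chosen so every operator/adjoint pair
used by the solver is exact — and Poisson solves use the DCT eigenbasis of
that operator (zero-mean gauge). Textureless tracking windows are flagged
and inpainted from neighbours; an all-zero reference, incongruent grids,
non-positive distances and out-of-range parameters raise immediate errors;
amplitude correction clamps its square root at 1e-3 with a diagnostic
count. Zero-curvature, zero-amplitude and flat-field limits of every
generator return exact degenerate outputs rather than approximations.

## Known limitations

* The simulator is monochromatic and noise-free by default (optional
  Gaussian/Poisson noise can be added externally); quantitative transfer
  numbers at high `omega` will differ from a broadband prototype.
* The geometric data model ignores diffraction of the *sample* field over
  `z`; agreement with the wave simulator at the image level is ~20% RMS of
  the speckle amplitude (the flow-level agreement that drives
  reconstruction accuracy is within 5%).
* Reconstruction resolution is limited by the solver's pre-filter floor and
  by speckle diffusion; wavefront features below ~15 sensor pixels are
  attenuated.
* The amplitude/caustic separation relies on `|z lap OPD| << 1`; beyond
  roughly half that bound the recovered bright-field image mixes absorption
  with caustic modulation, as the model predicts.
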