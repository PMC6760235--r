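# specklephase

Snapshot quantitative phase and intensity microscopy with a coded wavefront
sensor, in R.

Most living cells are nearly transparent: bright-field microscopy shows
little, and classical phase-contrast or DIC images are only qualitative. A
coded wavefront sensor turns an ordinary camera into a quantitative phase
imager with one cheap part: a random binary (0/π) phase mask placed
z ≈ 1.5 mm in front of the pixels. The mask casts a fixed diffraction
speckle pattern (the reference image *I*₀); a sample in the light path
tilts the wavefront φ locally, and the speckle translates by

&nbsp;&nbsp;&nbsp;&nbsp;**u**(**r**) = (λz/2π) ∇φ(**r**) = z ∇OPD(**r**),

while wavefront curvature and sample absorption modulate its brightness:

&nbsp;&nbsp;&nbsp;&nbsp;I(**r** + (λz/2π)∇φ) = |A(**r**)|² (1 − (λz/2π)∇²φ) I₀(**r**).

From a *single* measurement image this package jointly recovers the sample
amplitude A and the wavefront (as optical path difference, OPD, in µm) by
minimizing

&nbsp;&nbsp;&nbsp;&nbsp;‖I(**r** + (λz/2π)∇φ) − |Ã|² I₀‖₂² + α‖∇φ‖₁ +
β(‖∇φ‖₂² + ‖∇²φ‖₂²) + γ(‖∇|Ã|²‖₁ + ‖∇²|Ã|²‖₁) + τ(‖∇|Ã|²‖₂² + ‖∇²|Ã|²‖₂²)

by alternating Gauss–Newton / ADMM steps, then removing the caustic factor
(A = Ã √(1 + (λz/2π)∇²φ)) and the best-fit tilt plane. Because everything
depends on the wavefront only through the OPD, the method works under
broadband illumination; 532.8 nm is used as the nominal wavelength.

The package contains the full tool chain:

* **Sensor simulator** — random 0/π mask synthesis, band-limited
  angular-spectrum propagation, area-integrating pixel sampling
  (`make_mask()`, `simulate_reference()`, `simulate_measurement()`,
  `simulate_speckle_pair()`).
* **Phantoms with analytic truth** — microlens arrays, sinusoidal and
  constant-curvature wavefronts, torus-shaped cell OPDs, tilts
  (`microlens_phantom()`, `sinusoid_phantom()`, `curvature_phantom()`,
  `cell_phantom()`, `tilt_phantom()`).
* **Reconstruction** — the joint solver (`solve_joint()`), the curl-free
  optical-flow and windowed slope-tracking baselines (`curl_free_flow()`,
  `track_slopes()`, `integrate_slopes()`), and the transport-of-intensity
  model used as an analytic cross-check (`tie_predict()`, `tie_solve()`).
* **Calibration & refocusing** — closed-loop mask-to-sensor distance
  calibration (`calibrate_sensor_distance()`), digital refocusing and best
  focus search (`refocus_field()`, `find_best_focus()`), wavefront
  resolution analysis (`measure_phase_transfer()`, `h_upper_bound()`,
  `curvature_upper_bound()`).
* **Files & CLI** — TIFF/YAML/CSV/JSON I/O (`run_simulate()`,
  `run_reconstruct()`, `run_refocus()`, `run_calibrate()`,
  `run_transfer()`) and a thin command-line wrapper at
  `inst/cli/specklephase.R` with those five subcommands.

See the vignette (`vignettes/coded-wavefront-sensing.Rmd`) for the models,
the solver's numerical design, and known limitations.

## Worked example

Simulate a red-blood-cell-like phantom (a 0.4 µm torus-shaped OPD with a
25% central absorption dip) through the wave-optics sensor model, then
reconstruct it from the speckle pair:

```r
library(specklephase)

geom <- sensor_geometry()      # z = 1.43 mm, 532.8 nm, 6.45 um pixels
shape <- c(96L, 96L)
sim_grid <- sensor_sim_shape(shape)

cell <- cell_phantom("torus", peak_opd_um = 0.4, amplitude_dip = 0.25,
                     grid = sim_grid, sample_pitch_um = geom$sensor_pitch_um / 4)
pair <- simulate_speckle_pair(cell, geom, shape, seed = 1)

rec <- solve_joint(pair$I0, pair$I, geom)
rec
#> <recon_result> 96 x 96 px, OPD range [-0.08496, 0.3729] um, residual RMS 5.744, 3 outer steps

truth <- remove_tilt(pair$truth_opd)$opd_um
err <- sqrt(mean((rec$wavefront$opd_um - truth)^2))
sprintf("OPD RMS error: %.4f um (%.1f%% of the %.2f um range)",
        err, 100 * err / diff(range(truth)), diff(range(truth)))
#> "OPD RMS error: 0.0118 um (3.0% of the 0.40 um range)"

flow <- curl_free_flow(pair$I0, pair$I, geom)   # phase-only baseline
sqrt(mean((flow$opd_um - truth)^2))
#> 0.0141
```

The joint solver recovers the 0.40 µm cell profile to 12 nm RMS (3% of the
range) and, because it models the amplitude dip, beats the phase-only flow
baseline (14 nm) — the absorbing-sample regime where sequential
speckle-tracking methods fail to reconstruct the bowl-like indentation.
`rec$amplitude` holds the caustic-corrected bright-field image with the
speckle fully removed, and `rec$objective_trace` the (non-increasing)
objective values.

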