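# Shared fixtures, built lazily and memoized so expensive simulations run
# once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_geometry <- function() sensor_geometry()

# reference speckle image on a 96 x 96 sensor grid (mask seed 1)
fx_ref96 <- function() {
  fixture("ref96", function() {
    g <- fx_geometry()
    shape <- c(96L, 96L)
    ss <- sensor_sim_shape(shape)
    mask <- make_mask(1L, ss, g)
    list(geometry = g, shape = shape, sim_shape = ss,
         sim_pitch = g$sensor_pitch_um / 4,
         mask = mask,
         I0 = simulate_reference(mask, g, shape))
  })
}

# wave-optics pair for a smooth pure-phase blob (max displacement ~0.4 px)
fx_wave_blob <- function() {
  fixture("wave_blob", function() {
    r <- fx_ref96()
    ph <- cell_phantom("blob", peak_opd_um = 0.35, width_um = 110,
                       grid = r$sim_shape, sample_pitch_um = r$sim_pitch)
    pair <- simulate_speckle_pair(ph, r$geometry, r$shape, seed = 1L)
    c(pair, list(phantom = ph))
  })
}

# wave-optics pair for an absorbing torus cell (the amplitude/refraction
# tangle case)
fx_wave_torus <- function() {
  fixture("wave_torus", function() {
    r <- fx_ref96()
    ph <- cell_phantom("torus", peak_opd_um = 0.4, width_um = 110,
                       dip_width_um = 55, amplitude_dip = 0.25,
                       grid = r$sim_shape, sample_pitch_um = r$sim_pitch)
    pair <- simulate_speckle_pair(ph, r$geometry, r$shape, seed = 1L)
    c(pair, list(phantom = ph))
  })
}

# joint reconstruction of the wave blob (reused by several tests)
fx_joint_blob <- function() {
  fixture("joint_blob", function() {
    p <- fx_wave_blob()
    solve_joint(p$I0, p$I, fx_geometry())
  })
}

rel_rms_error <- function(est_wf, truth_wf) {
  truth <- remove_tilt(truth_wf)$opd_um
  est <- est_wf$opd_um - mean(est_wf$opd_um)
  rms(est - truth) / diff(range(truth))
}

rms <- function(x) sqrt(mean(x^2))

expect_nonincreasing <- function(trace, slack = 1e-6) {
  drops <- diff(trace)
  expect_true(all(drops <= slack * pmax(1, abs(trace[-length(trace)]))),
              label = paste("objective trace non-increasing:",
                            paste(signif(trace, 6), collapse = " ")))
}
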