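# Coded-wavefront-sensor simulator: mask synthesis, angular-spectrum
# propagation, and speckle image generation.

test_that("mask synthesis is deterministic, binary, and feature-blocked", {
  g <- fx_geometry()
  ss <- sensor_sim_shape(c(32L, 32L))
  m1 <- make_mask(0L, ss, g)
  m2 <- make_mask(0L, ss, g)
  expect_identical(m1$values, m2$values)
  expect_true(all(m1$values %in% c(0L, 1L)))
  # 12.9 um features at 6.45/4 um simulation pitch: 8-sample blocks
  expect_identical(m1$block_px, 8L)
  # different seed, different pattern
  m3 <- make_mask(99L, ss, g)
  expect_false(identical(m1$values, m3$values))
  expect_error(make_mask(0L, c(-4L, 8L), g), "positive")
})

test_that("mask fill fraction is binomially consistent with 1/2", {
  g <- fx_geometry()
  m <- make_mask(7L, sensor_sim_shape(c(256L, 256L)), g)
  n <- length(m$values)
  expect_lt(abs(mean(m$values) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("angular-spectrum propagation is unitary and identity at zero", {
  g <- fx_geometry()
  n <- 128L
  ax <- (1:n - (n + 1) / 2) * 1.6
  amp <- exp(-outer(ax^2, ax^2, `+`) / (2 * 20^2))
  fld <- complex_field(amp, matrix(0.3, n, n), 1.6, g$wavelength_um)
  expect_identical(angular_spectrum_propagate(fld, 0), fld)
  fwd <- angular_spectrum_propagate(fld, 800)
  back <- angular_spectrum_propagate(fwd, -800)
  u0 <- amp * exp(1i * 0.3)
  ub <- back$amplitude * exp(1i * back$phase_rad)
  expect_lt(max(Mod(ub - u0)) / max(Mod(u0)), 1e-6)
  # energy conservation (field well inside the propagating band)
  expect_equal(sum(fwd$amplitude^2), sum(amp^2), tolerance = 1e-6)
})

test_that("a tilted beam's intensity centroid shifts by the ray-optics law", {
  g <- fx_geometry()
  n <- 256L
  pitch <- 1.6
  ax <- (1:n - (n + 1) / 2) * pitch
  amp <- exp(-outer(ax^2, ax^2, `+`) / (2 * 30^2))
  s <- 0.05                                  # phase slope, rad/um (along x)
  phase <- matrix(rep(s * ax, each = n), n, n)
  fld <- complex_field(amp, phase, pitch, g$wavelength_um)
  z <- 1430
  I <- Mod(specklephase:::field_complex_values(angular_spectrum_propagate(fld, z)))^2
  cx0 <- sum(t(amp^2) * ax) / sum(amp^2)
  cx1 <- sum(t(I) * ax) / sum(I)
  expected <- z * g$wavelength_um * s / (2 * pi)
  expect_equal(cx1 - cx0, expected, tolerance = pitch / expected)
})

test_that("reference image is a speckle pattern within the sensor bandwidth", {
  r <- fx_ref96()
  I0 <- r$I0
  expect_gt(stats::sd(I0$values) / mean(I0$values), 0.1)
  # spectral content of the fine-grid diffraction pattern beyond the sensor
  # Nyquist frequency is a small fraction of the total AC power
  g <- r$geometry
  Tm <- specklephase:::mask_transmission(r$mask)
  f0 <- complex_field(Mod(Tm), Arg(Tm), r$sim_pitch, g$wavelength_um)
  If <- Mod(specklephase:::field_complex_values(
    angular_spectrum_propagate(f0, g$z_um)))^2
  S <- Mod(stats::fft(If - mean(If)))^2
  fy <- specklephase:::fft_freq_idx(nrow(If)) / (nrow(If) * r$sim_pitch)
  fx <- specklephase:::fft_freq_idx(ncol(If)) / (ncol(If) * r$sim_pitch)
  nyq <- 0.5 / g$sensor_pitch_um
  beyond <- outer(abs(fy) > nyq, rep(TRUE, length(fx))) |
    outer(rep(TRUE, length(fy)), abs(fx) > nyq)
  expect_lt(sum(S[beyond]) / sum(S), 0.10)
})

test_that("an all-zero mask phase produces a uniform (non-speckle) image", {
  g <- fx_geometry()
  shape <- c(48L, 48L)
  ss <- sensor_sim_shape(shape)
  m <- make_mask(0L, ss, g)
  m$values[] <- 0L
  I0 <- simulate_reference(m, g, shape)
  expect_lt(stats::sd(I0$values) / mean(I0$values), 1e-4)
})

test_that("a flat unit-amplitude sample reproduces the reference exactly", {
  r <- fx_ref96()
  flat <- tilt_phantom(0, 0, grid = r$sim_shape, sample_pitch_um = r$sim_pitch)
  I <- simulate_measurement(r$mask, r$geometry, phantom_field(flat, r$geometry$wavelength_um))
  expect_identical(I$values, r$I0$values)
})

test_that("a tilt shifts the speckle pattern by (lambda z / 2 pi) grad(phi)", {
  r <- fx_ref96()
  g <- r$geometry
  for (px_shift in c(0.8, 1.5)) {
    gslope <- px_shift * g$sensor_pitch_um / g$z_um   # OPD slope
    ph <- tilt_phantom(gslope, 0, grid = r$sim_shape, sample_pitch_um = r$sim_pitch)
    I <- simulate_measurement(r$mask, g, phantom_field(ph, g$wavelength_um))
    s <- specklephase:::estimate_shift(r$I0$values, I$values, upsample = 200L)
    expect_equal(s[["dx"]], px_shift, tolerance = 0.05 * px_shift)
    expect_lt(abs(s[["dy"]]), 0.05)
  }
})

test_that("microlens speckle flow points along the analytic OPD gradient", {
  r <- fx_ref96()
  g <- r$geometry
  ph <- microlens_phantom(grid = r$sim_shape, sample_pitch_um = r$sim_pitch,
                          magnification = 5)
  I <- simulate_measurement(r$mask, g, phantom_field(ph, g$wavelength_um))
  sl <- track_slopes(r$I0, I, g, window_px = 16L, stride = 8L)
  truth_opd <- specklephase:::crop_guard(
    specklephase:::box_downsample(ph$wavefront$opd_um, 4L), 32L)
  gx <- specklephase:::dx_forward(truth_opd) / g$sensor_pitch_um
  gy <- specklephase:::dy_forward(truth_opd) / g$sensor_pitch_um
  ux_true <- g$z_um * gx / g$sensor_pitch_um      # px
  uy_true <- g$z_um * gy / g$sensor_pitch_um
  sel <- sqrt(ux_true^2 + uy_true^2) > 0.1
  cosang <- (sl$dx * ux_true + sl$dy * uy_true)[sel] /
    (sqrt(sl$dx^2 + sl$dy^2) * sqrt(ux_true^2 + uy_true^2))[sel]
  expect_gt(mean(cosang), 0.7)
})

test_that("sensor noise toggles behave statistically and reproducibly", {
  r <- fx_ref96()
  clean <- r$I0
  noisy <- add_sensor_noise(clean, gaussian_sd = 0.02, seed = 4L)
  expect_identical(add_sensor_noise(clean, gaussian_sd = 0.02, seed = 4L)$values,
                   noisy$values)
  expect_equal(stats::sd(noisy$values - clean$values), 0.02, tolerance = 0.1)
  shot <- add_sensor_noise(clean, photons_per_unit = 1e4, seed = 5L)
  expect_equal(mean(shot$values), mean(clean$values), tolerance = 0.01)
  expect_gt(stats::sd(shot$values - clean$values), 0)
  # disabled toggles are the identity
  expect_identical(add_sensor_noise(clean)$values, clean$values)
})

test_that("simulation is bit-reproducible for identical seeds", {
  g <- fx_geometry()
  shape <- c(32L, 32L)
  ss <- sensor_sim_shape(shape)
  I_a <- simulate_reference(make_mask(5L, ss, g), g, shape)
  I_b <- simulate_reference(make_mask(5L, ss, g), g, shape)
  expect_identical(I_a$values, I_b$values)
})
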