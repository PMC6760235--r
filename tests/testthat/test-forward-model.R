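# Geometric forward model and its transport-of-intensity linearization.

test_that("curvature factor: flat wavefront, constant curvature, and bounds", {
  g <- fx_geometry()
  flat <- wavefront_map(matrix(0, 32, 32), g$sensor_pitch_um)
  expect_equal(curvature_factor(flat, g), matrix(1, 32, 32))
  # constant curvature c: factor = 1 - z c everywhere (lambda cancels at
  # fixed OPD); c = 75 / m at z = 1.43 mm gives ~0.893
  ph <- curvature_phantom(75, grid = c(48L, 48L), sample_pitch_um = g$sensor_pitch_um)
  # boundary rows carry the Neumann closure artefact of the paraboloid;
  # assert on the interior
  fac <- suppressWarnings(curvature_factor(ph$wavefront, g))[5:44, 5:44]
  expect_equal(mean(fac), 1 - 1430e-6 * 75, tolerance = 1e-6)
  expect_lt(diff(range(fac)), 1e-9)
  expect_equal(1 - 0.00143 * 75, 0.89275, tolerance = 1e-12)
  # wavelength invariance at fixed OPD
  wf2 <- wavefront_map(ph$wavefront$opd_um, g$sensor_pitch_um, wavelength_um = 0.633)
  expect_equal(suppressWarnings(curvature_factor(wf2, g)),
               suppressWarnings(curvature_factor(ph$wavefront, g)))
  # model-validity error when the factor folds through zero
  steep <- curvature_phantom(900, grid = c(48L, 48L),
                             sample_pitch_um = g$sensor_pitch_um)
  expect_error(suppressWarnings(curvature_factor(steep$wavefront, g)),
               "validity")
})

test_that("geometric forward model: identity, tilt shift, flux", {
  r <- fx_ref96()
  g <- r$geometry
  flat <- tilt_phantom(0, 0, grid = r$shape, sample_pitch_um = g$sensor_pitch_um)
  expect_equal(geometric_forward(r$I0, flat, g)$values, r$I0$values,
               tolerance = 1e-12)
  # pure tilt: output is the reference shifted by the analytic displacement
  px <- 1.2
  ph <- tilt_phantom(px * g$sensor_pitch_um / g$z_um, 0, grid = r$shape,
                     sample_pitch_um = g$sensor_pitch_um)
  # the ramp's Neumann boundary closure folds the factor on the last
  # column; the clamp warning is expected
  I <- suppressWarnings(geometric_forward(r$I0, ph, g))
  s <- specklephase:::estimate_shift(r$I0$values, I$values, upsample = 100L)
  expect_equal(s[["dx"]], px, tolerance = 0.05)
  # flux preserved away from boundaries
  inner <- 17:80
  expect_equal(sum(I$values[inner, inner]), sum(r$I0$values[inner, inner]),
               tolerance = 0.01)
  bad <- tilt_phantom(0, 0, grid = c(10L, 10L), sample_pitch_um = g$sensor_pitch_um)
  expect_error(geometric_forward(r$I0, bad, g), "congruent")
})

test_that("wave simulation and ray model agree on a smooth phantom", {
  r <- fx_ref96()
  p <- fx_wave_blob()
  g <- r$geometry
  ph_coarse <- cell_phantom("blob", peak_opd_um = 0.35, width_um = 110,
                            grid = r$shape, sample_pitch_um = g$sensor_pitch_um)
  I_ray <- geometric_forward(r$I0, ph_coarse, g)
  inner <- 17:80
  diff_rms <- rms((I_ray$values - p$I$values)[inner, inner])
  speckle_rms <- stats::sd(r$I0$values)
  expect_lt(diff_rms / speckle_rms, 0.25)
})

test_that("transport predictor: identity and first-order curvature response", {
  g <- fx_geometry()
  I1 <- intensity_image(matrix(100, 48, 48), g$sensor_pitch_um)
  flat <- wavefront_map(matrix(0, 48, 48), g$sensor_pitch_um)
  expect_equal(tie_predict(I1, flat, 1430)$values, I1$values)
  ph <- curvature_phantom(30, grid = c(48L, 48L), sample_pitch_um = g$sensor_pitch_um)
  I2 <- tie_predict(I1, ph$wavefront, 1430, 0.5328)
  expect_equal(I2$values[24, 24] / 100, 1 - 1430e-6 * 30, tolerance = 1e-3)
})

test_that("transport predictor is the first-order Taylor of the warp model", {
  # periodic smooth reference + compact phantom keep both discretizations in
  # their accurate regime; halving z must quarter the max discrepancy
  h <- 6.45
  n <- 96L
  I1v <- 100 + 30 * cos(2 * pi * outer(rep(1, n), 1:n) / n * 3) *
    sin(2 * pi * outer(1:n, rep(1, n)) / n * 2)
  I1 <- intensity_image(I1v, h)
  ph <- cell_phantom("blob", peak_opd_um = 0.4, width_um = 80,
                     grid = c(n, n), sample_pitch_um = h)
  dmax <- function(z) {
    gz <- sensor_geometry(z_um = z)
    Ig <- geometric_forward(I1, ph, gz)
    It <- tie_predict(I1, ph$wavefront, z, 0.5328, gradient = "spectral")
    max(abs(Ig$values - It$values)[17:80, 17:80])
  }
  ratio <- dmax(800) / dmax(400)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.2)
})

test_that("transport solver inverts the predictor on smooth wavefronts", {
  g <- fx_geometry()
  I1 <- intensity_image(matrix(100, 96, 96), g$sensor_pitch_um)
  ph <- cell_phantom("blob", peak_opd_um = 0.3, width_um = 120,
                     grid = c(96L, 96L), sample_pitch_um = g$sensor_pitch_um)
  I2 <- tie_predict(I1, ph$wavefront, 1430, 0.5328)
  wf <- tie_solve(I1, I2, 1430, 0.5328)
  truth <- ph$wavefront$opd_um - mean(ph$wavefront$opd_um)
  expect_lt(rms(wf$opd_um - truth) / diff(range(truth)), 0.02)
  # identical images give a zero wavefront
  zero <- tie_solve(I1, I1, 1430, 0.5328)
  expect_lt(max(abs(zero$opd_um)), 1e-10)
  expect_error(tie_solve(intensity_image(matrix(0, 8, 8), 6.45),
                         intensity_image(matrix(1, 8, 8), 6.45), 1430),
               "positive")
})

test_that("transport solver matches a dense least-squares oracle", {
  # small grid: build the two-step inversion explicitly from dense Neumann
  # difference matrices and compare
  n <- 8L
  h <- 2
  set.seed(21)
  D1 <- diag(-1, n); D1[cbind(1:(n - 1), 2:n)] <- 1; D1[n, n] <- 0
  Dx <- kronecker(D1, diag(n))    # columns vary fastest? build both and test
  Dy <- kronecker(diag(n), D1)
  L <- -(t(Dx) %*% Dx + t(Dy) %*% Dy)
  I1v <- matrix(3 + runif(n * n), n, n)
  phi_true <- as.vector(outer((1:n)^2, (1:n), `+`)) / 50
  # src = div(I1 grad phi) in the package's discretization
  gpx <- Dx %*% phi_true / h; gpy <- Dy %*% phi_true / h
  src <- -(t(Dx) %*% (as.vector(I1v) * gpx) + t(Dy) %*% (as.vector(I1v) * gpy)) / h
  z <- 500; lam <- 0.5
  k <- 2 * pi / lam
  I2v <- matrix(as.vector(I1v) - as.numeric(z / k * src), n, n)
  wf <- tie_solve(intensity_image(I1v, h), intensity_image(I2v, h), z, lam)
  phi_est <- 2 * pi * wf$opd_um / lam
  # compare against dense pseudo-inverse route (zero-mean gauge)
  psi <- MASS::ginv(L / h^2) %*% src
  g2 <- (Dx %*% psi / h) / as.vector(I1v)
  g3 <- (Dy %*% psi / h) / as.vector(I1v)
  rhs2 <- -(t(Dx) %*% g2 + t(Dy) %*% g3) / h
  phi_dense <- MASS::ginv(L / h^2) %*% rhs2
  phi_dense <- phi_dense - mean(phi_dense)
  expect_equal(as.vector(phi_est), as.numeric(phi_dense), tolerance = 1e-6)
})
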