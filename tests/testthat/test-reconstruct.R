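# Joint solver, objective, post-processing, and the sequential baselines.

test_that("objective: exact zero at the null solution and piston invariance", {
  r <- fx_ref96()
  g <- r$geometry
  flat <- wavefront_map(matrix(0, 96, 96), g$sensor_pitch_um)
  v1 <- matrix(1, 96, 96)
  expect_equal(eval_objective(flat, v1, r$I0, r$I0, g), 0)
  # adding a constant to the wavefront changes nothing (gradient terms only)
  p <- fx_wave_blob()
  wf <- wavefront_map(matrix(0.3, 96, 96), g$sensor_pitch_um)
  e_piston <- eval_objective(wf, v1, r$I0, p$I, g)
  e_zero <- eval_objective(flat, v1, r$I0, p$I, g)
  expect_equal(e_piston, e_zero, tolerance = 1e-10)
  expect_error(eval_objective(flat, matrix(NaN, 96, 96), r$I0, p$I, g), "finite")
})

test_that("objective matches a brute-force evaluation on a tiny grid", {
  # independent re-implementation with explicit loops on a 4 x 4 case
  set.seed(31)
  g <- sensor_geometry(z_um = 1000, wavelength_um = 0.5, sensor_pitch_um = 5)
  n <- 4L
  I0v <- matrix(5 + runif(n * n, 0, 5), n, n)
  Iv <- matrix(5 + runif(n * n, 0, 5), n, n)
  opd <- matrix(rnorm(n * n, 0, 0.02), n, n)
  v <- matrix(1 + rnorm(n * n, 0, 0.05), n, n)
  params <- solver_params(alpha = 0.3, beta = 0.2, gamma = 2, tau = 0.5)

  sc <- 255 / max(I0v)
  I0n <- I0v * sc; In <- Iv * sc
  phi <- 2 * pi * opd / g$wavelength_um
  cpix <- g$wavelength_um * g$z_um / (2 * pi * g$sensor_pitch_um^2)
  dxm <- function(u) { o <- u * 0; for (i in 1:n) for (j in 1:(n - 1)) o[i, j] <- u[i, j + 1] - u[i, j]; o }
  dym <- function(u) { o <- u * 0; for (j in 1:n) for (i in 1:(n - 1)) o[i, j] <- u[i + 1, j] - u[i, j]; o }
  lapm <- function(u) {
    o <- u * 0
    for (i in 1:n) for (j in 1:n) {
      up <- u[max(i - 1, 1), j]; dn <- u[min(i + 1, n), j]
      lf <- u[i, max(j - 1, 1)]; rt <- u[i, min(j + 1, n)]
      o[i, j] <- up + dn + lf + rt - 4 * u[i, j]
    }
    o
  }
  # warp by sampling the sinc-upsampled measurement (as documented), with an
  # explicit Catmull-Rom evaluation independent of the package's interpolator
  fine <- specklephase:::fft_upsample(In, 4L)
  crw <- function(t) c((-t^3 + 2 * t^2 - t) / 2, (3 * t^3 - 5 * t^2 + 2) / 2,
                       (-3 * t^3 + 4 * t^2 + t) / 2, (t^3 - t^2) / 2)
  cr_interp <- function(img, xq, yq) {
    nr <- nrow(img); nc <- ncol(img)
    j0 <- floor(xq); i0 <- floor(yq)
    wx <- crw(xq - j0); wy <- crw(yq - i0)
    acc <- 0
    for (a in -1:2) for (b in -1:2) {
      ii <- min(max(i0 + a, 1), nr); jj <- min(max(j0 + b, 1), nc)
      acc <- acc + wy[a + 2] * wx[b + 2] * img[ii, jj]
    }
    acc
  }
  ux <- cpix * dxm(phi); uy <- cpix * dym(phi)
  Iw <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Iw[i, j] <- cr_interp(fine, (j + ux[i, j] - 1) * 4 + 1,
                          (i + uy[i, j] - 1) * 4 + 1)
  }
  expected <- sum((Iw - v * I0n)^2) +
    params$alpha * (sum(abs(dxm(phi))) + sum(abs(dym(phi)))) +
    params$beta * (sum(dxm(phi)^2) + sum(dym(phi)^2) + sum(lapm(phi)^2)) +
    params$gamma * (sum(abs(dxm(v))) + sum(abs(dym(v))) + sum(abs(lapm(v)))) +
    params$tau * (sum(dxm(v)^2) + sum(dym(v)^2) + sum(lapm(v)^2))
  got <- eval_objective(wavefront_map(opd, g$sensor_pitch_um, g$wavelength_um),
                        v, intensity_image(I0v, g$sensor_pitch_um),
                        intensity_image(Iv, g$sensor_pitch_um), g, params)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("tilt removal is exact on affine input, idempotent, and matches lm", {
  g <- fx_geometry()
  n <- 24L
  x <- matrix(rep(1:n, each = n), n, n); y <- matrix(rep(1:n, n), n, n)
  affine <- wavefront_map(2 + 0.3 * x - 0.7 * y, g$sensor_pitch_um)
  expect_lt(max(abs(remove_tilt(affine)$opd_um)), 1e-10)
  quad <- wavefront_map(0.01 * (x - 5)^2 + 0.02 * x * y, g$sensor_pitch_um)
  once <- remove_tilt(quad)
  twice <- remove_tilt(once)
  expect_equal(once$opd_um, twice$opd_um, tolerance = 1e-12)
  # against an independent least-squares fit
  fit <- stats::lm(as.vector(quad$opd_um) ~ as.vector(x) + as.vector(y))
  expect_equal(as.vector(once$opd_um), as.numeric(stats::residuals(fit)),
               tolerance = 1e-10)
  # output orthogonal to {1, x, y}
  expect_lt(abs(sum(once$opd_um)), 1e-8)
  expect_lt(abs(sum(once$opd_um * (x - mean(x)))), 1e-6)
  expect_lt(abs(sum(once$opd_um * (y - mean(y)))), 1e-6)
})

test_that("amplitude correction applies the caustic factor", {
  g <- fx_geometry()
  n <- 48L
  # flat wavefront: amplitude unchanged
  res_flat <- structure(list(
    wavefront = wavefront_map(matrix(0, n, n), g$sensor_pitch_um),
    modulated_intensity = matrix(0.81, n, n)), class = "recon_result")
  expect_equal(correct_amplitude(res_flat, g), matrix(0.9, n, n))
  # constant curvature c with flat modulated amplitude: A = sqrt(1 + z c)
  c_m <- 50
  ph <- curvature_phantom(c_m, grid = c(n, n), sample_pitch_um = g$sensor_pitch_um)
  res_c <- structure(list(wavefront = ph$wavefront,
                          modulated_intensity = matrix(1, n, n)),
                     class = "recon_result")
  A <- correct_amplitude(res_c, g)[5:44, 5:44]
  expect_equal(mean(A), sqrt(1 + 1430e-6 * c_m), tolerance = 1e-6)
  # composing the curvature factor with the correction recovers |A|^2 to
  # first order in z c
  v_exact <- suppressWarnings(curvature_factor(ph$wavefront, g))  # |A~|^2, A = 1
  res_x <- structure(list(wavefront = ph$wavefront,
                          modulated_intensity = v_exact),
                     class = "recon_result")
  A2 <- correct_amplitude(res_x, g)[5:44, 5:44]^2
  expect_equal(mean(A2), 1, tolerance = (1430e-6 * c_m)^2 * 1.5)
})

test_that("slope integration inverts the discrete gradient exactly", {
  g <- fx_geometry()
  n <- 64L
  x <- matrix(rep(1:n, each = n), n, n); y <- matrix(rep(1:n, n), n, n)
  phi_true <- 0.002 * (x - n / 2)^2 + 0.001 * (y - n / 3)^2
  cpix <- specklephase:::pixel_disp_scale(g)
  sl <- slope_field(cpix * specklephase:::dx_forward(phi_true),
                    cpix * specklephase:::dy_forward(phi_true), g)
  wf <- integrate_slopes(sl)
  phi_rec <- 2 * pi * wf$opd_um / g$wavelength_um
  truth <- phi_true - mean(phi_true)
  expect_lt(rms(phi_rec - truth) / diff(range(truth)), 1e-10)
  # zero slopes integrate to zero
  z0 <- integrate_slopes(slope_field(matrix(0, 8, 8), matrix(0, 8, 8), g))
  expect_equal(max(abs(z0$opd_um)), 0)
})

test_that("slope integration projects out the curl component", {
  # adding a pure-curl field to the slopes must not change the integral,
  # verified against a dense least-squares oracle on a small grid
  g <- fx_geometry()
  n <- 10L
  set.seed(32)
  D1 <- diag(-1, n); D1[cbind(1:(n - 1), 2:n)] <- 1; D1[n, n] <- 0
  Dx <- kronecker(D1, diag(n)); Dy <- kronecker(diag(n), D1)
  phi_true <- as.vector(0.1 * outer((1:n) / n, ((1:n) / n)^2, `+`))
  psi <- as.vector(matrix(rnorm(n * n), n, n))
  cpix <- specklephase:::pixel_disp_scale(g)
  sx <- Dx %*% phi_true + Dy %*% psi          # gradient + curl
  sy <- Dy %*% phi_true - Dx %*% psi
  wf <- integrate_slopes(slope_field(cpix * matrix(sx, n, n),
                                     cpix * matrix(sy, n, n), g))
  phi_rec <- 2 * pi * wf$opd_um / g$wavelength_um
  # dense normal-equation solution of min ||D phi - s||^2
  A <- rbind(Dx, Dy)
  phi_dense <- MASS::ginv(t(A) %*% A) %*% (t(A) %*% rbind(matrix(sx), matrix(sy)))
  phi_dense <- phi_dense - mean(phi_dense)
  expect_equal(as.vector(phi_rec), as.numeric(phi_dense), tolerance = 1e-6)
})

test_that("windowed tracking recovers known displacements", {
  r <- fx_ref96()
  g <- r$geometry
  # identical images: zero displacement
  sl0 <- track_slopes(r$I0, r$I0, g, window_px = 24L)
  expect_lt(max(abs(c(sl0$dx, sl0$dy))), 0.02)
  # global 2 px shift synthesized by exact spectral translation
  shifted <- specklephase:::fft_upsample(r$I0$values, 2L)
  Ish <- shifted[seq(1, 191, 2), seq(1, 191, 2) ]
  Ish <- cbind(Ish[, c(3:96, 95, 96)])        # integer 2 px shift along -x
  sl2 <- track_slopes(r$I0, intensity_image(pmax(Ish, 0), g$sensor_pitch_um),
                      g, window_px = 32L)
  expect_equal(mean(sl2$dx[, 9:80]), -2, tolerance = 0.1)
  # tilt phantom: tracked slopes match the analytic displacement within 5%
  px <- 1.5
  ph <- tilt_phantom(px * g$sensor_pitch_um / g$z_um, 0, grid = r$sim_shape,
                     sample_pitch_um = r$sim_pitch)
  I <- simulate_measurement(r$mask, g, phantom_field(ph, g$wavelength_um))
  sl <- track_slopes(r$I0, I, g, window_px = 32L)
  expect_equal(mean(sl$dx[9:88, 9:88]), px, tolerance = 0.05 * px)
  expect_error(track_slopes(r$I0, r$I0, g, window_px = 4L), "at least 8")
})

test_that("joint solver: null input recovers a flat pure-transmission sample", {
  r <- fx_ref96()
  res <- solve_joint(r$I0, r$I0, r$geometry)
  expect_lt(rms(res$wavefront$opd_um), 1e-3 * 1e-3)   # < 1 nm OPD
  expect_lt(rms(res$modulated_intensity - 1), 1e-3)
  expect_nonincreasing(res$objective_trace)
})

test_that("joint solver recovers phase and intensity from model-generated data", {
  r <- fx_ref96()
  g <- r$geometry
  ph <- cell_phantom("blob", peak_opd_um = 0.35, width_um = 110,
                     grid = r$shape, sample_pitch_um = g$sensor_pitch_um)
  I <- geometric_forward(r$I0, ph, g)
  res <- solve_joint(r$I0, I, g)
  expect_lt(rel_rms_error(res$wavefront, ph$wavefront), 0.05)
  v_true <- ph$amplitude^2 * curvature_factor(ph$wavefront, g)
  expect_lt(rms(res$modulated_intensity - v_true), 0.02)
  expect_nonincreasing(res$objective_trace)
})

test_that("joint solver recovers a microlens through the ray model", {
  g <- fx_geometry()
  shape <- c(128L, 128L)
  ss <- sensor_sim_shape(shape)
  mask <- make_mask(1L, ss, g)
  I0 <- simulate_reference(mask, g, shape)
  ph <- microlens_phantom(grid = shape, sample_pitch_um = g$sensor_pitch_um,
                          magnification = 5)
  I <- suppressWarnings(geometric_forward(I0, ph, g))
  res <- solve_joint(I0, I, g)
  truth <- remove_tilt(ph$wavefront)$opd_um
  expect_lt(rms(res$wavefront$opd_um - truth) / ph$truth$opd_drop_um, 0.05)
})

test_that("curl-free flow matches the joint solver on pure-phase samples", {
  p <- fx_wave_blob()
  g <- fx_geometry()
  res <- fx_joint_blob()
  cf <- curl_free_flow(p$I0, p$I, g)
  expect_lt(rel_rms_error(res$wavefront, p$truth_opd), 0.05)
  expect_lt(rel_rms_error(cf, p$truth_opd), 0.05)
  # identical images: flat wavefront
  cf0 <- curl_free_flow(p$I0, p$I0, g)
  expect_lt(rms(cf0$opd_um), 1e-6)
})

test_that("degenerate solver inputs raise errors", {
  g <- fx_geometry()
  zero <- intensity_image(matrix(0, 16, 16), g$sensor_pitch_um)
  some <- intensity_image(matrix(1, 16, 16), g$sensor_pitch_um)
  expect_error(solve_joint(zero, some, g), "zero")
  small <- intensity_image(matrix(1, 8, 8), g$sensor_pitch_um)
  expect_error(solve_joint(some, small, g), "congruent")
})
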