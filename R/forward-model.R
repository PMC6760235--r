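# Geometric (ray-optics) forward model of the coded wavefront sensor and its
# transport-of-intensity linearization.
#
# The measurement obeys I(r + (lambda z / 2 pi) grad(phi))
#   = |A|^2 (1 - (lambda z / 2 pi) lap(phi)) I0(r):
# speckle displacement proportional to the wavefront slope, modulated by the
# sample intensity and by the caustic (curvature) factor. Because
# (lambda / 2 pi) phi = OPD, both the displacement (z grad OPD) and the
# curvature factor (1 - z lap OPD) depend on the wavefront only through the
# OPD, making the model independent of the nominal wavelength.

# displacement field in sensor pixels for a wavefront on the same grid
wavefront_displacement_px <- function(wavefront, geometry) {
  h <- wavefront$pitch_um
  gx <- dx_forward(wavefront$opd_um) / h      # grad OPD, um/um
  gy <- dy_forward(wavefront$opd_um) / h
  list(ux = geometry$z_um * gx / h, uy = geometry$z_um * gy / h)
}

#' Caustic (curvature) factor of a wavefront
#'
#' Returns `1 - (lambda z / 2 pi) lap(phi) = 1 - z lap(OPD)`: the local
#' intensity modulation caused by wavefront focusing or defocusing. The
#' Laplacian uses the 5-point stencil with Neumann (replicate) boundaries.
#' A warning is issued when the curvature term exceeds 0.5 anywhere (the
#' model assumes it is small), and an error when the factor is nonpositive
#' (caustic folding; the model is invalid there).
#'
#' @param wavefront a [wavefront_map()].
#' @param geometry a [sensor_geometry()].
#' @return Matrix of curvature factors.
#' @export
curvature_factor <- function(wavefront, geometry) {
  h <- wavefront$pitch_um
  lap_opd <- laplacian_px(wavefront$opd_um) / h^2
  term <- geometry$z_um * lap_opd
  if (max(abs(term)) > 0.5) {
    warning("curvature term |z lap(OPD)| exceeds 0.5; geometric model is inaccurate",
            call. = FALSE)
  }
  f <- 1 - term
  if (any(f <= 0)) {
    stop("curvature factor is nonpositive somewhere: wavefront outside model validity",
         call. = FALSE)
  }
  f
}

#' Geometric forward model: speckle warp with intensity modulation
#'
#' Synthesizes the measurement image implied by the ray-optics model for a
#' sample phantom and reference image: the right-hand side
#' `|A|^2 (1 - z lap OPD) I0` is resampled from the warped coordinates
#' `r + z grad(OPD)` onto the pixel grid (inverse warp, fixed-point
#' inversion of the coordinate map, cubic interpolation).
#'
#' @param I0 reference [intensity_image()].
#' @param sample a [sample_phantom()] on the same grid.
#' @param geometry a [sensor_geometry()].
#' @param clamp_factor_eps floor for the curvature factor. Sharp features
#'   (e.g. lenslet junction cusps) fold the local curvature beyond the model
#'   validity on a thin set; there the factor is clamped to this floor with
#'   a warning rather than rejecting the whole field. Use
#'   [curvature_factor()] directly for the strict validity check.
#' @return An [intensity_image()].
#' @export
geometric_forward <- function(I0, sample, geometry, clamp_factor_eps = 0.05) {
  if (!grids_congruent(I0$values, sample$wavefront$opd_um)) {
    stop("reference image and sample grids must be congruent", call. = FALSE)
  }
  disp <- wavefront_displacement_px(sample$wavefront, geometry)
  if (max(abs(c(disp$ux, disp$uy))) > 10) {
    warning("speckle displacement exceeds 10 px; geometric model is unreliable",
            call. = FALSE)
  }
  h <- sample$wavefront$pitch_um
  cf <- 1 - geometry$z_um * laplacian_px(sample$wavefront$opd_um) / h^2
  n_bad <- sum(cf < clamp_factor_eps)
  if (n_bad > 0) {
    warning(sprintf("curvature factor clamped at %d px (caustic folding)", n_bad),
            call. = FALSE)
    cf[cf < clamp_factor_eps] <- clamp_factor_eps
  }
  rhs <- sample$amplitude^2 * cf * I0$values
  # invert r' = r + u(r) by fixed point: r = r' - u(r)
  nr <- nrow(rhs); nc <- ncol(rhs)
  bx <- matrix(0, nr, nc); by <- matrix(0, nr, nc)
  for (it in 1:3) {
    bx_new <- -interp_bilinear(disp$ux, col(rhs) + bx, row(rhs) + by)
    by_new <- -interp_bilinear(disp$uy, col(rhs) + bx, row(rhs) + by)
    bx <- bx_new; by <- by_new
  }
  # resample through the sinc-upsampled image: the reference speckle lives
  # near the sensor Nyquist rate, where direct cubic interpolation degrades
  samp <- make_fine_sampler(rhs, 4L)
  out <- samp(col(rhs) + bx, row(rhs) + by)
  out[out < 0] <- 0
  intensity_image(out, I0$pitch_um)
}

#' Transport-of-intensity predictor
#'
#' Predicts the defocused intensity `I2` at distance `z` from the in-focus
#' intensity `I1` and a wavefront, by solving the transport relation
#' `grad(I2) . grad(phi) + I1 lap(phi) = (k / z)(I1 - I2)` for `I2` with a
#' fixed-point iteration (the `grad(I2)` term lags one iteration, starting
#' from `I2 = I1`).
#'
#' @param I1 in-focus [intensity_image()].
#' @param wavefront a [wavefront_map()] on the same grid.
#' @param z_um propagation distance in micrometres.
#' @param wavelength_um wavelength in micrometres.
#' @param max_iters,tol fixed-point controls.
#' @param gradient discretization of the intensity gradient: `"forward"`
#'   (forward differences, matching the reconstruction operators) or
#'   `"spectral"` (FFT derivative, exact for band-limited periodic fields;
#'   use when comparing against the sinc-resampling geometric model).
#' @return An [intensity_image()] holding `I2`.
#' @export
tie_predict <- function(I1, wavefront, z_um, wavelength_um = wavefront$wavelength_um,
                        max_iters = 50L, tol = 1e-10,
                        gradient = c("forward", "spectral")) {
  gradient <- match.arg(gradient)
  if (!grids_congruent(I1$values, wavefront$opd_um)) {
    stop("I1 and wavefront grids must be congruent", call. = FALSE)
  }
  h <- I1$pitch_um
  k <- 2 * pi / wavelength_um
  phi <- 2 * pi * wavefront$opd_um / wavelength_um
  gx <- dx_forward(phi) / h; gy <- dy_forward(phi) / h
  lap_phi <- laplacian_px(phi) / h^2
  grad_fn <- if (gradient == "spectral") {
    function(u) spectral_gradient(u, h)
  } else {
    function(u) list(gx = dx_forward(u) / h, gy = dy_forward(u) / h)
  }
  I2 <- I1$values
  for (it in seq_len(max_iters)) {
    gI2 <- grad_fn(I2)
    I2_new <- I1$values - (z_um / k) * (gI2$gx * gx + gI2$gy * gy + I1$values * lap_phi)
    delta <- max(abs(I2_new - I2))
    I2 <- I2_new
    if (delta < tol * max(abs(I1$values))) break
    if (it == max_iters && delta > 1e-3 * max(abs(I1$values))) {
      stop("transport fixed-point iteration did not converge", call. = FALSE)
    }
  }
  I2[I2 < 0] <- 0
  intensity_image(I2, I1$pitch_um)
}

#' Transport-of-intensity wavefront solver
#'
#' Standard two-step inversion of the transport relation from an in-focus /
#' defocused intensity pair: a Poisson solve for the auxiliary potential from
#' `k (I1 - I2) / z`, division of its gradient by `I1`, and a second Poisson
#' solve for the wavefront. Both solves use the DCT (Neumann) spectral
#' inverse; the result is zero-mean.
#'
#' @param I1 in-focus [intensity_image()], strictly positive.
#' @param I2 defocused [intensity_image()] at distance `z_um`.
#' @param z_um defocus distance in micrometres.
#' @param wavelength_um wavelength in micrometres.
#' @return A [wavefront_map()] (OPD in micrometres, zero mean).
#' @export
tie_solve <- function(I1, I2, z_um, wavelength_um = 0.5328) {
  if (!grids_congruent(I1$values, I2$values)) {
    stop("I1 and I2 must be congruent", call. = FALSE)
  }
  if (any(I1$values <= 0)) stop("I1 must be strictly positive", call. = FALSE)
  h <- I1$pitch_um
  k <- 2 * pi / wavelength_um
  src <- k * (I1$values - I2$values) / z_um        # = div(I1 grad phi)
  psi <- poisson_neumann_px(src * h^2)             # lap psi = src (physical units)
  gpx <- dx_forward(psi) / h / I1$values
  gpy <- dy_forward(psi) / h / I1$values
  div_g <- -(dx_adjoint(gpx) + dy_adjoint(gpy)) / h
  phi <- poisson_neumann_px(div_g * h^2)
  phi <- phi - mean(phi)
  wavefront_map(wavelength_um * phi / (2 * pi), h, wavelength_um)
}
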