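# Physical-optics simulator of the coded wavefront sensor: binary 0/pi mask
# synthesis, band-limited angular-spectrum propagation over the mask-to-sensor
# gap, and area-integrating sensor sampling.
#
# The simulation grid oversamples the sensor pitch by an integer factor
# (default 4x) so the 12.9 um mask features and their diffraction fringes are
# resolved; an apodized guard border absorbs the periodic wrap-around implied
# by the spectral propagator and is cropped from every output.

#' Simulation grid shape for a requested sensor image
#'
#' The simulator works on a fine grid of pitch `sensor_pitch / oversample`
#' padded by `guard_px` sensor pixels on every side. This helper returns the
#' fine-grid dimensions matching a requested sensor output shape.
#'
#' @param shape integer vector `c(rows, cols)` of the sensor image (after
#'   guard cropping).
#' @param oversample integer oversampling factor (default 4).
#' @param guard_px guard border in sensor pixels (default 32).
#' @return Integer vector `c(rows, cols)` of the simulation grid.
#' @export
sensor_sim_shape <- function(shape, oversample = 4L, guard_px = 32L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L)) {
    stop("shape must be two positive integers", call. = FALSE)
  }
  (shape + 2L * as.integer(guard_px)) * as.integer(oversample)
}

#' Synthesize a random binary 0/pi phase mask
#'
#' Draws an i.i.d. uniform binary pattern at the mask feature pitch and
#' records the upsampling block size that maps it onto the simulation grid by
#' nearest-neighbour replication. The pattern is reproducible from the seed.
#'
#' @param seed integer seed for the mask pattern.
#' @param shape simulation grid dimensions `c(rows, cols)` the mask must
#'   cover (see [sensor_sim_shape()]).
#' @param geometry a [sensor_geometry()].
#' @param oversample simulation oversampling factor relative to the sensor
#'   pitch; the simulation pitch is `sensor_pitch_um / oversample`.
#' @param edge_sigma_um Gaussian rounding of the fabricated feature edges in
#'   micrometres, applied to the complex mask transmission. The default
#'   (2 um) models the finite edge sharpness of a photolithographic mask and
#'   keeps the resulting speckle within the sensor sampling cutoff; 0 gives
#'   ideal sharp features.
#' @return An object of class `mask_pattern` with fields `values` (binary
#'   matrix at mask-pixel resolution), `mask_pixel_um`, `phase_levels`
#'   (`c(0, pi)`), `block_px` (features-to-grid replication factor), `seed`,
#'   `edge_sigma_um`.
#' @export
make_mask <- function(seed, shape, geometry, oversample = 4L,
                      edge_sigma_um = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L)) {
    stop("shape must be two positive integers", call. = FALSE)
  }
  sim_pitch <- geometry$sensor_pitch_um / oversample
  block <- as.integer(ceiling(geometry$mask_pixel_um / sim_pitch))
  mdims <- as.integer(ceiling(shape / block))
  values <- with_local_seed(seed, {
    matrix(sample(c(0L, 1L), prod(mdims), replace = TRUE), mdims[1], mdims[2])
  })
  structure(list(values = values, mask_pixel_um = geometry$mask_pixel_um,
                 phase_levels = c(0, pi), block_px = block, seed = seed,
                 sim_shape = shape, edge_sigma_um = edge_sigma_um,
                 sim_pitch_um = sim_pitch),
            class = "mask_pattern")
}

#' @export
print.mask_pattern <- function(x, ...) {
  cat(sprintf(
    "<mask_pattern> %d x %d features of %.4g um (block %d px), seed %s, fill %.3f\n",
    nrow(x$values), ncol(x$values), x$mask_pixel_um, x$block_px,
    format(x$seed), mean(x$values)))
  invisible(x)
}

# Upsample the binary feature grid to the simulation grid (nearest neighbour)
# and return the mask phase in radians.
mask_phase_grid <- function(mask, shape = mask$sim_shape) {
  up <- mask$values[rep(seq_len(nrow(mask$values)), each = mask$block_px),
                    rep(seq_len(ncol(mask$values)), each = mask$block_px),
                    drop = FALSE]
  up <- up[seq_len(shape[1]), seq_len(shape[2]), drop = FALSE]
  mask$phase_levels[1] + up * diff(mask$phase_levels)
}

# complex transmission of the mask on the simulation grid, with the
# fabricated edge rounding applied to the complex profile
mask_transmission <- function(mask, shape = mask$sim_shape) {
  U <- exp(1i * mask_phase_grid(mask, shape))
  sig <- mask$edge_sigma_um / mask$sim_pitch_um
  if (sig > 0) {
    U <- gauss_blur_fft(Re(U), sig) + 1i * gauss_blur_fft(Im(U), sig)
  }
  U
}

#' Angular-spectrum propagation of a complex field
#'
#' Exact scalar free-space propagation: the field's spatial spectrum is
#' multiplied by `exp(j 2 pi d sqrt(1/lambda^2 - fx^2 - fy^2))`. Evanescent
#' components (`fx^2 + fy^2 > 1/lambda^2`) are suppressed, and the transfer
#' function is zeroed beyond the aliasing-safe band limit
#' `f_lim = 1 / (lambda sqrt((2 d df)^2 + 1))` per axis (df = frequency
#' resolution of the grid), so the chirped kernel never wraps. Negative
#' distances back-propagate; total energy is conserved up to the removed
#' band.
#'
#' @param field a [complex_field()].
#' @param distance_um propagation distance in micrometres (may be negative).
#' @return A [complex_field()] at the new plane.
#' @export
angular_spectrum_propagate <- function(field, distance_um) {
  if (!inherits(field, "complex_field")) stop("field must be a complex_field", call. = FALSE)
  lambda <- field$wavelength_um
  if (!is.finite(lambda) || lambda <= 0) stop("wavelength must be positive", call. = FALSE)
  if (distance_um == 0) return(field)
  U <- field_complex_values(field)
  nr <- nrow(U); nc <- ncol(U)
  d <- field$pitch_um
  fy <- fft_freq_idx(nr) / (nr * d)
  fx <- fft_freq_idx(nc) / (nc * d)
  fy2 <- matrix(fy^2, nr, nc)
  fx2 <- matrix(rep(fx^2, each = nr), nr, nc)
  arg <- 1 / lambda^2 - fx2 - fy2
  H <- matrix(0 + 0i, nr, nc)
  prop <- arg > 0
  H[prop] <- exp(2i * pi * distance_um * sqrt(arg[prop]))
  # aliasing-safe band limit of the sampled chirp (per axis)
  dfy <- 1 / (nr * d); dfx <- 1 / (nc * d)
  fy_lim <- 1 / (lambda * sqrt((2 * abs(distance_um) * dfy)^2 + 1))
  fx_lim <- 1 / (lambda * sqrt((2 * abs(distance_um) * dfx)^2 + 1))
  H[fy2 > fy_lim^2 | fx2 > fx_lim^2] <- 0
  V <- stats::fft(stats::fft(U) * H, inverse = TRUE) / (nr * nc)
  complex_field(Mod(V), Arg(V), field$pitch_um, lambda)
}

# the raised-cosine illumination taper occupies half the guard border; both
# reference and measurement use it, so a flat sample reproduces the
# reference image exactly
guard_apod_px <- function(oversample, guard_px) {
  as.integer(guard_px) * as.integer(oversample) %/% 2L
}

# raised-cosine apodization over `border` fine-grid pixels on every side
apodize_border <- function(values, border) {
  if (border <= 0) return(values)
  n1 <- nrow(values); n2 <- ncol(values)
  ramp <- function(n) {
    w <- rep(1, n)
    b <- min(border, floor(n / 2))
    t <- (seq_len(b) - 0.5) / b
    w[seq_len(b)] <- 0.5 * (1 - cos(pi * t))
    w[n + 1 - seq_len(b)] <- w[seq_len(b)]
    w
  }
  values * outer(ramp(n1), ramp(n2))
}

# box-average os x os blocks (area-integrating sensor pixel)
box_downsample <- function(values, os) {
  if (os == 1L) return(values)
  nr <- nrow(values) %/% os; nc <- ncol(values) %/% os
  v <- values[seq_len(nr * os), seq_len(nc * os), drop = FALSE]
  dim(v) <- c(os, nr, os * nc)
  v <- colMeans(v)                 # nr x (os*nc)
  dim(v) <- c(nr, os, nc)
  v <- apply(v, c(1, 3), mean)
  matrix(v, nr, nc)
}

crop_guard <- function(values, guard_px) {
  if (guard_px <= 0) return(values)
  r <- (guard_px + 1):(nrow(values) - guard_px)
  c <- (guard_px + 1):(ncol(values) - guard_px)
  values[r, c, drop = FALSE]
}

sim_field_to_sensor <- function(field, geometry, oversample, guard_px) {
  I_fine <- Mod(field_complex_values(field))^2
  I_sens <- box_downsample(I_fine, as.integer(oversample))
  I_sens <- crop_guard(I_sens, as.integer(guard_px))
  intensity_image(I_sens, geometry$sensor_pitch_um)
}

#' Simulate the reference speckle image of the sensor
#'
#' Propagates a collimated unit-amplitude wave through the binary phase mask
#' over the mask-to-sensor distance and integrates the resulting intensity
#' over the sensor pixel areas: the reference image is the diffraction
#' pattern of the high-frequency mask.
#'
#' @param mask a [make_mask()] pattern on the matching simulation grid.
#' @param geometry a [sensor_geometry()].
#' @param shape sensor image dimensions `c(rows, cols)` after guard cropping.
#' @param oversample,guard_px simulation controls; must match the values used
#'   to size the mask (see [sensor_sim_shape()]).
#' @return An [intensity_image()] at the sensor pitch.
#' @export
simulate_reference <- function(mask, geometry, shape, oversample = 4L,
                               guard_px = 32L) {
  sim_shape <- sensor_sim_shape(shape, oversample, guard_px)
  if (!identical(sim_shape, mask$sim_shape)) {
    stop("mask grid is incompatible with the requested sensor shape", call. = FALSE)
  }
  sim_pitch <- geometry$sensor_pitch_um / oversample
  Tm <- mask_transmission(mask)
  amp <- apodize_border(matrix(1, sim_shape[1], sim_shape[2]),
                        guard_apod_px(oversample, guard_px))
  f0 <- complex_field(amp * Mod(Tm), Arg(Tm), sim_pitch, geometry$wavelength_um)
  fz <- angular_spectrum_propagate(f0, geometry$z_um)
  sim_field_to_sensor(fz, geometry, oversample, guard_px)
}

#' Simulate a measurement speckle image for a sample field
#'
#' The sample field (conjugated to the mask plane) multiplies the mask field;
#' the product is propagated to the sensor and pixel-integrated. With a flat
#' unit-amplitude sample the result equals [simulate_reference()] exactly.
#'
#' @param mask a [make_mask()] pattern.
#' @param geometry a [sensor_geometry()].
#' @param sample a [complex_field()] on the simulation grid (same dimensions
#'   as the mask grid, pitch `sensor_pitch / oversample`).
#' @param oversample,guard_px simulation controls matching the mask.
#' @return An [intensity_image()] at the sensor pitch.
#' @export
simulate_measurement <- function(mask, geometry, sample, oversample = 4L,
                                 guard_px = 32L) {
  sim_shape <- mask$sim_shape
  if (!identical(as.integer(dim(sample$amplitude)), sim_shape)) {
    stop("sample grid does not match the mask simulation grid", call. = FALSE)
  }
  sim_pitch <- geometry$sensor_pitch_um / oversample
  Tm <- mask_transmission(mask)
  amp <- apodize_border(sample$amplitude, guard_apod_px(oversample, guard_px))
  f0 <- complex_field(amp * Mod(Tm), sample$phase_rad + Arg(Tm),
                      sim_pitch, geometry$wavelength_um)
  fz <- angular_spectrum_propagate(f0, geometry$z_um)
  sim_field_to_sensor(fz, geometry, oversample, guard_px)
}

#' Add sensor noise to a simulated intensity image
#'
#' Optional additive Gaussian read noise and Poisson shot noise. Shot noise
#' scales the image to an expected photon count per pixel
#' (`photons_per_unit * value`), draws Poisson counts, and scales back.
#'
#' @param img an [intensity_image()].
#' @param gaussian_sd standard deviation of additive read noise, in image
#'   units (0 disables).
#' @param photons_per_unit photons corresponding to one image unit for shot
#'   noise (`Inf` disables).
#' @param seed RNG seed (noise is reproducible given the seed).
#' @return An [intensity_image()] with noise applied, clipped at zero.
#' @export
add_sensor_noise <- function(img, gaussian_sd = 0, photons_per_unit = Inf,
                             seed = 0L) {
  v <- img$values
  v <- with_local_seed(seed, {
    if (is.finite(photons_per_unit)) {
      if (photons_per_unit <= 0) stop("photons_per_unit must be positive", call. = FALSE)
      v <- stats::rpois(length(v), lambda = v * photons_per_unit) / photons_per_unit
      v <- matrix(v, nrow(img$values), ncol(img$values))
    }
    if (gaussian_sd > 0) {
      v <- v + matrix(stats::rnorm(length(v), sd = gaussian_sd),
                      nrow(img$values), ncol(img$values))
    }
    v
  })
  v[v < 0] <- 0
  intensity_image(v, img$pitch_um)
}

#' Simulate a matched reference/measurement speckle image pair
#'
#' Convenience wrapper running [make_mask()], [simulate_reference()] and
#' [simulate_measurement()] for a sample phantom defined on the simulation
#' grid, and box-averaging the phantom truth onto the sensor grid for error
#' metrics.
#'
#' @param phantom a [sample_phantom()] on the simulation grid (generate it
#'   with `grid = sensor_sim_shape(shape, ...)` and
#'   `pitch_um = sensor_pitch / oversample`).
#' @param geometry a [sensor_geometry()].
#' @param shape sensor image dimensions `c(rows, cols)`.
#' @param seed mask seed.
#' @param oversample,guard_px simulation controls.
#' @return List with `I0`, `I` ([intensity_image()]s), `truth_opd`
#'   ([wavefront_map()] on the sensor grid), `truth_amplitude` (matrix on the
#'   sensor grid) and `mask`.
#' @export
simulate_speckle_pair <- function(phantom, geometry, shape, seed = 0L,
                                  oversample = 4L, guard_px = 32L) {
  sim_shape <- sensor_sim_shape(shape, oversample, guard_px)
  if (!identical(as.integer(dim(phantom$wavefront$opd_um)), sim_shape)) {
    stop("phantom grid must equal sensor_sim_shape(shape, ...)", call. = FALSE)
  }
  mask <- make_mask(seed, sim_shape, geometry, oversample)
  I0 <- simulate_reference(mask, geometry, shape, oversample, guard_px)
  sample <- phantom_field(phantom, geometry$wavelength_um)
  I <- simulate_measurement(mask, geometry, sample, oversample, guard_px)
  os <- as.integer(oversample)
  truth_opd <- crop_guard(box_downsample(phantom$wavefront$opd_um, os), guard_px)
  truth_amp <- crop_guard(box_downsample(phantom$amplitude, os), guard_px)
  list(I0 = I0, I = I,
       truth_opd = wavefront_map(truth_opd, geometry$sensor_pitch_um,
                                 geometry$wavelength_um),
       truth_amplitude = truth_amp, mask = mask)
}
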