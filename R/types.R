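#' Sensor geometry of a coded wavefront sensor
#'
#' Bundles the physical constants of the sensor: the mask-to-sensor distance
#' `z`, the nominal wavelength `lambda`, the sensor pixel pitch and the mask
#' feature pitch. The scale factor between wavefront phase gradient and
#' speckle displacement, `lambda * z / (2 pi)` (micrometres of displacement
#' per rad/um of phase slope), is derived from these, as is the wavenumber
#' `k = 2 pi / lambda` — neither is stored separately.
#'
#' Defaults reproduce the calibrated prototype: `z` = 1.43 mm, nominal
#' wavelength 532.8 nm, sensor pitch 6.45 um, mask pixel 12.9 um.
#'
#' @param z_um mask-to-sensor distance in micrometres.
#' @param wavelength_um nominal wavelength in micrometres.
#' @param sensor_pitch_um sensor pixel pitch in micrometres.
#' @param mask_pixel_um mask feature pitch in micrometres.
#' @return An object of class `sensor_geometry`.
#' @export
#' @examples
#' g <- sensor_geometry()
#' slope_scale_um(g)  # displacement (um) per unit phase slope (rad/um)
sensor_geometry <- function(z_um = 1430, wavelength_um = 0.5328,
                            sensor_pitch_um = 6.45, mask_pixel_um = 12.9) {
  vals <- c(z_um = z_um, wavelength_um = wavelength_um,
            sensor_pitch_um = sensor_pitch_um, mask_pixel_um = mask_pixel_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all sensor_geometry lengths must be finite and positive", call. = FALSE)
  }
  structure(list(z_um = z_um, wavelength_um = wavelength_um,
                 sensor_pitch_um = sensor_pitch_um,
                 mask_pixel_um = mask_pixel_um),
            class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf(
    "<sensor_geometry> z = %.4g mm, lambda = %.4g nm, sensor pitch = %.4g um, mask pixel = %.4g um\n",
    x$z_um / 1000, x$wavelength_um * 1000, x$sensor_pitch_um, x$mask_pixel_um))
  invisible(x)
}

#' Displacement scale of the sensor
#'
#' Returns `lambda * z / (2 pi)`: the lateral speckle displacement in
#' micrometres produced by a unit wavefront phase slope (1 rad/um).
#' Equivalently, displacement in micrometres equals `z` times the OPD slope.
#'
#' @param geometry a [sensor_geometry()].
#' @return Scalar, micrometres per (rad/um).
#' @export
slope_scale_um <- function(geometry) {
  geometry$wavelength_um * geometry$z_um / (2 * pi)
}

#' Wavenumber at the nominal wavelength
#' @param geometry a [sensor_geometry()].
#' @return `2 pi / lambda` in rad/um.
#' @export
wavenumber <- function(geometry) 2 * pi / geometry$wavelength_um

#' Nonnegative irradiance map on a pixel grid
#'
#' @param values numeric matrix of nonnegative intensities (rows = y,
#'   columns = x).
#' @param pitch_um pixel pitch in micrometres.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, pitch_um) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("intensity values must be finite", call. = FALSE)
  if (any(values < 0)) stop("intensity values must be nonnegative", call. = FALSE)
  if (!is.finite(pitch_um) || pitch_um <= 0) stop("pitch_um must be positive", call. = FALSE)
  structure(list(values = values, pitch_um = pitch_um), class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, pitch %.4g um, mean %.4g\n",
              nrow(x$values), ncol(x$values), x$pitch_um, mean(x$values)))
  invisible(x)
}

#' Scalar wavefront as an optical path difference map
#'
#' The wavefront is stored as OPD in micrometres; phase in radians at the
#' nominal wavelength is `2 pi * OPD / lambda` (see [wavefront_phase()]),
#' the exact inverse of `OPD = lambda * phi / (2 pi)`.
#'
#' @param opd_um numeric matrix, optical path difference in micrometres.
#' @param pitch_um sample spacing in micrometres.
#' @param wavelength_um nominal wavelength used for OPD/phase conversion.
#' @return An object of class `wavefront_map`.
#' @export
wavefront_map <- function(opd_um, pitch_um, wavelength_um = 0.5328) {
  opd_um <- as.matrix(opd_um)
  if (any(!is.finite(opd_um))) stop("OPD values must be finite", call. = FALSE)
  if (!is.finite(pitch_um) || pitch_um <= 0) stop("pitch_um must be positive", call. = FALSE)
  if (!is.finite(wavelength_um) || wavelength_um <= 0) {
    stop("wavelength_um must be positive", call. = FALSE)
  }
  structure(list(opd_um = opd_um, pitch_um = pitch_um,
                 wavelength_um = wavelength_um),
            class = "wavefront_map")
}

#' @export
print.wavefront_map <- function(x, ...) {
  cat(sprintf("<wavefront_map> %d x %d px, pitch %.4g um, OPD range [%.4g, %.4g] um\n",
              nrow(x$opd_um), ncol(x$opd_um), x$pitch_um,
              min(x$opd_um), max(x$opd_um)))
  invisible(x)
}

#' Phase of a wavefront map at its nominal wavelength
#' @param wavefront a [wavefront_map()].
#' @return Matrix of phase values in radians.
#' @export
wavefront_phase <- function(wavefront) {
  2 * pi * wavefront$opd_um / wavefront$wavelength_um
}

#' Sampled complex scalar field A(r) exp(j phi(r))
#'
#' @param amplitude nonnegative numeric matrix.
#' @param phase_rad numeric matrix of the same dimensions, phase in radians.
#' @param pitch_um sample spacing in micrometres.
#' @param wavelength_um wavelength in micrometres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(amplitude, phase_rad, pitch_um, wavelength_um) {
  amplitude <- as.matrix(amplitude)
  phase_rad <- as.matrix(phase_rad)
  if (!identical(dim(amplitude), dim(phase_rad))) {
    stop("amplitude and phase grids must be congruent", call. = FALSE)
  }
  if (any(amplitude < 0)) stop("amplitude must be nonnegative", call. = FALSE)
  if (!is.finite(wavelength_um) || wavelength_um <= 0) {
    stop("wavelength_um must be positive", call. = FALSE)
  }
  if (!is.finite(pitch_um) || pitch_um <= 0) stop("pitch_um must be positive", call. = FALSE)
  structure(list(amplitude = amplitude, phase_rad = phase_rad,
                 pitch_um = pitch_um, wavelength_um = wavelength_um),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px, pitch %.4g um, lambda %.4g nm\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pitch_um,
              x$wavelength_um * 1000))
  invisible(x)
}

field_complex_values <- function(field) {
  field$amplitude * exp(1i * field$phase_rad)
}

#' Speckle displacement field in sensor pixels
#'
#' Holds the optically encoded displacement `(lambda z / 2 pi) grad(phi)`
#' expressed in sensor pixels, together with the geometry that converts it
#' back to wavefront slopes in rad/um.
#'
#' @param dx,dy displacement matrices in pixels (x along columns).
#' @param geometry a [sensor_geometry()].
#' @return An object of class `slope_field`.
#' @export
slope_field <- function(dx, dy, geometry) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!identical(dim(dx), dim(dy))) stop("dx and dy must be congruent", call. = FALSE)
  if (any(!is.finite(dx)) || any(!is.finite(dy))) {
    stop("slope field must be finite", call. = FALSE)
  }
  structure(list(dx = dx, dy = dy, geometry = geometry), class = "slope_field")
}

#' Wavefront slopes in rad/um from a pixel displacement field
#' @param slopes a [slope_field()].
#' @return List with matrices `sx`, `sy`: phase slopes in rad/um.
#' @export
slope_to_phase_gradient <- function(slopes) {
  f <- slopes$geometry$sensor_pitch_um / slope_scale_um(slopes$geometry)
  list(sx = slopes$dx * f, sy = slopes$dy * f)
}

#' Reconstruction solver parameters
#'
#' Tradeoff weights and iteration controls of the joint amplitude + phase
#' solver. The weights apply to images normalized to the 0--255 gray scale:
#' `alpha` (L1 on the phase gradient), `beta` (L2 on phase gradient and
#' Laplacian), `gamma` (L1 on gradient and Laplacian of the modulated
#' intensity), `tau` (L2 on the same). Defaults are the typical values for
#' that normalization: alpha = 0.1, beta = 0.1, gamma = 100, tau = 5.
#'
#' @param alpha,beta,gamma,tau nonnegative regularization weights.
#' @param outer_iters alternating (phase / intensity) steps, default 3.
#' @param inner_iters proximal-splitting iterations per subproblem.
#' @param warp_linearizations Gauss-Newton relinearizations of the warp per
#'   outer step.
#' @param tol relative objective-decrease stopping tolerance.
#' @param rho_phase ADMM penalty for the phase subproblem.
#' @param rho_intensity ADMM penalty for the intensity subproblem; defaults
#'   to `max(1, gamma)` so the L1 threshold `gamma / rho` is of order one on
#'   the normalized intensity scale.
#' @param pyramid `"auto"` (coarse-to-fine when expected displacement exceeds
#'   3 px), `"on"` or `"off"`.
#' @param cg_iters conjugate-gradient iterations per linear subproblem.
#' @param increment_smooth relative weight of the smoothness penalty on each
#'   Gauss-Newton phase increment (scaled by the mean data-term curvature).
#'   Stabilizes the speckle matching; at convergence the increments vanish,
#'   so this does not bias the final wavefront.
#' @param data_smooth_px Gaussian pre-filter floor (pixels) of the data term.
#'   The sensor samples the speckle near its Nyquist rate, where warp
#'   linearization is biased; a light pre-filter (default 0.7 px) commutes
#'   with the displacement, so it leaves the encoded wavefront slopes intact
#'   while removing the bias. The solver's objective trace is reported at
#'   this smoothing level.
#' @param init `"track"` initializes the wavefront from windowed
#'   cross-correlation tracking plus Poisson integration (robust default);
#'   `"zero"` starts from a flat wavefront.
#' @return An object of class `solver_params`.
#' @export
solver_params <- function(alpha = 0.1, beta = 0.1, gamma = 100, tau = 5,
                          outer_iters = 3L, inner_iters = 8L,
                          warp_linearizations = 3L, tol = 1e-5,
                          rho_phase = 1, rho_intensity = NULL,
                          pyramid = c("auto", "on", "off"),
                          cg_iters = 25L, increment_smooth = 0.5,
                          data_smooth_px = 0.7,
                          init = c("track", "zero")) {
  pyramid <- match.arg(pyramid)
  init <- match.arg(init)
  w <- c(alpha, beta, gamma, tau)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("regularization weights must be finite and nonnegative", call. = FALSE)
  }
  its <- c(outer_iters, inner_iters, warp_linearizations, cg_iters)
  if (any(its < 1)) stop("iteration counts must be >= 1", call. = FALSE)
  if (is.null(rho_intensity)) rho_intensity <- max(1, gamma)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau,
                 outer_iters = as.integer(outer_iters),
                 inner_iters = as.integer(inner_iters),
                 warp_linearizations = as.integer(warp_linearizations),
                 tol = tol, rho_phase = rho_phase,
                 rho_intensity = rho_intensity, pyramid = pyramid,
                 cg_iters = as.integer(cg_iters),
                 increment_smooth = increment_smooth,
                 data_smooth_px = data_smooth_px, init = init),
            class = "solver_params")
}

grids_congruent <- function(a, b) identical(dim(a), dim(b))
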