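# Digital refocusing of a recovered complex field, calibration of the
# mask-to-sensor distance from known tilts, and wavefront-resolution /
# phase-transfer analysis.

#' Digitally refocus a complex field
#'
#' Propagates the field by a defocus distance `delta_f` with the
#' angular-spectrum method. For broadband acquisitions the wavefront is
#' OPD-valued; convert it to phase at the nominal wavelength (532.8 nm by
#' default) before refocusing.
#'
#' @param field a [complex_field()].
#' @param delta_f_um defocus distance in micrometres (negative
#'   back-propagates).
#' @return A [complex_field()] at the refocused plane.
#' @export
refocus_field <- function(field, delta_f_um) {
  angular_spectrum_propagate(field, delta_f_um)
}

#' Complex field of a single illuminated lenslet
#'
#' Builds the transmitted field of one plano-convex lenslet under collimated
#' unit illumination: a circular aperture with the spherical-sag OPD profile
#' converted to phase at the given wavelength. The canonical input for
#' digital-refocusing experiments: propagating it by the back focal length
#' focuses it to a diffraction-limited spot.
#'
#' @param focal_mm back focal length in millimetres.
#' @param aperture_um lenslet aperture (diameter) in micrometres.
#' @param n refractive index.
#' @param grid field dimensions `c(rows, cols)`.
#' @param pitch_um grid sample spacing in micrometres (should resolve the
#'   edge-ray fringes; ~1.6 um suffices for millimetre focal lengths).
#' @param wavelength_um wavelength in micrometres.
#' @return A [complex_field()].
#' @export
lenslet_field <- function(focal_mm = 6.7, aperture_um = 150, n = 1.46,
                          grid = c(512L, 512L), pitch_um = 1.6125,
                          wavelength_um = 0.5328) {
  R <- focal_mm * 1000 * (n - 1)
  a <- aperture_um / 2
  if (a >= R) stop("aperture radius exceeds the surface radius", call. = FALSE)
  ax <- grid_axes(grid, pitch_um)
  r2 <- outer(ax$y^2, ax$x^2, `+`)
  inside <- r2 <= a^2
  sag_edge <- R - sqrt(R^2 - a^2)
  opd <- matrix(0, grid[1], grid[2])
  opd[inside] <- (n - 1) * (sag_edge - (R - sqrt(R^2 - r2[inside])))
  amp <- matrix(0, grid[1], grid[2])
  amp[inside] <- 1
  complex_field(amp, 2 * pi * opd / wavelength_um, pitch_um, wavelength_um)
}

#' Find the best digital focus distance
#'
#' Sweeps the defocus distance over a range, evaluates a peak-intensity
#' sharpness metric at each plane, and returns the argmax refined by
#' parabolic interpolation.
#'
#' The peak intensity is compensated by the geometric spreading factor
#' `(delta_f)^2` of a converging beam: the on-axis irradiance of a beam
#' focusing at `f` is a symmetric function of `(1/z - 1/f)` divided by
#' `z^2`, so the raw intensity maximum of a low-Fresnel-number lenslet is
#' shifted toward the aperture (the classical focal-shift effect), while
#' the compensated maximum sits at the paraxial focus. Millimetre-focal
#' lenslets at visible wavelengths have Fresnel numbers of order one, where
#' this correction is essential for the recovered best focus to match the
#' design focal length.
#'
#' If the metric peaks on the range boundary, or the uncompensated peak
#' intensity varies by less than 1% over the sweep (nothing to focus), the
#' result is flagged.
#'
#' @param field a [complex_field()].
#' @param f_range_um length-2 numeric range of defocus distances to sweep
#'   (must bracket the focus; positive distances).
#' @param steps number of sweep planes (>= 16).
#' @return List with `best_df_um`, `metric` (compensated per-plane values),
#'   `metric_raw` (uncompensated peak intensities), `df_um` (sweep grid) and
#'   `boundary` flag.
#' @export
find_best_focus <- function(field, f_range_um, steps = 32L) {
  if (steps < 16L) stop("steps must be at least 16", call. = FALSE)
  dfs <- seq(f_range_um[1], f_range_um[2], length.out = steps)
  metric_raw <- vapply(dfs, function(d) {
    max(Mod(field_complex_values(refocus_field(field, d)))^2)
  }, numeric(1))
  metric <- (dfs / mean(abs(f_range_um)))^2 * metric_raw
  i <- which.max(metric)
  boundary <- (i == 1L || i == steps) ||
    (diff(range(metric_raw)) < 0.01 * max(metric_raw))
  list(best_df_um = parabolic_refine(dfs, metric, i),
       metric = metric, metric_raw = metric_raw,
       df_um = dfs, boundary = boundary)
}

#' Calibration record from one known tilt
#'
#' Inverts the tilt-to-shift scaling `shift = (lambda z / 2 pi) grad(phi)`
#' for the implied mask-to-sensor distance: one row of the calibration
#' experiment, in which a known wavefront slope is applied and the speckle
#' displacement tracked.
#'
#' @param applied_slope known wavefront phase slope in rad/um.
#' @param measured_shift_px tracked speckle displacement in sensor pixels.
#' @param geometry a [sensor_geometry()] (pitch and wavelength are used; the
#'   stored `z` is not).
#' @return One-row data frame with `applied_slope`, `measured_shift_px`,
#'   `implied_z_um`.
#' @export
calibration_record <- function(applied_slope, measured_shift_px, geometry) {
  implied <- if (applied_slope == 0) NA_real_ else {
    measured_shift_px * geometry$sensor_pitch_um *
      (2 * pi / geometry$wavelength_um) / applied_slope
  }
  data.frame(applied_slope = applied_slope,
             measured_shift_px = measured_shift_px,
             implied_z_um = implied)
}

#' Mean mask-to-sensor distance from calibration records
#'
#' @param records data frame of [calibration_record()] rows.
#' @return Mean implied distance in micrometres over records with nonzero
#'   slope.
#' @export
calibrate_z <- function(records) {
  ok <- is.finite(records$implied_z_um) & records$applied_slope != 0
  if (!any(ok)) stop("calibration is degenerate: all applied slopes are zero",
                     call. = FALSE)
  mean(records$implied_z_um[ok])
}

#' Closed-loop calibration of the mask-to-sensor distance
#'
#' Simulates the coded sensor at the geometry's `z`, applies a set of known
#' tilt wavefronts, tracks the global speckle shift of each measurement
#' against the reference by subpixel cross-correlation, and inverts the
#' tilt-to-shift scaling per tilt. Returns the per-tilt records and their
#' mean: a synthetic re-run of the laboratory calibration procedure.
#'
#' @param geometry a [sensor_geometry()]; `z_um` is the ground truth being
#'   recovered.
#' @param opd_slopes numeric vector of OPD tilts (um of OPD per um, along x).
#'   The defaults span roughly 0.5 to 3 px of speckle shift at the default
#'   geometry.
#' @param shape sensor image dimensions.
#' @param seed mask seed.
#' @param oversample,guard_px simulation controls.
#' @return List with `z_um` (mean recovered distance), `records` (data
#'   frame), `geometry`.
#' @export
calibrate_sensor_distance <- function(geometry,
                                      opd_slopes = seq(0.5, 3, length.out = 6) *
                                        geometry$sensor_pitch_um / geometry$z_um,
                                      shape = c(192L, 192L), seed = 0L,
                                      oversample = 4L, guard_px = 32L) {
  sim_shape <- sensor_sim_shape(shape, oversample, guard_px)
  sim_pitch <- geometry$sensor_pitch_um / oversample
  mask <- make_mask(seed, sim_shape, geometry, oversample)
  I0 <- simulate_reference(mask, geometry, shape, oversample, guard_px)
  recs <- lapply(opd_slopes, function(g) {
    ph <- tilt_phantom(gx = g, grid = sim_shape, sample_pitch_um = sim_pitch,
                       wavelength_um = geometry$wavelength_um)
    I <- simulate_measurement(mask, geometry, phantom_field(ph),
                              oversample, guard_px)
    s <- estimate_shift(I0$values, I$values, upsample = 200L)
    phase_slope <- 2 * pi * g / geometry$wavelength_um   # rad/um
    calibration_record(phase_slope, s[["dx"]], geometry)
  })
  records <- do.call(rbind, recs)
  list(z_um = calibrate_z(records), records = records, geometry = geometry)
}

#' Upper bound on recoverable wavefront curvature
#'
#' The geometric model requires the OPD Laplacian to be far below `1/z`;
#' this returns that bound in 1/m.
#'
#' @param z_um mask-to-sensor distance in micrometres.
#' @return Curvature bound in m^-1.
#' @export
curvature_upper_bound <- function(z_um) {
  if (!is.finite(z_um) || z_um <= 0) stop("z_um must be positive", call. = FALSE)
  1e6 / z_um
}

#' Amplitude bound for a sinusoidal wavefront
#'
#' For `OPD = H cos(omega x)` the curvature bound translates into
#' `H << 1 / (z omega^2)`; this returns that amplitude bound in micrometres.
#'
#' @param z_um mask-to-sensor distance in micrometres.
#' @param omega_rad_per_um angular frequency in rad/um.
#' @return Bound on `H` in micrometres.
#' @export
h_upper_bound <- function(z_um, omega_rad_per_um) {
  if (!is.finite(z_um) || z_um <= 0 ||
      !is.finite(omega_rad_per_um) || omega_rad_per_um <= 0) {
    stop("z_um and omega must be positive", call. = FALSE)
  }
  1 / (z_um * omega_rad_per_um^2)
}

#' Rayleigh resolution at the image plane
#'
#' `M * 0.61 * lambda / NA`: the objective's Rayleigh resolution magnified
#' onto the sensor.
#'
#' @param magnification objective magnification (>= 1).
#' @param NA_obj numerical aperture, in (0, 1].
#' @param wavelength_um wavelength in micrometres.
#' @return Resolution in micrometres at the image plane.
#' @export
rayleigh_resolution <- function(magnification, NA_obj, wavelength_um = 0.5328) {
  if (!(NA_obj > 0 && NA_obj <= 1)) stop("NA must be in (0, 1]", call. = FALSE)
  if (magnification < 1) stop("magnification must be >= 1", call. = FALSE)
  magnification * 0.61 * wavelength_um / NA_obj
}

#' Angular cutoff frequency of a characteristic length
#'
#' Converts a resolution length (Rayleigh spot, pixel pitch) into an angular
#' frequency using the `pi / length` convention: one half-cycle per length.
#'
#' @param length_um characteristic length in micrometres.
#' @return Angular frequency in rad/um.
#' @export
cutoff_omega <- function(length_um) {
  if (!is.finite(length_um) || length_um <= 0) {
    stop("length_um must be positive", call. = FALSE)
  }
  pi / length_um
}

#' Measure the phase transfer function of the sensor
#'
#' For each sinusoid amplitude `H` and frequency `omega`, generates the
#' sinusoidal phantom, pushes it through the wave-optics simulator,
#' reconstructs with the supplied solver, and records the relative RMS
#' recovery error along with the `valid` score `1 - error` clipped to
#' `[0, 1]`. Degradation is expected to grow with the curvature `H omega^2`
#' relative to the `1/z` bound.
#'
#' @param solver function `(I0, I, geometry) -> wavefront_map` (e.g. a
#'   wrapper around [solve_joint()] or [curl_free_flow()]).
#' @param geometry a [sensor_geometry()].
#' @param H_um vector of sinusoid amplitudes in micrometres.
#' @param omega_rad_per_um vector of angular frequencies in rad/um.
#' @param shape sensor image dimensions.
#' @param seed mask seed.
#' @param oversample,guard_px simulation controls.
#' @return Data frame with one row per `(H, omega)` pair: `H_um`,
#'   `omega_rad_per_um`, `curvature_per_m` (= `H omega^2`),
#'   `recovery_error`, `valid`.
#' @export
measure_phase_transfer <- function(solver, geometry, H_um, omega_rad_per_um,
                                   shape = c(96L, 96L), seed = 0L,
                                   oversample = 4L, guard_px = 32L) {
  sim_shape <- sensor_sim_shape(shape, oversample, guard_px)
  sim_pitch <- geometry$sensor_pitch_um / oversample
  grid_cases <- expand.grid(H_um = H_um, omega = omega_rad_per_um)
  rows <- lapply(seq_len(nrow(grid_cases)), function(i) {
    H <- grid_cases$H_um[i]; om <- grid_cases$omega[i]
    err <- tryCatch({
      ph <- sinusoid_phantom(H, om, grid = sim_shape,
                             sample_pitch_um = sim_pitch,
                             wavelength_um = geometry$wavelength_um)
      pair <- simulate_speckle_pair(ph, geometry, shape, seed = seed,
                                    oversample = oversample,
                                    guard_px = guard_px)
      rec <- solver(pair$I0, pair$I, geometry)
      truth <- pair$truth_opd$opd_um - mean(pair$truth_opd$opd_um)
      est <- rec$opd_um - mean(rec$opd_um)
      rms(est - truth) / rms(truth)
    }, error = function(e) Inf)
    data.frame(H_um = H, omega_rad_per_um = om,
               curvature_per_m = H * om^2 * 1e6,
               recovery_error = err,
               valid = clamp(1 - err, 0, 1))
  })
  do.call(rbind, rows)
}
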