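# Synthetic sample phantoms with analytic ground truth: microlens arrays,
# sinusoidal and constant-curvature wavefronts, torus-shaped cell OPD maps,
# and pure tilts. Every phantom stores the analytic parameters it was built
# from, so downstream error metrics never re-derive them.

#' Sample phantom: amplitude plus wavefront with stored ground truth
#'
#' @param amplitude nonnegative matrix (by convention in `[0, 1]`).
#' @param wavefront a [wavefront_map()], congruent with `amplitude`.
#' @param truth named list of the analytic parameters used.
#' @return An object of class `sample_phantom`.
#' @export
sample_phantom <- function(amplitude, wavefront, truth = list()) {
  amplitude <- as.matrix(amplitude)
  if (!grids_congruent(amplitude, wavefront$opd_um)) {
    stop("amplitude and wavefront grids must be congruent", call. = FALSE)
  }
  if (any(amplitude < 0)) stop("amplitude must be nonnegative", call. = FALSE)
  structure(list(amplitude = amplitude, wavefront = wavefront, truth = truth),
            class = "sample_phantom")
}

#' @export
print.sample_phantom <- function(x, ...) {
  cat(sprintf("<sample_phantom> %d x %d px, OPD range [%.4g, %.4g] um, amplitude [%.3g, %.3g]\n",
              nrow(x$amplitude), ncol(x$amplitude),
              min(x$wavefront$opd_um), max(x$wavefront$opd_um),
              min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' Complex sample field of a phantom
#'
#' @param phantom a [sample_phantom()].
#' @param wavelength_um wavelength at which OPD converts to phase.
#' @return A [complex_field()] `A exp(j 2 pi OPD / lambda)`.
#' @export
phantom_field <- function(phantom, wavelength_um = phantom$wavefront$wavelength_um) {
  complex_field(phantom$amplitude,
                2 * pi * phantom$wavefront$opd_um / wavelength_um,
                phantom$wavefront$pitch_um, wavelength_um)
}

# pixel-centred physical coordinate axes, origin at the grid centre
grid_axes <- function(grid, pitch_um) {
  grid <- as.integer(grid)
  list(x = (seq_len(grid[2]) - (grid[2] + 1) / 2) * pitch_um,
       y = (seq_len(grid[1]) - (grid[1] + 1) / 2) * pitch_um)
}

#' Plano-convex microlens array phantom
#'
#' Square-grid array of spherical-sag lenslet thickness profiles. The lens
#' surface radius follows the thin-lens relation `R = f (n - 1)`; thickness
#' sag at radius `r` is `R - sqrt(R^2 - r^2)` and the optical path difference
#' is `(n - 1)` times the local thickness. Defaults are a common fused-silica
#' array: 150 um pitch, 6.7 mm back focal length, n = 1.46 at 532.8 nm.
#'
#' @param pitch_um lenslet pitch in micrometres (object plane).
#' @param focal_mm lenslet back focal length in millimetres (Inf gives a flat
#'   phantom).
#' @param n refractive index, in (1, 2).
#' @param grid output dimensions `c(rows, cols)`.
#' @param sample_pitch_um grid sample spacing in micrometres.
#' @param wavelength_um nominal wavelength for the OPD map.
#' @param magnification lateral magnification of the imaging objective
#'   relaying the array onto the grid: the lenslet pattern is stretched by
#'   this factor while the OPD values are unchanged (a conjugate-plane image
#'   preserves phase). 1 places the array directly on the grid.
#' @return A [sample_phantom()] with unit amplitude; `truth` holds
#'   `R_um`, `sag_um` (centre-to-edge thickness drop), `opd_drop_um` and the
#'   generating parameters.
#' @export
microlens_phantom <- function(pitch_um = 150, focal_mm = 6.7, n = 1.46,
                              grid = c(256L, 256L), sample_pitch_um = 6.45,
                              wavelength_um = 0.5328, magnification = 1) {
  if (magnification < 1) stop("magnification must be >= 1", call. = FALSE)
  if (!(n > 1 && n < 2)) stop("refractive index must be in (1, 2)", call. = FALSE)
  if (focal_mm <= 0) stop("focal_mm must be positive", call. = FALSE)
  pitch_img <- pitch_um * magnification     # lenslet pitch on the grid, um
  if (pitch_img < 2 * sample_pitch_um) {
    stop("lenslet pitch must span at least two grid samples", call. = FALSE)
  }
  ax <- grid_axes(grid, sample_pitch_um)
  if (is.infinite(focal_mm)) {
    opd <- matrix(0, grid[1], grid[2])
    wf <- wavefront_map(opd, sample_pitch_um, wavelength_um)
    return(sample_phantom(matrix(1, grid[1], grid[2]), wf,
                          list(kind = "microlens", focal_mm = Inf)))
  }
  R <- focal_mm * 1000 * (n - 1)            # surface radius, um
  a <- pitch_um / 2                          # lenslet aperture radius, um
  if (a >= R) stop("aperture radius exceeds the surface radius: lens un-manufacturable",
                   call. = FALSE)
  # fold coordinates into one lenslet cell (image-plane scale), then map to
  # object-plane radii
  fold <- function(v) (v + pitch_img / 2) %% pitch_img - pitch_img / 2
  xf <- fold(ax$x) / magnification
  yf <- fold(ax$y) / magnification
  r2 <- outer(yf^2, xf^2, `+`)
  sag_edge <- R - sqrt(R^2 - a^2)
  thick <- matrix(0, grid[1], grid[2])
  inside <- r2 <= a^2
  thick[inside] <- sag_edge - (R - sqrt(R^2 - r2[inside]))  # 0 at edge, max at centre
  opd <- (n - 1) * thick
  wf <- wavefront_map(opd, sample_pitch_um, wavelength_um)
  sample_phantom(matrix(1, grid[1], grid[2]), wf,
                 list(kind = "microlens", pitch_um = pitch_um,
                      focal_mm = focal_mm, n = n, R_um = R,
                      magnification = magnification,
                      sag_um = sag_edge, opd_drop_um = (n - 1) * sag_edge))
}

#' Sinusoidal OPD phantom
#'
#' `OPD(x, y) = H cos(omega x)` with unit amplitude; the maximum OPD
#' curvature `H omega^2` is recorded in the truth metadata.
#'
#' @param H_um sinusoid amplitude in micrometres.
#' @param omega_rad_per_um angular frequency along x in rad/um; must be below
#'   the grid Nyquist `pi / sample_pitch`.
#' @param grid output dimensions `c(rows, cols)`.
#' @param sample_pitch_um grid sample spacing in micrometres.
#' @param wavelength_um nominal wavelength for the OPD map.
#' @return A [sample_phantom()].
#' @export
sinusoid_phantom <- function(H_um, omega_rad_per_um, grid = c(256L, 256L),
                             sample_pitch_um = 6.45, wavelength_um = 0.5328) {
  if (omega_rad_per_um > pi / sample_pitch_um) {
    stop("omega is above the grid Nyquist frequency", call. = FALSE)
  }
  ax <- grid_axes(grid, sample_pitch_um)
  opd <- matrix(rep(H_um * cos(omega_rad_per_um * ax$x), each = grid[1]),
                grid[1], grid[2])
  wf <- wavefront_map(opd, sample_pitch_um, wavelength_um)
  sample_phantom(matrix(1, grid[1], grid[2]), wf,
                 list(kind = "sinusoid", H_um = H_um,
                      omega_rad_per_um = omega_rad_per_um,
                      max_curvature_per_um = H_um * omega_rad_per_um^2))
}

#' Constant-curvature OPD phantom
#'
#' Paraboloid `OPD = (c / 4) (x^2 + y^2)` whose Laplacian is the constant
#' curvature `c` everywhere.
#'
#' @param curvature_per_m OPD Laplacian in 1/m (1 m^-1 = 1e-6 um^-1).
#' @param grid output dimensions `c(rows, cols)`.
#' @param sample_pitch_um grid sample spacing in micrometres.
#' @param wavelength_um nominal wavelength for the OPD map.
#' @return A [sample_phantom()].
#' @export
curvature_phantom <- function(curvature_per_m, grid = c(256L, 256L),
                              sample_pitch_um = 6.45, wavelength_um = 0.5328) {
  if (!is.finite(curvature_per_m)) stop("curvature must be finite", call. = FALSE)
  c_um <- curvature_per_m * 1e-6            # 1/um
  ax <- grid_axes(grid, sample_pitch_um)
  opd <- (c_um / 4) * outer(ax$y^2, ax$x^2, `+`)
  wf <- wavefront_map(opd, sample_pitch_um, wavelength_um)
  sample_phantom(matrix(1, grid[1], grid[2]), wf,
                 list(kind = "curvature", curvature_per_m = curvature_per_m))
}

#' Torus / blob cell phantom
#'
#' Parametric optical-path-difference model of a thin transparent cell. The
#' `torus` kind emulates the bowl-like indentation of a red blood cell as a
#' difference of two radial Gaussians: a broad disc minus a narrower central
#' dip, giving a ring maximum and a local minimum at the centre. An optional
#' amplitude dip inside the cell (values in `[1 - amplitude_dip, 1]`) creates
#' the absorption/refraction tangle typical of stained or dense samples. The
#' `blob` kind is a single smooth Gaussian bump.
#'
#' @param kind `"torus"` or `"blob"`.
#' @param peak_opd_um peak OPD in micrometres (default 0.4).
#' @param width_um Gaussian width of the OPD envelope; the torus ring radius
#'   emerges from `width_um`, `dip_width_um` and `dip_depth`.
#' @param dip_width_um width of the central indentation (torus only).
#' @param dip_depth relative depth of the central OPD indentation, in
#'   `[0, 1]` (torus only).
#' @param amplitude_dip amplitude attenuation at the cell centre, in
#'   `[0, 0.3]`; 0 gives a pure-phase object.
#' @param grid output dimensions `c(rows, cols)`.
#' @param sample_pitch_um grid sample spacing in micrometres.
#' @param wavelength_um nominal wavelength for the OPD map.
#' @param center_um cell centre `c(x, y)` in micrometres from the grid centre.
#' @return A [sample_phantom()].
#' @export
cell_phantom <- function(kind = c("torus", "blob"), peak_opd_um = 0.4,
                         width_um = 90, dip_width_um = 60,
                         dip_depth = 0.6, amplitude_dip = 0,
                         grid = c(256L, 256L), sample_pitch_um = 6.45,
                         wavelength_um = 0.5328, center_um = c(0, 0)) {
  kind <- match.arg(kind)
  if (amplitude_dip < 0 || amplitude_dip > 0.3) {
    stop("amplitude_dip must be in [0, 0.3]", call. = FALSE)
  }
  ax <- grid_axes(grid, sample_pitch_um)
  r2 <- outer((ax$y - center_um[2])^2, (ax$x - center_um[1])^2, `+`)
  envelope <- exp(-r2 / (2 * width_um^2))
  if (kind == "torus") {
    dip <- dip_depth * exp(-r2 / (2 * dip_width_um^2))
    shape <- envelope * (1 - dip)
  } else {
    shape <- envelope
  }
  opd <- peak_opd_um * shape / max(shape)
  amp <- 1 - amplitude_dip * exp(-r2 / (2 * (0.9 * width_um)^2))
  wf <- wavefront_map(opd, sample_pitch_um, wavelength_um)
  sample_phantom(amp, wf,
                 list(kind = kind, peak_opd_um = peak_opd_um,
                      width_um = width_um,
                      dip_width_um = dip_width_um, dip_depth = dip_depth,
                      amplitude_dip = amplitude_dip))
}

#' Pure tilt phantom
#'
#' Linear OPD ramp `OPD = gx x + gy y` (slopes in um of OPD per um), the
#' canonical calibration wavefront: it shifts the whole speckle pattern by
#' `z * grad(OPD)` micrometres.
#'
#' @param gx,gy OPD slopes along x and y (dimensionless, um/um).
#' @param grid output dimensions `c(rows, cols)`.
#' @param sample_pitch_um grid sample spacing in micrometres.
#' @param wavelength_um nominal wavelength for the OPD map.
#' @return A [sample_phantom()] with unit amplitude.
#' @export
tilt_phantom <- function(gx, gy = 0, grid = c(256L, 256L),
                         sample_pitch_um = 6.45, wavelength_um = 0.5328) {
  ax <- grid_axes(grid, sample_pitch_um)
  opd <- outer(gy * ax$y, gx * ax$x, `+`)
  wf <- wavefront_map(opd, sample_pitch_um, wavelength_um)
  sample_phantom(matrix(1, grid[1], grid[2]), wf,
                 list(kind = "tilt", gx = gx, gy = gy))
}
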