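# File formats: 8/16-bit grayscale TIFF in, 32-bit float TIFF out, YAML run
# configuration, CSV tables, and a small JSON diagnostics writer.

#' Read a grayscale TIFF as an intensity image
#'
#' Integer TIFFs are returned by the reader on a 0--1 scale; the
#' reconstruction pipeline is invariant to a global intensity scale, so no
#' rescaling is applied.
#'
#' @param path TIFF file path.
#' @param pitch_um pixel pitch to attach, micrometres.
#' @return An [intensity_image()].
#' @export
read_intensity_tiff <- function(path, pitch_um) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  intensity_image(v, pitch_um)
}

#' Write an intensity image as a 16-bit grayscale TIFF
#'
#' Values are scaled by the image maximum onto the full 16-bit range.
#'
#' @param img an [intensity_image()].
#' @param path output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_intensity_tiff <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  mx <- max(img$values)
  v <- if (mx > 0) img$values / mx else img$values
  tiff::writeTIFF(v, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write a numeric matrix as a 32-bit TIFF with a scale sidecar
#'
#' Used for OPD maps (micrometres) and amplitude images, which need signed
#' fractional values. The matrix is affinely mapped onto the full 32-bit
#' range and the offset/scale recorded in a `.meta` text sidecar, so
#' [read_float_tiff()] restores the physical values to better than 1e-9
#' relative precision.
#'
#' @param values numeric matrix.
#' @param path output path; the sidecar is written at `paste0(path, ".meta")`.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(values, path) {
  lo <- min(values)
  rng <- max(values) - lo
  if (rng == 0) rng <- 1
  tiff::writeTIFF((values - lo) / rng, path, bits.per.sample = 32L,
                  reduce = FALSE)
  writeLines(c(sprintf("offset: %.17g", lo), sprintf("scale: %.17g", rng)),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read a 32-bit scaled TIFF (with sidecar) as a matrix
#'
#' Restores physical values using the `.meta` sidecar written by
#' [write_float_tiff()]; without a sidecar the raw 0--1 values are returned.
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_float_tiff <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    ln <- readLines(meta)
    off <- as.numeric(sub("^offset: *", "", ln[grepl("^offset:", ln)]))
    sc <- as.numeric(sub("^scale: *", "", ln[grepl("^scale:", ln)]))
    v <- v * sc + off
  }
  v
}

#' Write a mask pattern to TIFF plus a text sidecar
#'
#' The binary feature pattern is stored as an 8-bit TIFF; the sidecar
#' records seed, feature pitch, phase levels and grid metadata so the mask
#' is fully reproducible.
#'
#' @param mask a [make_mask()] pattern.
#' @param path output TIFF path; the sidecar gets extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask$values * 1.0, path, bits.per.sample = 8L)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".txt")
  writeLines(c(
    sprintf("seed: %s", format(mask$seed)),
    sprintf("mask_pixel_um: %.6g", mask$mask_pixel_um),
    sprintf("phase_levels_rad: %.8g %.8g", mask$phase_levels[1], mask$phase_levels[2]),
    sprintf("block_px: %d", mask$block_px),
    sprintf("sim_shape: %d %d", mask$sim_shape[1], mask$sim_shape[2]),
    sprintf("edge_sigma_um: %.6g", mask$edge_sigma_um)
  ), sidecar)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration (YAML).

config_schema <- list(
  geometry = c("z_um", "wavelength_um", "sensor_pitch_um", "mask_pixel_um"),
  solver = c("alpha", "beta", "gamma", "tau", "outer_iters", "inner_iters",
             "warp_linearizations", "tol"),
  simulation = c("seed", "oversample", "guard_px", "shape"),
  paths = c("output_dir")
)

#' Default run configuration
#'
#' The calibrated prototype geometry, the published solver weights, and the
#' default simulation controls, as a nested list matching the YAML layout.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    geometry = list(z_um = 1430, wavelength_um = 0.5328,
                    sensor_pitch_um = 6.45, mask_pixel_um = 12.9),
    solver = list(alpha = 0.1, beta = 0.1, gamma = 100, tau = 5,
                  outer_iters = 3L, inner_iters = 8L,
                  warp_linearizations = 3L, tol = 1e-5),
    simulation = list(seed = 0L, oversample = 4L, guard_px = 32L,
                      shape = c(96L, 96L)),
    paths = list(output_dir = ".")
  )
}

validate_run_config <- function(config) {
  unknown_blocks <- setdiff(names(config), names(config_schema))
  if (length(unknown_blocks)) {
    stop("unknown configuration block(s): ", paste(unknown_blocks, collapse = ", "),
         call. = FALSE)
  }
  for (block in names(config_schema)) {
    if (is.null(config[[block]])) {
      stop("missing configuration block: ", block, call. = FALSE)
    }
    unknown <- setdiff(names(config[[block]]), config_schema[[block]])
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in '%s': %s", block,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    missing <- setdiff(config_schema[[block]], names(config[[block]]))
    if (length(missing)) {
      stop(sprintf("missing key(s) in '%s': %s", block,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(config)
}

#' Read and validate a YAML run configuration
#'
#' The configuration has four blocks with unit-suffixed keys — `geometry`
#' (`z_um`, `wavelength_um`, `sensor_pitch_um`, `mask_pixel_um`), `solver`
#' (`alpha`, `beta`, `gamma`, `tau`, `outer_iters`, `inner_iters`,
#' `warp_linearizations`, `tol`), `simulation` (`seed`, `oversample`,
#' `guard_px`, `shape`) and `paths` (`output_dir`). Unknown or missing keys
#' raise a named error.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

config_geometry <- function(config) {
  gb <- config$geometry
  sensor_geometry(z_um = gb$z_um, wavelength_um = gb$wavelength_um,
                  sensor_pitch_um = gb$sensor_pitch_um,
                  mask_pixel_um = gb$mask_pixel_um)
}

config_solver_params <- function(config) {
  sb <- config$solver
  solver_params(alpha = sb$alpha, beta = sb$beta, gamma = sb$gamma,
                tau = sb$tau, outer_iters = sb$outer_iters,
                inner_iters = sb$inner_iters,
                warp_linearizations = sb$warp_linearizations, tol = sb$tol)
}

# minimal JSON writer for flat named lists of numbers/strings/logicals
write_json_simple <- function(x, path) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  fmt <- function(v) {
    if (is.character(v)) sprintf("\"%s\"", esc(v))
    else if (is.logical(v)) ifelse(v, "true", "false")
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  items <- vapply(names(x), function(k) {
    v <- x[[k]]
    val <- if (length(v) == 1L) fmt(v)
           else sprintf("[%s]", paste(vapply(v, fmt, character(1)), collapse = ", "))
    sprintf("  \"%s\": %s", esc(k), val)
  }, character(1))
  writeLines(c("{", paste(items, collapse = ",\n"), "}"), path)
  invisible(path)
}
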