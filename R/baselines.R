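# Classical sequential baseline: windowed subpixel cross-correlation of the
# speckle pattern (slope tracking), followed by least-squares curl-free
# integration of the tracked displacement field.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)

# core tracker on plain matrices; returns window-centre displacement grids
# upsampled to the full image grid
track_slopes_core <- function(ref, img, window_px = 32L, stride = window_px %/% 2L,
                              upsample = 50L) {
  nr <- nrow(ref); nc <- ncol(ref)
  w <- as.integer(window_px)
  stride <- as.integer(stride)
  cy <- seq(1L, nr - w + 1L, by = stride)
  cx <- seq(1L, nc - w + 1L, by = stride)
  taper <- outer(hann_window(w), hann_window(w))
  DX <- matrix(NA_real_, length(cy), length(cx))
  DY <- matrix(NA_real_, length(cy), length(cx))
  for (a in seq_along(cy)) {
    for (b in seq_along(cx)) {
      rr <- cy[a]:(cy[a] + w - 1L); cc <- cx[b]:(cx[b] + w - 1L)
      p0 <- ref[rr, cc]; p1 <- img[rr, cc]
      if (stats::sd(p0) < 1e-6 * (mean(p0) + 1e-12)) next   # textureless
      s <- estimate_shift((p0 - mean(p0)) * taper, (p1 - mean(p1)) * taper,
                          upsample = upsample)
      if (max(abs(s)) > w / 4) next                          # implausible
      DY[a, b] <- s[["dy"]]; DX[a, b] <- s[["dx"]]
    }
  }
  DX <- inpaint_na(DX); DY <- inpaint_na(DY)
  # window centres in full-grid pixel coordinates
  ctr_y <- cy + (w - 1) / 2
  ctr_x <- cx + (w - 1) / 2
  list(dx = grid_upsample(DX, ctr_y, ctr_x, nr, nc),
       dy = grid_upsample(DY, ctr_y, ctr_x, nr, nc))
}

# fill NA cells from the mean of available neighbours, iteratively
inpaint_na <- function(m) {
  if (!anyNA(m)) return(m)
  if (all(is.na(m))) stop("no valid displacement windows: is speckle present?",
                          call. = FALSE)
  while (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    filled <- m
    for (i in seq_len(nrow(bad))) {
      r <- bad[i, 1]; c <- bad[i, 2]
      nb <- c(if (r > 1) m[r - 1, c], if (r < nrow(m)) m[r + 1, c],
              if (c > 1) m[r, c - 1], if (c < ncol(m)) m[r, c + 1])
      if (any(!is.na(nb))) filled[r, c] <- mean(nb, na.rm = TRUE)
    }
    m <- filled
  }
  m
}

# bilinear upsampling from values at (ctr_y, ctr_x) to the full pixel grid,
# with replicate extrapolation beyond the outermost window centres
grid_upsample <- function(vals, ctr_y, ctr_x, nr, nc) {
  fy <- stats::approx(ctr_y, seq_along(ctr_y), xout = seq_len(nr), rule = 2)$y
  fx <- stats::approx(ctr_x, seq_along(ctr_x), xout = seq_len(nc), rule = 2)$y
  xq <- matrix(rep(fx, each = nr), nr, nc)
  yq <- matrix(rep(fy, nc), nr, nc)
  interp_bilinear(vals, xq, yq)
}

#' Track speckle displacements by windowed cross-correlation
#'
#' Classical slope tracking: the reference and measurement are divided into
#' overlapping Hann-tapered windows; each window's displacement is the
#' cross-correlation peak, refined to subpixel precision by local upsampled
#' DFT evaluation. Textureless or implausible windows are flagged invalid
#' and inpainted from their neighbours; the window-centre grid is bilinearly
#' upsampled to the full image grid.
#'
#' @param I0 reference [intensity_image()].
#' @param I measurement [intensity_image()].
#' @param geometry a [sensor_geometry()].
#' @param window_px correlation window size in pixels (>= 8).
#' @param stride window stride in pixels (default half the window).
#' @return A [slope_field()] of displacements in sensor pixels.
#' @export
track_slopes <- function(I0, I, geometry, window_px = 32L,
                         stride = window_px %/% 2L) {
  if (!grids_congruent(I0$values, I$values)) {
    stop("reference and measurement images must be congruent", call. = FALSE)
  }
  if (window_px < 8L) stop("window_px must be at least 8", call. = FALSE)
  tr <- track_slopes_core(I0$values, I$values, window_px, stride)
  slope_field(tr$dx, tr$dy, geometry)
}

#' Integrate a displacement field into a wavefront
#'
#' Least-squares curl-free integration: the per-pixel phase gradient implied
#' by the displacements is integrated by a single Neumann Poisson solve
#' (divergence of the slopes as source), yielding the zero-mean wavefront
#' whose gradient field is the curl-free projection of the input.
#'
#' @param slopes a [slope_field()] in sensor pixels.
#' @return A [wavefront_map()] (zero-mean OPD in micrometres).
#' @export
integrate_slopes <- function(slopes) {
  g <- slopes$geometry
  cpix <- pixel_disp_scale(g)
  sx <- slopes$dx / cpix          # phase gradient, rad per pixel
  sy <- slopes$dy / cpix
  phi <- poisson_neumann_px(-(dx_adjoint(sx) + dy_adjoint(sy)))
  phi <- phi - mean(phi)
  wavefront_map(g$wavelength_um * phi / (2 * pi), g$sensor_pitch_um,
                g$wavelength_um)
}

#' Slope-tracking wavefront reconstruction (sequential baseline)
#'
#' Runs [track_slopes()] followed by [integrate_slopes()] and tilt removal:
#' the classical two-stage speckle-tracking pipeline used as a comparison
#' baseline for [solve_joint()].
#'
#' @inheritParams track_slopes
#' @return A [wavefront_map()] (zero-mean, tilt-removed OPD).
#' @export
slope_tracking_reconstruct <- function(I0, I, geometry, window_px = 32L,
                                       stride = window_px %/% 2L) {
  remove_tilt(integrate_slopes(track_slopes(I0, I, geometry, window_px, stride)))
}
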