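# Joint amplitude + phase reconstruction from one reference/measurement
# speckle pair.
#
# The solver minimizes
#   || I(r + c grad phi) - v I0 ||_2^2
#     + alpha ||grad phi||_1 + beta (||grad phi||_2^2 + ||lap phi||_2^2)
#     + gamma (||grad v||_1 + ||lap v||_1) + tau (||grad v||_2^2 + ||lap v||_2^2)
# over the wavefront phi and the modulated intensity v = |A~|^2, alternating
# between the two unknowns. The warped data term is linearized by
# Gauss-Newton around the current phi; each subproblem is solved by
# scaled-form ADMM (soft-thresholding for the L1 terms, conjugate gradient
# for the quadratic normal equations). Images are normalized to the 0-255
# gray scale, the scale on which the default tradeoff weights are calibrated.
#
# Numerical safeguards specific to speckle data: the sensor samples the
# speckle close to its Nyquist rate, so (i) all warping samples a sinc
# (Fourier) upsampled measurement rather than interpolating the raw pixels,
# (ii) the Gauss-Newton passes run over a decreasing Gaussian pre-filter
# schedule (graduated non-convexity: heavily blurred speckle has a wide
# linearization basin, the final passes use the raw images), (iii) each step
# is Levenberg-damped and trust-region limited to a fraction of the speckle
# grain, and (iv) a backtracking safeguard accepts an update only if the
# objective does not increase, making the objective trace non-increasing by
# construction.

central_diff_x <- function(u) {
  n <- ncol(u)
  (u[, c(2:n, n), drop = FALSE] - u[, c(1, 1:(n - 1)), drop = FALSE]) / 2
}

central_diff_y <- function(u) {
  n <- nrow(u)
  (u[c(2:n, n), , drop = FALSE] - u[c(1, 1:(n - 1)), , drop = FALSE]) / 2
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# displacement scale: pixels of speckle shift per unit of per-pixel phase
# gradient (rad / px)
pixel_disp_scale <- function(geometry, pitch_um = geometry$sensor_pitch_um) {
  geometry$wavelength_um * geometry$z_um / (2 * pi * pitch_um^2)
}

normalize_pair <- function(I0, I) {
  s <- 255 / max(I0)
  list(I0n = I0 * s, In = I * s, scale = s)
}

# data-term context: (optionally pre-blurred) reference plus a sinc-fine
# sampler of the matching measurement, with cached pixel coordinate grids
make_warp_ctx <- function(I0n, In, sigma = 0, fine_factor = 4L) {
  nr <- nrow(I0n); nc <- ncol(I0n)
  if (sigma > 0) {
    I0s <- gauss_blur_fft(I0n, sigma)
    Ins <- gauss_blur_fft(In, sigma)
  } else {
    I0s <- I0n; Ins <- In
  }
  list(I0 = I0s,
       sampler = make_fine_sampler(Ins, fine_factor),
       xg = matrix(rep(seq_len(nc), each = nr), nr, nc),
       yg = matrix(rep(seq_len(nr), nc), nr, nc))
}

warp_measurement <- function(ctx, ux, uy) ctx$sampler(ctx$xg + ux, ctx$yg + uy)

# objective in a given data context; phi in rad, v dimensionless
objective_core <- function(phi, v, ctx, cpix, params) {
  ux <- cpix * dx_forward(phi); uy <- cpix * dy_forward(phi)
  Iw <- warp_measurement(ctx, ux, uy)
  data <- sum((Iw - v * ctx$I0)^2)
  dphx <- dx_forward(phi); dphy <- dy_forward(phi)
  lphi <- laplacian_px(phi)
  dvx <- dx_forward(v); dvy <- dy_forward(v)
  lv <- laplacian_px(v)
  data +
    params$alpha * (sum(abs(dphx)) + sum(abs(dphy))) +
    params$beta * (sum(dphx^2) + sum(dphy^2) + sum(lphi^2)) +
    params$gamma * (sum(abs(dvx)) + sum(abs(dvy)) + sum(abs(lv))) +
    params$tau * (sum(dvx^2) + sum(dvy^2) + sum(lv^2))
}

#' Evaluate the joint reconstruction objective
#'
#' Computes the data term plus all regularization terms for a candidate
#' wavefront and modulated intensity, with the images normalized to the
#' 0--255 scale assumed by the default tradeoff weights. Useful for
#' monitoring and for verifying monotonicity of the solver.
#'
#' @param wavefront a [wavefront_map()] on the sensor grid.
#' @param intensity_sq matrix of modulated intensity `|A~|^2`.
#' @param I0,I reference and measurement [intensity_image()]s.
#' @param geometry a [sensor_geometry()].
#' @param params a [solver_params()].
#' @return Scalar objective value.
#' @export
eval_objective <- function(wavefront, intensity_sq, I0, I, geometry,
                           params = solver_params()) {
  if (!grids_congruent(I0$values, I$values) ||
      !grids_congruent(I0$values, wavefront$opd_um) ||
      !grids_congruent(I0$values, as.matrix(intensity_sq))) {
    stop("all grids must be congruent", call. = FALSE)
  }
  if (any(!is.finite(wavefront$opd_um)) || any(!is.finite(intensity_sq))) {
    stop("inputs must be finite", call. = FALSE)
  }
  nrm <- normalize_pair(I0$values, I$values)
  ctx <- make_warp_ctx(nrm$I0n, nrm$In)
  phi <- 2 * pi * wavefront$opd_um / geometry$wavelength_um
  cpix <- pixel_disp_scale(geometry, I0$pitch_um)
  objective_core(phi, as.matrix(intensity_sq), ctx, cpix, params)
}

# One Gauss-Newton + ADMM pass over the phase in context ctx.
#
# The Gauss-Newton increment carries its own smoothness penalty
# (kappa * s * (||grad dphi||^2 + ||lap dphi||^2), with s the mean data-term
# curvature): pointwise, a speckle pattern can be re-matched by many small
# displacement fields, so the unregularized linearized step is dominated by
# a non-physical pixel-scale solution. Penalizing the *increment* (not the
# accumulated phase) disambiguates the matching without biasing the final
# wavefront amplitude: at convergence the increments vanish and the penalty
# contributes nothing.
phi_admm_update <- function(phi, v, ctx, cpix, params) {
  ux <- cpix * dx_forward(phi); uy <- cpix * dy_forward(phi)
  Iw <- warp_measurement(ctx, ux, uy)
  d <- 0.5
  Gx <- (ctx$sampler(ctx$xg + ux + d, ctx$yg + uy) -
           ctx$sampler(ctx$xg + ux - d, ctx$yg + uy)) / (2 * d)
  Gy <- (ctx$sampler(ctx$xg + ux, ctx$yg + uy + d) -
           ctx$sampler(ctx$xg + ux, ctx$yg + uy - d)) / (2 * d)
  r0 <- Iw - v * ctx$I0
  L <- function(p) cpix * (Gx * dx_forward(p) + Gy * dy_forward(p))
  Lt <- function(q) cpix * (dx_adjoint(Gx * q) + dy_adjoint(Gy * q))
  rho <- params$rho_phase
  beta <- params$beta
  ks <- params$increment_smooth * mean(2 * cpix^2 * (Gx^2 + Gy^2))
  reg_inc <- function(p) {
    ks * (-laplacian_px(p) + laplacian_px(laplacian_px(p)))
  }
  Aop <- function(p) {
    DtD <- -laplacian_px(p)
    2 * Lt(L(p)) + 2 * beta * (DtD + laplacian_px(laplacian_px(p))) +
      rho * DtD + reg_inc(p)
  }
  wxp <- 2 * cpix^2 * mean(Gx^2) + 2 * beta + rho + ks
  wyp <- 2 * cpix^2 * mean(Gy^2) + 2 * beta + rho + ks
  pre <- make_dct_preconditioner(nrow(phi), ncol(phi), wxp, wyp,
                                 2 * beta + ks, 1e-6 * (wxp + wyp))
  psi <- phi
  wx <- dx_forward(phi); wy <- dy_forward(phi)
  ddx <- 0 * phi; ddy <- 0 * phi
  b_data <- 2 * Lt(L(phi) - r0) + reg_inc(phi)
  for (it in seq_len(params$inner_iters)) {
    b <- b_data + rho * (dx_adjoint(wx - ddx) + dy_adjoint(wy - ddy))
    psi <- preconditioned_cg(Aop, b, pre, x0 = psi, maxit = params$cg_iters)
    px <- dx_forward(psi); py <- dy_forward(psi)
    wx <- soft_threshold(px + ddx, params$alpha / rho)
    wy <- soft_threshold(py + ddy, params$alpha / rho)
    ddx <- ddx + px - wx
    ddy <- ddy + py - wy
  }
  psi
}

# ADMM pass over the modulated intensity v = |A~|^2 (always in the
# unblurred context)
v_admm_update <- function(phi, v, ctx, cpix, params) {
  ux <- cpix * dx_forward(phi); uy <- cpix * dy_forward(phi)
  Iw <- warp_measurement(ctx, ux, uy)
  I0n <- ctx$I0
  rho <- params$rho_intensity
  tau <- params$tau
  Aop <- function(p) {
    DtD <- -laplacian_px(p)
    LtL <- laplacian_px(laplacian_px(p))
    2 * I0n^2 * p + 2 * tau * (DtD + LtL) + rho * DtD + rho * LtL
  }
  w1x <- dx_forward(v); w1y <- dy_forward(v); w2 <- laplacian_px(v)
  d1x <- 0 * v; d1y <- 0 * v; d2 <- 0 * v
  b_data <- 2 * I0n * Iw
  pre <- make_dct_preconditioner(nrow(v), ncol(v), 2 * tau + rho,
                                 2 * tau + rho, 2 * tau + rho,
                                 2 * mean(I0n^2))
  for (it in seq_len(params$inner_iters)) {
    b <- b_data + rho * (dx_adjoint(w1x - d1x) + dy_adjoint(w1y - d1y)) +
      rho * laplacian_px(w2 - d2)
    v <- preconditioned_cg(Aop, b, pre, x0 = v, maxit = params$cg_iters)
    px <- dx_forward(v); py <- dy_forward(v); pl <- laplacian_px(v)
    w1x <- soft_threshold(px + d1x, params$gamma / rho)
    w1y <- soft_threshold(py + d1y, params$gamma / rho)
    w2 <- soft_threshold(pl + d2, params$gamma / rho)
    d1x <- d1x + px - w1x
    d1y <- d1y + py - w1y
    d2 <- d2 + pl - w2
  }
  v[v < 0] <- 0
  v
}

# accept `new` only if the objective does not increase; otherwise backtrack
# toward `old` (halving up to 5 times), falling back to `old`
safeguarded_step <- function(old, new, eval_fn, E_old) {
  cand <- new
  for (k in 0:5) {
    E_new <- eval_fn(cand)
    if (E_new <= E_old + 1e-9 * max(1, abs(E_old))) {
      return(list(x = cand, E = E_new))
    }
    cand <- old + 0.5 * (cand - old)
  }
  list(x = old, E = E_old)
}

box_downsample2 <- function(x) box_downsample(x, 2L)

upsample2 <- function(x, shape) {
  nr <- shape[1]; nc <- shape[2]
  xq <- matrix(rep((seq_len(nc) + 0.5) / 2, each = nr), nr, nc)
  yq <- matrix(rep((seq_len(nr) + 0.5) / 2, nc), nr, nc)
  interp_bilinear(x, xq, yq)
}

# estimate the largest local speckle displacement with a coarse windowed track
estimate_max_displacement <- function(I0n, In) {
  sl <- track_slopes_core(I0n, In, window_px = 32L, stride = 32L,
                          upsample = 10L)
  max(abs(c(sl$dx, sl$dy)), na.rm = TRUE)
}

# pre-filter and increment-smoothing schedules for the Gauss-Newton passes
# of one pyramid level: geometric decay from (sigma0, kappa0) to the floors
blur_schedule <- function(n_pass, sigma0, sigma_min) {
  pmax(sigma_min, sigma0 * 2^(-(seq_len(n_pass) - 1)))
}

kappa_schedule <- function(n_pass, kappa0) {
  pmax(0.2 * kappa0, kappa0 * 2^(-(seq_len(n_pass) - 1) / 2))
}

# initial wavefront phase from windowed correlation tracking plus Poisson
# integration of the tracked displacement field
init_phi_track <- function(I0n, In, cpix) {
  n_min <- min(dim(I0n))
  w <- max(12L, min(24L, n_min %/% 4L))
  tr <- track_slopes_core(I0n, In, window_px = w, stride = max(4L, w %/% 3L))
  sx <- tr$dx / cpix
  sy <- tr$dy / cpix
  poisson_neumann_px(-(dx_adjoint(sx) + dy_adjoint(sy)))
}

joint_core <- function(I0n, In, cpix, params, update_v = TRUE, levels = 1L,
                       sigma0 = 1.5) {
  if (levels > 1L) {
    coarse <- joint_core(box_downsample2(I0n), box_downsample2(In),
                         cpix / 4, params, update_v, levels - 1L, sigma0)
    phi <- upsample2(coarse$phi, dim(I0n))
    v <- if (update_v) upsample2(coarse$v, dim(I0n))
         else matrix(1, nrow(I0n), ncol(I0n))
  } else {
    phi <- if (params$init == "track") {
      tryCatch(init_phi_track(I0n, In, cpix),
               error = function(e) matrix(0, nrow(I0n), ncol(I0n)))
    } else matrix(0, nrow(I0n), ncol(I0n))
    v <- matrix(1, nrow(I0n), ncol(I0n))
  }
  # the solver minimizes the objective with the data images pre-filtered at
  # the floor sigma; this is the objective reported in the trace
  sig_min <- params$data_smooth_px
  ctx_floor <- make_warp_ctx(I0n, In, sigma = sig_min)
  n_pass <- params$outer_iters * params$warp_linearizations
  sigmas <- blur_schedule(n_pass, sigma0, sig_min)
  kappas <- kappa_schedule(n_pass, params$increment_smooth)
  ctx_cache <- list()
  get_ctx <- function(sig) {
    if (abs(sig - sig_min) < 1e-9) return(ctx_floor)
    key <- sprintf("%.3f", sig)
    if (is.null(ctx_cache[[key]])) {
      ctx_cache[[key]] <<- make_warp_ctx(I0n, In, sigma = sig)
    }
    ctx_cache[[key]]
  }
  E <- objective_core(phi, v, ctx_floor, cpix, params)
  trace <- E
  pass <- 0L
  for (outer in seq_len(params$outer_iters)) {
    phi_bak <- phi; E_bak <- E
    for (gn in seq_len(params$warp_linearizations)) {
      pass <- pass + 1L
      ctx <- get_ctx(sigmas[pass])
      pars <- params
      pars$increment_smooth <- kappas[pass]
      cand <- phi_admm_update(phi, v, ctx, cpix, pars)
      st <- safeguarded_step(
        phi, cand, function(p) objective_core(p, v, ctx, cpix, params),
        objective_core(phi, v, ctx, cpix, params))
      phi <- st$x
    }
    # monotonicity of the floor objective across the outer iteration
    st <- safeguarded_step(phi_bak, phi,
                           function(p) objective_core(p, v, ctx_floor, cpix, params),
                           E_bak)
    phi <- st$x; E <- st$E
    if (update_v) {
      cand <- v_admm_update(phi, v, ctx_floor, cpix, params)
      st <- safeguarded_step(v, cand,
                             function(q) objective_core(phi, q, ctx_floor, cpix, params),
                             E)
      v <- st$x; E <- st$E
    }
    E_prev <- trace[length(trace)]
    trace <- c(trace, E)
    if (abs(E_prev - E) <= params$tol * max(1, abs(E_prev)) &&
        outer >= 2L) break
  }
  list(phi = phi, v = v, trace = trace)
}

solver_setup <- function(I0, I, geometry, params) {
  if (!grids_congruent(I0$values, I$values)) {
    stop("reference and measurement images must be congruent", call. = FALSE)
  }
  if (all(I0$values == 0)) stop("reference image is identically zero", call. = FALSE)
  nrm <- normalize_pair(I0$values, I$values)
  cpix <- pixel_disp_scale(geometry, I0$pitch_um)
  md <- if (params$pyramid == "auto") {
    tryCatch(estimate_max_displacement(nrm$I0n, nrm$In), error = function(e) 0)
  } else 0
  levels <- switch(params$pyramid,
                   off = 1L,
                   on = 2L,
                   auto = if (!is.finite(md) || md <= 3) 1L
                          else max(2L, 1L + ceiling(log2(md / 1.5))))
  sigma0 <- if (is.finite(md) && md > 1.5) min(4, md) else 1.5
  list(nrm = nrm, cpix = cpix, levels = levels, sigma0 = sigma0)
}

#' Joint amplitude and phase reconstruction
#'
#' Recovers the wavefront (as OPD) and the modulated intensity `|A~|^2` from
#' one reference/measurement speckle image pair by alternating regularized
#' optimization of the warped-speckle data model (see the package vignette
#' for the model and algorithm). The returned wavefront is zero-mean with
#' the least-squares affine plane removed; the sample amplitude is obtained
#' from `|A~|` by undoing the caustic modulation
#' (`A = A~ sqrt(1 + z lap OPD)`).
#'
#' @param I0 reference [intensity_image()] (no sample in the path).
#' @param I measurement [intensity_image()], same shape.
#' @param geometry a [sensor_geometry()] (calibrated `z`).
#' @param params a [solver_params()].
#' @return An object of class `recon_result` with fields `wavefront`
#'   ([wavefront_map()]), `modulated_intensity` (`|A~|^2` matrix),
#'   `amplitude` (corrected `A` matrix), `objective_trace` (non-increasing),
#'   and `diagnostics` (residual norm, curvature-factor range, amplitude
#'   clamp count, convergence flag).
#' @export
solve_joint <- function(I0, I, geometry, params = solver_params()) {
  su <- solver_setup(I0, I, geometry, params)
  fit <- joint_core(su$nrm$I0n, su$nrm$In, su$cpix, params, update_v = TRUE,
                    levels = su$levels, sigma0 = su$sigma0)
  finalize_recon(fit, su$nrm, geometry, I0$pitch_um, params)
}

#' Curl-free optical-flow baseline
#'
#' Phase-only variant of [solve_joint()]: the displacement field is
#' parameterized directly as the gradient of the wavefront (hence curl-free)
#' and optimized against the pure warp model `I(r + c grad phi) = I0(r)`
#' with the same phase priors, but sample amplitude and the caustic factor
#' are not modelled. This is the classical speckle-flow baseline: accurate
#' for pure-phase samples, biased when the sample absorbs.
#'
#' @inheritParams solve_joint
#' @return A [wavefront_map()] (zero-mean, tilt-removed OPD).
#' @export
curl_free_flow <- function(I0, I, geometry, params = solver_params()) {
  su <- solver_setup(I0, I, geometry, params)
  fit <- joint_core(su$nrm$I0n, su$nrm$In, su$cpix, params, update_v = FALSE,
                    levels = su$levels, sigma0 = su$sigma0)
  res <- finalize_recon(fit, su$nrm, geometry, I0$pitch_um, params)
  res$wavefront
}

finalize_recon <- function(fit, nrm, geometry, pitch_um, params) {
  lambda <- geometry$wavelength_um
  opd <- lambda * fit$phi / (2 * pi)
  wf_raw <- wavefront_map(opd, pitch_um, lambda)
  wf <- remove_tilt(wf_raw)
  corr <- amplitude_from_modulated(fit$v, wf, geometry)
  cpix <- pixel_disp_scale(geometry, pitch_um)
  ctx <- make_warp_ctx(nrm$I0n, nrm$In)
  ux <- cpix * dx_forward(fit$phi); uy <- cpix * dy_forward(fit$phi)
  resid <- warp_measurement(ctx, ux, uy) - fit$v * nrm$I0n
  h <- pitch_um
  cf <- 1 - geometry$z_um * laplacian_px(wf$opd_um) / h^2
  n_tr <- length(fit$trace)
  converged <- n_tr >= 2 &&
    abs(fit$trace[n_tr - 1] - fit$trace[n_tr]) <=
      params$tol * max(1, abs(fit$trace[n_tr - 1]))
  structure(list(
    wavefront = wf,
    modulated_intensity = fit$v,
    amplitude = corr$amplitude,
    objective_trace = fit$trace,
    diagnostics = list(residual_rms = rms(resid),
                       curvature_factor_range = range(cf),
                       amplitude_clamp_count = corr$clamped,
                       converged = converged)),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "<recon_result> %d x %d px, OPD range [%.4g, %.4g] um, residual RMS %.4g, %d outer steps\n",
    nrow(x$wavefront$opd_um), ncol(x$wavefront$opd_um),
    min(x$wavefront$opd_um), max(x$wavefront$opd_um),
    x$diagnostics$residual_rms, length(x$objective_trace) - 1L))
  invisible(x)
}

amplitude_from_modulated <- function(v, wavefront, geometry, eps = 1e-3) {
  h <- wavefront$pitch_um
  fac <- 1 + geometry$z_um * laplacian_px(wavefront$opd_um) / h^2
  clamped <- sum(fac < eps)
  fac[fac < eps] <- eps
  list(amplitude = sqrt(pmax(v, 0)) * sqrt(fac), clamped = clamped)
}

#' Undo the caustic modulation of the recovered amplitude
#'
#' Applies `A = A~ sqrt(1 + (lambda z / 2 pi) lap(phi))`: the modulated
#' amplitude recovered by the joint solver, corrected for the intensity
#' change caused by local wavefront curvature. Where the correction factor
#' falls below a small positive floor (`1e-3`) it is clamped and counted.
#'
#' @param result a `recon_result` from [solve_joint()].
#' @param geometry a [sensor_geometry()].
#' @return Matrix of corrected amplitudes `A`.
#' @export
correct_amplitude <- function(result, geometry) {
  amplitude_from_modulated(result$modulated_intensity, result$wavefront,
                           geometry)$amplitude
}

#' Remove the best-fit affine plane from a wavefront
#'
#' Subtracts the least-squares affine plane `a + b x + c y` from the OPD map,
#' removing piston and tilt: the standard post-processing that isolates the
#' sample-relative phase from coverslip or alignment tilt. The output is
#' orthogonal to `{1, x, y}` and the operation is idempotent.
#'
#' @param wavefront a [wavefront_map()].
#' @return A [wavefront_map()] with zero mean and zero net tilt.
#' @export
remove_tilt <- function(wavefront) {
  z <- wavefront$opd_um
  nr <- nrow(z); nc <- ncol(z)
  x <- rep(seq_len(nc) - (nc + 1) / 2, each = nr)
  y <- rep(seq_len(nr) - (nr + 1) / 2, nc)
  zz <- as.vector(z)
  # centred coordinates make the normal equations diagonal
  b <- sum(zz * x) / sum(x * x)
  c <- sum(zz * y) / sum(y * y)
  a <- mean(zz)
  fit <- a + b * x + c * y
  wavefront_map(matrix(zz - fit, nr, nc), wavefront$pitch_um,
                wavefront$wavelength_um)
}
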