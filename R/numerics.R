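# Internal numerical kernels shared by the simulator and the solvers.
#
# Conventions used throughout the package:
#   * images are numeric matrices, rows = y, columns = x;
#   * spatial derivatives use forward differences with replicate (Neumann)
#     boundaries, so the discrete gradient/divergence pair is an exact
#     adjoint pair and the Laplacian -(Dx'Dx + Dy'Dy) is symmetric;
#   * all physical lengths are micrometres.

# forward difference along x (columns); last column 0 (Neumann)
dx_forward <- function(u) {
  n <- ncol(u)
  u[, c(seq_len(n - 1L) + 1L, n), drop = FALSE] - u
}

dy_forward <- function(u) {
  n <- nrow(u)
  u[c(seq_len(n - 1L) + 1L, n), , drop = FALSE] - u
}

# exact adjoint of dx_forward (negative backward divergence)
dx_adjoint <- function(v) {
  n <- ncol(v)
  out <- matrix(0, nrow(v), n)
  out[, 1L] <- -v[, 1L]
  if (n > 2L) {
    j <- 2:(n - 1L)
    out[, j] <- v[, j - 1L] - v[, j]
  }
  out[, n] <- v[, n - 1L]
  out
}

dy_adjoint <- function(v) {
  n <- nrow(v)
  out <- matrix(0, n, ncol(v))
  out[1L, ] <- -v[1L, ]
  if (n > 2L) {
    i <- 2:(n - 1L)
    out[i, ] <- v[i - 1L, ] - v[i, ]
  }
  out[n, ] <- v[n - 1L, ]
  out
}

# 5-point Neumann Laplacian in pixel units, defined as -(Dx'Dx + Dy'Dy) so it
# is exactly self-adjoint with respect to the gradient pair above
laplacian_px <- function(u) {
  -(dx_adjoint(dx_forward(u)) + dy_adjoint(dy_forward(u)))
}

# ---------------------------------------------------------------------------
# DCT-II / DCT-III transforms via FFT of the even-mirrored sequence.

dct_cols <- function(x) {
  n <- nrow(x)
  y <- rbind(x, x[n:1, , drop = FALSE])
  yf <- stats::mvfft(y)
  w <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  Re(yf[seq_len(n), , drop = FALSE] * w) / 2
}

idct_cols <- function(X) {
  n <- nrow(X)
  w <- exp(1i * pi * (0:(n - 1)) / (2 * n))
  Yk <- 2 * X * w
  Ytail <- Conj(Yk[n:2, , drop = FALSE])
  Y <- rbind(Yk, matrix(0 + 0i, 1L, ncol(X)), Ytail)
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / (2 * n)
  y[seq_len(n), , drop = FALSE]
}

dct2d <- function(x) t(dct_cols(t(dct_cols(x))))

idct2d <- function(X) t(idct_cols(t(idct_cols(X))))

# Solve laplacian_px(u) = f (pixel units) with Neumann boundaries; the DCT-II
# basis diagonalizes -(D'D), eigenvalues 2 cos(pi k / n) - 2 per axis.
# Returns the zero-mean solution.
poisson_neumann_px <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  F <- dct2d(f - mean(f))
  ev_r <- 2 * cos(pi * (0:(nr - 1)) / nr) - 2
  ev_c <- 2 * cos(pi * (0:(nc - 1)) / nc) - 2
  den <- outer(ev_r, ev_c, `+`)
  den[1L, 1L] <- 1
  F <- F / den
  F[1L, 1L] <- 0
  idct2d(F)
}

# ---------------------------------------------------------------------------
# Interpolation / warping.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Catmull-Rom bicubic sampling of img at fractional 1-based coordinates
# (xq = column coordinate, yq = row coordinate); replicate boundary.
interp_bicubic <- function(img, xq, yq) {
  nr <- nrow(img); nc <- ncol(img)
  out_dim <- dim(xq)
  xq <- clamp(xq, 1, nc)
  yq <- clamp(yq, 1, nr)
  j0 <- floor(xq); i0 <- floor(yq)
  tx <- xq - j0; ty <- yq - i0

  wcub <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(
      (-t3 + 2 * t2 - t) / 2,
      (3 * t3 - 5 * t2 + 2) / 2,
      (-3 * t3 + 4 * t2 + t) / 2,
      (t3 - t2) / 2
    )
  }
  wx <- wcub(tx); wy <- wcub(ty)

  out <- 0
  for (a in -1:2) {
    ia <- clamp(i0 + a, 1, nr)
    row_acc <- 0
    for (b in -1:2) {
      jb <- clamp(j0 + b, 1, nc)
      row_acc <- row_acc + wx[[b + 2L]] * img[cbind(as.vector(ia), as.vector(jb))]
    }
    out <- out + as.vector(wy[[a + 2L]]) * row_acc
  }
  matrix(out, out_dim[1], out_dim[2])
}

interp_bilinear <- function(img, xq, yq) {
  nr <- nrow(img); nc <- ncol(img)
  out_dim <- dim(xq)
  xq <- clamp(xq, 1, nc)
  yq <- clamp(yq, 1, nr)
  j0 <- clamp(floor(xq), 1, nc - 1L); i0 <- clamp(floor(yq), 1, nr - 1L)
  tx <- xq - j0; ty <- yq - i0
  idx <- function(i, j) img[cbind(as.vector(i), as.vector(j))]
  v <- (1 - tx) * (1 - ty) * idx(i0, j0) +
    tx * (1 - ty) * idx(i0, j0 + 1L) +
    (1 - tx) * ty * idx(i0 + 1L, j0) +
    tx * ty * idx(i0 + 1L, j0 + 1L)
  matrix(v, out_dim[1], out_dim[2])
}

# Backward warp: sample img at (x + ux, y + uy) on the pixel grid.
warp_image <- function(img, ux, uy, method = c("cubic", "linear")) {
  method <- match.arg(method)
  nr <- nrow(img); nc <- ncol(img)
  xg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr), nc), nr, nc)
  if (method == "cubic") interp_bicubic(img, xg + ux, yg + uy)
  else interp_bilinear(img, xg + ux, yg + uy)
}

# ---------------------------------------------------------------------------
# Conjugate gradient for SPD operators given as closures over matrices.

cg_solve <- function(amul, b, x0 = NULL, maxit = 100L, tol = 1e-9) {
  x <- if (is.null(x0)) 0 * b else x0
  r <- b - amul(x)
  p <- r
  rs <- sum(r * r)
  b2 <- sum(b * b)
  if (b2 == 0) return(0 * b)
  for (it in seq_len(maxit)) {
    Ap <- amul(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (rs_new <= tol^2 * b2) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

# spectral (FFT) partial derivatives, periodic boundary; exact for
# band-limited fields
spectral_gradient <- function(u, h = 1) {
  nr <- nrow(u); nc <- ncol(u)
  fy <- fft_freq_idx(nr) / (nr * h)
  fx <- fft_freq_idx(nc) / (nc * h)
  U <- stats::fft(u)
  gx <- Re(stats::fft(U * matrix(rep(2i * pi * fx, each = nr), nr, nc),
                      inverse = TRUE)) / (nr * nc)
  gy <- Re(stats::fft(U * matrix(2i * pi * fy, nr, nc),
                      inverse = TRUE)) / (nr * nc)
  list(gx = gx, gy = gy)
}

preconditioned_cg <- function(amul, b, precond, x0 = NULL, maxit = 100L,
                              tol = 1e-9) {
  x <- if (is.null(x0)) 0 * b else x0
  r <- b - amul(x)
  z <- precond(r)
  p <- z
  rz <- sum(r * z)
  b2 <- sum(b * b)
  if (b2 == 0) return(0 * b)
  for (it in seq_len(maxit)) {
    Ap <- amul(p)
    alpha <- rz / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sum(r * r) <= tol^2 * b2) break
    z <- precond(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

# DCT-domain inverse of a constant-coefficient operator
#   wx * Dx'Dx + wy * Dy'Dy + wlap * (Dx'Dx + Dy'Dy)^2 + wid * I
# used as a preconditioner for the spatially varying normal equations
make_dct_preconditioner <- function(nr, nc, wx, wy, wlap, wid) {
  ev_r <- 2 - 2 * cos(pi * (0:(nr - 1)) / nr)   # eigenvalues of Dy'Dy
  ev_c <- 2 - 2 * cos(pi * (0:(nc - 1)) / nc)   # eigenvalues of Dx'Dx
  lam_x <- matrix(rep(ev_c, each = nr), nr, nc)
  lam_y <- matrix(ev_r, nr, nc)
  den <- wx * lam_x + wy * lam_y + wlap * (lam_x + lam_y)^2 + wid
  den[den < 1e-12] <- 1e-12
  function(r) idct2d(dct2d(r) / den)
}

# ---------------------------------------------------------------------------
# Subpixel image registration: FFT cross-correlation peak refined by local
# upsampled DFT evaluation (matrix-product kernel).

fft_freq_idx <- function(n) {
  # unshifted integer frequencies matching fft ordering
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
}

estimate_shift <- function(ref, img, upsample = 100L) {
  nr <- nrow(ref); nc <- ncol(ref)
  F1 <- stats::fft(ref - mean(ref))
  F2 <- stats::fft(img - mean(img))
  R <- F2 * Conj(F1)
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  if (upsample <= 1L) return(c(dy = dy, dx = dx))

  # refine within +-1.5 coarse pixels at 1/upsample resolution
  us <- as.numeric(upsample)
  half <- ceiling(1.5 * us)
  off_y <- (-half:half) / us + dy
  off_x <- (-half:half) / us + dx
  fy <- fft_freq_idx(nr) / nr
  fx <- fft_freq_idx(nc) / nc
  Ky <- exp(2i * pi * outer(off_y, fy))      # (ny_off x nr)
  Kx <- exp(2i * pi * outer(fx, off_x))      # (nc x nx_off)
  cc_up <- Re(Ky %*% R %*% Kx)
  pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
  c(dy = off_y[pk2[1]], dx = off_x[pk2[2]])
}

# quadratic refinement of a 1-d sampled maximum
parabolic_refine <- function(xs, ys, i) {
  n <- length(xs)
  if (i <= 1L || i >= n) return(xs[i])
  y1 <- ys[i - 1L]; y2 <- ys[i]; y3 <- ys[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den == 0) return(xs[i])
  xs[i] + 0.5 * (y1 - y3) / den * (xs[i + 1L] - xs[i])
}

# run code with a private RNG state so package simulation never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rms <- function(x) sqrt(mean(x^2))

# zero-pad a column-wise FFT spectrum for f-fold sinc upsampling; the
# Nyquist bin of even-length inputs is split symmetrically so real inputs
# stay real
pad_spectrum_cols <- function(X, f) {
  n <- nrow(X); N <- n * f
  Y <- matrix(0 + 0i, N, ncol(X))
  h <- floor(n / 2)
  if (n %% 2 == 0) {
    Y[1:h, ] <- X[1:h, , drop = FALSE]
    Y[h + 1, ] <- X[h + 1, ] / 2
    Y[N - h + 1, ] <- X[h + 1, ] / 2
    if (h > 1) Y[(N - h + 2):N, ] <- X[(h + 2):n, , drop = FALSE]
  } else {
    Y[1:(h + 1), ] <- X[1:(h + 1), , drop = FALSE]
    Y[(N - h + 1):N, ] <- X[(h + 2):n, , drop = FALSE]
  }
  Y
}

upsample_cols_fft <- function(x, f) {
  stats::mvfft(pad_spectrum_cols(stats::mvfft(x), f), inverse = TRUE) / nrow(x)
}

# band-limited (sinc) upsampling by integer factor f; fine-grid index k maps
# to coarse coordinate (k - 1) / f + 1
fft_upsample <- function(x, f = 2L) {
  if (f == 1L) return(x)
  Re(t(upsample_cols_fft(t(upsample_cols_fft(x + 0i, f)), f)))
}

# sample a coarse-grid image at fractional coarse coordinates using its
# sinc-upsampled version (cubic interpolation on the fine grid)
make_fine_sampler <- function(img, f = 4L) {
  fine <- fft_upsample(img, f)
  function(xq, yq) interp_bicubic(fine, (xq - 1) * f + 1, (yq - 1) * f + 1)
}

# isotropic Gaussian blur via FFT (periodic boundary), sigma in pixels
gauss_blur_fft <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  fy <- fft_freq_idx(nr) / nr
  fx <- fft_freq_idx(nc) / nc
  H <- exp(-2 * pi^2 * sigma_px^2 *
             (matrix(fy^2, nr, nc) + matrix(rep(fx^2, each = nr), nr, nc)))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / (nr * nc)
}
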