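#' Bilinear event weights on the analysis grid
#'
#' Distributes each event's unit mass onto the (at most) four nodes of the
#' 257 x 257 grid cell that contains it, with bilinear weights, so the
#' total grid mass equals the number of events exactly. This linear binning
#' is the prerequisite of the transform-based kernel density estimate.
#'
#' @param x,y Event coordinates on the unit scale (both in `[0, 1]`).
#' @return A 257 x 257 matrix of nonnegative weights; entry `[i, j]` is the
#'   mass at grid coordinate `((i-1)/256, (j-1)/256)`.
#' @export
compute_weights <- function(x, y) {
  stopifnot(length(x) == length(y))
  gx <- x * 256; gy <- y * 256
  i0 <- pmin(floor(gx), 255); fx <- gx - i0
  j0 <- pmin(floor(gy), 255); fy <- gy - j0
  idx <- c((i0 + 1) + 257 * j0,        # (i0, j0)
           (i0 + 2) + 257 * j0,        # (i0+1, j0)
           (i0 + 1) + 257 * (j0 + 1),  # (i0, j0+1)
           (i0 + 2) + 257 * (j0 + 1))  # (i0+1, j0+1)
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  agg <- rowsum(w, idx)
  out <- numeric(GRID_N * GRID_N)
  out[as.integer(rownames(agg))] <- agg
  matrix(out, GRID_N, GRID_N)
}

# Circularly symmetric sampled Gaussian on the period-512 even extension,
# normalized to unit sum, and its FFT. kernel_sd is in scale units.
kernel_fft <- function(kernel_sd) {
  sigma_g <- kernel_sd * 256
  k <- 0:511
  d <- pmin(k, 512 - k)
  kern <- exp(-0.5 * (d / sigma_g)^2)
  kern <- kern / sum(kern)
  list(kern = kern, fft = Re(stats::fft(kern)), fft2 = Re(stats::fft(kern^2)))
}

# Smooth a 257x257 array with the separable sampled-Gaussian kernel via FFT
# on the whole-sample even extension (period 2*257 - 2 = 512), i.e. exact
# DCT-I-domain filtering with reflective boundary conditions. `kf_col` is
# the (real) FFT of the 1-D kernel to apply in each direction.
dct_smooth <- function(arr, kf) {
  ext <- c(1:257, 256:2)
  E <- arr[ext, ext]
  FE <- stats::fft(E)
  Re(stats::fft(FE * outer(kf, kf), inverse = TRUE))[1:257, 1:257] / 512^2
}

#' Gaussian kernel density estimate via discrete cosine transform
#'
#' Smooths a bilinear weight array with an isotropic Gaussian kernel of
#' standard deviation `kernel_sd` (in scale units), applied in the cosine
#' transform domain as multiplication by the transform of the discretely
#' sampled kernel. The cosine transform implies reflective (even) boundary
#' conditions at the edges of the unit square. The result is normalized so
#' its trapezoidal integral over the unit square is exactly 1.
#'
#' @param weights 257 x 257 weight array from [compute_weights()].
#' @param kernel_sd Kernel standard deviation W as a fraction of full
#'   scale; must be at least one grid step (1/256).
#' @return A 257 x 257 density array (unit integral).
#' @export
kde_dct <- function(weights, kernel_sd) {
  if (kernel_sd < GRID_STEP)
    stop("kernel_sd below the grid resolution (1/256) is not supported")
  kf <- kernel_fft(kernel_sd)
  smooth <- dct_smooth(weights, kf$fft)
  smooth[smooth < 0] <- 0
  normalize_density(smooth)
}

trapz_integral <- function(arr) {
  wt <- rep(1, GRID_N); wt[c(1, GRID_N)] <- 0.5
  as.numeric(t(wt) %*% arr %*% wt) * GRID_STEP^2
}

normalize_density <- function(arr) arr / trapz_integral(arr)

#' Density grid for one dimension pair
#'
#' Bundles the weight array, the normalized density estimate, and the
#' pointwise variance of the estimate (from a second, squared-kernel
#' transform pass) for one two-dimensional projection.
#'
#' @param x,y Unit-scale event coordinates.
#' @param kernel_sd Initial kernel standard deviation W.
#' @return An `epp_density_grid`: list with `weights`, `density`,
#'   `variance`, `kernel_sd`, `n_events`, `pass_count`, `prev_density`.
#' @export
density_grid <- function(x, y, kernel_sd) {
  w <- compute_weights(x, y)
  g <- list(weights = w, n_events = length(x), kernel_sd = kernel_sd,
            pass_count = 0L, prev_density = NULL)
  class(g) <- "epp_density_grid"
  refresh_density(g)
}

# (Re)compute density and variance arrays for the current kernel width.
refresh_density <- function(grid) {
  kf <- kernel_fft(grid$kernel_sd)
  smooth <- dct_smooth(grid$weights, kf$fft)
  smooth[smooth < 0] <- 0
  raw <- smooth * 256^2 / grid$n_events
  I <- trapz_integral(raw)
  grid$density <- raw / I
  s <- 256^2 / (grid$n_events * I)
  v <- dct_smooth(grid$weights, kf$fft2) * s^2
  v[v < 0] <- 0
  grid$variance <- v
  grid
}

#' Widen the kernel by sqrt(2)
#'
#' Used when a projection yields too many clusters or a pathological
#' cluster graph: the bandwidth is coarsened by a factor of sqrt(2) and the
#' density recomputed from the same weights. The previous density array is
#' retained on the grid object.
#'
#' @param grid An `epp_density_grid`.
#' @param max_passes Cap on the number of widenings; exceeding it is an
#'   error (callers treat the population as a leaf for this projection).
#' @return The updated `epp_density_grid`.
#' @export
widen_kernel <- function(grid, max_passes = 8L) {
  if (grid$pass_count >= max_passes)
    stop("kernel widening cap exceeded")
  grid$prev_density <- grid$density
  grid$kernel_sd <- grid$kernel_sd * sqrt(2)
  grid$pass_count <- grid$pass_count + 1L
  refresh_density(grid)
}
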