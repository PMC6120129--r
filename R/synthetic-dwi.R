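#' Diffusion gradient schemes
#'
#' A gradient scheme pairs a b-value (s/mm^2) with a unit gradient direction
#' for every acquisition volume; b = 0 volumes carry a zero vector. The
#' default scheme mirrors a high angular resolution post-mortem acquisition:
#' 60 directions spread quasi-uniformly on the sphere by a golden-spiral
#' construction, acquired twice with opposite gradient polarity, plus 4
#' non-diffusion-weighted volumes, at b = 2871.50 s/mm^2.
#'
#' @param bvals numeric vector of b-values, one per volume.
#' @param bvecs numeric matrix (n x 3) of gradient directions; rows with
#'   b > 0 must be unit-norm within 1e-9, b = 0 rows must be zero.
#' @return object of class `gradient_scheme` with fields `bvals`, `bvecs`,
#'   `n_b0`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  stopifnot(ncol(bvecs) == 3L, length(bvals) == nrow(bvecs), all(bvals >= 0))
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-9)) {
    stop("diffusion-weighted directions must be unit vectors (|norm - 1| <= 1e-9)")
  }
  if (any(nrm[!dw] > 1e-12)) stop("b = 0 volumes must have zero direction")
  if (sum(dw) > 0 && length(unique(round(bvals[dw], 6))) != 1L) {
    stop("all diffusion-weighted volumes must share one nominal b-value")
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 n_b0 = sum(!dw)),
            class = "gradient_scheme")
}

#' @rdname gradient_scheme
#' @param n_directions number of distinct directions before polarity doubling.
#' @param b nominal b-value in s/mm^2.
#' @param n_b0 number of b = 0 volumes.
#' @export
default_gradient_scheme <- function(n_directions = 60L, b = 2871.50,
                                    n_b0 = 4L) {
  dirs <- sphere_spiral_directions(n_directions)
  bvecs <- rbind(matrix(0, n_b0, 3L), dirs, -dirs)
  bvals <- c(rep(0, n_b0), rep(b, 2L * n_directions))
  gradient_scheme(bvals, bvecs)
}

# n quasi-uniform unit vectors on the sphere (golden-spiral / Fibonacci).
sphere_spiral_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  d / sqrt(rowSums(d^2))
}

#' Simulate diffusion-weighted signal from a tensor field
#'
#' Applies the mono-exponential tensor forward model
#' `S = s0 * exp(-b * g' D g)` voxel-wise for every volume of the gradient
#' scheme, optionally adding independent Gaussian noise. The additive Gaussian
#' (rather than Rician) noise model reflects a high-SNR post-mortem regime and
#' keeps the log-linear tensor fit an exact inverse at zero noise.
#'
#' @param tensors a [tensor_volume].
#' @param scheme a [gradient_scheme].
#' @param s0 non-diffusion-weighted signal amplitude (> 0).
#' @param noise_sd standard deviation of additive Gaussian noise, in signal
#'   units (0 = noise-free).
#' @param seed integer seed for the noise substream.
#' @return a [dwi_volume] with `length(scheme$bvals)` volumes.
#' @export
simulate_dwi <- function(tensors, scheme, s0 = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(tensors, "tensor_volume"),
            inherits(scheme, "gradient_scheme"))
  if (s0 <= 0) stop("s0 must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dims <- dim(tensors$D)[1:3]
  nvox <- prod(dims)
  nvol <- length(scheme$bvals)
  Dm <- matrix(tensors$D, nvox, 6L)
  # per-volume quadratic form coefficients against (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz)
  g <- scheme$bvecs
  Q <- rbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  Qb <- sweep(Q, 2, scheme$bvals, "*")   # 6 x nvol, b folded in
  S <- s0 * exp(-(Dm %*% Qb))            # nvox x nvol
  if (noise_sd > 0) {
    S <- S + with_substream(seed, "dwi_noise",
                            matrix(stats::rnorm(nvox * nvol, sd = noise_sd),
                                   nvox, nvol))
  }
  dwi_volume(array(S, dim = c(dims, nvol)), tensors$voxel_size)
}
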