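#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves the ordinary least-squares problem
#' `log S_k = log s0 - b_k g_k' D g_k` for the six unique tensor elements and
#' `log s0`, using all volumes of the scheme. Exact on noise-free
#' mono-exponential data. Voxels containing any non-positive signal are
#' excluded from the fit (zero tensor) and counted in the
#' `"n_excluded"` attribute.
#'
#' @param dwi a [dwi_volume].
#' @param scheme the matching [gradient_scheme]; needs at least six
#'   non-collinear diffusion-weighted directions and one b = 0 volume.
#' @param mask optional 3D logical array; voxels outside are zeroed.
#' @return a [tensor_volume] with attribute `"n_excluded"`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(scheme, "gradient_scheme"))
  dims <- dim(dwi$data)[1:3]
  nvol <- dim(dwi$data)[4]
  if (nvol != length(scheme$bvals)) {
    stop("gradient table length does not match DWI volume count")
  }
  if (sum(scheme$bvals > 0) < 6L || scheme$n_b0 < 1L) {
    stop("need >= 6 diffusion-weighted directions and >= 1 b = 0 volume")
  }
  g <- scheme$bvecs
  X <- cbind(1, -scheme$bvals * cbind(
    g[, 1]^2, g[, 2]^2, g[, 3]^2,
    2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]))
  if (qr(X)$rank < 7L) stop("gradient directions are collinear; cannot fit")
  nvox <- prod(dims)
  S <- matrix(dwi$data, nvox, nvol)
  use <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)
  pos <- rowSums(S > 0) == nvol
  fit_vox <- use & pos
  n_excluded <- sum(use & !pos)
  Dm <- matrix(0, nvox, 6L)
  if (any(fit_vox)) {
    beta <- qr.solve(X, t(log(S[fit_vox, , drop = FALSE])))  # 7 x nfit
    Dm[fit_vox, ] <- t(beta[2:7, , drop = FALSE])
  }
  out <- tensor_volume(array(Dm, dim = c(dims, 6L)), dwi$voxel_size,
                       mask = if (is.null(mask)) NULL else mask)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Eigen-decompose a tensor volume
#'
#' @param tensors a [tensor_volume].
#' @param mask optional 3D logical array restricting the decomposition; the
#'   tensor volume's own mask is used when present.
#' @return list with `values` (4D array, dims `c(grid, 3)`, eigenvalues in
#'   descending order) and `vectors` (5D array, dims `c(grid, 3, 3)`, column
#'   `[, , , , j]` holding the eigenvector of the j-th eigenvalue); voxels with
#'   non-finite tensor entries get NA values and are counted in attribute
#'   `"n_flagged"`.
#' @export
eigen_decompose <- function(tensors, mask = NULL) {
  stopifnot(inherits(tensors, "tensor_volume"))
  dims <- dim(tensors$D)[1:3]
  nvox <- prod(dims)
  Dm <- matrix(tensors$D, nvox, 6L)
  if (is.null(mask)) mask <- tensors$mask
  use <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)
  vals <- matrix(NA_real_, nvox, 3L)
  vecs <- array(NA_real_, dim = c(nvox, 3L, 3L))
  n_flagged <- 0L
  for (i in which(use)) {
    v <- Dm[i, ]
    if (!all(is.finite(v))) { n_flagged <- n_flagged + 1L; next }
    e <- eigen(tensor6_to_mat(v), symmetric = TRUE)
    vals[i, ] <- e$values
    vecs[i, , ] <- e$vectors
  }
  out <- list(values = array(vals, dim = c(dims, 3L)),
              vectors = array(vecs, dim = c(dims, 3L, 3L)),
              voxel_size = tensors$voxel_size)
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Fractional anisotropy, radial and axial diffusivity maps
#'
#' Standard eigenvalue definitions: `FA = sqrt(3/2) * sqrt(sum((l - MD)^2) /
#' sum(l^2))`, `RD = (l2 + l3) / 2`, `AD = l1`. The degenerate all-zero tensor
#' maps to FA = 0 (avoids 0/0); negative eigenvalues are clamped to zero
#' before the FA computation and counted in the `"n_clamped"` attribute.
#'
#' @param eig result of [eigen_decompose()].
#' @return a [scalar_volume] of the requested kind.
#' @export
fa_map <- function(eig) {
  ev <- eigenvalue_matrix(eig)
  neg <- ev < 0
  n_clamped <- sum(neg, na.rm = TRUE)
  if (n_clamped > 0) {
    warning(sprintf("%d negative eigenvalues clamped to 0", n_clamped))
    ev[neg] <- 0
  }
  md <- rowMeans(ev)
  ss <- rowSums(ev^2)
  dev <- rowSums((ev - md)^2)
  fa <- sqrt(1.5) * sqrt(dev / ss)
  fa[!is.finite(fa)] <- 0        # all-zero tensors and unmasked NA voxels
  fa <- pmin(pmax(fa, 0), 1)
  out <- scalar_volume(array(fa, dim = dim(eig$values)[1:3]),
                       eig$voxel_size, kind = "FA")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' @rdname fa_map
#' @export
rd_map <- function(eig) {
  ev <- eigenvalue_matrix(eig)
  rd <- (ev[, 2] + ev[, 3]) / 2
  rd[!is.finite(rd)] <- 0
  scalar_volume(array(rd, dim = dim(eig$values)[1:3]), eig$voxel_size,
                kind = "RD")
}

#' @rdname fa_map
#' @export
ad_map <- function(eig) {
  ad <- eigenvalue_matrix(eig)[, 1]
  ad[!is.finite(ad)] <- 0
  scalar_volume(array(ad, dim = dim(eig$values)[1:3]), eig$voxel_size,
                kind = "AD")
}

eigenvalue_matrix <- function(eig) {
  dims <- dim(eig$values)
  matrix(eig$values, prod(dims[1:3]), 3L)
}

#' White matter mask from an FA map
#'
#' A voxel is white matter iff its FA is at or above the threshold and it lies
#' inside the hemisphere mask; the complement within the hemisphere is gray
#' matter.
#'
#' @param fa an FA [scalar_volume].
#' @param threshold FA threshold (default 0.2).
#' @param hemisphere_mask optional 3D logical array (default: whole grid).
#' @return 3D logical array.
#' @export
white_matter_mask <- function(fa, threshold = 0.2, hemisphere_mask = NULL) {
  stopifnot(inherits(fa, "scalar_volume"))
  m <- fa$data >= threshold
  if (!is.null(hemisphere_mask)) m <- m & hemisphere_mask
  m
}

#' Tissue volumes and white-matter diffusion summaries
#'
#' Volumes are voxel counts times the voxel volume; FA/RD/AD means are taken
#' over white matter voxels only. With an empty white matter mask the means
#' are reported as NA while the volumes are still emitted.
#'
#' @param fa,rd,ad scalar volumes on a common grid.
#' @param wm_mask white matter mask (3D logical).
#' @param hemisphere_mask hemisphere mask (3D logical).
#' @param voxel_size voxel edge lengths in mm (default taken from `fa`).
#' @return data.frame with one row: wm/gm/hemisphere volumes (mm^3) and mean
#'   FA, RD, AD over white matter.
#' @export
tissue_summary <- function(fa, rd, ad, wm_mask, hemisphere_mask,
                           voxel_size = fa$voxel_size) {
  stopifnot(identical(dim(fa$data), dim(wm_mask)),
            identical(dim(fa$data), dim(hemisphere_mask)))
  wm <- wm_mask & hemisphere_mask
  vv <- prod(expand_voxel_size(voxel_size))
  n_hemi <- sum(hemisphere_mask)
  n_wm <- sum(wm)
  data.frame(
    wm_volume = n_wm * vv,
    gm_volume = (n_hemi - n_wm) * vv,
    hemisphere_volume = n_hemi * vv,
    mean_fa = if (n_wm > 0) mean(fa$data[wm]) else NA_real_,
    mean_rd = if (n_wm > 0) mean(rd$data[wm]) else NA_real_,
    mean_ad = if (n_wm > 0) mean(ad$data[wm]) else NA_real_
  )
}

#' Welch two-sample comparison of group values
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @return list with `t` and `p` (two-sided). Degenerate zero-variance input
#'   with equal means yields `t = 0, p = 1`; with unequal means,
#'   `t = +/-Inf, p = 0`.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    if (d == 0) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  ht <- stats::t.test(values_a, values_b)   # Welch by default
  list(t = unname(ht$statistic), p = ht$p.value)
}
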