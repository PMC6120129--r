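#' Generate a block-parcellated atlas phantom
#'
#' Partitions the interior of a 3D grid into one contiguous rectangular block
#' per region, arranged on the deterministic lattice of [region_layout()], with
#' a one-voxel background margin (label 0) around the grid. Axis cut points
#' are jittered by up to one voxel under the given seed, so different seeds
#' give slightly different parcellations while every region stays non-empty.
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_size voxel edge length in mm (default 0.2, isotropic).
#' @param regions region table (default the bundled 42-region catalogue).
#' @param seed integer seed for the boundary jitter.
#' @return an [atlas_volume] whose non-zero labels are exactly the region ids.
#' @export
make_atlas_phantom <- function(grid_shape, voxel_size = 0.2,
                               regions = region_table(), seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3))
  n <- nrow(regions)
  lay <- region_layout(n)
  ldim <- attr(lay, "lattice_dim")
  interior <- grid_shape - 2L  # one-voxel background margin per side
  if (any(interior < ldim)) {
    stop(sprintf("grid too small: interior %s cannot host a %s region lattice",
                 paste(interior, collapse = "x"),
                 paste(ldim, collapse = "x")))
  }
  cuts <- with_substream(seed, "atlas_phantom", {
    lapply(1:3, function(a) jittered_cuts(interior[a], ldim[a]))
  })
  labels <- array(0L, dim = grid_shape)
  for (r in seq_len(n)) {
    sx <- cuts[[1]][lay$ix[r] + 1L]:(cuts[[1]][lay$ix[r] + 2L] - 1L)
    sy <- cuts[[2]][lay$iy[r] + 1L]:(cuts[[2]][lay$iy[r] + 2L] - 1L)
    sz <- cuts[[3]][lay$iz[r] + 1L]:(cuts[[3]][lay$iz[r] + 2L] - 1L)
    labels[sx + 1L, sy + 1L, sz + 1L] <- regions$id[r]
  }
  got <- sort(unique(as.vector(labels)))
  if (!all(regions$id %in% got)) {
    stop("grid too small for all regions to be non-empty")
  }
  atlas_volume(labels, voxel_size)
}

# Monotone 0-based cut points splitting `len` interior voxels (offset by the
# margin) into `k` non-empty segments, jittered by at most one voxel.
jittered_cuts <- function(len, k) {
  base <- round(seq(0, len, length.out = k + 1L))
  if (k > 1L) {
    jit <- sample(c(-1L, 0L, 1L), k - 1L, replace = TRUE)
    base[2:k] <- base[2:k] + jit
    base <- cummax(pmin(pmax(base, 0), len))
    # enforce non-empty segments
    for (i in 2:(k + 1L)) if (base[i] <= base[i - 1L]) base[i] <- base[i - 1L] + 1L
    if (base[k + 1L] > len) stop("grid too small for jittered partition")
  }
  base + 1L  # shift past the 1-voxel margin; still 0-based voxel indices
}

#' Specify a fiber bundle for the tensor phantom
#'
#' @param start_region,end_region region ids the bundle is meant to connect
#'   (provenance metadata; endpoint placement is up to the caller).
#' @param centerline numeric matrix (k x 3) of points in mm tracing the bundle.
#' @param radius tube radius in mm.
#' @param axial_diffusivity,radial_diffusivity tensor eigenvalues in mm^2/s
#'   along and across the bundle; axial must exceed radial. Defaults are
#'   typical fixed post-mortem white matter values.
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(start_region, end_region, centerline, radius,
                        axial_diffusivity = 0.7e-3,
                        radial_diffusivity = 0.2e-3) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3L, nrow(centerline) >= 2L,
            radius > 0,
            axial_diffusivity > radial_diffusivity,
            radial_diffusivity > 0)
  structure(list(start_region = start_region, end_region = end_region,
                 centerline = centerline, radius = radius,
                 axial_diffusivity = axial_diffusivity,
                 radial_diffusivity = radial_diffusivity),
            class = "bundle_spec")
}

#' Build a diffusion tensor field containing fiber bundles
#'
#' Voxels whose centers lie within a bundle tube receive the anisotropic
#' tensor `RD*I + (AD-RD) * t t'` whose principal eigenvector `t` is the local
#' centerline tangent; all other voxels receive the isotropic tensor
#' `background_diffusivity * I`. All tensors are symmetric positive-definite
#' by construction. Where bundles overlap, the last bundle in the list wins
#' and a warning is raised.
#'
#' @param atlas an [atlas_volume] fixing the grid and voxel size.
#' @param bundles list of [bundle_spec] objects.
#' @param background_diffusivity isotropic background diffusivity in mm^2/s.
#' @param seed reserved for future stochastic phantom features; the current
#'   construction is fully deterministic.
#' @return a [tensor_volume].
#' @export
make_bundle_tensor_field <- function(atlas, bundles,
                                     background_diffusivity = 0.3e-3,
                                     seed = 1L) {
  stopifnot(inherits(atlas, "atlas_volume"), background_diffusivity > 0)
  dims <- dim(atlas$labels)
  vs <- atlas$voxel_size
  D <- array(0, dim = c(dims, 6L))
  D[, , , 1:3] <- background_diffusivity
  owner <- array(0L, dim = dims)
  overlap <- FALSE

  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    dense <- densify_polyline(b$centerline, min(vs) / 4)
    pts <- dense$points
    tans <- dense$tangents
    if (any(pts < 0) ||
        any(sweep(pts, 2, dims * vs, ">="))) {
      stop(sprintf("bundle %d centerline leaves the grid", bi))
    }
    # candidate voxels: bounding box of the centerline padded by the radius
    lo <- pmax(floor((apply(pts, 2, min) - b$radius) / vs), 0)
    hi <- pmin(floor((apply(pts, 2, max) + b$radius) / vs), dims - 1L)
    vx <- seq(lo[1], hi[1]); vy <- seq(lo[2], hi[2]); vz <- seq(lo[3], hi[3])
    cand <- as.matrix(expand.grid(x = vx, y = vy, z = vz))
    centers <- sweep(cand + 0.5, 2, vs, "*")
    # nearest densified centerline point per candidate voxel center
    nn <- nearest_point_index(centers, pts)
    d2 <- rowSums((centers - pts[nn, , drop = FALSE])^2)
    inside <- d2 <= b$radius^2
    if (!any(inside)) next
    sel <- cand[inside, , drop = FALSE] + 1L  # to 1-based array indices
    tsel <- tans[nn[inside], , drop = FALSE]
    if (any(owner[sel] > 0L)) overlap <- TRUE
    owner[sel] <- bi
    ad <- b$axial_diffusivity; rd <- b$radial_diffusivity
    idx6 <- function(k) cbind(sel, k)
    D[idx6(1L)] <- rd + (ad - rd) * tsel[, 1]^2
    D[idx6(2L)] <- rd + (ad - rd) * tsel[, 2]^2
    D[idx6(3L)] <- rd + (ad - rd) * tsel[, 3]^2
    D[idx6(4L)] <- (ad - rd) * tsel[, 1] * tsel[, 2]
    D[idx6(5L)] <- (ad - rd) * tsel[, 1] * tsel[, 3]
    D[idx6(6L)] <- (ad - rd) * tsel[, 2] * tsel[, 3]
  }
  if (overlap) warning("overlapping bundles: last writer wins")
  tensor_volume(D, vs)
}

# Resample a polyline at roughly `step` spacing; returns points and unit
# tangents (segment direction carried by both segment ends, averaged at
# interior knots through the dense resampling).
densify_polyline <- function(pts, step) {
  segs <- diff(pts)
  lens <- sqrt(rowSums(segs^2))
  out_p <- list(); out_t <- list()
  for (i in seq_len(nrow(segs))) {
    if (lens[i] < .Machine$double.eps) next
    k <- max(2L, ceiling(lens[i] / step) + 1L)
    tt <- seq(0, 1, length.out = k)
    if (i > 1L) tt <- tt[-1L]  # avoid duplicating knots
    p <- outer(rep(1, length(tt)), pts[i, ]) + outer(tt, segs[i, ])
    out_p[[i]] <- p
    out_t[[i]] <- matrix(segs[i, ] / lens[i], nrow(p), 3L, byrow = TRUE)
  }
  list(points = do.call(rbind, out_p), tangents = do.call(rbind, out_t))
}

# For each query row, index of the nearest reference row (Euclidean).
# Chunked to bound memory on large candidate sets.
nearest_point_index <- function(query, ref) {
  nq <- nrow(query)
  out <- integer(nq)
  ref2 <- rowSums(ref^2)
  chunk <- max(1L, floor(2e6 / nrow(ref)))
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    # squared distance = |q|^2 - 2 q.r + |r|^2; |q|^2 constant per row
    cross <- q %*% t(ref)
    d2 <- sweep(-2 * cross, 2, ref2, "+")
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}
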