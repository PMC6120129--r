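#' Tractography parameters
#'
#' Defaults follow a high-specificity deterministic tensor tracking setup for
#' intra-hemispheric rat connectome reconstruction: FA termination threshold
#' 0.15 (low enough to let tracts terminate inside cortical gray matter),
#' step size 0.13 mm, angular threshold 20 degrees, 25000 seeded streamlines,
#' and a 20 mm safety bound on streamline length.
#'
#' @param fa_threshold FA below which tracking terminates (0 < x < 1).
#' @param step_size step length in mm.
#' @param angle_threshold maximum turning angle between consecutive steps,
#'   degrees (0 < x < 90).
#' @param n_streamlines number of seed points.
#' @param max_length maximum streamline length in mm.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(fa_threshold = 0.15, step_size = 0.13,
                            angle_threshold = 20, n_streamlines = 25000L,
                            max_length = 20) {
  stopifnot(fa_threshold > 0, fa_threshold < 1, step_size > 0,
            angle_threshold > 0, angle_threshold < 90,
            n_streamlines >= 1, max_length > 0)
  structure(list(fa_threshold = fa_threshold, step_size = step_size,
                 angle_threshold = angle_threshold,
                 n_streamlines = as.integer(n_streamlines),
                 max_length = max_length),
            class = "tracking_params")
}

#' Draw seed points uniformly over a voxel mask
#'
#' Seeds are equally distributed over the mask: a voxel is drawn uniformly
#' among masked voxels, then a point uniformly within that voxel.
#'
#' @param mask 3D logical array.
#' @param n number of seeds.
#' @param voxel_size voxel edge lengths in mm.
#' @param seed integer seed.
#' @return numeric matrix (n x 3) of points in mm.
#' @export
generate_seeds <- function(mask, n, voxel_size, seed = 1L) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("seed mask is empty")
  vs <- expand_voxel_size(voxel_size)
  dims <- dim(mask)
  with_substream(seed, "seeds", {
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    vox <- cbind((pick - 1L) %% dims[1],
                 ((pick - 1L) %/% dims[1]) %% dims[2],
                 (pick - 1L) %/% (dims[1] * dims[2]))
    u <- matrix(stats::runif(3L * n), n, 3L)
    sweep(vox + u, 2, vs, "*")
  })
}

# voxel index (0-based triple) of a point; NA rows when outside the grid
point_to_voxel <- function(p, voxel_size, dims) {
  v <- floor(p / voxel_size)
  if (any(v < 0) || any(v >= dims)) return(NULL)
  as.integer(v)
}

#' Track one streamline from a seed point
#'
#' Deterministic principal-direction tracking with nearest-neighbor direction
#' lookup: from the seed the streamline propagates in both polarities of the
#' seed voxel's principal eigenvector, each step moving `step_size` mm along
#' the current voxel's principal direction, sign-aligned with the incoming
#' direction. Propagation stops on entering a voxel with FA below threshold
#' (that point is not kept), on a turning angle above threshold, on leaving
#' the grid, or on exceeding the length bound. The two half-tracks are joined
#' at the seed. A seed in a sub-threshold voxel yields an empty streamline.
#'
#' @param seed_point numeric length-3 position in mm.
#' @param principal_dirs 4D array `c(grid, 3)` of principal eigenvectors.
#' @param fa FA [scalar_volume].
#' @param params [tracking_params].
#' @return numeric matrix (k x 3) of ordered points (k = 0 if not started).
#' @export
track_streamline <- function(seed_point, principal_dirs, fa, params) {
  vs <- fa$voxel_size
  dims <- dim(fa$data)
  v0 <- point_to_voxel(seed_point, vs, dims)
  if (is.null(v0) || fa$data[v0[1] + 1L, v0[2] + 1L, v0[3] + 1L] <
      params$fa_threshold) {
    return(matrix(numeric(0), 0L, 3L))
  }
  dir0 <- principal_dirs[v0[1] + 1L, v0[2] + 1L, v0[3] + 1L, ]
  cos_thr <- cos(params$angle_threshold * pi / 180)
  max_steps <- floor(params$max_length / params$step_size)

  walk <- function(d_in) {
    pts <- vector("list", max_steps)
    p <- seed_point
    n_pts <- 0L
    repeat {
      v <- point_to_voxel(p, vs, dims)
      dirv <- principal_dirs[v[1] + 1L, v[2] + 1L, v[3] + 1L, ]
      if (sum(dirv * d_in) < 0) dirv <- -dirv
      if (n_pts > 0L && sum(dirv * d_in) < cos_thr) break  # sharp bend
      p_new <- p + params$step_size * dirv
      v_new <- point_to_voxel(p_new, vs, dims)
      if (is.null(v_new)) break                             # left the grid
      if (fa$data[v_new[1] + 1L, v_new[2] + 1L, v_new[3] + 1L] <
          params$fa_threshold) break                        # sub-threshold
      n_pts <- n_pts + 1L
      pts[[n_pts]] <- p_new
      if (n_pts >= max_steps) break                         # length bound
      p <- p_new
      d_in <- dirv
    }
    if (n_pts == 0L) matrix(numeric(0), 0L, 3L)
    else do.call(rbind, pts[seq_len(n_pts)])
  }

  fwd <- walk(dir0)
  bwd <- walk(-dir0)
  rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
        matrix(seed_point, 1L, 3L),
        fwd)
}

#' Run whole-mask deterministic tractography
#'
#' Seeds `params$n_streamlines` points in the mask, tracks one streamline per
#' seed, and retains those with at least two points.
#'
#' @param x a [tensor_volume], or a list with elements `dirs` (principal
#'   eigenvector array) and `fa` (FA [scalar_volume]) if the eigensystem is
#'   already available.
#' @param mask 3D logical seeding mask.
#' @param params [tracking_params].
#' @param seed integer seed for seed placement.
#' @return object of class `tractogram`: list of streamline point matrices,
#'   the parameters, seed, voxel size, attempt/retention counts and (initially
#'   NULL) per-streamline weights.
#' @export
run_tractography <- function(x, mask, params = tracking_params(), seed = 1L) {
  if (inherits(x, "tensor_volume")) {
    eig <- eigen_decompose(x)
    fa <- fa_map(eig)
    dims <- dim(fa$data)
    dirs <- array(eig$vectors[, , , , 1L], dim = c(dims, 3L))
  } else {
    dirs <- x$dirs
    fa <- x$fa
  }
  seeds <- generate_seeds(mask, params$n_streamlines, fa$voxel_size, seed)
  lines <- vector("list", nrow(seeds))
  keep <- logical(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    sl <- track_streamline(seeds[i, ], dirs, fa, params)
    if (nrow(sl) >= 2L) {
      attr(sl, "seed_index") <- i
      lines[[i]] <- sl
      keep[i] <- TRUE
    }
  }
  structure(list(streamlines = lines[keep], params = params, seed = seed,
                 voxel_size = fa$voxel_size,
                 n_attempted = nrow(seeds), n_retained = sum(keep),
                 weights = NULL),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram: %d/%d streamlines retained, step %.3g mm%s>\n",
              x$n_retained, x$n_attempted, x$params$step_size,
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' Global streamline-count normalization (density-filtering surrogate)
#'
#' Assigns every retained streamline the weight
#' `target_count / retained_count`, so the total streamline weight is the
#' same constant across subjects regardless of per-subject retention. This is
#' a deliberately simple surrogate for signal-informed tractogram filtering
#' (SIFT): it reproduces the property the downstream network analysis relies
#' on -- tract counts comparable across datasets -- without modeling the
#' diffusion signal fit.
#'
#' @param tractogram a [tractogram].
#' @param target_count the nominal streamline count (default: the seeding
#'   target in the tractogram's parameters).
#' @return the tractogram with per-streamline `weights` filled in.
#' @export
normalize_tract_weights <- function(tractogram,
                                    target_count =
                                      tractogram$params$n_streamlines) {
  if (tractogram$n_retained == 0L) {
    stop("cannot normalize an empty tractogram")
  }
  tractogram$weights <- rep(target_count / tractogram$n_retained,
                            tractogram$n_retained)
  tractogram
}

#' Weighted fiber density map
#'
#' Per voxel, the summed weight of streamlines visiting it (each streamline
#' counts once per voxel it touches). Unit weights are used when the
#' tractogram has not been normalized.
#'
#' @param tractogram a [tractogram].
#' @param grid_dim integer triple of voxel counts.
#' @param voxel_size voxel edge lengths in mm (default from tractogram).
#' @return a [scalar_volume] of kind "fiber_density".
#' @export
fiber_density_map <- function(tractogram, grid_dim,
                              voxel_size = tractogram$voxel_size) {
  vs <- expand_voxel_size(voxel_size)
  dens <- array(0, dim = grid_dim)
  w <- tractogram$weights
  if (is.null(w)) w <- rep(1, tractogram$n_retained)
  for (i in seq_along(tractogram$streamlines)) {
    sl <- tractogram$streamlines[[i]]
    vox <- floor(sweep(sl, 2, vs, "/"))
    vox <- unique(vox)
    inside <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
      vox[, 1] < grid_dim[1] & vox[, 2] < grid_dim[2] & vox[, 3] < grid_dim[3]
    vox <- vox[inside, , drop = FALSE]
    idx <- vox + 1L
    dens[idx] <- dens[idx] + w[i]
  }
  scalar_volume(dens, vs, kind = "fiber_density")
}
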