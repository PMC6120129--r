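#' Volume containers
#'
#' Lightweight S3 containers for the image-like objects the pipeline passes
#' around. All volumes carry an isotropic-or-not voxel size in mm. Spatial
#' convention throughout the package: continuous coordinates are in mm, voxel
#' indices are 0-based, and a point `p` belongs to voxel `floor(p / voxel_size)`
#' (half-open voxels). R array indexing adds 1.
#'
#' @name volumes
NULL

#' Construct a scalar volume (FA, RD, AD, density, ... maps)
#'
#' @param data 3D numeric array.
#' @param voxel_size voxel edge lengths in mm (scalar or length-3).
#' @param kind value-kind tag, e.g. "FA", "RD", "AD".
#' @return object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, voxel_size, kind = "scalar") {
  stopifnot(length(dim(data)) == 3L)
  structure(list(data = data, voxel_size = expand_voxel_size(voxel_size),
                 kind = kind),
            class = "scalar_volume")
}

#' Construct an atlas label volume
#'
#' @param labels 3D integer array; 0 = background, positive integers = regions.
#' @param voxel_size voxel edge lengths in mm.
#' @return object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, voxel_size) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("atlas labels must be >= 0")
  structure(list(labels = labels, voxel_size = expand_voxel_size(voxel_size)),
            class = "atlas_volume")
}

#' Construct a diffusion tensor volume
#'
#' Tensors are stored as their six unique elements in the order
#' (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), units mm^2/s.
#'
#' @param D 4D array, dims `c(nx, ny, nz, 6)`.
#' @param voxel_size voxel edge lengths in mm.
#' @param mask optional 3D logical array restricting valid voxels.
#' @return object of class `tensor_volume`.
#' @export
tensor_volume <- function(D, voxel_size, mask = NULL) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4] == 6L)
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(D)[1:3]))
  structure(list(D = D, voxel_size = expand_voxel_size(voxel_size),
                 mask = mask),
            class = "tensor_volume")
}

#' Construct a 4D diffusion-weighted volume
#'
#' @param data 4D numeric array, 4th dimension indexing acquisition volumes.
#' @param voxel_size voxel edge lengths in mm.
#' @return object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size) {
  stopifnot(length(dim(data)) == 4L)
  structure(list(data = data, voxel_size = expand_voxel_size(voxel_size)),
            class = "dwi_volume")
}

expand_voxel_size <- function(voxel_size) {
  stopifnot(is.numeric(voxel_size), all(voxel_size > 0))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L)
  as.numeric(voxel_size)
}

# 3x3 symmetric matrix from a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

mat_to_tensor6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume [%s] %s, voxel %s mm, range [%.4g, %.4g]>\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.atlas_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<atlas_volume %s, voxel %s mm, %d labels>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(labs > 0)))
  invisible(x)
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume %s, voxel %s mm>\n",
              paste(dim(x$D)[1:3], collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat(sprintf("<dwi_volume %s voxels x %d volumes, voxel %s mm>\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}
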