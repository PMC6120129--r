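#' Read and write volumes as NIfTI-1
#'
#' Scalar, atlas, tensor and DWI volumes round-trip through NIfTI-1 files
#' (via RNifti) with the voxel size honored in the header. Atlas volumes are
#' stored as integers and read back as integers.
#'
#' @param vol a [scalar_volume], [atlas_volume], [tensor_volume] or
#'   [dwi_volume].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns the path invisibly; `read_volume` returns a
#'   volume object of the requested kind.
#' @export
write_volume <- function(vol, path) {
  data <- switch(class(vol)[1],
                 scalar_volume = vol$data,
                 atlas_volume = vol$labels,
                 tensor_volume = vol$D,
                 dwi_volume = vol$data,
                 stop("unsupported volume class: ", class(vol)[1]))
  img <- RNifti::asNifti(
    data,
    reference = list(pixdim = c(-1, vol$voxel_size, rep(1, 4))),
    datatype = if (inherits(vol, "atlas_volume")) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param kind one of "scalar", "atlas", "tensor", "dwi" selecting the
#'   container for the read data.
#' @export
read_volume <- function(path, kind = c("scalar", "atlas", "tensor", "dwi")) {
  kind <- match.arg(kind)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf(
                    "cannot read NIfTI volume '%s': %s", path,
                    conditionMessage(e))))
  vs <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  switch(kind,
         scalar = scalar_volume(arr, vs),
         atlas = {
           if (max(abs(arr - round(arr))) > 0) {
             stop("atlas volume contains non-integer labels: ", path)
           }
           atlas_volume(array(as.integer(round(arr)), dim = dim(arr)), vs)
         },
         tensor = tensor_volume(arr, vs),
         dwi = dwi_volume(arr, vs))
}

#' Read and write connectivity matrices as labeled TSV
#'
#' Square matrices with a header row and a leading label column. On read the
#' matrix is validated (square, unique labels, symmetric within 1e-9) and
#' optionally reordered to a reference node order, so label order on disk does
#' not matter.
#'
#' @param net a [weighted_network] (or prevalence matrix of the same class).
#' @param path file path.
#' @return `write_matrix` returns the path invisibly; `read_matrix` a
#'   [weighted_network].
#' @export
write_matrix <- function(net, path) {
  df <- data.frame(node = rownames(net), unclass(net), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param node_order optional character vector; the matrix is reordered to
#'   this node order after reading.
#' @export
read_matrix <- function(path, node_order = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(M) != ncol(M)) stop("matrix in ", path, " is not square")
  if (anyDuplicated(labels)) stop("duplicate node labels in ", path)
  if (!identical(labels, colnames(M))) {
    stop("row and column labels disagree in ", path)
  }
  rownames(M) <- labels
  if (max(abs(M - t(M))) > 1e-9) stop("matrix in ", path, " is asymmetric")
  M <- (M + t(M)) / 2  # absorb sub-tolerance asymmetry from text round-trip
  if (!is.null(node_order)) {
    if (!setequal(node_order, labels)) {
      stop("node_order does not match the labels in ", path)
    }
    M <- M[node_order, node_order]
  }
  weighted_network(M)
}

#' Write a JSON run manifest
#'
#' Records the parameters, global seed and stage counts of a pipeline run so
#' every output is reproducible from the manifest alone.
#'
#' @param path output path.
#' @param seed global seed of the run.
#' @param params named list of parameters (coerced to JSON).
#' @param counts named list of stage counts (streamlines attempted/retained,
#'   excluded subjects, ...).
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, seed, params = list(), counts = list()) {
  jsonlite::write_json(
    list(package = "mstbackbone",
         version = as.character(utils::packageVersion("mstbackbone")),
         seed = seed, params = params, counts = counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
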