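#' The default 42-region unilateral atlas catalogue
#'
#' Returns the bundled region table: 42 named cortical and subcortical regions
#' of one rat hemisphere, 16 of them flagged as sensorimotor (primary and
#' secondary motor cortex, caudate putamen, thalamus, globus pallidus, ten
#' sub-regions of the primary somatosensory cortex, and the secondary
#' somatosensory cortex). This is a synthetic catalogue that mirrors the
#' naming and sensorimotor partition of standard rat brain atlas parcellations;
#' it is not a digitised atlas.
#'
#' @return a data.frame with columns `id` (integer, 1..42), `name` (character)
#'   and `sensorimotor` (logical; exactly 16 `TRUE`).
#' @export
region_table <- function() {
  path <- system.file("extdata", "region_table.tsv", package = "mstbackbone",
                      mustWork = TRUE)
  read_region_table(path)
}

#' Read or write a region table (TSV: id, name, sensorimotor)
#'
#' @param path file path.
#' @return `read_region_table` returns a validated data.frame.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "sensorimotor") %in% names(tab)))
  tab$id <- as.integer(tab$id)
  tab$sensorimotor <- as.logical(tab$sensorimotor)
  validate_region_table(tab)
  tab
}

#' @rdname read_region_table
#' @param regions a region table data.frame.
#' @export
write_region_table <- function(regions, path) {
  validate_region_table(regions)
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_region_table <- function(regions) {
  if (anyDuplicated(regions$id) || anyDuplicated(regions$name)) {
    stop("region ids and names must be unique")
  }
  if (!identical(sort(regions$id), seq_len(nrow(regions)))) {
    stop("region ids must be contiguous 1..N")
  }
  invisible(regions)
}

#' Deterministic spatial layout of regions on a block lattice
#'
#' Assigns each region a slot on the smallest 3D lattice covering the region
#' count (4 x 4 x 3 for 42 regions) and returns the slot coordinates, in
#' lattice units. The same layout drives both the atlas phantom's block
#' partition and the distance-dependent edge probabilities of the synthetic
#' network cohorts, so "nearby" regions in the phantom are also the ones most
#' likely to be connected.
#'
#' @param n_regions number of regions.
#' @return data.frame with columns `id`, `ix`, `iy`, `iz` (0-based lattice
#'   coordinates) plus the lattice dimensions as attribute `"lattice_dim"`.
#' @export
region_layout <- function(n_regions) {
  stopifnot(n_regions >= 1)
  lx <- max(1L, ceiling(n_regions^(1 / 3)))
  ly <- max(1L, ceiling(sqrt(n_regions / lx)))
  lz <- ceiling(n_regions / (lx * ly))
  slot <- seq_len(n_regions) - 1L
  out <- data.frame(
    id = seq_len(n_regions),
    ix = slot %% lx,
    iy = (slot %/% lx) %% ly,
    iz = slot %/% (lx * ly)
  )
  attr(out, "lattice_dim") <- c(lx, ly, lz)
  out
}

# Euclidean inter-region distance in lattice units, as a symmetric matrix.
region_block_distance <- function(n_regions) {
  lay <- region_layout(n_regions)
  as.matrix(stats::dist(lay[, c("ix", "iy", "iz")]))
}
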