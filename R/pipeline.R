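#' Run the full backbone analysis pipeline on synthetic data
#'
#' End-to-end driver covering every stage on a synthetic study: (1) phantom
#' generation -- atlas labels, a bundle tensor field and forward-simulated
#' DWI for one exemplar subject; (2) tensor fitting with FA/RD/AD maps and a
#' tissue summary; (3) deterministic tractography and tract-count
#' normalization; (4) network construction from streamline endpoints, plus a
#' cohort of synthetic networks; (5) MST backbone extraction with nodal and
#' network metrics and group MST prevalence; (6) regression of backbone
#' metrics against deficit scores and lesion volumes, and nodal metric
#' rankings. Tables and a JSON run manifest are written under `out_dir`;
#' every output is a pure function of the seed.
#'
#' @param seed global integer seed.
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param spec a [cohort_spec]; its seed is re-derived from `seed`.
#' @param grid_shape phantom grid (voxels).
#' @param n_streamlines seeding target for the exemplar tractography.
#' @param noise_sd DWI noise level in units of s0.
#' @return (invisibly) a list with the per-stage results.
#' @export
run_pipeline <- function(seed = 1L, out_dir = NULL,
                         spec = cohort_spec(seed = derive_seed(seed, "cohort")),
                         grid_shape = c(30L, 30L, 24L),
                         n_streamlines = 2000L,
                         noise_sd = 0.005) {
  regions <- region_table()

  # 1 --- phantom subject
  atlas <- make_atlas_phantom(grid_shape, 0.2, regions,
                              seed = derive_seed(seed, "atlas"))
  bundles <- default_phantom_bundles(atlas)
  tensors <- make_bundle_tensor_field(atlas, bundles)
  scheme <- default_gradient_scheme()
  dwi <- simulate_dwi(tensors, scheme, s0 = 1, noise_sd = noise_sd,
                      seed = derive_seed(seed, "dwi"))

  # 2 --- tensor fit and anatomical characteristics
  fitted <- fit_tensor(dwi, scheme)
  eig <- eigen_decompose(fitted)
  fa <- fa_map(eig); rd <- rd_map(eig); ad <- ad_map(eig)
  hemi <- atlas$labels > 0L
  wm <- white_matter_mask(fa, 0.2, hemi)
  tissue <- tissue_summary(fa, rd, ad, wm, hemi)

  # 3 --- tractography
  dims <- dim(fa$data)
  dirs <- array(eig$vectors[, , , , 1L], dim = c(dims, 3L))
  params <- tracking_params(n_streamlines = n_streamlines)
  tg <- run_tractography(list(dirs = dirs, fa = fa), hemi, params,
                         seed = derive_seed(seed, "tractography"))
  tg <- normalize_tract_weights(tg)

  # 4 --- networks
  exemplar_net <- build_network(tg, atlas, regions)
  cohort <- make_network_cohort(spec, regions)

  # 5 --- backbones
  metrics <- backbone_metric_table(cohort, regions)
  nets_by_group <- split(lapply(cohort, `[[`, "network"),
                         vapply(cohort, `[[`, character(1), "group"))
  mst_prev <- lapply(nets_by_group, group_mst_prevalence)
  net_prev <- lapply(nets_by_group, group_prevalence)

  # 6 --- behavior and associations
  records <- make_deficit_scores(cohort, spec, regions)
  screen <- metric_outcome_screen(metrics, records)
  ranking <- rank_nodal_metric(metrics$nodal, "strength")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tissue, file.path(out_dir, "tissue_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix(exemplar_net, file.path(out_dir, "exemplar_network.tsv"))
    for (g in names(mst_prev)) {
      write_matrix(mst_prev[[g]],
                   file.path(out_dir, sprintf("mst_prevalence_%s.tsv", g)))
      write_matrix(net_prev[[g]],
                   file.path(out_dir, sprintf("network_prevalence_%s.tsv", g)))
    }
    utils::write.table(metrics$network,
                       file.path(out_dir, "backbone_network_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(metrics$nodal,
                       file.path(out_dir, "backbone_nodal_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(records, file.path(out_dir, "subject_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(screen, file.path(out_dir, "metric_outcome_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ranking, file.path(out_dir, "strength_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(
      file.path(out_dir, "manifest.json"), seed,
      params = list(grid_shape = grid_shape,
                    voxel_size = 0.2,
                    n_streamlines = n_streamlines,
                    noise_sd = noise_sd,
                    tracking = unclass(params),
                    cohort = unclass(spec)),
      counts = list(streamlines_attempted = tg$n_attempted,
                    streamlines_retained = tg$n_retained,
                    tensor_voxels_excluded = attr(fitted, "n_excluded"),
                    subjects_excluded = length(attr(metrics, "excluded"))))
  }

  invisible(list(atlas = atlas, tensors = tensors, dwi = dwi,
                 fitted = fitted, fa = fa, tissue = tissue,
                 tractogram = tg, exemplar_network = exemplar_net,
                 cohort = cohort, metrics = metrics,
                 mst_prevalence = mst_prev, network_prevalence = net_prev,
                 records = records, screen = screen, ranking = ranking))
}

#' Default bundles for the phantom subject
#'
#' Three straight tubes connecting centroids of region pairs of the atlas
#' phantom (motor-to-somatosensory and subcortical pairs), with fixed
#' post-mortem-like diffusivities.
#'
#' @param atlas an [atlas_volume] from [make_atlas_phantom()].
#' @param pairs list of region-id pairs to connect.
#' @return list of [bundle_spec]s.
#' @export
default_phantom_bundles <- function(atlas,
                                    pairs = list(c(1L, 6L), c(3L, 4L),
                                                 c(8L, 14L))) {
  cents <- atlas_region_centroids(atlas)
  lapply(pairs, function(pr) {
    bundle_spec(pr[1], pr[2],
                rbind(cents[pr[1], ], cents[pr[2], ]),
                radius = 0.35)
  })
}

#' Region centroids of an atlas volume, in mm
#'
#' @param atlas an [atlas_volume].
#' @return matrix (n_regions x 3) of label centroids in mm.
#' @export
atlas_region_centroids <- function(atlas) {
  labs <- sort(setdiff(unique(as.vector(atlas$labels)), 0L))
  dims <- dim(atlas$labels)
  idx <- which(atlas$labels > 0L)
  lab <- atlas$labels[idx]
  vox <- cbind((idx - 1L) %% dims[1],
               ((idx - 1L) %/% dims[1]) %% dims[2],
               (idx - 1L) %/% (dims[1] * dims[2]))
  cents <- matrix(NA_real_, max(labs), 3L)
  for (l in labs) {
    cents[l, ] <- (colMeans(vox[lab == l, , drop = FALSE]) + 0.5) *
      atlas$voxel_size
  }
  cents
}
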