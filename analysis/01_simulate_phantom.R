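#!/usr/bin/env Rscript
# Stage 1: build the synthetic study subject. A 42-region atlas phantom is
# parcellated on a block lattice, three fiber bundles connect region pairs
# (motor-somatosensory, striato-thalamic, and the S1 upper lip - jaw pair),
# and diffusion-weighted volumes are forward-simulated at b = 2871.50 s/mm^2
# over 2 x 60 directions + 4 b0 volumes.

suppressPackageStartupMessages(library(mstbackbone))
source("analysis/00_config.R")

regions <- region_table()
atlas <- make_atlas_phantom(GRID, VOXEL, regions,
                            seed = derive_seed(SEED, "atlas"))
bundles <- default_phantom_bundles(atlas)
tensors <- make_bundle_tensor_field(atlas, bundles)
scheme <- default_gradient_scheme()
dwi <- simulate_dwi(tensors, scheme, s0 = 1, noise_sd = DWI_NOISE_SD,
                    seed = derive_seed(SEED, "dwi"))

write_volume(atlas, file.path(PHANTOM_DIR, "atlas.nii.gz"))
write_volume(tensors, file.path(PHANTOM_DIR, "tensors_true.nii.gz"))
write_volume(dwi, file.path(PHANTOM_DIR, "dwi.nii.gz"))
utils::write.table(
  data.frame(b = scheme$bvals, gx = scheme$bvecs[, 1],
             gy = scheme$bvecs[, 2], gz = scheme$bvecs[, 3]),
  file.path(PHANTOM_DIR, "gradients.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
write_manifest(file.path(RESULTS_DIR, "01_simulate_manifest.json"), SEED,
               params = list(grid = GRID, voxel_mm = VOXEL,
                             b_value = 2871.50, n_directions = 120,
                             n_b0 = 4, noise_sd = DWI_NOISE_SD,
                             n_bundles = length(bundles)),
               counts = list(n_regions = nrow(regions),
                             n_volumes = length(scheme$bvals)))

cat(sprintf("Phantom: %s grid, %d regions, %d bundles, %d DWI volumes.\n",
            paste(GRID, collapse = "x"), nrow(regions), length(bundles),
            length(scheme$bvals)))
cat(sprintf("Anisotropic voxels (tube tensors): %d of %d.\n",
            sum(tensors$D[, , , 4] != 0 | tensors$D[, , , 1] !=
                  tensors$D[, , , 2]), prod(GRID)))
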