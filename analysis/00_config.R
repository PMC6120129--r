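# Shared configuration for the analysis scripts. Everything downstream is a
# pure function of this seed.
SEED <- 42L
GRID <- c(30L, 30L, 24L)      # phantom grid, 0.2 mm isotropic voxels
VOXEL <- 0.2                  # mm
N_STREAMLINES <- 2000L        # seeding target for the exemplar subject
DWI_NOISE_SD <- 0.005         # additive noise, units of s0

PHANTOM_DIR <- "scratch/phantom"   # large image intermediates (regenerated)
RESULTS_DIR <- "results"           # tables and manifests (text)

dir.create(PHANTOM_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
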