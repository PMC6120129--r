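#!/usr/bin/env Rscript
# Stage 4: weighted structural networks. The exemplar subject's network is
# built from streamline endpoints against the atlas labels; the cohort
# (10 control vs 8 stroke, the stroke group with the S1 upper lip - jaw edge
# doubled) comes from the synthetic network generator. Group prevalence
# matrices summarize connection consistency after binarization.

suppressPackageStartupMessages(library(mstbackbone))
source("analysis/00_config.R")

regions <- region_table()
atlas <- read_volume(file.path(PHANTOM_DIR, "atlas.nii.gz"), "atlas")
tg <- readRDS(file.path(PHANTOM_DIR, "tractogram.rds"))

exemplar <- build_network(tg, atlas, regions)
write_matrix(exemplar, file.path(RESULTS_DIR, "exemplar_network.tsv"))

spec <- cohort_spec(seed = derive_seed(SEED, "cohort"))
cohort <- make_network_cohort(spec, regions)
nets <- lapply(cohort, `[[`, "network")
groups <- vapply(cohort, `[[`, character(1), "group")
for (g in unique(groups)) {
  prev <- group_prevalence(nets[groups == g])
  write_matrix(prev, file.path(RESULTS_DIR,
                               sprintf("network_prevalence_%s.tsv", g)))
  write_matrix(extract_subnetwork(prev, regions),
               file.path(RESULTS_DIR,
                         sprintf("sensorimotor_prevalence_%s.tsv", g)))
}

dens <- vapply(nets, network_density, numeric(1))
cmp <- group_compare(dens[groups == "control"], dens[groups == "stroke"])
cat(sprintf("Exemplar network: %d nodes, density %.3f, total weight %.0f.\n",
            nrow(exemplar), network_density(exemplar),
            sum(exemplar) / 2))
cat(sprintf("Cohort density: control %.3f +/- %.3f, stroke %.3f +/- %.3f (Welch t = %.2f, p = %.2f).\n",
            mean(dens[groups == "control"]), sd(dens[groups == "control"]),
            mean(dens[groups == "stroke"]), sd(dens[groups == "stroke"]),
            cmp$t, cmp$p))
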