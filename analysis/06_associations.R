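#!/usr/bin/env Rscript
# Stage 6: brain-behavior associations. Deficit scores (0-20) are generated
# from the planted link to sensorimotor backbone eccentricity; every backbone
# metric is regressed (univariable OLS) against deficit score and lesion
# volume over the 8 stroke subjects, for the total network and the
# sensorimotor sub-network.

suppressPackageStartupMessages(library(mstbackbone))
source("analysis/00_config.R")

regions <- region_table()
spec <- cohort_spec(seed = derive_seed(SEED, "cohort"))
cohort <- make_network_cohort(spec, regions)
metrics <- backbone_metric_table(cohort, regions)
records <- make_deficit_scores(cohort, spec, regions)

utils::write.table(records, file.path(RESULTS_DIR, "subject_records.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
screen <- metric_outcome_screen(metrics, records)
utils::write.table(screen,
                   file.path(RESULTS_DIR, "metric_outcome_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

st <- records[records$group == "stroke", ]
cat(sprintf("Stroke group: deficit score %.1f +/- %.1f points, lesion volume %.0f +/- %.0f mm^3.\n",
            mean(st$deficit_score), sd(st$deficit_score),
            mean(st$lesion_volume), sd(st$lesion_volume)))
hit <- screen[screen$metric == "mean_eccentricity" &
                screen$scope == "sensorimotor" &
                screen$outcome == "deficit_score", ]
cat(sprintf("Planted link (sensorimotor mean eccentricity vs deficit): slope %.2f, R^2 %.2f, p %.4f.\n",
            hit$slope, hit$r_squared, hit$p))
sig <- screen[screen$p < 0.05 & screen$outcome == "deficit_score", ]
cat(sprintf("%d of %d deficit-score regressions significant at p < 0.05.\n",
            nrow(sig), sum(screen$outcome == "deficit_score")))
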