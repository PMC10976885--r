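#!/usr/bin/env Rscript
# Stage 2 — preprocessing.
#
# Applies the exclusion cascade (participants without chemical measurements,
# then those missing >= 50% of dietary items), imputes below-LOD
# concentrations from per-compound truncated Gaussians fitted by censored
# MLE, completes remaining technical missingness by iterative conditional
# imputation, log10-transforms the exposures, and summarizes diet by PCA
# (components covering > 95% of variance). Writes the analysis matrix
# consumed by all later stages.

library(mtess)

seed <- 2026
raw <- read_cohort("results/cohort/cohort.csv", "results/cohort/lod.csv")

fl <- filter_cohort(raw)
print(fl$log)
cohort <- fl$cohort
jsonlite::write_json(
  list(initial = attr(fl$log, "initial"), rules = fl$log$rule,
       excluded = fl$log$excluded, retained = attr(fl$log, "retained")),
  "results/exclusion_log.json", auto_unbox = TRUE)

expo <- cohort$columns$exposures
emat <- as.matrix(cohort$data[, expo])
emat <- impute_below_lod(emat, cohort$lod, cohort$below_lod, seed = seed)
cohort$data[, expo] <- emat
cohort$data <- cbind(cohort$data["id"],
                     impute_missing(cohort$data[, -1], seed = seed))
lx <- log10_exposures(as.matrix(cohort$data[, expo]))

dp <- diet_pca(cohort$data[, cohort$columns$diet])
message("Diet PCA: ", dp$n_retained, " components cover ",
        round(100 * cumsum(dp$variance_fraction)[dp$n_retained], 1),
        "% of the variance of the five intake variables.")

s <- summarize_cohort(cohort)
write.table(s$numeric, "results/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(s$detection, "results/detection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

amat <- data.frame(cohort$data[, c("id", cohort$columns$covariates,
                                   cohort$columns$diet,
                                   cohort$columns$traits)],
                   dp$scores, lx, check.names = FALSE)
write.csv(amat, "results/analysis_matrix.csv", row.names = FALSE)
message("Wrote results/analysis_matrix.csv (",
        nrow(amat), " x ", ncol(amat), ").")
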