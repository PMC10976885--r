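#!/usr/bin/env Rscript
# Stage 5 — univariate baseline and attenuation ladder.
#
# (i) The 33 x 9 univariate scan: each trait regressed on each log10
# exposure with the full covariate block, Bonferroni-flagged at 0.05/33 per
# trait. (ii) MPPI attenuation: the multitrait BVS rerun under sequentially
# richer adjustment sets (none; age + gender; + education + smoking; + diet
# PCs) to show how confounder adjustment attenuates per-feature inclusion
# probabilities.

library(mtess)

seed <- 2026
amat <- read.csv("results/analysis_matrix.csv", check.names = FALSE)
selected <- readLines("results/selected_traits.txt")
expo_cols <- default_compound_panel()$compound
trait_cols <- colnames(default_trait_corr())
pc_cols <- grep("^PC[0-9]+$", colnames(amat), value = TRUE)

covdf <- amat[, c("age", "gender", "education", "smoking")]
for (cn in c("gender", "education", "smoking"))
  covdf[[cn]] <- factor(covdf[[cn]])

X <- as.matrix(amat[, expo_cols])
traits_all <- as.matrix(amat[, trait_cols])

sc <- univariate_scan(traits_all, X,
                      cbind(covdf, amat[, pc_cols, drop = FALSE]))
write.table(sc, "results/scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- sc[sc$significant, c("trait", "exposure", "estimate", "p_value")]
message("Univariate scan: ", nrow(sc), " models, ", nrow(sig),
        " Bonferroni-significant pairs.")
if (nrow(sig) > 0) {
  message("Significant pairs per trait (correlated exposures smear the ",
          "marginal signal that the joint BVS model disentangles):")
  print(table(factor(sig$trait, levels = unique(sc$trait))))
}

Y <- as.matrix(amat[, selected])
prior <- size_prior(5, 4, 7, ncol(X))
cfg <- sampler_config(n_sweeps = 30000, burn_in = 10000, n_chains = 3,
                      seed = seed)
ladders <- list(
  unadjusted = NULL,
  age_sex = stats::model.matrix(~ age + gender, covdf),
  edu_smoking = stats::model.matrix(~ age + gender + education + smoking,
                                    covdf),
  diet = cbind(stats::model.matrix(~., covdf), as.matrix(amat[, pc_cols])))

runs <- lapply(ladders, function(Cl) {
  rz <- residualize(Y, X, Cl)
  compute_mppi(run_guess(rz$Y, rz$X, prior, cfg,
                         nu = nrow(Y) - rz$df_adjust))
})
att <- mppi_attenuation(runs)
write.table(att, "results/attenuation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

wide <- do.call(cbind, runs)
drift <- wide[, "unadjusted"] - wide[, "diet"]
message("Largest MPPI attenuation from no adjustment to the full model: ",
        names(which.max(drift)), " (", round(max(drift), 3), ")")
message("Wrote results/scan.tsv and results/attenuation.tsv.")
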