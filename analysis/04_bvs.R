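#!/usr/bin/env Rscript
# Stage 4 — Bayesian variable selection.
#
# Runs the evolutionary-stochastic-search sampler (30,000 sweeps, 10,000
# burn-in, three tempered chains) on the residualized data: the selected
# central traits jointly as a multivariate outcome, and each of them
# separately. Adjustment covariates are age, gender, education, smoking and
# the retained diet PCA scores, removed by residualization. Posthoc: model
# posterior probabilities, marginal posterior probabilities of inclusion,
# the permutation-based empirical-FDR MPPI threshold (20 permutations),
# Bayes factors and their ratio to the threshold feature, and the
# effect-size posterior of the top best model visited.

library(mtess)

seed <- 2026
amat <- read.csv("results/analysis_matrix.csv", check.names = FALSE)
selected <- readLines("results/selected_traits.txt")
expo_cols <- default_compound_panel()$compound
pc_cols <- grep("^PC[0-9]+$", colnames(amat), value = TRUE)

covdf <- amat[, c("age", "gender", "education", "smoking")]
covdf$gender <- factor(covdf$gender)
covdf$education <- factor(covdf$education)
covdf$smoking <- factor(covdf$smoking)
C <- cbind(stats::model.matrix(~., covdf),
           as.matrix(amat[, pc_cols]))

Y <- as.matrix(amat[, selected])
X <- as.matrix(amat[, expo_cols])
rz <- residualize(Y, X, C)
n <- nrow(Y)
nu <- n - rz$df_adjust
p <- ncol(X)
prior <- size_prior(5, 4, 7, p)
print(prior)
cfg <- sampler_config(n_sweeps = 30000, burn_in = 10000, n_chains = 3,
                      seed = seed)

message("Multitrait GUESS on ", paste(selected, collapse = "+"),
        " (", n, " x ", p, ") ...")
fit <- run_guess(rz$Y, rz$X, prior, cfg, nu = nu)
print(fit)
write.table(fit$trace, "results/trace_multitrait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mpp <- compute_mpp(fit)
mppi <- compute_mppi(fit)
message("Top model: {", mpp$model[1], "} with MPP ", round(mpp$mpp[1], 3))
write.table(head(mpp, 50), "results/top_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

perm <- permutation_mppi(rz$Y, rz$X, prior, cfg, n_perm = 20,
                         seed = seed + 1, nu = nu)
fdr <- empirical_fdr_threshold(mppi, perm, level = 0.05)
print(fdr)
rt <- rbf_table(mppi, fdr, pi0 = 5 / p, eps = 1 / fit$n_kept)
write.table(rt, "results/rbf.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Informative features (RBF >= 1): ",
        paste(rt$feature[rt$rbf >= 1], collapse = ", "))

top_gamma <- match(strsplit(mpp$model[1], ",")[[1]], colnames(X))
if (length(top_gamma) > 0 && !anyNA(top_gamma)) {
  ep <- effect_posterior(rz$Y, rz$X, top_gamma, n_rounds = 500,
                         nu = nu, seed = seed)
  write.table(ep$summary, "results/effects.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  called <- ep$summary[ep$summary$sign != "none", ]
  message("Sign-called coefficients (25th-75th percentile excludes 0): ",
          nrow(called), " of ", nrow(ep$summary))
}

# single-trait runs for the per-outcome comparison
single <- lapply(setNames(selected, selected), function(tr) {
  f <- run_guess(rz$Y[, tr, drop = FALSE], rz$X, prior, cfg, nu = nu)
  compute_mppi(f)
})
st <- data.frame(feature = colnames(X),
                 do.call(cbind, single), check.names = FALSE)
write.table(st, "results/mppi_single_trait.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(feature = names(mppi), mppi = unname(mppi)),
            "results/mppi.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("Wrote results/mppi.tsv, rbf.tsv, top_models.tsv, effects.tsv.")
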