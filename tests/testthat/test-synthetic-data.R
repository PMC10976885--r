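test_that("exposure generation respects the configured detection fraction", {
  sp <- exposure_spec(n_compounds = 1, family_labels = "oc",
                      compound_names = "hcb", detection_target = 0.10,
                      missing_rate = 0)
  e <- generate_exposures(sp, 1e5, seed = 5)
  expect_equal(mean(!e$below_lod), 0.10, tolerance = 0.005 / 0.10)
  expect_true(all(e$concentration > 0))
  # censoring honesty within 3 binomial sd at moderate n
  sp2 <- exposure_spec(n_compounds = 3, family_labels = rep("a", 3),
                       detection_target = c(0.3, 0.7, 0.95),
                       missing_rate = 0)
  n <- 5000
  e2 <- generate_exposures(sp2, n, seed = 6)
  for (j in 1:3) {
    d <- sp2$detection_target[j]
    expect_lt(abs(mean(e2$below_lod[, j]) - (1 - d)),
              3 * sqrt(d * (1 - d) / n))
  }
})

test_that("a zero-variance compound is degenerate and uncensored", {
  sp <- exposure_spec(n_compounds = 2, family_labels = c("a", "a"),
                      log10_mean = c(1, 0), log10_sd = c(0, 0.5),
                      detection_target = c(1, 0.7), missing_rate = 0)
  e <- generate_exposures(sp, 100, seed = 1)
  expect_true(all(e$concentration[, 1] == 10))
  expect_true(all(!e$below_lod[, 1]))
})

test_that("the family copula reproduces the configured latent correlation", {
  sp <- exposure_spec(n_compounds = 2, family_labels = c("a", "a"),
                      latent_corr_within = 0.5, missing_rate = 0)
  e <- generate_exposures(sp, 1e4, seed = 6)
  expect_equal(cor(log10(e$concentration))[1, 2], 0.5, tolerance = 0.03 / 0.5)
  expect_equal(cor(e$concentration, method = "spearman")[1, 2], 0.5,
               tolerance = 0.06)
})

test_that("exposure specs reject invalid configurations", {
  expect_error(exposure_spec(detection_target = 0.05), "0.10")
  expect_error(exposure_spec(missing_rate = 0.6), "missing_rate")
  expect_error(exposure_spec(latent_corr_within = 1.0), "latent")
})

test_that("identical seeds give bitwise-identical cohorts", {
  a <- generate_cohort(n = 40, seed = 9)
  b <- generate_cohort(n = 40, seed = 9)
  expect_identical(a, b)
  c <- generate_cohort(n = 40, seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("covariate marginals match their configured targets", {
  cv <- generate_covariates(1e5, seed = 7)
  expect_equal(mean(cv$covariates$age), 44.8, tolerance = 0.2 / 44.8)
  expect_equal(mean(cv$covariates$gender == "female"), 0.690,
               tolerance = 0.005 / 0.690)
  expect_equal(cor(cv$diet$energy, cv$diet$fats), 0.88,
               tolerance = 0.02 / 0.88)
  expect_true(all(as.matrix(cv$diet) > 0))
})

test_that("empty covariate tables keep the full column schema", {
  cv <- generate_covariates(0, seed = 1)
  expect_equal(nrow(cv$covariates), 0)
  expect_named(cv$covariates, c("age", "gender", "education", "smoking"))
  expect_named(cv$diet,
               c("energy", "proteins", "fats", "carbohydrates", "fibres"))
})

test_that("invalid category frequencies are rejected", {
  expect_error(generate_covariates(10, education_probs = c(a = 0.5, b = 0.4)),
               "sum to 1")
})

test_that("trait residual correlations are realized empirically", {
  lx <- matrix(rnorm(1e4 * 2), 1e4, 2)
  colnames(lx) <- c("c1", "c2")
  tr <- generate_traits(lx, NULL, trait_spec(), seed = 8)
  expect_equal(cor(tr$traits[, "BMI"], tr$traits[, "WC"]), 0.89,
               tolerance = 0.02 / 0.89)
  # identity residuals, no effects: trait means near zero
  ts <- trait_spec(paste0("t", 1:3), diag(3))
  tr2 <- generate_traits(lx, NULL, ts, seed = 9)
  expect_true(all(abs(colMeans(tr2$traits)) < 3 / sqrt(1e4)))
})

test_that("the noiseless limit reproduces the linear predictor exactly", {
  set.seed(3)
  lx <- matrix(rnorm(200), 100, 2)
  colnames(lx) <- c("c1", "c2")
  eff <- data.frame(compound = "c1", trait = "t1", beta = 1)
  ts <- trait_spec(c("t1", "t2"), diag(2), true_effects = eff)
  tr <- generate_traits(lx, NULL, ts, seed = 4, residual_scale = 0)
  fit <- lm(tr$traits[, "t1"] ~ scale(lx[, "c1"]))
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1,
               tolerance = 1e-10)
  expect_equal(unname(tr$truth$gamma_true), c(1, 0))
})

test_that("trait generation validates its inputs", {
  lx <- matrix(rnorm(20), 10, 2)
  colnames(lx) <- c("c1", "c2")
  cv <- generate_covariates(5, seed = 1)$covariates
  expect_error(generate_traits(lx, cv, trait_spec(), seed = 1),
               "row counts")
  eff <- data.frame(compound = "nope", trait = "BMI", beta = 1)
  expect_error(generate_traits(lx, NULL, trait_spec(true_effects = eff)),
               "unknown compounds")
  bad <- default_trait_corr()
  bad[1, 2] <- bad[2, 1] <- 0.999  # breaks positive definiteness
  bad2 <- bad; bad2[1, 1] <- 2
  expect_error(trait_spec(residual_corr = bad2), "unit diagonal")
})

test_that("cohort round-trips through CSV with censoring flags intact", {
  co <- generate_cohort(n = 30, seed = 12, exposure_spec = exposure_spec(
    n_compounds = 4, family_labels = rep("a", 4), detection_target = 0.6,
    missing_rate = 0.05))
  dir <- tempfile()
  write_cohort(co, dir)
  rc <- read_cohort(file.path(dir, "cohort.csv"), file.path(dir, "lod.csv"))
  expect_equal(unname(rc$lod), unname(co$lod), tolerance = 1e-6)
  expect_equal(unname(rc$below_lod), unname(co$below_lod))
  j <- co$columns$exposures[1]
  obs <- !co$below_lod[, j] & !co$missing[, j]
  expect_equal(rc$data[obs, j], co$data[obs, j], tolerance = 1e-6)
})

test_that("planted-graph Gaussian panels have the declared adjacency", {
  g <- default_trait_graph()
  sim <- generate_graph_gaussian(colnames(default_trait_corr()), g,
                                 n = 100, seed = 2)
  expect_true(isSymmetric(sim$adjacency))
  expect_equal(sum(sim$adjacency) / 2, nrow(g))
  ev <- eigen(sim$sigma, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  # six central traits have degree >= 2 by construction
  deg <- rowSums(sim$adjacency)
  expect_true(all(deg[c("BMI", "WC", "TG", "HDLC", "SBP", "DBP")] >= 2))
})
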