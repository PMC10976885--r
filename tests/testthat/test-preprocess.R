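make_toy_raw <- function() {
  # 10 participants: 3 lack the whole exposure panel, 1 further row misses
  # 3 of 5 diet items
  d <- data.frame(id = paste0("P", 1:10),
                  age = rnorm(10, 45, 10),
                  energy = runif(10, 1500, 2500),
                  proteins = runif(10, 60, 120),
                  fats = runif(10, 60, 130),
                  carbohydrates = runif(10, 150, 300),
                  fibres = runif(10, 10, 35),
                  e1 = runif(10, 1, 5), e2 = runif(10, 1, 5))
  d[1:3, c("e1", "e2")] <- NA
  d[4, c("energy", "proteins", "fats")] <- NA
  below <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("e1", "e2")))
  miss <- is.na(as.matrix(d[, c("e1", "e2")]))
  structure(list(data = d, below_lod = below, missing = miss,
                 lod = c(e1 = 0.1, e2 = 0.1),
                 columns = list(exposures = c("e1", "e2"),
                                diet = c("energy", "proteins", "fats",
                                         "carbohydrates", "fibres"),
                                traits = character(0),
                                covariates = "age")),
            class = "raw_cohort")
}

test_that("exclusion rules are applied in order with a conserved log", {
  raw <- make_toy_raw()
  fl <- filter_cohort(raw)
  expect_equal(fl$log$excluded, c(3, 1))
  expect_equal(attr(fl$log, "retained"), 6)
  expect_equal(attr(fl$log, "initial"),
               attr(fl$log, "retained") + sum(fl$log$excluded))
  expect_equal(nrow(fl$cohort$data), 6)
  # no rule matches -> all retained with zero counts
  raw2 <- make_toy_raw()
  raw2$data[1:3, "e1"] <- 1
  raw2$missing[1:3, "e1"] <- FALSE
  raw2$data[4, c("energy", "proteins", "fats")] <- 1000
  fl2 <- filter_cohort(raw2)
  expect_equal(fl2$log$excluded, c(0, 0))
  expect_equal(attr(fl2$log, "retained"), 10)
  expect_error(filter_cohort(raw, rules = "nonsense"), "unknown exclusion")
})

test_that("a cohort with the standard exclusion counts filters to 941", {
  co <- generate_cohort(n = 941, n_missing_chem = 439, n_missing_diet = 48,
                        seed = 4,
                        exposure_spec = exposure_spec(
                          n_compounds = 6, family_labels = rep("a", 6)))
  expect_equal(nrow(co$data), 1428)
  fl <- filter_cohort(co)
  expect_equal(fl$log$excluded, c(439, 48))
  expect_equal(attr(fl$log, "retained"), 941)
})

test_that("below-LOD imputation stays inside (0, LOD) and preserves observed", {
  set.seed(9)
  n <- 1e4
  x <- 10^rnorm(n, 0.5, 0.6)
  lod <- unname(quantile(x, 0.3))
  below <- matrix(x < lod)
  xm <- matrix(x)
  imp <- impute_below_lod(xm, lod, below, seed = 10)
  expect_true(all(imp[below] > 0 & imp[below] < lod))
  expect_identical(imp[!below], xm[!below])
  # post-imputation mean of the full column within 2% of the true mean
  expect_equal(mean(imp), mean(x), tolerance = 0.02)
  # seeded determinism
  imp2 <- impute_below_lod(xm, lod, below, seed = 10)
  expect_identical(imp, imp2)
})

test_that("the fixed fallback concentrates draws around LOD/2", {
  xm <- matrix(c(NA, NA, NA, 4, 5), ncol = 1)
  below <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE), ncol = 1)
  expect_warning(imp <- impute_below_lod(xm, lod = 2, below, seed = 2),
                 "falling back")
  expect_true(all(imp[1:3] > 0 & imp[1:3] < 2))
  imp3 <- impute_below_lod(xm, lod = 2, below, seed = 3, method = "fixed")
  draws <- replicate(50, mean(
    impute_below_lod(matrix(c(rep(NA, 20), 4), ncol = 1), 2,
                     matrix(c(rep(TRUE, 20), FALSE), ncol = 1),
                     seed = sample.int(1e6, 1), method = "fixed")[1:20]))
  expect_equal(mean(draws), 1, tolerance = 0.05)
})

test_that("iterative imputation is exact for linearly dependent columns", {
  tab <- data.frame(A = runif(50, 1, 5))
  tab$B <- 2 * tab$A
  tab$B[17] <- NA
  out <- impute_missing(tab)
  expect_equal(out$B[17], 2 * tab$A[17], tolerance = 0.01)
  # observed entries never altered; complete tables returned unchanged
  expect_identical(out$A, tab$A)
  full <- data.frame(x = 1:5, y = 6:10)
  expect_identical(impute_missing(full)[, c("x", "y")], full)
  expect_error(impute_missing(data.frame(x = 1:3, y = NA_real_)),
               "entirely missing")
})

test_that("imputation beats the marginal-mean baseline under MCAR", {
  set.seed(11)
  n <- 400
  Z <- mtess:::rmvnorm_chol(n, diag(4) * 0.3 + 0.7)
  colnames(Z) <- paste0("v", 1:4)
  tab <- as.data.frame(Z)
  miss <- matrix(runif(n * 4) < 0.1, n, 4)
  tab_m <- tab
  tab_m[miss] <- NA
  out <- impute_missing(tab_m, seed = 2)
  rmse <- sqrt(mean((as.matrix(out)[miss] - Z[miss])^2))
  base <- sqrt(mean((matrix(colMeans(tab_m, na.rm = TRUE), n, 4,
                            byrow = TRUE)[miss] - Z[miss])^2))
  expect_lt(rmse, base)
})

test_that("log10 transform round-trips and rejects non-positive entries", {
  expect_equal(log10_exposures(matrix(100)), matrix(2))
  x <- matrix(10^runif(20, -2, 3), 4, 5)
  expect_equal(log10_exposures(x), log10(x))
  x[2, 3] <- 0
  colnames(x) <- paste0("c", 1:5)
  expect_error(log10_exposures(x), "row 2, column 3")
})

test_that("diet PCA retains the expected number of components", {
  cv <- generate_covariates(2000, seed = 7)
  dp <- diet_pca(cv$diet)
  expect_equal(dp$n_retained, 3)
  # independent unit-variance columns: all five needed
  ind <- as.data.frame(matrix(rnorm(5000), 1000, 5))
  expect_equal(diet_pca(ind)$n_retained, 5)
  # rank-1 diet: one component suffices
  base <- runif(100, 1, 2)
  r1 <- data.frame(a = base, b = 2 * base, c = 3 * base, d = 0.5 * base,
                   e = 10 * base)
  expect_equal(diet_pca(r1)$n_retained, 1)
  expect_error(diet_pca(ind[, 1:4]), "five")
})

test_that("diet PCA scores are orthogonal and reconstruct the input", {
  cv <- generate_covariates(500, seed = 3)
  dp <- diet_pca(cv$diet, variance_threshold = 0.999999)
  cors <- cor(dp$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  expect_true(all(abs(colMeans(dp$scores)) < 1e-10))
  recon <- dp$scores %*% t(dp$loadings[, seq_len(dp$n_retained)])
  expect_equal(recon, scale(as.matrix(cv$diet)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cohort summaries use non-missing denominators", {
  co <- generate_cohort(n = 941, seed = 21)
  # force the reference gender composition: 649 female, 292 male
  co$data$gender <- factor(c(rep("female", 649), rep("male", 292)),
                           levels = c("male", "female"))
  s <- summarize_cohort(co)
  pf <- s$categorical$percent[s$categorical$variable == "gender" &
                                s$categorical$level == "female"]
  expect_equal(round(pf, 1), 69.0)
  # constant column has SD zero; Spearman diagonal is 1
  co$data$BMI <- 1
  s2 <- suppressWarnings(summarize_cohort(co))  # zero-SD column in cor()
  expect_equal(s2$numeric$sd[s2$numeric$variable == "BMI"], 0)
  expect_true(all(abs(diag(s$spearman_traits) - 1) < 1e-12))
  expect_true(isSymmetric(s$spearman_traits))
})
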