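#' Default hair-biomonitoring compound panel
#'
#' A 33-compound panel mirroring the composition of a typical hair
#' biomonitoring study: 13 persistent organic pollutants (3 polychlorinated
#' biphenyls, 1 polybrominated diphenyl ether, 9 organochlorines) and 20
#' nonpersistent pesticides or metabolites (9 organophosphorus, 4
#' pyrethroids, 2 phenylpyrazoles, 2 carbamates, 1 carboxamide,
#' 1 dinitroaniline, 1 oxadiazole).
#'
#' @return A data frame with columns `compound` and `family`.
#' @export
default_compound_panel <- function() {
  data.frame(
    compound = c(
      "PCB_138", "PCB_153", "PCB_180",
      "PBDE_47",
      "HCB", "alpha_HCH", "beta_HCH", "gamma_HCH", "pp_DDT", "pp_DDE",
      "dieldrin", "PCP", "heptachlor",
      "DMP", "DEP", "PNP", "chlorpyrifos", "diazinon", "parathion",
      "Me4NP_3", "malathion", "TCPy",
      "PBA_3", "Cl2CA", "cypermethrin", "permethrin",
      "fipronil", "fipronil_sulfone",
      "carbofuran", "propoxur",
      "boscalid",
      "trifluralin",
      "oxadiazon"),
    family = c(
      rep("PCB", 3), "PBDE", rep("organochlorine", 9),
      rep("organophosphorus", 9), rep("pyrethroid", 4),
      rep("phenylpyrazole", 2), rep("carbamate", 2),
      "carboxamide", "dinitroaniline", "oxadiazole"),
    stringsAsFactors = FALSE)
}

#' Specify the synthetic exposure panel
#'
#' Exposures are generated through a Gaussian copula on the log10
#' concentration scale: compounds of the same chemical family share a latent
#' correlation `latent_corr_within`, compounds of different families
#' `latent_corr_between`. Each compound has its own log10 location/scale and a
#' target detection fraction that determines its limit of detection (LOD).
#'
#' @param n_compounds Number of compounds.
#' @param family_labels Character vector of family labels (length
#'   `n_compounds`).
#' @param compound_names Compound names; defaults to the built-in panel when
#'   `n_compounds` is 33, otherwise `X1..Xp`.
#' @param latent_corr_within,latent_corr_between Latent correlations in
#'   `[0, 1)` within and between families.
#' @param log10_mean,log10_sd Per-compound location and scale of log10
#'   concentration (pg/mg); recycled.
#' @param detection_target Per-compound fraction of samples above the LOD, in
#'   `[0.10, 1]`; the 0.10 floor mirrors the usual inclusion criterion that a
#'   compound be detected in at least 10% of samples.
#' @param missing_rate Fraction of entries made missing completely at random
#'   (technical missingness), in `[0, 0.5)`.
#' @return An object of class `exposure_spec`.
#' @export
exposure_spec <- function(n_compounds = 33,
                          family_labels = NULL,
                          compound_names = NULL,
                          latent_corr_within = 0.5,
                          latent_corr_between = 0.1,
                          log10_mean = 0.5,
                          log10_sd = 0.6,
                          detection_target = 0.7,
                          missing_rate = 0.02) {
  panel <- default_compound_panel()
  if (is.null(family_labels)) {
    family_labels <- if (n_compounds == 33) panel$family else
      rep("family1", n_compounds)
  }
  if (is.null(compound_names)) {
    compound_names <- if (n_compounds == 33) panel$compound else
      paste0("X", seq_len(n_compounds))
  }
  stopifnot(length(family_labels) == n_compounds,
            length(compound_names) == n_compounds)
  if (latent_corr_within < 0 || latent_corr_within >= 1 ||
      latent_corr_between < 0 || latent_corr_between >= 1)
    stop("latent correlations must lie in [0, 1)")
  detection_target <- rep_len(detection_target, n_compounds)
  if (any(detection_target < 0.10 | detection_target > 1))
    stop("detection_target must lie in [0.10, 1] (compounds detected in ",
         "fewer than 10% of samples are excluded from analysis)")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("missing_rate must lie in [0, 0.5)")
  spec <- list(
    n_compounds = n_compounds,
    compound_names = compound_names,
    family_labels = family_labels,
    latent_corr_within = latent_corr_within,
    latent_corr_between = latent_corr_between,
    log10_mean = rep_len(log10_mean, n_compounds),
    log10_sd = rep_len(log10_sd, n_compounds),
    detection_target = detection_target,
    missing_rate = missing_rate)
  class(spec) <- "exposure_spec"
  # fail early if the implied latent correlation matrix is degenerate
  R <- latent_correlation(spec)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    fam <- names(which.max(table(family_labels)))
    stop(sprintf(
      "implied latent correlation matrix is not positive definite (min eigenvalue %.3g); largest block: family '%s'",
      ev, fam))
  }
  spec
}

latent_correlation <- function(spec) {
  p <- spec$n_compounds
  R <- matrix(spec$latent_corr_between, p, p)
  for (f in unique(spec$family_labels)) {
    i <- which(spec$family_labels == f)
    R[i, i] <- spec$latent_corr_within
  }
  diag(R) <- 1
  R
}

#' Generate censored, partially missing exposure concentrations
#'
#' Draws latent Gaussian scores from the family-block copula, maps them to
#' log-normal concentrations, sets each compound's LOD at the
#' `1 - detection_target` quantile of its generating log-normal, flags (but
#' does not replace) below-LOD values, and finally applies an MCAR missing
#' mask.
#'
#' @param spec An [exposure_spec()].
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return A list with elements `concentration` (n x p matrix of true
#'   generated values, pg/mg), `observed` (same matrix with below-LOD and
#'   missing entries set to `NA` — what an assay would report numerically),
#'   `below_lod` and `missing` (logical masks), and `lod` (named per-compound
#'   LOD vector, pg/mg).
#' @export
generate_exposures <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "exposure_spec"), n >= 1)
  set.seed(seed)
  p <- spec$n_compounds
  R <- latent_correlation(spec)
  assert_pd(R, "latent exposure correlation")
  Z <- rmvnorm_chol(n, R)
  logc <- sweep(sweep(Z, 2, spec$log10_sd, `*`), 2, spec$log10_mean, `+`)
  conc <- 10^logc
  colnames(conc) <- spec$compound_names
  # LOD at the (1 - detection_target) quantile of the generating log-normal;
  # a full-detection compound effectively has no quantification limit
  z <- qnorm(1 - spec$detection_target)
  lod <- ifelse(is.finite(z), 10^(spec$log10_mean + spec$log10_sd * z), 0)
  names(lod) <- spec$compound_names
  below <- sweep(conc, 2, lod, `<`)
  missing <- matrix(runif(n * p) < spec$missing_rate, n, p,
                    dimnames = dimnames(conc))
  observed <- conc
  observed[below] <- NA
  observed[missing] <- NA
  list(concentration = conc, observed = observed,
       below_lod = below & !missing, missing = missing, lod = lod)
}

#' Generate covariate and dietary-intake tables
#'
#' Defaults emulate the marginals of a two-centre European adult cohort:
#' age ~ N(44.8, 13.5^2) years, 69% female, education low/intermediate/high,
#' smoking never/former/current, and five positively correlated dietary
#' intake variables (energy kcal/day; proteins, fats, carbohydrates, fibres
#' g/day) with corr(energy, fat) = 0.88.
#'
#' @param n Number of participants (0 gives empty tables with full schema).
#' @param seed Integer seed.
#' @param age_mean,age_sd Age distribution (years).
#' @param female_fraction Probability of female gender.
#' @param education_probs,smoking_probs Named category frequencies (must sum
#'   to 1).
#' @param diet_mean,diet_sd Length-5 means/SDs for energy, proteins, fats,
#'   carbohydrates, fibres.
#' @param diet_corr 5 x 5 correlation matrix of the dietary variables.
#' @return A list with data frames `covariates` (age, gender, education,
#'   smoking) and `diet`.
#' @export
generate_covariates <- function(n, seed = 1,
                                age_mean = 44.8, age_sd = 13.5,
                                female_fraction = 0.69,
                                education_probs = c(low = 0.389,
                                                    intermediate = 0.228,
                                                    high = 0.383),
                                smoking_probs = c(never = 0.553,
                                                  former = 0.235,
                                                  current = 0.212),
                                diet_mean = c(energy = 2266.5, proteins = 88.6,
                                              fats = 96.6,
                                              carbohydrates = 239.4,
                                              fibres = 24.0),
                                diet_sd = c(763.3, 30.7, 37.7, 89.0, 8.9),
                                diet_corr = default_diet_corr()) {
  stopifnot(n >= 0)
  if (abs(sum(education_probs) - 1) > 1e-6)
    stop("education_probs must sum to 1")
  if (abs(sum(smoking_probs) - 1) > 1e-6)
    stop("smoking_probs must sum to 1")
  set.seed(seed)
  edu_levels <- names(education_probs)
  smk_levels <- names(smoking_probs)
  diet_names <- names(diet_mean)
  if (n == 0) {
    cov <- data.frame(age = numeric(0),
                      gender = factor(character(0), c("male", "female")),
                      education = factor(character(0), edu_levels),
                      smoking = factor(character(0), smk_levels))
    diet <- as.data.frame(matrix(numeric(0), 0, 5,
                                 dimnames = list(NULL, diet_names)))
    return(list(covariates = cov, diet = diet))
  }
  cov <- data.frame(
    age = rnorm(n, age_mean, age_sd),
    gender = factor(ifelse(runif(n) < female_fraction, "female", "male"),
                    levels = c("male", "female")),
    education = factor(sample(edu_levels, n, TRUE, education_probs),
                       levels = edu_levels),
    smoking = factor(sample(smk_levels, n, TRUE, smoking_probs),
                     levels = smk_levels))
  assert_pd(diet_corr, "diet correlation")
  Z <- rmvnorm_chol(n, diet_corr)
  diet <- sweep(sweep(Z, 2, diet_sd, `*`), 2, diet_mean, `+`)
  # intakes are physically positive; clamp the rare negative tail draw
  diet <- pmax(diet, matrix(diet_mean * 0.01, n, 5, byrow = TRUE))
  colnames(diet) <- diet_names
  list(covariates = cov, diet = as.data.frame(diet))
}

#' Default dietary-intake correlation structure
#'
#' One dominant total-intake factor (energy tracks the macronutrients, with
#' corr(energy, fat) = 0.88) plus a partly independent fibre axis, chosen so
#' that three principal components carry over 95% of the variance of the five
#' standardized variables, as observed in food-frequency questionnaire data.
#'
#' @return A 5 x 5 correlation matrix (energy, proteins, fats, carbohydrates,
#'   fibres).
#' @export
default_diet_corr <- function() {
  nm <- c("energy", "proteins", "fats", "carbohydrates", "fibres")
  R <- matrix(c(
    1.000, 0.843, 0.880, 0.915, 0.609,
    0.843, 1.000, 0.780, 0.676, 0.520,
    0.880, 0.780, 1.000, 0.796, 0.406,
    0.915, 0.676, 0.796, 1.000, 0.663,
    0.609, 0.520, 0.406, 0.663, 1.000), 5, 5, dimnames = list(nm, nm))
  R
}

#' Default residual correlation of the nine cardiometabolic traits
#'
#' Encodes the strong empirical trait couplings seen in adult cohorts:
#' BMI-WC 0.89, TC-LDL-C 0.90, SBP-DBP 0.76, WC-FPG 0.51, with moderate
#' adiposity-lipid-pressure cross-correlations and HDL-C inversely related
#' to adiposity and triglycerides.
#'
#' @return A 9 x 9 correlation matrix over BMI, WC, TG, TC, HDLC, LDLC, SBP,
#'   DBP, FPG.
#' @export
default_trait_corr <- function() {
  nm <- c("BMI", "WC", "TG", "TC", "HDLC", "LDLC", "SBP", "DBP", "FPG")
  R <- diag(9)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("BMI", "WC", 0.89)
  set_r("TC", "LDLC", 0.90)
  set_r("SBP", "DBP", 0.76)
  set_r("WC", "FPG", 0.51)
  set_r("BMI", "FPG", 0.45)
  set_r("BMI", "TG", 0.35); set_r("WC", "TG", 0.35)
  set_r("BMI", "SBP", 0.35); set_r("WC", "SBP", 0.35)
  set_r("BMI", "DBP", 0.30); set_r("WC", "DBP", 0.30)
  set_r("BMI", "TC", 0.20); set_r("WC", "TC", 0.20)
  set_r("BMI", "LDLC", 0.20); set_r("WC", "LDLC", 0.20)
  set_r("BMI", "HDLC", -0.35); set_r("WC", "HDLC", -0.40)
  set_r("TG", "HDLC", -0.45); set_r("TG", "TC", 0.35)
  set_r("TG", "LDLC", 0.25); set_r("TG", "SBP", 0.20)
  set_r("TG", "DBP", 0.20); set_r("TG", "FPG", 0.30)
  set_r("TC", "HDLC", 0.10); set_r("TC", "SBP", 0.15)
  set_r("TC", "DBP", 0.15); set_r("TC", "FPG", 0.10)
  set_r("HDLC", "LDLC", -0.05); set_r("HDLC", "SBP", -0.15)
  set_r("HDLC", "DBP", -0.15); set_r("HDLC", "FPG", -0.25)
  set_r("LDLC", "SBP", 0.15); set_r("LDLC", "DBP", 0.15)
  set_r("LDLC", "FPG", 0.10)
  set_r("SBP", "FPG", 0.25); set_r("DBP", "FPG", 0.20)
  R
}

#' Specify the synthetic trait model
#'
#' Traits are a sparse linear function of standardized log10 exposures and of
#' covariates, plus correlated Gaussian residuals with unit variances.
#'
#' @param trait_names Trait names (default: the nine cardiometabolic traits).
#' @param residual_corr Trait residual correlation matrix (unit diagonal,
#'   positive definite).
#' @param true_effects Data frame `(compound, trait, beta)` of standardized
#'   exposure effects; `NULL` for a global null.
#' @param covariate_effects Data frame `(covariate, trait, beta)` where
#'   `covariate` names a column of the one-hot covariate design (e.g. `age`,
#'   `genderfemale`, `smokingcurrent`); `NULL` for none.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(trait_names = colnames(default_trait_corr()),
                       residual_corr = default_trait_corr(),
                       true_effects = NULL,
                       covariate_effects = NULL) {
  q <- length(trait_names)
  stopifnot(nrow(residual_corr) == q, ncol(residual_corr) == q)
  if (max(abs(diag(residual_corr) - 1)) > 1e-8)
    stop("residual_corr must have unit diagonal")
  if (max(abs(residual_corr - t(residual_corr))) > 1e-8)
    stop("residual_corr must be symmetric")
  assert_pd(residual_corr, "trait residual correlation")
  if (!is.null(true_effects)) {
    stopifnot(all(c("compound", "trait", "beta") %in% names(true_effects)))
    if (!all(true_effects$trait %in% trait_names))
      stop("true_effects references unknown traits: ",
           paste(setdiff(true_effects$trait, trait_names), collapse = ", "))
  }
  structure(list(trait_names = trait_names, residual_corr = residual_corr,
                 true_effects = true_effects,
                 covariate_effects = covariate_effects),
            class = "trait_spec")
}

#' Generate trait values from exposures and covariates
#'
#' @param log_exposures n x p matrix of log10 exposure values (standardized
#'   internally before applying the standardized effect sizes).
#' @param covariates Covariate data frame (one-hot encoded internally, first
#'   level as reference).
#' @param spec A [trait_spec()].
#' @param seed Integer seed.
#' @param residual_scale Multiplier on the residual SDs (1 = unit variances);
#'   0 gives noiseless traits.
#' @return A list with `traits` (n x q matrix) and `truth` (gamma_true,
#'   B_true, Sigma_true, seed).
#' @export
generate_traits <- function(log_exposures, covariates, spec, seed = 1,
                            residual_scale = 1) {
  stopifnot(inherits(spec, "trait_spec"))
  n <- nrow(log_exposures)
  if (!is.null(covariates) && nrow(covariates) != n)
    stop("row counts of log_exposures and covariates differ (",
         n, " vs ", nrow(covariates), ")")
  set.seed(seed)
  q <- length(spec$trait_names)
  p <- ncol(log_exposures)
  if (!all(spec$true_effects$compound %in% colnames(log_exposures)))
    stop("true_effects references unknown compounds: ",
         paste(setdiff(spec$true_effects$compound, colnames(log_exposures)),
               collapse = ", "))
  B <- matrix(0, p, q, dimnames = list(colnames(log_exposures),
                                       spec$trait_names))
  if (!is.null(spec$true_effects))
    for (i in seq_len(nrow(spec$true_effects)))
      B[spec$true_effects$compound[i], spec$true_effects$trait[i]] <-
        spec$true_effects$beta[i]
  Xs <- scale(log_exposures)
  Xs[is.na(Xs)] <- 0  # constant columns carry no effect
  eta <- Xs %*% B
  if (!is.null(spec$covariate_effects) && nrow(spec$covariate_effects) > 0) {
    Cm <- stats::model.matrix(~., data = covariates)[, -1, drop = FALSE]
    Cs <- scale(Cm)
    Cs[is.na(Cs)] <- 0
    ce <- spec$covariate_effects
    bad <- setdiff(ce$covariate, colnames(Cs))
    if (length(bad))
      stop("covariate_effects references unknown design columns: ",
           paste(bad, collapse = ", "))
    for (i in seq_len(nrow(ce)))
      eta[, ce$trait[i]] <- eta[, ce$trait[i]] +
        Cs[, ce$covariate[i]] * ce$beta[i]
  }
  E <- rmvnorm_chol(n, spec$residual_corr) * residual_scale
  traits <- eta + E
  colnames(traits) <- spec$trait_names
  gamma_true <- as.integer(rowSums(abs(B)) > 0)
  names(gamma_true) <- rownames(B)
  list(traits = traits,
       truth = list(gamma_true = gamma_true, B_true = B,
                    Sigma_true = spec$residual_corr * residual_scale^2,
                    seed = seed))
}

#' Generate a complete synthetic cohort
#'
#' Ties exposures, covariates, diet and traits together into one
#' participant-level object, optionally appending participants that will be
#' caught by the standard exclusion rules: `n_missing_chem` participants with
#' no valid exposure panel at all and `n_missing_diet` participants missing
#' at least half of the dietary items.
#'
#' @param n Number of analysable participants (default 941, a typical
#'   analysed sample).
#' @param exposure_spec,trait_spec Specs; defaults used when `NULL`.
#' @param n_missing_chem,n_missing_diet Extra to-be-excluded participants.
#' @param seed Integer seed.
#' @param ... Passed to [generate_covariates()].
#' @return An object of class `synthetic_cohort`: a list with `data` (one
#'   data frame: id, covariates, diet, traits, exposures on the observed
#'   scale), masks `below_lod`/`missing`, `lod`, column-group metadata and
#'   the generating `truth`.
#' @export
generate_cohort <- function(n = 941, exposure_spec = NULL, trait_spec = NULL,
                            n_missing_chem = 0, n_missing_diet = 0,
                            seed = 1, ...) {
  if (is.null(exposure_spec)) exposure_spec <- mtess::exposure_spec()
  if (is.null(trait_spec)) trait_spec <- mtess::trait_spec()
  ntot <- n + n_missing_chem + n_missing_diet
  expo <- generate_exposures(exposure_spec, ntot, seed = seed)
  cova <- generate_covariates(ntot, seed = seed + 1, ...)
  tr <- generate_traits(log10(expo$concentration), cova$covariates,
                        trait_spec, seed = seed + 2)
  data <- data.frame(id = sprintf("P%04d", seq_len(ntot)),
                     cova$covariates, cova$diet,
                     as.data.frame(tr$traits),
                     as.data.frame(expo$observed),
                     check.names = FALSE)
  expo_cols <- colnames(expo$observed)
  diet_cols <- colnames(cova$diet)
  trait_cols <- colnames(tr$traits)
  if (n_missing_chem > 0) {
    i <- n + seq_len(n_missing_chem)
    data[i, expo_cols] <- NA
    expo$below_lod[i, ] <- FALSE
    expo$missing[i, ] <- TRUE
  }
  if (n_missing_diet > 0) {
    i <- n + n_missing_chem + seq_len(n_missing_diet)
    data[i, diet_cols[1:3]] <- NA  # 3 of 5 items -> >= 50% missing
  }
  structure(list(
    data = data,
    below_lod = expo$below_lod, missing = expo$missing, lod = expo$lod,
    columns = list(exposures = expo_cols, diet = diet_cols,
                   traits = trait_cols,
                   covariates = c("age", "gender", "education", "smoking")),
    truth = c(tr$truth, list(cohort_seed = seed))),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$data), "participants,",
      length(x$columns$exposures), "exposures,",
      length(x$columns$traits), "traits\n")
  cat("  below-LOD entries:", sum(x$below_lod),
      " missing entries:", sum(x$missing), "\n")
  invisible(x)
}

#' Write a cohort to CSV (plus LOD table and generating truth)
#'
#' Exposure columns are written the way an analytical laboratory would report
#' them: a concentration in pg/mg, the string `<LOD` for censored entries, or
#' an empty field for missing measurements.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`cohort.csv`, `lod.csv`,
#'   `truth.json`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- cohort$data
  for (j in seq_along(cohort$columns$exposures)) {
    cn <- cohort$columns$exposures[j]
    v <- ifelse(is.na(d[[cn]]), "", format(d[[cn]], digits = 8, trim = TRUE))
    v[cohort$below_lod[, j]] <- "<LOD"
    d[[cn]] <- v
  }
  paths <- file.path(dir, c("cohort.csv", "lod.csv", "truth.json"))
  write.csv(d, paths[1], row.names = FALSE, na = "")
  write.csv(data.frame(compound = names(cohort$lod),
                       lod_pg_per_mg = unname(cohort$lod)),
            paths[2], row.names = FALSE)
  truth <- cohort$truth
  truth$B_true <- as.data.frame(truth$B_true)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param cohort_csv,lod_csv File paths.
#' @return A `raw_cohort` object: `data` (numeric exposure columns with `NA`
#'   where censored or missing), masks `below_lod`/`missing`, `lod`, and
#'   column groups.
#' @export
read_cohort <- function(cohort_csv, lod_csv) {
  d <- read.csv(cohort_csv, check.names = FALSE, stringsAsFactors = FALSE,
                na.strings = "")
  lodt <- read.csv(lod_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "lod_pg_per_mg") %in% names(lodt)))
  expo_cols <- intersect(lodt$compound, names(d))
  if (!length(expo_cols))
    stop("no exposure columns of the LOD table found in the cohort table")
  lod <- setNames(lodt$lod_pg_per_mg, lodt$compound)[expo_cols]
  below <- matrix(FALSE, nrow(d), length(expo_cols),
                  dimnames = list(NULL, expo_cols))
  miss <- below
  for (j in seq_along(expo_cols)) {
    v <- as.character(d[[expo_cols[j]]])
    below[, j] <- !is.na(v) & v == "<LOD"
    miss[, j] <- is.na(v)
    v[below[, j]] <- NA
    d[[expo_cols[j]]] <- as.numeric(v)
  }
  for (cn in intersect(c("gender", "education", "smoking"), names(d)))
    d[[cn]] <- factor(d[[cn]])
  diet_cols <- intersect(c("energy", "proteins", "fats", "carbohydrates",
                           "fibres"), names(d))
  trait_cols <- intersect(colnames(default_trait_corr()), names(d))
  structure(list(
    data = d, below_lod = below, missing = miss, lod = lod,
    columns = list(exposures = expo_cols, diet = diet_cols,
                   traits = trait_cols,
                   covariates = intersect(c("age", "gender", "education",
                                            "smoking"), names(d)))),
    class = "raw_cohort")
}

#' Sample a Gaussian panel with a planted conditional-independence graph
#'
#' Builds a precision matrix with entries `-partial` on the planted edges
#' (diagonally dominated for positive definiteness), inverts and rescales it
#' to a correlation matrix, and samples `n` rows. Used to test graph
#' recovery: the planted edges are exactly the nonzero partial correlations.
#'
#' @param nodes Node names.
#' @param edges Two-column matrix or data frame of node-name pairs.
#' @param n Sample size.
#' @param partial Magnitude of the precision off-diagonal entries.
#' @param seed Integer seed.
#' @return List with `data` (n x p), `adjacency` (logical), `sigma`.
#' @export
generate_graph_gaussian <- function(nodes, edges, n, partial = 0.35,
                                    seed = 1) {
  p <- length(nodes)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  edges <- as.matrix(edges)
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- TRUE
    A[edges[i, 2], edges[i, 1]] <- TRUE
  }
  Th <- -partial * A
  diag(Th) <- 1
  # enforce diagonal dominance so Theta is positive definite
  dom <- rowSums(abs(Th)) - 1
  diag(Th) <- pmax(1, dom + 0.1)
  D <- diag(1 / sqrt(diag(Th)))
  Th <- D %*% Th %*% D
  assert_pd(Th, "planted precision matrix")
  S <- solve(Th)
  D2 <- diag(1 / sqrt(diag(S)))
  S <- D2 %*% S %*% D2
  dimnames(S) <- list(nodes, nodes)
  set.seed(seed)
  X <- rmvnorm_chol(n, S)
  colnames(X) <- nodes
  list(data = X, adjacency = A, sigma = S)
}

#' A trait conditional-independence graph with six central traits
#'
#' Edge list for a nine-trait panel in which the six traits BMI, WC, TG,
#' HDL-C, SBP and DBP each connect to at least two other traits, while TC,
#' LDL-C and FPG are peripheral.
#'
#' @return Two-column character matrix of edges.
#' @export
default_trait_graph <- function() {
  rbind(c("BMI", "WC"), c("BMI", "SBP"), c("BMI", "HDLC"),
        c("WC", "DBP"), c("WC", "TG"), c("WC", "FPG"),
        c("SBP", "DBP"), c("TG", "HDLC"),
        c("TC", "LDLC"))
}
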