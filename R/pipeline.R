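#' Default pipeline configuration
#'
#' Full-scale defaults: 30000 sweeps with 10000 burn-in over 3 chains,
#' 100 stability subsamples, PFER bounds 10 (trait network) and 20 (exposure
#' network), empirical FDR at 0.05 with 20 permutation runs, size prior
#' E = 5, S = 4, F = 7.
#'
#' @param ... Named overrides of any default (nested lists are merged).
#' @return A validated `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = "mtess_run",
    simulate = list(n = 941, n_compounds = 33, n_missing_chem = 0,
                    n_missing_diet = 0),
    input = NULL,               # list(cohort_csv=, lod_csv=) to skip simulate
    sampler = list(n_sweeps = 30000, burn_in = 10000, n_chains = 3),
    prior = list(E = 5, S = 4, F = 7),
    network = list(K = 100, pfer_traits = 10, pfer_exposures = 20),
    fdr = list(level = 0.05, permutations = 20),
    effect_rounds = 500,
    attenuation = TRUE)
  ov <- list(...)
  validate_config_keys(ov, cfg, "config")
  modify_deep(cfg, ov)
}

modify_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- modify_deep(base[[nm]], over[[nm]])
    else base[nm] <- over[nm]
  }
  base
}

validate_config_keys <- function(given, reference, path) {
  unknown <- setdiff(names(given), names(reference))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(given))
    if (is.list(reference[[nm]]) && is.list(given[[nm]]))
      validate_config_keys(given[[nm]], reference[[nm]],
                           paste0(path, "$", nm))
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys raise an error naming the key; missing keys take the
#' [default_config()] values.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  ov <- yaml::read_yaml(path)
  do.call(default_config, ov)
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %-12s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (unless input files are given), preprocess
#' (exclusions, below-LOD imputation, iterative missing-data imputation,
#' log10 transform, diet PCA), descriptive summary, trait and multiblock
#' exposure networks with Louvain communities, trait selection (degree >= 2
#' in the calibrated trait network), multitrait BVS on the selected traits,
#' posthoc summaries (MPP/MPPI, permutation-FDR threshold, BF/RBF,
#' effect-size posterior of the top model), the 33 x 9-style univariate
#' scan, and the covariate-ladder MPPI attenuation runs. All tables are
#' written under `config$out_dir` together with a JSON run manifest and a
#' plain-text log.
#'
#' @param config A `run_config` from [default_config()] / [read_config()].
#' @return Invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logfile))
  stage <- "init"
  res <- list()
  run_stage <- function(name, expr) {
    stage <- name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- simulate / load ----
  if (is.null(config$input)) {
    run_stage("simulate", {
      sim <- config$simulate
      espec <- if (sim$n_compounds == 33) exposure_spec() else {
        fams <- rep(paste0("family", 1:4), length.out = sim$n_compounds)
        exposure_spec(n_compounds = sim$n_compounds, family_labels = fams)
      }
      cohort <- generate_cohort(n = sim$n, exposure_spec = espec,
                                n_missing_chem = sim$n_missing_chem,
                                n_missing_diet = sim$n_missing_diet,
                                seed = config$seed)
      write_cohort(cohort, file.path(config$out_dir, "input"))
      res$cohort <- cohort
      pipeline_log(logfile, "simulate",
                   sprintf("generated %d participants, %d compounds",
                           nrow(cohort$data), sim$n_compounds))
    })
  } else {
    run_stage("load", {
      res$cohort <- read_cohort(config$input$cohort_csv,
                                 config$input$lod_csv)
      pipeline_log(logfile, "load",
                   sprintf("read %d participants", nrow(res$cohort$data)))
    })
  }

  # ---- preprocess ----
  run_stage("preprocess", {
    fl <- filter_cohort(res$cohort)
    res$exclusions <- fl$log
    cohort <- fl$cohort
    jsonlite::write_json(
      list(initial = attr(fl$log, "initial"),
           rules = fl$log$rule, excluded = fl$log$excluded,
           retained = attr(fl$log, "retained")),
      file.path(config$out_dir, "exclusion_log.json"), auto_unbox = TRUE)
    expo_cols <- cohort$columns$exposures
    emat <- as.matrix(cohort$data[, expo_cols, drop = FALSE])
    emat <- impute_below_lod(emat, cohort$lod, cohort$below_lod,
                             seed = config$seed)
    cohort$data[, expo_cols] <- emat
    cohort$data <- impute_missing(
      cohort$data[, setdiff(names(cohort$data), "id")],
      seed = config$seed) |>
      (\(d) cbind(cohort$data["id"], d))()
    lmat <- log10_exposures(as.matrix(cohort$data[, expo_cols]))
    dp <- diet_pca(cohort$data[, cohort$columns$diet])
    res$cohort_clean <- cohort
    res$log_exposures <- lmat
    res$diet_scores <- dp
    pipeline_log(logfile, "preprocess",
                 sprintf("retained %d; diet PCA kept %d components",
                         attr(fl$log, "retained"), dp$n_retained))
  })

  # ---- descriptive summary ----
  run_stage("summary", {
    s <- summarize_cohort(res$cohort_clean)
    res$summary <- s
    write.table(s$numeric, file.path(config$out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pipeline_log(logfile, "summary", "wrote summary.tsv")
  })

  cohort <- res$cohort_clean
  traits <- as.matrix(cohort$data[, cohort$columns$traits, drop = FALSE])
  nK <- config$network$K

  # ---- networks ----
  run_stage("network", {
    net_t <- calibrate_network(
      traits, stability_config(K = nK, pfer_max = config$network$pfer_traits,
                               seed = config$seed))
    net_t <- detect_communities(net_t, seed = config$seed)
    diet <- as.matrix(cohort$data[, cohort$columns$diet, drop = FALSE])
    xmat <- cbind(diet, res$log_exposures)
    blocks <- c(rep("diet", ncol(diet)),
                rep("chemical", ncol(res$log_exposures)))
    net_e <- calibrate_network(
      xmat, stability_config(K = nK,
                             pfer_max = config$network$pfer_exposures,
                             seed = config$seed),
      blocks = blocks)
    net_e <- detect_communities(net_e, seed = config$seed)
    write_network(net_t, file.path(config$out_dir, "network_traits.tsv"),
                  file.path(config$out_dir, "network_traits.graphml"))
    write_network(net_e, file.path(config$out_dir, "network_exposures.tsv"),
                  file.path(config$out_dir, "network_exposures.graphml"))
    res$network_traits <- net_t
    res$network_exposures <- net_e
    pipeline_log(logfile, "network",
                 sprintf("trait net: %d stable edges; exposure net: %d",
                         sum(net_t$edges$stable), sum(net_e$edges$stable)))
  })

  # ---- trait selection: degree >= 2 in the calibrated trait network ----
  run_stage("trait_select", {
    deg <- rowSums(res$network_traits$adjacency)
    sel <- names(deg)[deg >= 2]
    if (length(sel) < 2) {
      pipeline_log(logfile, "trait_select",
                   "fewer than 2 central traits; falling back to all traits")
      sel <- colnames(traits)
    }
    res$selected_traits <- sel
    pipeline_log(logfile, "trait_select",
                 paste("selected:", paste(sel, collapse = ", ")))
  })

  # ---- BVS ----
  covdf <- cohort$data[, cohort$columns$covariates, drop = FALSE]
  Cfull <- cbind(stats::model.matrix(~., data = covdf),
                 res$diet_scores$scores)
  prior <- size_prior(config$prior$E, config$prior$S, config$prior$F,
                      p = ncol(res$log_exposures))
  scfg <- sampler_config(n_sweeps = config$sampler$n_sweeps,
                         burn_in = config$sampler$burn_in,
                         n_chains = config$sampler$n_chains,
                         seed = config$seed)
  pi0 <- config$prior$E / ncol(res$log_exposures)

  run_stage("bvs", {
    rz <- residualize(traits[, res$selected_traits, drop = FALSE],
                      res$log_exposures, Cfull)
    nu <- nrow(rz$Y) - rz$df_adjust
    fit <- run_guess(rz$Y, rz$X, prior, scfg, nu = nu)
    res$bvs_multitrait <- fit
    res$bvs_residualized <- rz
    res$bvs_nu <- nu
    # single-trait runs over the selected traits
    res$bvs_single <- lapply(setNames(res$selected_traits,
                                       res$selected_traits), function(tr) {
      run_guess(rz$Y[, tr, drop = FALSE], rz$X, prior, scfg, nu = nu)
    })
    pipeline_log(logfile, "bvs",
                 sprintf("multitrait: %d visited models, exchange rate %.2f",
                         nrow(fit$models), fit$exchange_rate))
  })

  # ---- posthoc ----
  run_stage("posthoc", {
    fit <- res$bvs_multitrait
    rz <- res$bvs_residualized
    mpp <- compute_mpp(fit)
    mppi <- compute_mppi(fit)
    perm <- permutation_mppi(rz$Y[, res$selected_traits, drop = FALSE],
                             rz$X, prior, scfg,
                             n_perm = config$fdr$permutations,
                             seed = config$seed, nu = res$bvs_nu)
    fdr <- empirical_fdr_threshold(mppi, perm, level = config$fdr$level)
    eps <- 1 / fit$n_kept
    rt <- rbf_table(mppi, fdr, pi0, eps = eps)
    top <- mpp$model[1]
    res$mpp <- mpp; res$mppi <- mppi; res$fdr <- fdr; res$rbf <- rt
    write.table(head(mpp, 50), file.path(config$out_dir, "top_models.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(feature = names(mppi), mppi = unname(mppi)),
                file.path(config$out_dir, "mppi.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rt, file.path(config$out_dir, "rbf.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nchar(top) > 0) {
      gam <- match(strsplit(top, ",")[[1]], fit$predictors)
      ep <- effect_posterior(rz$Y[, res$selected_traits, drop = FALSE],
                             rz$X, gam, n_rounds = config$effect_rounds,
                             nu = res$bvs_nu, seed = config$seed)
      res$effects <- ep
      write.table(ep$summary, file.path(config$out_dir, "effects.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      pipeline_log(logfile, "posthoc", "top model is empty; no effects table")
    }
    pipeline_log(logfile, "posthoc",
                 sprintf("FDR threshold %s; %d significant features",
                         format(fdr$threshold), length(fdr$significant)))
  })

  # ---- univariate scan ----
  run_stage("scan", {
    covs <- cbind(covdf, as.data.frame(res$diet_scores$scores))
    sc <- univariate_scan(traits, res$log_exposures, covs)
    res$scan <- sc
    write.table(sc, file.path(config$out_dir, "scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pipeline_log(logfile, "scan",
                 sprintf("%d pair models, %d Bonferroni-significant",
                         nrow(sc), sum(sc$significant)))
  })

  # ---- attenuation ladder ----
  if (isTRUE(config$attenuation)) run_stage("attenuation", {
    ladders <- list(
      unadjusted = NULL,
      age_sex = stats::model.matrix(~ age + gender, covdf),
      edu_smoking = stats::model.matrix(~ age + gender + education + smoking,
                                        covdf),
      diet = Cfull)
    runs <- lapply(ladders, function(C) {
      rz <- residualize(traits[, res$selected_traits, drop = FALSE],
                        res$log_exposures, C)
      compute_mppi(run_guess(rz$Y, rz$X, prior, scfg,
                             nu = nrow(rz$Y) - rz$df_adjust))
    })
    att <- mppi_attenuation(runs)
    res$attenuation <- att
    write.table(att, file.path(config$out_dir, "attenuation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pipeline_log(logfile, "attenuation",
                 sprintf("%d rows over %d adjustment sets", nrow(att),
                         length(runs)))
  })

  # ---- manifest ----
  run_stage("manifest", {
    manifest <- list(
      seed = config$seed,
      config = config[setdiff(names(config), "input")],
      package_version = as.character(utils::packageVersion("mtess")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  pipeline_log(logfile, "done", paste("artifacts in", config$out_dir))
  invisible(c(res, list(out_dir = config$out_dir)))
}
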