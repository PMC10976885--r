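#' Apply cohort exclusion rules
#'
#' Rules are applied in the order given. Built-in rules:
#' \describe{
#'   \item{`missing_chemical`}{participant has no valid exposure measurement
#'     at all (the whole panel is missing or censored-and-unmeasured);
#'     per-compound technical missingness is left for imputation.}
#'   \item{`diet_missing_50`}{participant is missing 50% or more of the
#'     dietary intake items.}
#' }
#'
#' @param raw A `raw_cohort` (see [read_cohort()]) or `synthetic_cohort`.
#' @param rules Character vector of rule names, applied in order.
#' @return A list with `cohort` (the filtered object) and `log` (an
#'   `exclusion_log` data frame: rule, excluded, plus attributes `initial`
#'   and `retained`).
#' @export
filter_cohort <- function(raw,
                          rules = c("missing_chemical", "diet_missing_50")) {
  stopifnot(inherits(raw, c("raw_cohort", "synthetic_cohort")))
  d <- raw$data
  expo <- raw$columns$exposures
  diet <- raw$columns$diet
  initial <- nrow(d)
  keep <- rep(TRUE, initial)
  counts <- integer(0)
  for (rule in rules) {
    drop <- switch(rule,
      missing_chemical = {
        # "missing" means no numeric value and not a known below-LOD censor
        obs <- !is.na(as.matrix(d[, expo, drop = FALSE])) |
          raw$below_lod[, expo, drop = FALSE]
        rowSums(obs) == 0
      },
      diet_missing_50 =
        rowMeans(is.na(d[, diet, drop = FALSE])) >= 0.5,
      stop("unknown exclusion rule: ", rule))
    drop <- drop & keep
    counts <- c(counts, sum(drop))
    keep <- keep & !drop
  }
  log <- data.frame(rule = rules, excluded = counts)
  attr(log, "initial") <- initial
  attr(log, "retained") <- sum(keep)
  class(log) <- c("exclusion_log", "data.frame")
  out <- raw
  out$data <- d[keep, , drop = FALSE]
  out$below_lod <- raw$below_lod[keep, , drop = FALSE]
  out$missing <- raw$missing[keep, , drop = FALSE]
  if (!is.null(out$truth)) out$truth$retained_rows <- which(keep)
  list(cohort = out, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusions (initial n =", attr(x, "initial"), "):\n")
  for (i in seq_len(nrow(x)))
    cat("  ", x$rule[i], ": ", x$excluded[i], " excluded\n", sep = "")
  cat("Retained:", attr(x, "retained"), "\n")
  invisible(x)
}

# inverse-CDF draw from N(mu, sd) truncated to (lo, hi)
rtruncnorm_icdf <- function(n, mu, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mu, lo), hi), n))
  a <- pnorm(lo, mu, sd)
  b <- pnorm(hi, mu, sd)
  if (b - a < 1e-12) {
    # the untruncated fit puts essentially no mass in (lo, hi); fall back to
    # a flat draw over the interval
    return(runif(n, lo, hi))
  }
  q <- qnorm(a + runif(n) * (b - a), mu, sd)
  pmin(pmax(q, lo + 1e-12), hi - 1e-12)
}

# censored-Gaussian MLE on the natural concentration scale: observed values
# above the LOD plus the count of left-censored observations
fit_censored_normal <- function(obs, n_cens, lod) {
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    -(sum(dnorm(obs, mu, s, log = TRUE)) +
        n_cens * pnorm(lod, mu, s, log.p = TRUE))
  }
  init <- c(mean(obs), log(max(sd(obs), lod / 10, 1e-6)))
  fit <- tryCatch(optim(init, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  c(mu = fit$par[1], sd = exp(fit$par[2]))
}

#' Impute below-LOD concentrations from a truncated Gaussian
#'
#' Each flagged entry is replaced by a draw from a Gaussian truncated to
#' `(0, LOD)`. By default the Gaussian's location and scale are fitted per
#' compound by censored-likelihood MLE on the natural concentration scale
#' (observed values plus the censoring fraction); with fewer than 10 observed
#' values, or with `method = "fixed"`, the fallback `mu = LOD/2`,
#' `sd = LOD/4` is used (with a warning in the fallback case).
#'
#' @param values Numeric matrix (participants x compounds); censored entries
#'   may hold `NA` or any placeholder — they are overwritten.
#' @param lod Per-compound LOD vector (pg/mg), positive.
#' @param below_lod Logical mask of censored entries, same shape as `values`.
#' @param seed Integer seed.
#' @param method `"censored_mle"` (default) or `"fixed"`.
#' @return `values` with every flagged entry strictly inside `(0, LOD)`;
#'   observed entries untouched.
#' @export
impute_below_lod <- function(values, lod, below_lod, seed = 1,
                             method = c("censored_mle", "fixed")) {
  method <- match.arg(method)
  stopifnot(all(lod >= 0), all(dim(values) == dim(below_lod)))
  if (any(lod[colSums(below_lod) > 0] <= 0))
    stop("flagged compounds must have a positive LOD")
  set.seed(seed)
  out <- values
  for (j in seq_len(ncol(values))) {
    flag <- below_lod[, j]
    if (!any(flag)) next
    obs <- values[!flag, j]
    obs <- obs[!is.na(obs)]
    par <- NULL
    if (method == "censored_mle") {
      if (length(obs) >= 10) {
        par <- fit_censored_normal(obs, sum(flag), lod[j])
      } else {
        warning(sprintf(
          "compound %d: %d observed values (< 10); falling back to mu = LOD/2, sd = LOD/4",
          j, length(obs)))
      }
    }
    if (is.null(par)) par <- c(mu = lod[j] / 2, sd = lod[j] / 4)
    out[flag, j] <- rtruncnorm_icdf(sum(flag), par["mu"], par["sd"],
                                    0, lod[j])
  }
  out
}

# single-column learner for the iterative imputer: linear model for numeric
# targets (exact for linearly related columns), classification tree for
# factors
impute_learner <- function(y, X, miss) {
  df <- data.frame(.y = y, X, check.names = TRUE)
  if (is.factor(y)) {
    fit <- rpart::rpart(.y ~ ., data = df[!miss, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(cp = 1e-3, xval = 0,
                                                       minsplit = 10))
    return(predict(fit, df[miss, , drop = FALSE], type = "class"))
  }
  fit <- lm(.y ~ ., data = df[!miss, , drop = FALSE])
  pred <- suppressWarnings(predict(fit, df[miss, , drop = FALSE]))
  # no extrapolation beyond the observed range (keeps skewed, strictly
  # positive measurements such as concentrations in their support)
  pmin(pmax(pred, min(y[!miss])), max(y[!miss]))
}

#' Iterative conditional imputation of missing values
#'
#' Round-robin iterative conditional modelling: each incomplete column is
#' modelled on all other columns with a regression/classification tree, and
#' its missing entries refreshed, cycling until the relative change of the
#' imputed numeric values drops below `tol` or `max_iter` is reached.
#' Columns may be numeric or factor.
#'
#' @param table Data frame.
#' @param tol Relative-change convergence tolerance (default 1e-3).
#' @param max_iter Maximum sweeps over the columns (default 10).
#' @param seed Integer seed (initialisation and tie-breaks).
#' @return The completed data frame (observed entries untouched), with
#'   attribute `iterations`.
#' @export
impute_missing <- function(table, tol = 1e-3, max_iter = 10, seed = 1) {
  stopifnot(is.data.frame(table))
  set.seed(seed)
  miss <- lapply(table, is.na)
  any_miss <- vapply(miss, any, logical(1))
  if (!any(any_miss)) {
    attr(table, "iterations") <- 0L
    return(table)
  }
  if (any(vapply(miss, all, logical(1))))
    stop("column(s) entirely missing: ",
         paste(names(table)[vapply(miss, all, logical(1))], collapse = ", "))
  usable <- vapply(table, function(x) is.numeric(x) || is.factor(x),
                   logical(1))
  work <- table[usable]
  wmiss <- miss[usable]
  # initialise with median / modal category
  for (cn in names(work)) {
    m <- wmiss[[cn]]
    if (!any(m)) next
    work[[cn]][m] <- if (is.factor(work[[cn]]))
      names(which.max(table(work[[cn]][!m])))
    else median(work[[cn]][!m])
  }
  cols <- names(work)[vapply(wmiss, any, logical(1))]
  # most-complete columns first, as iterative imputers conventionally do
  cols <- cols[order(vapply(wmiss[cols], sum, integer(1)))]
  iter_used <- max_iter
  for (it in seq_len(max_iter)) {
    delta <- 0; denom <- 0
    for (cn in cols) {
      m <- wmiss[[cn]]
      old <- work[[cn]][m]
      pred <- impute_learner(work[[cn]], work[setdiff(names(work), cn)], m)
      work[[cn]][m] <- pred
      if (is.numeric(old)) {
        delta <- delta + sum((as.numeric(pred) - old)^2)
        denom <- denom + sum(as.numeric(pred)^2)
      }
    }
    if (denom == 0 || sqrt(delta / denom) < tol) { iter_used <- it; break }
  }
  out <- table
  for (cn in names(work)) out[[cn]] <- work[[cn]]
  attr(out, "iterations") <- iter_used
  out
}

#' Log10-transform an exposure matrix
#'
#' @param matrix Numeric matrix of strictly positive concentrations
#'   (post-imputation).
#' @return Elementwise log10.
#' @export
log10_exposures <- function(matrix) {
  bad <- which(!(matrix > 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive entry at row %d, column %d (%s)",
                 bad[1, 1], bad[1, 2],
                 if (!is.null(colnames(matrix))) colnames(matrix)[bad[1, 2]]
                 else "unnamed"))
  log10(matrix)
}

#' Summarise the five dietary variables by PCA
#'
#' PCA on the standardized variables; retains the smallest number of
#' components whose cumulative variance fraction exceeds `variance_threshold`.
#'
#' @param diet5 Data frame or matrix with five complete numeric columns.
#' @param variance_threshold Cumulative variance to exceed (default 0.95).
#' @return A `diet_scores` list: `scores` (n x n_retained, centered),
#'   `loadings`, `variance_fraction` (all five), `n_retained`.
#' @export
diet_pca <- function(diet5, variance_threshold = 0.95) {
  diet5 <- as.matrix(diet5)
  if (ncol(diet5) < 5) stop("diet_pca expects the five dietary variables")
  if (anyNA(diet5)) stop("diet_pca requires complete data (impute first)")
  pc <- prcomp(diet5, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(vf) > variance_threshold)[1]
  structure(list(scores = pc$x[, seq_len(m), drop = FALSE],
                 loadings = pc$rotation,
                 variance_fraction = vf,
                 n_retained = m),
            class = "diet_scores")
}

#' Descriptive summary of a cohort table
#'
#' Means/SDs for numeric variables, counts and percentages (on non-missing
#' denominators) for categorical ones, per-compound detection fractions, and
#' Spearman correlation matrices for the traits and for the exposures + diet
#' block.
#'
#' @param cohort A `raw_cohort` or `synthetic_cohort`.
#' @return A list: `numeric` (variable, mean, sd, n), `categorical`
#'   (variable, level, count, percent), `detection` (compound, fraction
#'   above LOD), `spearman_traits`, `spearman_exposures`.
#' @export
summarize_cohort <- function(cohort) {
  d <- cohort$data
  if (nrow(d) == 0)
    return(list(numeric = data.frame(), categorical = data.frame(),
                detection = data.frame(), spearman_traits = NULL,
                spearman_exposures = NULL))
  num_cols <- names(d)[vapply(d, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "id")
  num <- data.frame(
    variable = num_cols,
    mean = vapply(d[num_cols], function(x) mean(x, na.rm = TRUE), 0),
    sd = vapply(d[num_cols], function(x) sd(x, na.rm = TRUE), 0),
    n = vapply(d[num_cols], function(x) sum(!is.na(x)), 0L),
    row.names = NULL)
  cat_cols <- names(d)[vapply(d, function(x) is.factor(x) ||
                                is.character(x), logical(1))]
  cat_cols <- setdiff(cat_cols, "id")
  cats <- do.call(rbind, lapply(cat_cols, function(cn) {
    x <- d[[cn]][!is.na(d[[cn]])]
    tab <- table(x)
    data.frame(variable = cn, level = names(tab),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / length(x),
               row.names = NULL)
  }))
  expo <- cohort$columns$exposures
  det <- NULL
  if (length(expo) > 0 && !is.null(cohort$below_lod)) {
    measured <- !cohort$missing[, expo, drop = FALSE]
    det <- data.frame(
      compound = expo,
      detected_fraction = colSums(measured &
                                    !cohort$below_lod[, expo, drop = FALSE]) /
        pmax(1, colSums(measured)),
      row.names = NULL)
  }
  sp <- function(cols) {
    if (length(cols) < 2) return(NULL)
    cor(as.matrix(d[, cols, drop = FALSE]), method = "spearman",
        use = "pairwise.complete.obs")
  }
  list(numeric = num, categorical = cats, detection = det,
       spearman_traits = sp(cohort$columns$traits),
       spearman_exposures = sp(c(cohort$columns$diet,
                                 cohort$columns$exposures)))
}
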