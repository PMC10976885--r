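#' Residualize outcomes and predictors on a covariate block
#'
#' Projects both `Y` and `X` onto the orthogonal complement of the column
#' span of `C` (covariate adjustment by residualization) and standardizes the
#' resulting columns to unit variance. An intercept column is added to `C`
#' when absent, so the projection always removes column means.
#'
#' @param Y n x q outcome matrix.
#' @param X n x p predictor matrix.
#' @param C n x c covariate design matrix (or `NULL` for intercept only).
#' @return A list `Y`, `X` (residualized, unit-variance columns) and
#'   `df_adjust` = number of covariate columns projected out (used as the
#'   degrees-of-freedom correction `nu = n - df_adjust` downstream).
#' @export
residualize <- function(Y, X, C = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (is.null(C)) C <- matrix(1, n, 1)
  C <- as.matrix(C)
  if (!any(apply(C, 2, function(x) sd(x) < 1e-12)))
    C <- cbind(1, C)
  if (anyNA(Y) || anyNA(X) || anyNA(C))
    stop("residualize requires complete data")
  qc <- qr(C)
  Yt <- qr.resid(qc, Y)
  Xt <- qr.resid(qc, X)
  v <- apply(Xt, 2, function(x) sum(x^2) / (n - 1))
  if (any(v < 1e-10)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("X", seq_len(ncol(X)))
    stop("predictor(s) collinear with the covariates: ",
         paste(nm[v < 1e-10], collapse = ", "))
  }
  Xt <- sweep(Xt, 2, sqrt(v), `/`)
  sy <- apply(Yt, 2, function(x) sqrt(sum(x^2) / (n - 1)))
  Yt <- sweep(Yt, 2, pmax(sy, 1e-12), `/`)
  list(Y = Yt, X = Xt, df_adjust = qc$rank)
}

#' Beta-binomial prior on model size, moment-matched and truncated
#'
#' The number of included predictors `k` follows a beta-binomial(p, a, b)
#' distribution whose (a, b) are chosen so the untruncated size distribution
#' has mean `E` and standard deviation `S`; mass beyond the truncation point
#' `T = min(p, E + F S)` is removed and the distribution renormalized. When
#' `S^2` does not exceed the binomial variance at mean `E` the moment match
#' is infeasible and a pure binomial(p, E/p) prior is used with a warning.
#'
#' @param E Prior expected model size (default 5).
#' @param S Prior SD of model size (default 4).
#' @param F Truncation factor (default 7).
#' @param p Number of candidate predictors.
#' @return A `size_prior` object: `a`, `b`, `T`, `log_size_pmf` (truncated,
#'   over k = 0..p), `log_model_prior` (per-model log prior,
#'   `log_size_pmf - log choose(p, k)`).
#' @export
size_prior <- function(E = 5, S = 4, F = 7, p = 33) {
  Tmax <- min(p, floor(E + F * S))
  mu <- E / p
  binom_var <- p * mu * (1 - mu)
  ratio <- S^2 / binom_var
  if (S^2 <= binom_var || ratio >= p) {
    warning(if (S^2 <= binom_var)
      "S^2 does not exceed the binomial variance at mean E; using a binomial size prior"
      else
        "S^2 exceeds the maximum beta-binomial variance for this p; using a binomial size prior")
    lpmf <- dbinom(0:p, p, mu, log = TRUE)
    a <- b <- NA_real_
  } else {
    ab <- (p - ratio) / (ratio - 1)
    a <- mu * ab
    b <- (1 - mu) * ab
    k <- 0:p
    lpmf <- lchoose(p, k) + lbeta(k + a, p - k + b) - lbeta(a, b)
  }
  lpmf[(0:p) > Tmax] <- -Inf
  lpmf <- lpmf - logsumexp(lpmf)
  structure(list(E = E, S = S, F = F, p = p, a = a, b = b, T = Tmax,
                 log_size_pmf = lpmf,
                 log_model_prior = lpmf - lchoose(p, 0:p)),
            class = "size_prior")
}

#' @export
print.size_prior <- function(x, ...) {
  cat(sprintf(
    "Truncated beta-binomial size prior: E = %g, S = %g, F = %g, p = %d, T = %d\n",
    x$E, x$S, x$F, x$p, x$T))
  cat(sprintf("  a = %.4g, b = %.4g, P(k <= 14) = %.4f\n", x$a, x$b,
              prior_size_cdf(x, 14)))
  invisible(x)
}

#' Log prior probability of a specific model of size k
#'
#' @param k Model size(s), `0 <= k <= p`.
#' @param prior A [size_prior()].
#' @return Log prior of any one model with `k` included predictors (`-Inf`
#'   beyond the truncation point).
#' @export
log_size_prior <- function(k, prior) {
  stopifnot(inherits(prior, "size_prior"), all(k >= 0), all(k <= prior$p))
  prior$log_model_prior[k + 1]
}

#' Cumulative size-prior probability P(k <= kmax)
#' @param prior A [size_prior()].
#' @param kmax Upper size.
#' @export
prior_size_cdf <- function(prior, kmax) {
  sum(exp(prior$log_size_pmf[0:kmax + 1]))
}

#' Log marginal likelihood of a model under the matrix-variate g-prior
#'
#' For the multivariate regression of `Y` (n x q) on the included columns of
#' `X`, with a g-prior on the included coefficient matrix (row covariance
#' `g (X_g' X_g)^{-1}`, column covariance the residual covariance) and a
#' Jeffreys prior on the residual covariance, the marginal likelihood up to a
#' model-independent constant is
#' \deqn{-\frac{qk}{2}\log(1+g) - \frac{\nu}{2}\log\det\left(Y'Y -
#'   \frac{g}{1+g} Y'P_\gamma Y\right)}
#' with `P_gamma` the projector onto the span of the included predictors and
#' `nu` the residual degrees of freedom.
#'
#' @param Y,X Residualized matrices (see [residualize()]).
#' @param gamma Logical/0-1 inclusion vector of length `ncol(X)`, or an
#'   integer vector of included column indices.
#' @param g Shrinkage scalar (default `nrow(Y)`, unit information).
#' @param nu Degrees of freedom (default `nrow(Y) - 1`).
#' @return Scalar log marginal likelihood (up to a constant).
#' @export
log_marginal <- function(Y, X, gamma, g = nrow(Y), nu = nrow(Y) - 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  idx <- gamma_indices(gamma, ncol(X))
  YtY <- crossprod(Y)
  q <- ncol(Y); k <- length(idx)
  M <- YtY
  if (k > 0) {
    Xg <- X[, idx, drop = FALSE]
    Gg <- crossprod(Xg)
    R <- tryCatch(chol(Gg), error = function(e)
      stop("included predictors are rank deficient"))
    Z <- forwardsolve(t(R), crossprod(Xg, Y))
    M <- M - (g / (1 + g)) * crossprod(Z)
  }
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("non-positive-definite residual cross-product; model too large?")
  -0.5 * q * k * log1p(g) - 0.5 * nu * as.numeric(ld$modulus)
}

# interpret gamma as a binary inclusion vector when it has length p and only
# 0/1 entries, otherwise as included column indices
gamma_indices <- function(gamma, p) {
  if (is.logical(gamma)) return(which(gamma))
  gamma <- as.numeric(gamma)
  if (length(gamma) == p && all(gamma %in% c(0, 1)))
    return(which(gamma == 1))
  as.integer(gamma)
}

#' Sampler configuration for [run_guess()]
#'
#' @param n_sweeps Total sweeps (default 30000).
#' @param burn_in Burn-in sweeps (default 10000).
#' @param n_chains Number of tempered chains (default 3).
#' @param temp_ratio Initial geometric temperature ratio (default 1.3);
#'   adapted during burn-in toward a 0.5 exchange acceptance rate, then
#'   frozen.
#' @param prob_crossover Per-sweep probability of one crossover move between
#'   two random chains (default 0.33).
#' @param g Shrinkage scalar; `NULL` means `n` (unit information).
#' @param seed Integer seed.
#' @param adapt_temps Adapt the ladder during burn-in (default TRUE).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_sweeps = 30000, burn_in = 10000, n_chains = 3,
                           temp_ratio = 1.3, prob_crossover = 0.33,
                           g = NULL, seed = 1, adapt_temps = TRUE) {
  if (burn_in >= n_sweeps) stop("burn_in must be smaller than n_sweeps")
  structure(list(n_sweeps = n_sweeps, burn_in = burn_in, n_chains = n_chains,
                 temp_ratio = temp_ratio, prob_crossover = prob_crossover,
                 g = g, seed = seed, adapt_temps = adapt_temps),
            class = "sampler_config")
}

#' Evolutionary stochastic search over models with parallel tempering
#'
#' MCMC over inclusion indicators: per sweep each chain attempts a mutation
#' (add with probability 0.45, delete 0.45, swap 0.10, Metropolis-Hastings
#' acceptance at the chain's temperature), with probability
#' `prob_crossover` one uniform crossover between two random chains is
#' proposed and accepted jointly, and one state exchange between an
#' adjacent-temperature pair is attempted. The temperature ladder is
#' geometric, adapted during burn-in toward a 0.5 exchange acceptance rate.
#' Cold-chain (temperature 1) states after burn-in form the visited-model
#' record.
#'
#' @param Y,X Residualized outcome and predictor matrices (see
#'   [residualize()]).
#' @param prior A [size_prior()] for `p = ncol(X)`.
#' @param config A [sampler_config()].
#' @param nu Degrees of freedom for the marginal likelihood (default
#'   `nrow(Y) - 1`; pass `nrow(Y) - df_adjust` after covariate
#'   residualization).
#' @return A `visited_models` object: `models` data frame (model key =
#'   comma-separated sorted predictor names, size, count, log_post), `mppi_counts`
#'   per-feature inclusion counts, `trace` (per-sweep cold-chain size and log
#'   posterior over all sweeps), `n_kept` post-burn-in sweeps, `predictors`,
#'   `temperatures`, `exchange_rate`.
#' @export
run_guess <- function(Y, X, prior, config = sampler_config(), nu = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(inherits(prior, "size_prior"), prior$p == p)
  n <- nrow(Y)
  if (is.null(nu)) nu <- n - 1
  g <- if (is.null(config$g)) n else config$g
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("X", seq_len(p))
  set.seed(config$seed)
  res <- .guess_sampler_cpp(crossprod(X), crossprod(X, Y), crossprod(Y),
                            nu, g, prior$log_model_prior, prior$T,
                            config$n_sweeps, config$burn_in, config$n_chains,
                            config$temp_ratio, config$prob_crossover,
                            config$adapt_temps)
  states <- res$cold_states
  keys <- apply(states, 1, function(r) paste(nm[r == 1], collapse = ","))
  lp_kept <- res$trace_logpost[(config$burn_in + 1):config$n_sweeps]
  agg <- tapply(seq_along(keys), keys, identity)
  models <- data.frame(
    model = names(agg),
    size = vapply(agg, function(i) sum(states[i[1], ]), 0L),
    count = vapply(agg, length, 0L),
    log_post = vapply(agg, function(i) lp_kept[i[1]], 0),
    row.names = NULL)
  models <- models[order(-models$count, models$model), ]
  structure(list(
    models = models,
    mppi_counts = setNames(colSums(states), nm),
    n_kept = nrow(states),
    trace = data.frame(sweep = seq_len(config$n_sweeps),
                       size = res$trace_size,
                       log_post = res$trace_logpost),
    predictors = nm,
    temperatures = res$temperatures,
    exchange_rate = res$exchange_rate,
    mutation_rate = res$mutation_rate,
    config = config, g = g, nu = nu),
    class = "visited_models")
}

#' @export
print.visited_models <- function(x, ...) {
  cat("Visited models:", nrow(x$models), "distinct over", x$n_kept,
      "post-burn-in sweeps\n")
  cat("  exchange acceptance:", round(x$exchange_rate, 3),
      " temperatures:", paste(signif(x$temperatures, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exact posterior over all models for small predictor panels
#'
#' Enumerates all `2^p` inclusion vectors (`p <= 15`) and normalizes the
#' marginal-likelihood-times-prior scores; used as the exact reference for
#' the stochastic sampler.
#'
#' @inheritParams run_guess
#' @param g,nu As in [log_marginal()].
#' @return A list: `models` (data frame with key, size, prob), `mppi` (named
#'   exact inclusion probabilities), `size_posterior`.
#' @export
enumerate_posterior <- function(Y, X, prior, g = nrow(as.matrix(Y)),
                                nu = nrow(as.matrix(Y)) - 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  p <- ncol(X)
  if (p > 15) stop("enumeration is limited to p <= 15")
  stopifnot(inherits(prior, "size_prior"), prior$p == p)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("X", seq_len(p))
  lp <- .guess_enumerate_cpp(crossprod(X), crossprod(X, Y), crossprod(Y),
                             nu, g, prior$log_model_prior, prior$T)
  prob <- exp(lp - logsumexp(lp))
  masks <- 0:(2^p - 1)
  bit <- function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0
  inmat <- vapply(seq_len(p), bit, logical(2^p))
  sizes <- rowSums(inmat)
  keys <- apply(inmat, 1, function(r) paste(nm[r], collapse = ","))
  mppi <- setNames(as.numeric(crossprod(inmat, prob)), nm)
  size_post <- tapply(prob, sizes, sum)
  list(models = data.frame(model = keys, size = sizes, prob = prob),
       mppi = mppi,
       size_posterior = size_post)
}
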