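#' Model posterior probabilities and best-models-visited ranking
#'
#' The MPP of a model is its visit frequency on the cold chain after
#' burn-in. Ties in the ranking are broken lexicographically on the model
#' key (the sorted, comma-separated predictor names) so reports are
#' deterministic.
#'
#' @param log A `visited_models` object from [run_guess()].
#' @return Data frame (model, size, count, mpp, cum_mpp) in descending MPP.
#' @export
compute_mpp <- function(log) {
  stopifnot(inherits(log, "visited_models"))
  if (nrow(log$models) == 0) stop("empty visited-model log")
  m <- log$models
  m$mpp <- m$count / log$n_kept
  m <- m[order(-m$mpp, m$model), ]
  m$cum_mpp <- cumsum(m$mpp)
  rownames(m) <- NULL
  keep <- intersect(c("model", "size", "count", "log_post", "mpp",
                      "cum_mpp"), names(m))
  m[, keep]
}

#' Marginal posterior probabilities of inclusion
#'
#' MPPI of a feature is the sum of the MPPs of the visited models containing
#' it — equivalently its cold-chain inclusion frequency after burn-in.
#'
#' @param log A `visited_models` object.
#' @return Named numeric vector over the predictor panel.
#' @export
compute_mppi <- function(log) {
  stopifnot(inherits(log, "visited_models"))
  if (log$n_kept == 0) stop("empty visited-model log")
  log$mppi_counts / log$n_kept
}

#' Rerun the sampler on permuted outcomes
#'
#' Generates the permutation null for the empirical-FDR threshold: the rows
#' of `Y` are permuted jointly across traits (preserving the trait
#' correlation under the null) while `X` stays fixed, and the sampler is
#' rerun per permutation.
#'
#' @inheritParams run_guess
#' @param n_perm Number of permutation runs.
#' @param seed Integer seed controlling both the permutations and the
#'   sampler reruns.
#' @return Matrix (n_perm x p) of null MPPIs.
#' @export
permutation_mppi <- function(Y, X, prior, config = sampler_config(),
                             n_perm = 20, seed = 1, nu = NULL) {
  Y <- as.matrix(Y)
  out <- matrix(NA_real_, n_perm, ncol(X))
  colnames(out) <- colnames(X)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    Yp <- Y[sample.int(nrow(Y)), , drop = FALSE]
    cfg <- config
    cfg$seed <- seed + 7919L * b + 1L
    out[b, ] <- compute_mppi(run_guess(Yp, X, prior, cfg, nu = nu))
  }
  out
}

#' MPPI threshold controlling the empirical FDR
#'
#' For a candidate threshold `t`, the estimated FDR is the expected number of
#' null (permutation-run) MPPIs at or above `t` — estimated with a
#' pseudocount of one exceedance, so a finite permutation set can never
#' certify a zero false-discovery rate — divided by the number of observed
#' MPPIs at or above `t`. The selected threshold `t*` is the smallest
#' observed MPPI whose estimated FDR is at or below `level`; when no
#' observed value qualifies the significant set is empty and `t*` is `Inf`
#' ("above the maximum observed MPPI").
#'
#' @param observed_mppi Named numeric vector of observed MPPIs.
#' @param perm_mppi Matrix of permutation-run MPPIs (runs x features), e.g.
#'   from [permutation_mppi()].
#' @param level Target FDR (default 0.05).
#' @return An `fdr_result` list: `threshold`, `significant` (feature names),
#'   `level`, `n_perm`, `fdr_at` (data frame of candidate thresholds and
#'   estimated FDR).
#' @export
empirical_fdr_threshold <- function(observed_mppi, perm_mppi, level = 0.05) {
  if (is.null(dim(perm_mppi))) perm_mppi <- matrix(perm_mppi, nrow = 1)
  if (nrow(perm_mppi) == 0) stop("at least one permutation run is required")
  cand <- sort(unique(observed_mppi))
  fdr_hat <- vapply(cand, function(t) {
    v_mean <- (1 + sum(perm_mppi >= t)) / nrow(perm_mppi)
    r <- sum(observed_mppi >= t)
    v_mean / max(1, r)
  }, 0)
  ok <- fdr_hat <= level
  tstar <- if (any(ok)) min(cand[ok]) else Inf
  sig <- if (is.finite(tstar)) names(observed_mppi)[observed_mppi >= tstar]
  else character(0)
  structure(list(threshold = tstar, significant = sig, level = level,
                 n_perm = nrow(perm_mppi),
                 fdr_at = data.frame(threshold = cand, fdr = fdr_hat)),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("Empirical FDR threshold at level", x$level, ":",
      if (is.finite(x$threshold)) signif(x$threshold, 4)
      else "above max observed MPPI", "\n")
  cat("  significant features:", length(x$significant), "\n")
  invisible(x)
}

#' Bayes factor of a feature from its MPPI
#'
#' The posterior odds of inclusion against the prior odds:
#' `BF = [mppi / (1 - mppi)] / [pi0 / (1 - pi0)]`, where `pi0` is the
#' marginal prior inclusion probability (for the moment-matched size prior,
#' `E / p`). MPPIs are capped at `1 - eps` so a feature retained in every
#' sweep yields a finite BF; the natural cap resolution is one post-burn-in
#' sweep, `eps = 1 / n_kept`.
#'
#' @param mppi MPPI value(s) in `[0, 1]`.
#' @param pi0 Prior inclusion probability in (0, 1).
#' @param eps Cap on `1 - mppi` (default `1e-6`).
#' @return Bayes factor(s).
#' @export
bayes_factor <- function(mppi, pi0, eps = 1e-6) {
  if (pi0 <= 0 || pi0 >= 1) stop("pi0 must lie strictly in (0, 1)")
  if (any(mppi < 0 | mppi > 1)) stop("mppi must lie in [0, 1]")
  m <- pmin(mppi, 1 - eps)
  (m / (1 - m)) / (pi0 / (1 - pi0))
}

#' Ratio of Bayes factors against the FDR-threshold feature
#'
#' `RBF = BF(mppi) / BF(t_star)`: the importance of a feature relative to
#' one sitting exactly at the empirical-FDR MPPI threshold. A feature at the
#' threshold has RBF exactly 1; features with RBF >= 1 are interpreted as
#' informative. With the sentinel threshold `Inf` (no feature reached the
#' FDR level) the reference is the maximum observed MPPI instead, and the
#' result carries attribute `reference = "max_observed"`.
#'
#' @param mppi MPPI value(s).
#' @param t_star Threshold MPPI (possibly `Inf`).
#' @param pi0 Prior inclusion probability.
#' @param eps Cap passed to [bayes_factor()].
#' @return RBF value(s).
#' @export
rbf <- function(mppi, t_star, pi0, eps = 1e-6) {
  flag <- NULL
  if (!is.finite(t_star)) {
    t_star <- max(mppi)
    flag <- "max_observed"
  }
  out <- bayes_factor(mppi, pi0, eps) / bayes_factor(t_star, pi0, eps)
  if (!is.null(flag)) attr(out, "reference") <- flag
  out
}

#' Per-feature MPPI / BF / RBF table
#'
#' @param mppi Named MPPI vector.
#' @param fdr An `fdr_result` (or a numeric threshold).
#' @param pi0 Prior inclusion probability.
#' @param eps Cap passed to [bayes_factor()].
#' @return Data frame (feature, mppi, bf, rbf, significant), sorted by
#'   descending MPPI.
#' @export
rbf_table <- function(mppi, fdr, pi0, eps = 1e-6) {
  tstar <- if (inherits(fdr, "fdr_result")) fdr$threshold else fdr
  out <- data.frame(feature = names(mppi), mppi = unname(mppi),
                    bf = unname(bayes_factor(mppi, pi0, eps)),
                    rbf = as.numeric(rbf(unname(mppi), tstar, pi0, eps)),
                    significant = unname(is.finite(tstar) & mppi >= tstar))
  out[order(-out$mppi, out$feature), ]
}

#' Posterior of the regression coefficients conditional on a model
#'
#' Simulates coefficient matrices for the included predictors of a
#' conditioning model (typically the top best model visited): per round,
#' `n_sigma` residual-covariance draws from the conjugate inverse-Wishart
#' posterior, and per covariance draw `n_beta` coefficient matrices from the
#' matching matrix-Gaussian posterior (the classical 2 x 2 inner structure,
#' repeated over rounds). A sign is called for a coefficient when its
#' 25th-75th percentile interval excludes zero.
#'
#' @param Y,X Residualized matrices.
#' @param gamma Conditioning model (binary vector or index vector).
#' @param n_rounds Rounds (default 500, i.e. 2000 draws per coefficient with
#'   the default 2 x 2 inner structure).
#' @param n_sigma,n_beta Inner draw counts (defaults 2 and 2).
#' @param g,nu As in [log_marginal()].
#' @param seed Integer seed.
#' @return An `effect_posterior` list: `draws` (array k x q x n_draws),
#'   `summary` (data frame: predictor, trait, mean, q2.5, q25, q50, q75,
#'   q97.5, sign).
#' @export
effect_posterior <- function(Y, X, gamma, n_rounds = 500, n_sigma = 2,
                             n_beta = 2, g = nrow(as.matrix(Y)),
                             nu = nrow(as.matrix(Y)) - 1, seed = 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  idx <- gamma_indices(gamma, ncol(X))
  if (length(idx) == 0) stop("the conditioning model is empty")
  Xg <- X[, idx, drop = FALSE]
  k <- length(idx); q <- ncol(Y)
  Gg <- crossprod(Xg)
  R <- tryCatch(chol(Gg), error = function(e)
    stop("singular design for the conditioning model"))
  s <- g / (1 + g)
  Bhat <- backsolve(R, forwardsolve(t(R), crossprod(Xg, Y)))
  M <- s * Bhat                                   # posterior mean
  rowcov <- s * chol2inv(R)                       # row covariance factor
  Q <- crossprod(Y) - s * crossprod(forwardsolve(t(R), crossprod(Xg, Y)))
  Q <- (Q + t(Q)) / 2
  set.seed(seed)
  n_draws <- n_rounds * n_sigma * n_beta
  draws <- array(NA_real_, c(k, q, n_draws))
  Rrow <- chol(rowcov)
  Qinv <- chol2inv(chol(Q))
  d <- 0
  for (r in seq_len(n_rounds)) {
    for (si in seq_len(n_sigma)) {
      W <- rWishart(1, df = nu, Sigma = Qinv)[, , 1]
      Sigma <- chol2inv(chol(W))
      Rs <- chol(Sigma)
      for (bi in seq_len(n_beta)) {
        d <- d + 1
        Z <- matrix(rnorm(k * q), k, q)
        draws[, , d] <- M + t(Rrow) %*% Z %*% Rs
      }
    }
  }
  nmx <- colnames(X)
  if (is.null(nmx)) nmx <- paste0("X", seq_len(ncol(X)))
  nmy <- colnames(Y)
  if (is.null(nmy)) nmy <- paste0("Y", seq_len(q))
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summ <- do.call(rbind, lapply(seq_len(k), function(i) {
    do.call(rbind, lapply(seq_len(q), function(j) {
      v <- draws[i, j, ]
      qq <- quantile(v, qs, names = FALSE)
      data.frame(predictor = nmx[idx[i]], trait = nmy[j], mean = mean(v),
                 q2.5 = qq[1], q25 = qq[2], q50 = qq[3], q75 = qq[4],
                 q97.5 = qq[5],
                 sign = if (qq[2] > 0) "positive"
                 else if (qq[4] < 0) "negative" else "none")
    }))
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, model = nmx[idx],
                 n_draws = n_draws),
            class = "effect_posterior")
}

#' Long-format MPPI attenuation table across adjustment sets
#'
#' @param runs Named list of MPPI vectors (one per covariate-adjustment
#'   ladder step), all over the same predictor panel.
#' @return Data frame (feature, run, mppi) with `n_features * n_runs` rows;
#'   `run` is an ordered factor following the list order.
#' @export
mppi_attenuation <- function(runs) {
  stopifnot(is.list(runs), length(runs) > 0)
  panel <- names(runs[[1]])
  for (r in runs)
    if (!identical(names(r), panel))
      stop("all runs must share the same predictor panel")
  labels <- names(runs)
  if (is.null(labels)) labels <- paste0("run", seq_along(runs))
  out <- do.call(rbind, lapply(seq_along(runs), function(i)
    data.frame(feature = panel, run = labels[i],
               mppi = unname(runs[[i]]))))
  out$run <- factor(out$run, levels = labels, ordered = TRUE)
  rownames(out) <- NULL
  out
}
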