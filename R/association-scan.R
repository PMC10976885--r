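#' Univariate trait-exposure regression scan
#'
#' One ordinary least-squares model per (trait, exposure) pair, adjusted for
#' the covariate block, reporting the exposure coefficient, standard error
#' and two-sided p-value, with a Bonferroni flag whose family is the set of
#' exposures scanned per trait.
#'
#' @param traits n x q numeric matrix (or data frame).
#' @param exposures n x p numeric matrix of log10-scale exposures.
#' @param covariates Data frame of adjustment covariates (may be `NULL`).
#' @param fwer Family-wise error rate for the Bonferroni flag (default 0.05).
#' @return A `scan_result` data frame (trait, exposure, estimate, se,
#'   p_value, significant) with `q * p` rows; attribute `m` is the
#'   Bonferroni divisor.
#' @export
univariate_scan <- function(traits, exposures, covariates = NULL,
                            fwer = 0.05) {
  traits <- as.matrix(traits)
  exposures <- as.matrix(exposures)
  stopifnot(nrow(traits) == nrow(exposures))
  C <- if (is.null(covariates)) matrix(1, nrow(traits), 1) else
    stats::model.matrix(~., data = as.data.frame(covariates))
  tn <- colnames(traits)
  if (is.null(tn)) tn <- paste0("trait", seq_len(ncol(traits)))
  en <- colnames(exposures)
  if (is.null(en)) en <- paste0("exposure", seq_len(ncol(exposures)))
  m <- ncol(exposures)
  rows <- vector("list", ncol(traits) * m)
  r <- 0
  for (i in seq_len(ncol(traits))) {
    for (j in seq_len(m)) {
      fit <- stats::lm.fit(cbind(C, exposures[, j]), traits[, i])
      cf <- fit$coefficients
      if (anyNA(cf))
        stop(sprintf("collinear design for pair (%s, %s)", tn[i], en[j]))
      df <- length(fit$residuals) - fit$rank
      sigma2 <- sum(fit$residuals^2) / df
      XtXinv <- chol2inv(chol(crossprod(cbind(C, exposures[, j]))))
      se <- sqrt(sigma2 * XtXinv[fit$rank, fit$rank])
      est <- cf[length(cf)]
      pv <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
      r <- r + 1
      rows[[r]] <- data.frame(trait = tn[i], exposure = en[j],
                              estimate = unname(est), se = se, p_value = pv)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- bonferroni_flag(out$p_value, fwer = fwer, m = m)
  attr(out, "m") <- m
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Bonferroni significance flags
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param fwer Family-wise error rate (default 0.05).
#' @param m Number of tests in the family (default 33).
#' @return Logical vector: `p < fwer / m`.
#' @export
bonferroni_flag <- function(p_values, fwer = 0.05, m = 33) {
  if (m < 1) stop("m must be at least 1")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p_values < fwer / m
}
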