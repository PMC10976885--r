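# shared fixtures and small oracles, all built in code at test time

# total-variation distance between two discrete distributions given as
# named probability vectors
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- p[keys]; pv[is.na(pv)] <- 0
  qv <- q[keys]; qv[is.na(qv)] <- 0
  0.5 * sum(abs(pv - qv))
}

# small residualized regression problem with a known sparse signal
make_toy_regression <- function(n = 50, p = 6, q = 2, seed = 42,
                                beta = 0.8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  B <- matrix(0, p, q)
  B[1, 1] <- beta
  B[2, ] <- beta * 0.6
  Y <- X %*% B + matrix(rnorm(n * q), n, q)
  rz <- residualize(Y, X)
  list(Y = rz$Y, X = rz$X, n = n, p = p, q = q, truth = c(1, 2))
}

# independent oracle for the g-prior log marginal: explicit thin-QR of the
# included columns, projector applied to Y directly (no precomputed
# cross-products)
oracle_log_marginal <- function(Y, X, idx, g, nu) {
  q <- ncol(Y)
  k <- length(idx)
  M <- crossprod(Y)
  if (k > 0) {
    Q <- qr.Q(qr(X[, idx, drop = FALSE]))
    QtY <- crossprod(Q, Y)
    M <- M - (g / (1 + g)) * crossprod(QtY)
  }
  -0.5 * q * k * log1p(g) - 0.5 * nu * determinant(M)$modulus[1]
}

# hand-built visited-model log for posthoc arithmetic tests
fake_visited <- function(models, counts, predictors) {
  sizes <- vapply(strsplit(models, ","),
                  function(x) length(x[nzchar(x)]), 0L)
  counts_by_feature <- vapply(predictors, function(f) {
    inmod <- vapply(strsplit(models, ","), function(x) f %in% x, TRUE)
    sum(counts[inmod])
  }, 0)
  structure(list(
    models = data.frame(model = models, size = sizes, count = counts,
                        log_post = seq_along(models)),
    mppi_counts = counts_by_feature,
    n_kept = sum(counts),
    predictors = predictors),
    class = "visited_models")
}
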