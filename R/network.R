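#' Configuration for stability-calibrated network estimation
#'
#' @param K Number of subsamples (default 100).
#' @param subsample_fraction Fraction of rows per subsample (default 0.5).
#' @param n_lambda Penalty-grid size; the grid is log-spaced between the
#'   smallest penalty giving an empty graph and 1% of it.
#' @param pi_grid Selection-proportion thresholds in (0.5, 1].
#' @param pfer_max Upper bound on the expected number of falsely selected
#'   edges (per-family error rate); conventional values are 10 for a small
#'   trait network and 20 for a larger exposure network.
#' @param seed Integer seed for the shared subsamples.
#' @return A `stability_config` list.
#' @export
stability_config <- function(K = 100, subsample_fraction = 0.5,
                             n_lambda = 20,
                             pi_grid = seq(0.55, 1.00, by = 0.01),
                             pfer_max = 10, seed = 1) {
  if (K < 2) stop("K must be at least 2")
  if (any(pi_grid <= 0.5 | pi_grid > 1))
    stop("pi_grid must lie in (0.5, 1]")
  structure(list(K = K, subsample_fraction = subsample_fraction,
                 n_lambda = n_lambda, pi_grid = pi_grid,
                 pfer_max = pfer_max, seed = seed),
            class = "stability_config")
}

# shared subsample index sets, drawn once per calibration
subsample_rows <- function(n, K, fraction, seed) {
  set.seed(seed)
  m <- max(2, floor(fraction * n))
  lapply(seq_len(K), function(i) sample.int(n, m))
}

# upper-triangle index helpers (edges enumerated column-major over i < j)
ut_pairs <- function(p) which(upper.tri(diag(p)), arr.ind = TRUE)

#' Edge selection proportions over subsampled graphical LASSO fits
#'
#' Fits an L1-penalised Gaussian graphical model on each of `K` subsamples of
#' `subsample_fraction` of the rows at penalty `lambda` and counts how often
#' each edge (nonzero off-diagonal precision entry) is selected.
#'
#' @param data Numeric matrix (standardized internally).
#' @param lambda Positive penalty.
#' @param config A [stability_config()].
#' @param subsamples Optional list of row-index vectors (to share subsamples
#'   across penalties); defaults to drawing them from `config$seed`.
#' @return A data frame (node1, node2, count, proportion) covering all
#'   candidate edges, with attribute `q` = mean number of selected edges per
#'   subsample.
#' @export
selection_proportions <- function(data, lambda, config = stability_config(),
                                  subsamples = NULL) {
  if (lambda <= 0) stop("lambda must be positive")
  data <- as.matrix(data)
  p <- ncol(data)
  n <- nrow(data)
  if (floor(config$subsample_fraction * n) < p + 1)
    warning("subsample size below p + 1; graphical LASSO fits may be unstable")
  if (is.null(subsamples))
    subsamples <- subsample_rows(n, config$K, config$subsample_fraction,
                                 config$seed)
  counts <- matrix(0L, p, p)
  qsum <- 0
  Rho <- matrix(lambda, p, p)
  for (rows in subsamples) {
    S <- cor(data[rows, , drop = FALSE])
    Theta <- .glasso_cpp(S, Rho)
    adj <- abs(Theta) > 1e-8
    diag(adj) <- FALSE
    counts <- counts + adj
    qsum <- qsum + sum(adj[upper.tri(adj)])
  }
  pr <- ut_pairs(p)
  nm <- colnames(data)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  out <- data.frame(node1 = nm[pr[, 1]], node2 = nm[pr[, 2]],
                    count = counts[pr],
                    proportion = counts[pr] / length(subsamples))
  attr(out, "q") <- qsum / length(subsamples)
  out
}

#' Stability score of an edge-selection-count configuration
#'
#' Edges are partitioned by their selection counts `u_e` out of `K` into
#' stably selected (`u_e >= ceiling(K pi)`), stably excluded
#' (`u_e <= floor(K (1 - pi))`) and unstable. Under the instability null all
#' edges share the same selection probability, estimated as the pooled mean
#' `mu = sum(u_e) / (K N)`, and counts are i.i.d. Binomial(K, mu). The score
#' is the negative log null-probability of the confidently classified edges
#' (the stably selected and stably excluded ones); unstable edges carry no
#' stability evidence and contribute nothing. Larger values indicate a more
#' stable (more separated) classification. A configuration with all counts
#' at K/2 scores 0; one with all proportions at 0 or 1 is maximal for a
#' given pooled mean.
#'
#' @param counts Integer vector of per-edge selection counts at one penalty.
#' @param pi Selection-proportion threshold in (0.5, 1].
#' @param K Number of subsamples.
#' @return The score (non-negative scalar).
#' @export
stability_score <- function(counts, pi, K) {
  if (pi <= 0.5 || pi > 1) stop("pi must lie in (0.5, 1]")
  stopifnot(all(counts >= 0), all(counts <= K))
  N <- length(counts)
  mu <- sum(counts) / (K * N)
  lo <- floor(K * (1 - pi))
  hi <- ceiling(K * pi)
  p_exc <- pbinom(lo, K, mu)
  p_sel <- pbinom(hi - 1, K, mu, lower.tail = FALSE)
  n_sel <- sum(counts >= hi)
  n_exc <- sum(counts <= lo)
  lp <- function(n, pr) if (n == 0) 0 else n * log(max(pr, 1e-300))
  -(lp(n_sel, p_sel) + lp(n_exc, p_exc))
}

#' Upper bound on the per-family error rate of stability selection
#'
#' The expected number of falsely selected edges at selection-proportion
#' threshold `pi`, given an average of `q` selected edges per subsample among
#' `N_edges` candidates, is bounded by `q^2 / ((2 pi - 1) N_edges)`.
#'
#' @param q Average number of selected edges per subsample.
#' @param pi Threshold in (0.5, 1].
#' @param N_edges Number of candidate edges.
#' @return Non-negative scalar bound.
#' @export
pfer_bound <- function(q, pi, N_edges) {
  if (any(pi <= 0.5)) stop("pi must exceed 0.5")
  q^2 / ((2 * pi - 1) * N_edges)
}

# penalty grid from the empty-graph penalty down to 1% of it
lambda_grid <- function(data, n_lambda) {
  S <- cor(as.matrix(data))
  lmax <- max(abs(S[upper.tri(S)]))
  exp(seq(log(lmax), log(0.01 * lmax), length.out = n_lambda))
}

#' Calibrate a conditional-independence network by stability
#'
#' Runs the graphical LASSO on `K` shared subsamples over a penalty grid and
#' selects the `(lambda, pi)` pair maximizing the stability score subject to
#' the PFER bound staying below `config$pfer_max`. With `blocks`, each
#' block-pair (within-block-1, within-block-2, between) is calibrated by its
#' own stability score over the shared subsample fits, with the PFER
#' allowance apportioned to block-pairs by their share of candidate edges so
#' the network-wide bound still holds.
#'
#' @param data Numeric matrix (columns = variables; standardized internally).
#' @param config A [stability_config()].
#' @param blocks Optional per-variable block labels (multiblock mode).
#' @return A `calibrated_network`: `edges` (node1, node2, proportion, stable,
#'   block_pair), `adjacency` (logical, stable edges), `lambda`, `pi`,
#'   `score`, `q`, `pfer` (total bound), `communities` (NULL until
#'   [detect_communities()] is applied), `per_pair` (multiblock detail).
#' @export
calibrate_network <- function(data, config = stability_config(),
                              blocks = NULL) {
  data <- scale(as.matrix(data))
  p <- ncol(data)
  nm <- colnames(data)
  if (is.null(nm)) nm <- colnames(data) <- paste0("V", seq_len(p))
  if (!is.null(blocks) && length(blocks) != p)
    stop("blocks must label every variable")
  lambdas <- lambda_grid(data, config$n_lambda)
  subs <- subsample_rows(nrow(data), config$K, config$subsample_fraction,
                         config$seed)
  prop_tables <- lapply(lambdas, function(l) {
    tab <- selection_proportions(data, l, config, subsamples = subs)
    attr(tab, "lambda") <- l
    tab
  })
  pr <- ut_pairs(p)
  if (is.null(blocks)) {
    pair_labels <- rep("all", nrow(pr))
  } else {
    b1 <- pmin(blocks[pr[, 1]], blocks[pr[, 2]])
    b2 <- pmax(blocks[pr[, 1]], blocks[pr[, 2]])
    pair_labels <- ifelse(b1 == b2, paste0("within:", b1),
                          paste0("between:", b1, ":", b2))
  }
  N_total <- nrow(pr)
  per_pair <- list()
  stable <- rep(FALSE, N_total)
  proportion <- rep(0, N_total)
  total_pfer <- 0
  any_feasible <- FALSE
  for (pl in unique(pair_labels)) {
    sel <- pair_labels == pl
    allow <- config$pfer_max * sum(sel) / N_total
    best <- list(score = -Inf, lambda = NA_real_, pi = NA_real_, q = NA_real_,
                 pfer = NA_real_, feasible = FALSE, lambda_index = NA_integer_)
    for (li in seq_along(prop_tables)) {
      counts <- prop_tables[[li]]$count[sel]
      qsub <- sum(counts) / config$K
      for (pi in config$pi_grid) {
        bound <- pfer_bound(qsub, pi, sum(sel))
        if (bound > allow) next
        # require more stable edges than the expected-false-edge bound:
        # a configuration whose discoveries could all be false carries no
        # stability evidence
        if (sum(counts / config$K >= pi) <= bound) next
        sc <- stability_score(counts, pi, config$K)
        if (sc > best$score)
          best <- list(score = sc, lambda = lambdas[li], pi = pi, q = qsub,
                       pfer = bound, feasible = TRUE, lambda_index = li)
      }
    }
    if (best$feasible) {
      any_feasible <- TRUE
      counts <- prop_tables[[best$lambda_index]]$count[sel]
      stable[sel] <- counts / config$K >= best$pi
      proportion[sel] <- counts / config$K
      total_pfer <- total_pfer + best$pfer
    } else {
      warning("no (lambda, pi) carries stability evidence within the PFER ",
              "constraint for block-pair ", pl,
              "; returning no stable edges there")
    }
    per_pair[[pl]] <- best
  }
  if (!any_feasible)
    warning("no (lambda, pi) satisfies the PFER constraint; ",
            "returning an empty network")
  edges <- data.frame(node1 = nm[pr[, 1]], node2 = nm[pr[, 2]],
                      proportion = proportion, stable = stable,
                      block_pair = pair_labels)
  adj <- matrix(FALSE, p, p, dimnames = list(nm, nm))
  for (i in which(stable)) {
    adj[pr[i, 1], pr[i, 2]] <- TRUE
    adj[pr[i, 2], pr[i, 1]] <- TRUE
  }
  single <- is.null(blocks)
  structure(list(
    edges = edges, adjacency = adj,
    lambda = if (single) per_pair[["all"]]$lambda else
      vapply(per_pair, `[[`, 0, "lambda"),
    pi = if (single) per_pair[["all"]]$pi else
      vapply(per_pair, `[[`, 0, "pi"),
    score = if (single) per_pair[["all"]]$score else
      vapply(per_pair, `[[`, 0, "score"),
    q = if (single) per_pair[["all"]]$q else
      vapply(per_pair, `[[`, 0, "q"),
    pfer = total_pfer, pfer_max = config$pfer_max,
    per_pair = per_pair, communities = NULL,
    config = config),
    class = "calibrated_network")
}

#' @export
print.calibrated_network <- function(x, ...) {
  cat("Stability-calibrated network:", nrow(x$adjacency), "nodes,",
      sum(x$edges$stable), "stable edges\n")
  cat("  PFER bound:", signif(x$pfer, 3), "(max", x$pfer_max, ")\n")
  if (length(x$lambda) == 1)
    cat("  lambda* =", signif(x$lambda, 3), " pi* =", x$pi, "\n")
  invisible(x)
}

#' Louvain community detection on a calibrated network
#'
#' Communities of the stable-edge graph under the Louvain modularity
#' algorithm with unit edge weights. Isolated nodes form singleton
#' communities.
#'
#' @param network A `calibrated_network`, or a logical/0-1 adjacency matrix.
#' @param seed Integer seed (Louvain visits nodes in random order).
#' @return A list `membership` (named integer vector) and `modularity`; when
#'   called on a `calibrated_network` the network is returned with its
#'   `communities` field filled and the per-edge community of attached nodes.
#' @export
detect_communities <- function(network, seed = 1) {
  adj <- if (inherits(network, "calibrated_network")) network$adjacency
  else as.matrix(network)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  set.seed(seed)
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- rownames(adj)
    mod <- 0
  } else {
    cl <- igraph::cluster_louvain(g, resolution = 1)
    memb <- igraph::membership(cl)
    names(memb) <- rownames(adj)
    mod <- igraph::modularity(g, memb)
  }
  res <- list(membership = memb, modularity = mod)
  if (inherits(network, "calibrated_network")) {
    network$communities <- res
    return(network)
  }
  res
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param network A `calibrated_network` (optionally with communities).
#' @param path_tsv,path_graphml Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, path_tsv = NULL, path_graphml = NULL) {
  stopifnot(inherits(network, "calibrated_network"))
  ed <- network$edges
  if (!is.null(network$communities)) {
    memb <- network$communities$membership
    ed$community <- ifelse(
      ed$stable & memb[ed$node1] == memb[ed$node2],
      memb[ed$node1], NA)
  }
  if (!is.null(path_tsv))
    write.table(ed, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_adjacency_matrix(network$adjacency,
                                             mode = "undirected")
    if (!is.null(network$communities))
      igraph::V(g)$community <- as.integer(network$communities$membership)
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(c(path_tsv, path_graphml))
}
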