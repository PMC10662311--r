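#' Construct one exemplar-centered local domain
#'
#' A local domain collects a single positive sample (the exemplar) together
#' with its `k1` nearest positive neighbors and `k2` nearest negative
#' neighbors, by Euclidean distance in feature space. Local domains are the
#' subdomains on which the co-learned local classifiers are trained; each
#' carries the data block of its members and the normalized graph Laplacian
#' of a k-nearest-neighbor similarity graph over them.
#'
#' Ties in distance are broken towards the lower sample index, so
#' construction is fully deterministic. When fewer than `k1` positive (or
#' `k2` negative) candidates exist, all available candidates are used and a
#' warning reports the shortfall.
#'
#' @param X Numeric matrix, `d x n`, columns are samples.
#' @param y Numeric vector of labels in `{+1, -1}`, length `n`.
#' @param v Index of the exemplar sample; `y[v]` must be `+1`.
#' @param k1,k2 Number of positive / negative neighbors requested.
#' @param k_graph Neighbor count for the within-domain similarity graph
#'   (capped at one less than the domain size).
#' @param bandwidth Graph kernel bandwidth: `"median"` (median of nonzero
#'   pairwise squared distances in the block) or a fixed positive number.
#' @return An object of class `local_domain`: a list with elements
#'   `exemplar`, `pos`, `neg`, `indices` (exemplar first), `labels`,
#'   `X_block` (`d x k`), `S` (graph weights) and `laplacian` (`k x k`).
#' @seealso [build_all_local_domains()], [graph_weight_matrix()],
#'   [normalized_laplacian()]
#' @export
find_local_domain <- function(X, y, v, k1, k2, k_graph = 5L,
                              bandwidth = "median") {
  stopifnot_matrix(X, "X")
  n <- ncol(X)
  if (length(y) != n) abort("`y` must have one label per column of `X`.",
                            class = "localdg_shape_error")
  if (v < 1 || v > n) abort("`v` out of range.", class = "localdg_invalid_exemplar")
  if (y[v] != 1) {
    abort("The exemplar sample must carry label +1.",
          class = "localdg_invalid_exemplar")
  }
  pos_cand <- setdiff(which(y == 1), v)
  neg_cand <- which(y == -1)
  if (length(neg_cand) == 0) {
    abort("Need at least one negative sample.",
          class = "localdg_degenerate_labels")
  }
  d2 <- colSums((X - X[, v])^2)
  pick <- function(cand, k, what) {
    if (length(cand) < k) {
      warn(sprintf(
        "Local domain at sample %d: only %d %s neighbor(s) available (%d requested).",
        v, length(cand), what, k), class = "localdg_neighbor_shortfall")
      k <- length(cand)
    }
    cand[order(d2[cand], cand)][seq_len(k)]
  }
  pos <- pick(pos_cand, k1, "positive")
  neg <- pick(neg_cand, k2, "negative")
  idx <- c(v, pos, neg)
  k <- length(idx)
  Xb <- X[, idx, drop = FALSE]
  kg <- min(k_graph, k - 1L)
  S <- graph_weight_matrix(Xb, kg, bandwidth)
  L <- normalized_laplacian(S)
  structure(
    list(exemplar = v, pos = pos, neg = neg, indices = idx,
         labels = c(1, rep(1, length(pos)), rep(-1, length(neg))),
         X_block = Xb, S = S, laplacian = L),
    class = "local_domain")
}

#' Build all local domains of a labeled source
#'
#' One local domain is built per positive sample, ordered by exemplar index,
#' so a source with `p` positives yields `m = p` subdomains.
#'
#' @inheritParams find_local_domain
#' @return List of [find_local_domain()] results, one per positive sample.
#' @export
build_all_local_domains <- function(X, y, k1, k2, k_graph = 5L,
                                    bandwidth = "median") {
  pos <- which(y == 1)
  if (length(pos) == 0) {
    abort("No positive samples: cannot build local domains.",
          class = "localdg_degenerate_labels")
  }
  lapply(pos, function(v) find_local_domain(X, y, v, k1, k2, k_graph, bandwidth))
}

#' Gaussian k-nearest-neighbor graph weights of a data block
#'
#' Entry (i, j) is `exp(-||x_i - x_j||^2 / sigma)` when `x_i` is among the
#' `k_graph` nearest neighbors of `x_j` *or* vice versa, and 0 otherwise;
#' the diagonal is 0 (no self-loops). The bandwidth `sigma` defaults to the
#' median of the nonzero pairwise squared distances within the block
#' (median heuristic), with fallback 1 when all points coincide.
#'
#' @param X_block Numeric matrix `d x k`, columns are the domain members.
#' @param k_graph Number of nearest neighbors per node; must be `< k`.
#' @param bandwidth `"median"` or a fixed positive number.
#' @return Symmetric nonnegative `k x k` matrix with zero diagonal.
#' @export
graph_weight_matrix <- function(X_block, k_graph, bandwidth = "median") {
  stopifnot_matrix(X_block, "X_block")
  k <- ncol(X_block)
  if (k < 2) abort("Need at least two samples for a graph.",
                   class = "localdg_invalid_parameter")
  if (k_graph >= k) {
    abort("`k_graph` must be smaller than the number of samples in the block.",
          class = "localdg_invalid_parameter")
  }
  if (k_graph < 1) abort("`k_graph` must be at least 1.",
                         class = "localdg_invalid_parameter")
  D2 <- pairwise_sqdist(X_block)
  if (identical(bandwidth, "median")) {
    nz <- D2[upper.tri(D2)]
    nz <- nz[nz > 0]
    sigma <- if (length(nz) > 0) median(nz) else 1
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0) {
      abort("`bandwidth` must be \"median\" or a positive number.",
            class = "localdg_invalid_parameter")
    }
    sigma <- bandwidth
  }
  # either-neighbor adjacency, ties towards the lower index
  adj <- matrix(FALSE, k, k)
  for (j in seq_len(k)) {
    others <- setdiff(seq_len(k), j)
    nb <- others[order(D2[others, j], others)][seq_len(k_graph)]
    adj[nb, j] <- TRUE
  }
  adj <- adj | t(adj)
  S <- ifelse(adj, exp(-D2 / sigma), 0)
  diag(S) <- 0
  (S + t(S)) / 2
}

#' Symmetric normalized graph Laplacian
#'
#' Computes `L = E^{-1/2} (E - S) E^{-1/2}` where `E` is the diagonal degree
#' matrix of the weight matrix `S`. Eigenvalues lie in `[0, 2]`. Isolated
#' nodes (zero degree) get an all-zero row and column (the convention
#' `0^{-1/2} = 0`).
#'
#' @param S Symmetric nonnegative weight matrix.
#' @return Symmetric `k x k` Laplacian matrix.
#' @export
normalized_laplacian <- function(S) {
  stopifnot_matrix(S, "S")
  if (any(S < 0)) abort("Graph weights must be nonnegative.",
                        class = "localdg_invalid_graph")
  deg <- rowSums(S)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -S * tcrossprod(inv_sqrt)
  diag(L) <- ifelse(deg > 0, 1, 0) + diag(L)
  (L + t(L)) / 2
}

#' @export
print.local_domain <- function(x, ...) {
  cat(sprintf(
    "<local_domain> exemplar %d: %d positive + %d negative neighbors (k = %d)\n",
    x$exemplar, length(x$pos), length(x$neg), length(x$indices)))
  invisible(x)
}
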