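#' Fused local-classifier scores
#'
#' In the domain-generalization (DG) setting no target data is seen, and
#' the local classifiers are fused by their squared importance weights:
#' `score(x) = sum_v theta_v^2 (x'w_v + b_v)`. In the local
#' domain-adaptation (LDA) setting an unlabeled target block is available
#' and the fusion weights `zeta` come from [lda_weights()] instead:
#' `score(x) = sum_v zeta_v (x'w_v + b_v)`.
#'
#' For kernel-mode models the samples are first passed through the
#' empirical kernel map against the stored training reference block.
#'
#' @param X Samples to score, `d x q` matrix (a single vector is treated
#'   as one column).
#' @param bm A fitted [fit_ldg_binary()] model.
#' @param zeta Simplex weight vector of length `m` (LDA fusion).
#' @return Numeric vector of `q` real-valued scores.
#' @export
predict_dg_score <- function(X, bm) {
  X <- as_columns(X, bm$d_input)
  Xs <- solver_space(bm, X)
  S <- crossprod(Xs, bm$W)                       # q x m
  drop(sweep(S, 2, bm$b_local, "+") %*% (bm$theta^2))
}

#' @rdname predict_dg_score
#' @export
predict_lda_score <- function(X, bm, zeta) {
  if (length(zeta) != ncol(bm$W)) {
    abort("`zeta` must have one weight per local domain.",
          class = "localdg_shape_error")
  }
  X <- as_columns(X, bm$d_input)
  Xs <- solver_space(bm, X)
  S <- crossprod(Xs, bm$W)
  drop(sweep(S, 2, bm$b_local, "+") %*% zeta)
}

as_columns <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (nrow(X) != d) {
    abort(sprintf("Samples must have %d features (got %d).", d, nrow(X)),
          class = "localdg_shape_error")
  }
  X
}

#' Kernel maximum mean discrepancy between two sample blocks
#'
#' The biased kernel estimator of the MMD between the empirical
#' distributions of the two blocks:
#' `sqrt(max(0, mean(K_vv) - 2 mean(K_vt) + mean(K_tt)))`. By default a
#' Gaussian kernel is used with the bandwidth set by the median heuristic
#' over the pooled pairwise squared distances of both blocks.
#'
#' @param X_v,X_t Sample blocks (`d x k`, `d x K`), columns are samples.
#' @param spec A [kernel_spec()], or `NULL` for the median-heuristic
#'   Gaussian.
#' @return Nonnegative scalar distance.
#' @export
mmd_distance <- function(X_v, X_t, spec = NULL) {
  stopifnot_matrix(X_v, "X_v"); stopifnot_matrix(X_t, "X_t")
  if (nrow(X_v) != nrow(X_t)) {
    abort("Blocks must share the feature dimension.",
          class = "localdg_shape_error")
  }
  if (is.null(spec)) {
    pooled <- cbind(X_v, X_t)
    D2 <- pairwise_sqdist(pooled)
    nz <- D2[upper.tri(D2)]
    nz <- nz[nz > 0]
    sigma <- if (length(nz) > 0) 1 / median(nz) else 1
    spec <- kernel_spec("gaussian", bandwidth = sigma)
  }
  kvv <- mean(kernel_matrix(X_v, X_v, spec))
  kvt <- mean(kernel_matrix(X_v, X_t, spec))
  ktt <- mean(kernel_matrix(X_t, X_t, spec))
  sqrt(max(0, kvv - 2 * kvt + ktt))
}

#' Target-similarity fusion weights
#'
#' Converts per-domain MMD distances to the target into simplex fusion
#' weights, `zeta_v = exp(-Psi_v) / sum_u exp(-Psi_u)` (computed with
#' max-subtraction): local domains distributed like the target get the
#' largest weights.
#'
#' @param psi Vector of nonnegative per-domain distances.
#' @return Simplex vector of the same length.
#' @export
lda_weights <- function(psi) {
  if (any(!is.finite(psi))) {
    abort("Distances must be finite.", class = "localdg_invalid_parameter")
  }
  softmin_weights(psi, 1)
}

# per-domain MMDs of a binary model against a target block; domain blocks
# are kept in the original feature space, so no kernel mapping here
binary_model_psi <- function(bm, X_target) {
  vapply(bm$domains, function(dm) {
    mmd_distance(dm$X_block, X_target)
  }, numeric(1))
}
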