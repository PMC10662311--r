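#' Solver hyperparameters
#'
#' Collects the tuning constants of the local-domain solver.
#'
#' @param alpha Ridge penalty on each local model `w_v` (> 0).
#' @param beta Weight of the trace-norm coupling on the local-model matrix
#'   `W` and of the ridge on the global model (> 0).
#' @param mu Entropy temperature of the subdomain weights `lambda` (> 0).
#' @param r Exponent on the classifier-importance weights `theta`
#'   (default 2, matching the squared weights used at fusion time).
#' @param k1,k2 Positive / negative neighborhood sizes of a local domain.
#' @param k_graph Neighbor count of the within-domain similarity graph.
#' @param kernel A [kernel_spec()], or a list of them for a stacked
#'   multiple-kernel representation. The linear family keeps the solver in
#'   the raw feature space.
#' @param graph_bandwidth Bandwidth rule for the domain graphs
#'   (`"median"` or a fixed number).
#' @param tol Relative-objective stopping tolerance of the inner loop,
#'   in (0, 1).
#' @param max_iter Inner-iteration cap per local domain.
#' @param jitter Ridge added to near-singular linear systems.
#' @param sweeps Maximum number of passes over the local domains; after each
#'   full pass the loop stops early once the overall objective is stable.
#' @param init `"deterministic"` (zero models, pseudo-labels set to the
#'   labels, uniform weights) or `"random"` (small random models, seeded).
#' @param seed Integer seed used only by `init = "random"`.
#' @return An object of class `ldg_control`.
#' @export
ldg_control <- function(alpha = 1, beta = 1, mu = 1, r = 2,
                        k1 = 5L, k2 = 5L, k_graph = 5L,
                        kernel = kernel_spec("linear"),
                        graph_bandwidth = "median",
                        tol = 1e-4, max_iter = 100L, jitter = 1e-6,
                        sweeps = 1L, init = c("deterministic", "random"),
                        seed = 1L) {
  init <- match.arg(init)
  if (alpha <= 0 || beta <= 0 || mu <= 0) {
    abort("`alpha`, `beta` and `mu` must be positive.",
          class = "localdg_invalid_parameter")
  }
  if (tol <= 0 || tol >= 1) abort("`tol` must lie in (0, 1).",
                                  class = "localdg_invalid_parameter")
  if (max_iter < 1) abort("`max_iter` must be at least 1.",
                          class = "localdg_invalid_parameter")
  if (r < 1) abort("`r` must be at least 1.",
                   class = "localdg_invalid_parameter")
  if (inherits(kernel, "kernel_spec")) kernel <- list(kernel)
  if (!all(vapply(kernel, inherits, logical(1), "kernel_spec"))) {
    abort("`kernel` must be a kernel_spec or a list of them.",
          class = "localdg_invalid_parameter")
  }
  structure(
    list(alpha = alpha, beta = beta, mu = mu, r = r,
         k1 = as.integer(k1), k2 = as.integer(k2),
         k_graph = as.integer(k_graph), kernel = kernel,
         graph_bandwidth = graph_bandwidth, tol = tol,
         max_iter = as.integer(max_iter), jitter = jitter,
         sweeps = as.integer(sweeps), init = init, seed = as.integer(seed)),
    class = "ldg_control")
}

#' @export
print.ldg_control <- function(x, ...) {
  fams <- paste(vapply(x$kernel, `[[`, character(1), "family"), collapse = "+")
  cat(sprintf(
    paste0("<ldg_control> alpha=%g beta=%g mu=%g r=%g | k1=%d k2=%d k_graph=%d",
           " | kernel=%s | tol=%g max_iter=%d sweeps=%d\n"),
    x$alpha, x$beta, x$mu, x$r, x$k1, x$k2, x$k_graph, fams,
    x$tol, x$max_iter, x$sweeps))
  invisible(x)
}

#' Centering matrix
#'
#' `H_k = I_k - (1/k) 11'`, the projector removing the mean of a
#' `k`-vector. Symmetric and idempotent; annihilates constants.
#'
#' @param k Size (positive integer).
#' @return `k x k` matrix.
#' @export
centering_matrix <- function(k) {
  if (k < 1) abort("`k` must be positive.", class = "localdg_invalid_parameter")
  diag(k) - matrix(1 / k, k, k)
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# solve with escalating ridge; used where composite systems may be singular
solve_jitter <- function(A, b, jitter = 1e-6, max_jitter = 1e-2,
                         label = "linear system") {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  j <- jitter
  while (is.null(out) && j <= max_jitter) {
    warn(sprintf("%s near-singular; adding ridge %g.", label, j),
         class = "localdg_jitter")
    out <- tryCatch(solve(A + diag(j, nrow(A)), b), error = function(e) NULL)
    j <- j * 10
  }
  if (is.null(out)) {
    abort(sprintf("%s is singular even after ridge escalation.", label),
          class = "localdg_singular_system")
  }
  out
}

trace_norm <- function(W) sum(svd(W, nu = 0, nv = 0)$d)

#' Full objective of the local-domain solver
#'
#' Evaluates the complete objective for a solver state: the
#' importance-weighted local regression losses, the local ridge penalties,
#' the alignment of each local model with the global model, the
#' lambda-weighted graph-Laplacian smoothness of the global model, the
#' global regression loss, the pseudo-label fidelity `||f - y||^2`, the
#' trace-norm plus global ridge penalty, and the entropy of the subdomain
#' weights (with the convention `0 log 0 = 0`).
#'
#' @param state List with elements `W` (`d x m`), `w_tilde`, `b_local`
#'   (length `m`), `b_global`, `f_global` (length `n`), `f_local` (list of
#'   per-domain pseudo-label vectors), `theta`, `lambda`.
#' @param data List with elements `X` (`d x n` solver-space data), `y`
#'   (labels, +/-1), `blocks` (list of `d x k_v` solver-space domain
#'   blocks) and `laplacians` (list of `k_v x k_v` matrices).
#' @param hyper An [ldg_control()].
#' @return Scalar objective value.
#' @export
compute_objective <- function(state, data, hyper) {
  m <- length(data$blocks)
  if (ncol(state$W) != m || length(state$theta) != m ||
      length(state$lambda) != m || length(state$f_local) != m) {
    abort("State and data disagree on the number of local domains.",
          class = "localdg_shape_error")
  }
  if (length(state$f_global) != ncol(data$X)) {
    abort("`f_global` must have one entry per sample.",
          class = "localdg_shape_error")
  }
  wt <- state$w_tilde
  loss_local <- 0; ridge_local <- 0; align <- 0; lap <- 0
  for (u in seq_len(m)) {
    Xb <- data$blocks[[u]]
    r_u <- drop(crossprod(Xb, state$W[, u])) + state$b_local[u] -
      state$f_local[[u]]
    loss_local <- loss_local + state$theta[u]^hyper$r * sum(r_u^2)
    ridge_local <- ridge_local + sum(state$W[, u]^2)
    align <- align + sum((drop(crossprod(Xb, state$W[, u] - wt)))^2)
    pv <- drop(crossprod(Xb, wt))
    lap <- lap + state$lambda[u] *
      drop(crossprod(pv, data$laplacians[[u]] %*% pv))
  }
  fit_global <- sum((drop(crossprod(data$X, wt)) + state$b_global -
                       state$f_global)^2)
  fid <- sum((state$f_global - data$y)^2)
  lam <- state$lambda
  ent <- sum(ifelse(lam > 0, lam * log(lam), 0))
  loss_local + hyper$alpha * ridge_local + align + lap + fit_global + fid +
    hyper$beta * (trace_norm(state$W) + sum(wt^2)) + hyper$mu * ent
}

#' Closed-form bias updates
#'
#' The local bias absorbs the mean residual of its domain:
#' `b_v = (1/k) (1'f_v - 1'X_v'w_v)`; the global bias is the analogous mean
#' over all samples.
#'
#' @param w_v,w_tilde Model vectors.
#' @param X_v,X Data blocks (`d x k`, `d x n`), columns are samples.
#' @param f_v,f Pseudo-label vectors.
#' @return Scalar bias.
#' @export
update_local_bias <- function(w_v, X_v, f_v) {
  (sum(f_v) - sum(crossprod(X_v, w_v))) / ncol(X_v)
}

#' @rdname update_local_bias
#' @export
update_global_bias <- function(w_tilde, X, f) {
  (sum(f) - sum(crossprod(X, w_tilde))) / ncol(X)
}

#' Trace-norm majorization matrix
#'
#' `V = (W W' + jitter I)^{-1/2}`, computed by symmetric
#' eigendecomposition. Re-weighting the quadratic penalty
#' `tr(W' V W)` with this matrix majorizes the trace norm of `W`;
#' the jitter keeps the inverse square root defined when `W` is rank
#' deficient.
#'
#' @param W Local-model matrix, `d x m`.
#' @param jitter Nonnegative ridge inside the inverse square root.
#' @return Symmetric positive-definite `d x d` matrix.
#' @export
update_majorizer <- function(W, jitter = 1e-6) {
  G <- tcrossprod(W)
  diag(G) <- diag(G) + jitter
  e <- eigen(G, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  V <- e$vectors %*% (t(e$vectors) / sqrt(vals))
  (V + t(V)) / 2
}

#' System matrices of the per-domain closed-form updates
#'
#' `q_matrix` builds `Q_v = theta_v^r X_v H_k X_v' + X_v X_v' + beta V +
#' alpha I`; `a_matrix` builds `A_v = X H_n X' - X_v X_v' Q_v^{-1} X_v X_v'
#' + X_v X_v' + beta I + lambda_v X_v L_v X_v'`; `b_matrix` builds the
#' (singular) system of the local pseudo-label update, which annihilates
#' constants because each term is flanked by the centering matrix.
#'
#' @param X Solver-space data, `d x n`.
#' @param X_v Solver-space block of domain `v`, `d x k`.
#' @param L_v Normalized Laplacian of domain `v`.
#' @param theta_v,lambda_v Current weights of domain `v`.
#' @param V Majorization matrix from [update_majorizer()].
#' @param Q_v,A_v Previously built system matrices.
#' @param hyper An [ldg_control()].
#' @return Symmetric matrix of the stated dimension.
#' @export
q_matrix <- function(X_v, theta_v, V, hyper) {
  d <- nrow(X_v)
  Xbc <- X_v - rowMeans(X_v)
  Q <- theta_v^hyper$r * tcrossprod(Xbc) + tcrossprod(X_v) +
    hyper$beta * V + diag(hyper$alpha, d)
  if (rcond(Q) < 1e-12) {
    warn("Q_v ill-conditioned; adding jitter.", class = "localdg_jitter")
    Q <- Q + diag(hyper$jitter, d)
  }
  Q
}

#' @rdname q_matrix
#' @export
a_matrix <- function(X, X_v, Q_v, lambda_v, L_v, hyper) {
  d <- nrow(X)
  Gn <- X - rowMeans(X)
  XXv <- tcrossprod(X_v)
  tcrossprod(Gn) - XXv %*% solve(Q_v, XXv) + XXv + diag(hyper$beta, d) +
    lambda_v * (X_v %*% L_v %*% t(X_v))
}

#' @rdname q_matrix
#' @export
b_matrix <- function(X_v, Q_v, A_v, theta_v, hyper) {
  k <- ncol(X_v)
  th <- theta_v^hyper$r
  Xbc <- X_v - rowMeans(X_v)
  XXv <- tcrossprod(X_v)
  QiXbc <- solve(Q_v, Xbc)
  AiXXv <- solve_jitter(A_v, XXv, hyper$jitter, label = "A_v")
  B <- th * centering_matrix(k) -
    th^2 * t(QiXbc) %*% (XXv %*% AiXXv) %*% QiXbc -
    th^2 * crossprod(Xbc, QiXbc)
  (B + t(B)) / 2
}

#' Closed-form local model update
#'
#' `w_v = Q_v^{-1} (theta_v^r X_v H_k f_v + X_v X_v' w_tilde)`, the
#' stationary point of the objective in `w_v` with the trace norm majorized
#' by `tr(W' V W)`.
#'
#' @inheritParams q_matrix
#' @param f_v Local pseudo-label vector.
#' @param w_tilde Global model vector.
#' @return Updated `w_v`.
#' @export
update_local_model <- function(X_v, f_v, w_tilde, theta_v, V, hyper) {
  Q <- q_matrix(X_v, theta_v, V, hyper)
  Xbc <- X_v - rowMeans(X_v)
  rhs <- theta_v^hyper$r * (Xbc %*% (f_v - mean(f_v))) +
    tcrossprod(X_v) %*% w_tilde
  drop(solve(Q, rhs))
}

#' Closed-form global model update
#'
#' `w_tilde = A_v^{-1} (X H_n f + theta_v^r X_v X_v' Q_v^{-1} X_v H_k f_v)`,
#' where `A_v` carries the alignment, ridge and graph-Laplacian terms of
#' the active domain.
#'
#' @inheritParams q_matrix
#' @param f Global pseudo-label vector.
#' @param f_v Local pseudo-label vector of domain `v`.
#' @return Updated `w_tilde`.
#' @export
update_global_model <- function(X, f, X_v, f_v, Q_v, theta_v, lambda_v, L_v,
                                hyper) {
  A <- a_matrix(X, X_v, Q_v, lambda_v, L_v, hyper)
  Gn <- X - rowMeans(X)
  Xbc <- X_v - rowMeans(X_v)
  rhs <- Gn %*% (f - mean(f)) + theta_v^hyper$r *
    (tcrossprod(X_v) %*% solve(Q_v, Xbc %*% (f_v - mean(f_v))))
  drop(solve_jitter(A, rhs, hyper$jitter, label = "A_v"))
}

#' Closed-form local pseudo-label update
#'
#' Solves the (centered-subspace) system `B_v f_v = theta_v^r H_k X_v'
#' Q_v^{-1} X_v X_v' A_v^{-1} X H_n f` with the Moore-Penrose
#' pseudo-inverse of `B_v`; the constant component of `f_v` is annihilated
#' by construction and is absorbed by the local bias.
#'
#' @inheritParams update_global_model
#' @param A_v System matrix from [a_matrix()].
#' @return Updated `f_v` (mean-zero).
#' @export
update_pseudo_local <- function(X, X_v, f, Q_v, A_v, theta_v, hyper) {
  B <- b_matrix(X_v, Q_v, A_v, theta_v, hyper)
  k <- ncol(X_v)
  sv <- svd(B, nu = 0, nv = 0)$d
  tol <- k * .Machine$double.eps * max(sv)
  if (sum(sv > tol) < k - 1) {
    warn("B_v rank deficiency beyond its constant null space.",
         class = "localdg_rank_warning")
  }
  Gn <- X - rowMeans(X)
  Xbc <- X_v - rowMeans(X_v)
  rhs <- theta_v^hyper$r *
    crossprod(Xbc, solve(Q_v, tcrossprod(X_v) %*%
                           solve_jitter(A_v, Gn %*% (f - mean(f)),
                                        hyper$jitter, label = "A_v")))
  drop(pinv(B) %*% rhs)
}

#' Closed-form global pseudo-label update
#'
#' Assembles the printed `n x n` system matrix
#' `M = I - theta_v^r H_n X' A_v^{-1} X_v X_v' Q_v^{-1} X_v H_k B_v^+
#' theta_v^r H_k X_v' Q_v^{-1} X_v X_v' A_v^{-1} X H_n - H_n X' A_v^{-1} X
#' H_n + H_n` and solves `M f = y`.
#'
#' @inheritParams update_pseudo_local
#' @param y Label vector (+/-1).
#' @param B_v System matrix from [b_matrix()].
#' @return Updated global pseudo-label vector `f`.
#' @export
update_pseudo_global <- function(X, X_v, y, Q_v, A_v, B_v, theta_v, hyper) {
  n <- ncol(X)
  th <- theta_v^hyper$r
  Gn <- X - rowMeans(X)
  Xbc <- X_v - rowMeans(X_v)
  XXv <- tcrossprod(X_v)
  AiG <- solve_jitter(A_v, Gn, hyper$jitter, label = "A_v")
  QiXbc <- solve(Q_v, Xbc)
  Z <- th * t(QiXbc) %*% XXv %*% AiG        # k x n
  M <- diag(n) + centering_matrix(n) - t(Z) %*% pinv(B_v) %*% Z -
    crossprod(Gn, AiG)
  drop(solve_jitter(M, y, hyper$jitter, label = "pseudo-label system"))
}

#' Simplex weight updates
#'
#' `update_theta` recomputes the classifier-importance weights from the
#' local regression residuals, `theta_v` proportional to the inverse
#' residual (with a small floor for exactly-fit domains);
#' `update_lambda` recomputes the subdomain weights as a softmin of the
#' graph-smoothness traces of the global model at temperature `mu`,
#' evaluated with max-subtraction for overflow safety. Both return simplex
#' vectors.
#'
#' @param residuals Nonnegative vector of per-domain squared residuals.
#' @return Simplex vector of length `m`.
#' @export
update_theta <- function(residuals, eps = 1e-12) {
  w <- 1 / (residuals + eps)
  w / sum(w)
}

#' @rdname update_theta
#' @param w_tilde Global model vector.
#' @param domains List of solver-space blocks paired with Laplacians: each
#'   element a list with `X_block` and `laplacian` (a list of
#'   `local_domain` objects works directly).
#' @param mu Entropy temperature.
#' @param eps Floor added to residuals before inversion.
#' @export
update_lambda <- function(w_tilde, domains, mu) {
  traces <- vapply(domains, function(d) {
    pv <- drop(crossprod(d$X_block, w_tilde))
    drop(crossprod(pv, d$laplacian %*% pv))
  }, numeric(1))
  softmin_weights(traces, mu)
}

softmin_weights <- function(values, temperature = 1) {
  z <- -values / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
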