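#' Fit the binary local-domain solver
#'
#' Partitions the positive class into exemplar-centered local domains,
#' then alternates the closed-form block updates (subdomain weights
#' `lambda`, importance weights `theta`, the global and local pseudo-labels
#' `f` and `f_v`, the global model `w_tilde`, the local model `w_v`, the
#' biases, and the trace-norm majorizer `V`) for each local domain in turn
#' until the relative change of the objective over the last two iterates
#' falls below `hyper$tol` or `hyper$max_iter` is reached. The global
#' blocks (`W`, `V`, `f`, `w_tilde`, `b`) are shared, not reset, across
#' the domain loop.
#'
#' For nonlinear kernels the data are first passed through the empirical
#' kernel map against the training block, which becomes the stored
#' reference for prediction-time mapping.
#'
#' @param X Numeric matrix `d x n`, columns are samples.
#' @param y Labels in `{+1, -1}`, both classes present.
#' @param hyper An [ldg_control()].
#' @return Object of class `ldg_binary`: local domains, the fitted blocks
#'   (`W`, `b_local`, `theta`, `lambda`, `w_tilde`, `b_global`,
#'   pseudo-labels), per-domain objective traces (`objective_trace`, the
#'   quantity the inner loop minimizes, and `full_objective_trace`, the
#'   complete objective), per-domain iteration counts, and the kernel
#'   reference block when a nonlinear kernel is used.
#' @export
fit_ldg_binary <- function(X, y, hyper = ldg_control()) {
  stopifnot_matrix(X, "X")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) {
    abort("`y` must be coded +1 / -1.", class = "localdg_invalid_parameter")
  }
  if (length(unique(y)) < 2) {
    abort("Both classes must be present.", class = "localdg_degenerate_labels")
  }

  # local domains are found in the original feature space
  domains <- build_all_local_domains(X, y, hyper$k1, hyper$k2,
                                     hyper$k_graph, hyper$graph_bandwidth)
  m <- length(domains)

  # solver-space representation (empirical kernel map for nonlinear kernels)
  linear <- length(hyper$kernel) == 1 && hyper$kernel[[1]]$family == "linear"
  if (linear) {
    Xs <- X
    ref <- NULL
  } else {
    Xs <- mkl_concatenate(lapply(hyper$kernel, function(s)
      empirical_kernel_map(X, X, s)))
    ref <- X
  }
  d <- nrow(Xs)
  n <- ncol(Xs)

  blocks <- lapply(domains, function(dm) Xs[, dm$indices, drop = FALSE])
  laplacians <- lapply(domains, `[[`, "laplacian")

  # per-domain constants
  pre <- lapply(seq_len(m), function(u) {
    Xb <- blocks[[u]]
    Xbc <- Xb - rowMeans(Xb)
    list(Xb = Xb, tXb = t(Xb), Xbc = Xbc,
         XXv = tcrossprod(Xb), XHXv = tcrossprod(Xbc),
         XLXv = Xb %*% laplacians[[u]] %*% t(Xb))
  })
  Gn <- Xs - rowMeans(Xs)
  XHXt <- tcrossprod(Gn)

  # initialization
  if (hyper$init == "random") {
    withr::with_seed(hyper$seed, {
      W <- matrix(rnorm(d * m, sd = 0.01), d, m)
      w_tilde <- rnorm(d, sd = 0.01)
    })
  } else {
    W <- matrix(0, d, m)
    w_tilde <- numeric(d)
  }
  b_local <- numeric(m)
  b_global <- 0
  f <- y
  f_local <- lapply(domains, function(dm) y[dm$indices])
  theta <- rep(1 / m, m)
  lambda <- rep(1 / m, m)
  # start from the exact majorizer of the initial W (a scaled identity for
  # the zero init), so the first solve is a proper descent step too
  V <- update_majorizer(W, hyper$jitter)

  res_all <- vapply(seq_len(m), function(u) {
    sum((drop(pre[[u]]$tXb %*% W[, u]) + b_local[u] - f_local[[u]])^2)
  }, numeric(1))
  trace_fn <- function(wt) {
    vapply(seq_len(m), function(u) {
      pv <- drop(crossprod(blocks[[u]], wt))
      drop(crossprod(pv, laplacians[[u]] %*% pv))
    }, numeric(1))
  }
  align_term <- function(u, wt) {
    sum((drop(pre[[u]]$tXb %*% (W[, u] - wt)))^2)
  }

  # objective pieces shared by the descent surrogate and the full objective
  common_terms <- function() {
    loss <- sum(theta^hyper$r * res_all) + hyper$alpha * sum(W^2)
    fitg <- sum((drop(crossprod(Xs, w_tilde)) + b_global - f)^2)
    fid <- sum((f - y)^2)
    ent <- hyper$mu * sum(ifelse(lambda > 0, lambda * log(lambda), 0))
    loss + fitg + fid + hyper$beta * sum(w_tilde^2) + ent
  }
  # Lyapunov function of the inner loop: the smoothed trace norm enters at
  # twice the printed coefficient because the closed-form updates carry the
  # full (not halved) majorizer gradient; coupling terms restricted to the
  # active domain, matching the per-domain system matrices.
  smoothed_tn <- function(W) {
    sum(sqrt(svd(W, nu = 0, nv = 0)$d^2 + hyper$jitter))
  }
  surrogate_obj <- function(v, t_all) {
    common_terms() + align_term(v, w_tilde) + lambda[v] * t_all[v] +
      2 * hyper$beta * smoothed_tn(W)
  }
  full_obj <- function(t_all) {
    al <- sum(vapply(seq_len(m), align_term, numeric(1), wt = w_tilde))
    common_terms() + al + sum(lambda * t_all) + hyper$beta * trace_norm(W)
  }

  eps_floor <- .Machine$double.eps
  max_simplex_dev <- 0
  objective_trace <- vector("list", m)
  full_objective_trace <- vector("list", m)
  iterations <- integer(m)
  converged <- logical(m)
  use_fast_f <- (d + 1 + hyper$k1 + hyper$k2) < n

  prev_sweep_obj <- Inf
  for (sweep in seq_len(hyper$sweeps)) {
    for (v in seq_len(m)) {
      k <- length(domains[[v]]$indices)
      Hk <- centering_matrix(k)
      p <- pre[[v]]
      t_all <- trace_fn(w_tilde)
      sur <- numeric(0)
      ful <- numeric(0)
      it <- 0L
      repeat {
        it <- it + 1L
        # simplex weights
        lambda <- softmin_weights(t_all, hyper$mu)
        theta <- update_theta(res_all)
        max_simplex_dev <- max(max_simplex_dev,
                               abs(sum(lambda) - 1), abs(sum(theta) - 1))
        th <- theta[v]^hyper$r
        sur <- c(sur, surrogate_obj(v, t_all))
        ful <- c(ful, full_obj(t_all))

        # system matrices of the active domain; the theta^r factor of the
        # singular B_v system is kept outside the pseudo-inverse so its
        # conditioning does not degrade when theta_v is small
        Q <- th * p$XHXv + p$XXv + hyper$beta * V + diag(hyper$alpha, d)
        QiXXv <- solve(Q, p$XXv)
        QiXbc <- solve(Q, p$Xbc)
        A <- XHXt - p$XXv %*% QiXXv + p$XXv + diag(hyper$beta, d) +
          lambda[v] * p$XLXv
        AiG <- solve_jitter(A, Gn, hyper$jitter, label = "A_v")
        AiXXv <- solve_jitter(A, p$XXv, hyper$jitter, label = "A_v")
        Bt <- Hk - th * t(QiXbc) %*% (p$XXv %*% AiXXv) %*% QiXbc -
          th * crossprod(p$Xbc, QiXbc)          # B_v / theta^r
        Bt <- (Bt + t(Bt)) / 2
        Btp <- pinv(Bt)
        Zt <- t(QiXbc) %*% (p$XXv %*% AiG)       # k x n, Z / theta^r

        # global pseudo-labels:
        # M f = y, M = I + H_n - th Zt'Bt+ Zt - Gn'A^{-1}Gn
        f_new <- if (use_fast_f) {
          Dfun <- function(z) {
            if (is.matrix(z)) z / 2 + rep(colMeans(z), each = nrow(z)) / 2
            else z / 2 + mean(z) / 2
          }
          U <- cbind(t(Gn), t(Zt))                # n x (d+k)
          DU <- Dfun(U)
          core <- diag(d + k) -
            rbind(solve_jitter(A, Gn %*% DU, hyper$jitter, label = "A_v"),
                  th * (Btp %*% (Zt %*% DU)))
          Dy <- Dfun(y)
          cwdy <- rbind(solve_jitter(A, Gn %*% Dy, hyper$jitter, label = "A_v"),
                        th * (Btp %*% (Zt %*% Dy)))
          drop(Dy + DU %*% solve_jitter(core, cwdy, hyper$jitter,
                                        label = "pseudo-label core"))
        } else {
          M <- diag(n) + centering_matrix(n) - th * t(Zt) %*% Btp %*% Zt -
            crossprod(Gn, AiG)
          drop(solve_jitter(M, y, hyper$jitter, label = "pseudo-label system"))
        }
        f <- f_new

        # local pseudo-labels, global and local models, biases
        fv <- drop(Btp %*% (Zt %*% f))
        f_local[[v]] <- fv
        w_tilde <- drop(solve_jitter(
          A, Gn %*% f + th * (p$XXv %*% (QiXbc %*% fv)),
          hyper$jitter, label = "A_v"))
        w_v <- drop(solve(Q, th * (p$Xbc %*% fv) + p$XXv %*% w_tilde))
        W[, v] <- w_v
        b_local[v] <- (sum(fv) - sum(p$tXb %*% w_v)) / k
        b_global <- (sum(f) - sum(crossprod(Xs, w_tilde))) / n
        V <- update_majorizer(W, hyper$jitter)

        res_all[v] <- sum((drop(p$tXb %*% w_v) + b_local[v] - fv)^2)
        t_all <- trace_fn(w_tilde)
        s_end <- surrogate_obj(v, t_all)

        # relative stopping rule on the last two iterates; the scale is the
        # larger of the current and loop-entry objective magnitudes, so the
        # rule stays meaningful when the entropy term drives the converged
        # objective towards (or below) zero
        last2 <- c(tail(sur, 1), s_end)
        rel <- abs(max(last2) - min(last2)) /
          max(abs(last2), abs(sur[1]), eps_floor)
        if (rel < hyper$tol) {
          converged[v] <- TRUE
          sur <- c(sur, s_end)
          ful <- c(ful, full_obj(t_all))
          break
        }
        if (it >= hyper$max_iter) {
          sur <- c(sur, s_end)
          ful <- c(ful, full_obj(t_all))
          break
        }
      }
      iterations[v] <- iterations[v] + it
      objective_trace[[v]] <- c(objective_trace[[v]], sur)
      full_objective_trace[[v]] <- c(full_objective_trace[[v]], ful)
    }
    sweep_obj <- full_obj(trace_fn(w_tilde))
    if (abs(prev_sweep_obj - sweep_obj) /
        max(abs(sweep_obj), eps_floor) < hyper$tol) break
    prev_sweep_obj <- sweep_obj
  }

  if (!all(converged)) {
    warn(sprintf("%d of %d local domains hit max_iter before the stopping rule.",
                 sum(!converged), m), class = "localdg_nonconvergence")
  }

  structure(
    list(domains = domains, W = W, b_local = b_local, theta = theta,
         lambda = lambda, w_tilde = w_tilde, b_global = b_global,
         f_global = f, f_local = f_local,
         objective_trace = objective_trace,
         full_objective_trace = full_objective_trace,
         iterations = iterations, converged = converged,
         simplex_deviation = max_simplex_dev,
         kernel = hyper$kernel, reference = ref, d_input = nrow(X)),
    class = "ldg_binary")
}

#' @export
print.ldg_binary <- function(x, ...) {
  cat(sprintf(
    "<ldg_binary> %d local domains | median %g inner iterations | %s\n",
    length(x$domains), median(x$iterations),
    if (all(x$converged)) "all converged" else
      sprintf("%d not converged", sum(!x$converged))))
  invisible(x)
}

# map new samples into solver space (identity for the linear branch)
solver_space <- function(bm, Xnew) {
  if (is.null(bm$reference)) return(Xnew)
  mkl_concatenate(lapply(bm$kernel, function(s)
    empirical_kernel_map(bm$reference, Xnew, s)))
}
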