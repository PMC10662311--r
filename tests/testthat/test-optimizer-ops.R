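test_that("centering matrix removes means and is idempotent", {
  expect_equal(drop(centering_matrix(2) %*% c(1, 1)), c(0, 0))
  expect_equal(drop(centering_matrix(3) %*% c(1, 2, 3)), c(-1, 0, 1))
  H5 <- centering_matrix(5)
  expect_equal(H5 %*% H5, H5)
  expect_error(centering_matrix(0), class = "localdg_invalid_parameter")
})

test_that("objective at the zero-model state collapses to ||y||^2 - mu log m", {
  inst <- make_binary_instance(3, d = 3, n = 12)
  hyper <- small_control(mu = 0.7)
  doms <- build_all_local_domains(inst$X, inst$y, hyper$k1, hyper$k2,
                                  hyper$k_graph)
  m <- length(doms)
  data <- list(X = inst$X, y = inst$y,
               blocks = lapply(doms, `[[`, "X_block"),
               laplacians = lapply(doms, `[[`, "laplacian"))
  state <- list(W = matrix(0, 3, m), w_tilde = numeric(3),
                b_local = numeric(m), b_global = 0, f_global = inst$y,
                f_local = lapply(doms, function(d) numeric(length(d$indices))),
                theta = rep(1 / m, m), lambda = rep(1 / m, m))
  expect_equal(compute_objective(state, data, hyper),
               sum(inst$y^2) - 0.7 * log(m))
})

test_that("objective is permutation-invariant and matches a term-wise oracle", {
  inst <- make_binary_instance(11, d = 3, n = 8)
  hyper <- small_control(alpha = 0.5, beta = 2, mu = 1.3)
  doms <- build_all_local_domains(inst$X, inst$y, hyper$k1, hyper$k2,
                                  hyper$k_graph)
  m <- length(doms)
  st <- withr::with_seed(5, list(
    W = matrix(rnorm(3 * m), 3, m), w_tilde = rnorm(3),
    b_local = rnorm(m), b_global = rnorm(1), f_global = rnorm(8),
    f_local = lapply(doms, function(d) rnorm(length(d$indices))),
    theta = {
      u <- runif(m); u / sum(u)
    },
    lambda = {
      u <- runif(m); u / sum(u)
    }))
  data <- list(X = inst$X, y = inst$y,
               blocks = lapply(doms, `[[`, "X_block"),
               laplacians = lapply(doms, `[[`, "laplacian"))
  val <- compute_objective(st, data, hyper)

  # independent term-by-term recomputation, including SVD trace norm
  oracle <- 0
  for (u in seq_len(m)) {
    Xb <- data$blocks[[u]]; k <- ncol(Xb)
    res <- t(Xb) %*% st$W[, u] + st$b_local[u] * rep(1, k) - st$f_local[[u]]
    oracle <- oracle + st$theta[u]^hyper$r * sum(res^2) +
      hyper$alpha * sum(st$W[, u]^2) +
      sum((t(Xb) %*% (st$W[, u] - st$w_tilde))^2) +
      st$lambda[u] * drop(t(st$w_tilde) %*% Xb %*% data$laplacians[[u]] %*%
                            t(Xb) %*% st$w_tilde) +
      hyper$mu * st$lambda[u] * log(st$lambda[u])
  }
  oracle <- oracle +
    sum((t(inst$X) %*% st$w_tilde + st$b_global - st$f_global)^2) +
    sum((st$f_global - inst$y)^2) +
    hyper$beta * (sum(svd(st$W)$d) + sum(st$w_tilde^2))
  expect_equal(val, oracle)

  # permuting domains together with their weights leaves the value unchanged
  perm <- rev(seq_len(m))
  st_p <- st
  st_p$W <- st$W[, perm]; st_p$b_local <- st$b_local[perm]
  st_p$f_local <- st$f_local[perm]
  st_p$theta <- st$theta[perm]; st_p$lambda <- st$lambda[perm]
  data_p <- data
  data_p$blocks <- data$blocks[perm]; data_p$laplacians <- data$laplacians[perm]
  expect_equal(compute_objective(st_p, data_p, hyper), val)
})

test_that("bias updates absorb the mean residual (grid-search oracle)", {
  Xv <- matrix(rnorm(3 * 5), 3)
  # constant pseudo-labels with a zero model give the constant back
  expect_equal(update_local_bias(numeric(3), Xv, rep(2.5, 5)), 2.5)
  expect_equal(update_global_bias(numeric(3), Xv, rep(-1, 5)), -1)
  # centered data and mean-zero pseudo-labels give zero
  Xc <- Xv - rowMeans(Xv)
  fz <- rnorm(5); fz <- fz - mean(fz)
  w <- rnorm(3)
  expect_equal(update_local_bias(w, Xc, fz), 0)
  # random instance: matches the scalar minimizer of the residual term
  f <- rnorm(5)
  b_hat <- update_local_bias(w, Xv, f)
  b_opt <- optimize(function(b) sum((drop(crossprod(Xv, w)) + b - f)^2),
                    c(-50, 50), tol = 1e-10)$minimum
  expect_equal(b_hat, b_opt, tolerance = 1e-6)
})

test_that("the majorizer is the inverse matrix square root of WW'", {
  expect_equal(update_majorizer(diag(3), jitter = 0), diag(3))
  # orthogonal columns with known norms: eigenvalues (s^2 + jitter)^(-1/2)
  s <- c(2, 0.5)
  W <- cbind(c(s[1], 0, 0), c(0, s[2], 0))
  V <- update_majorizer(W, jitter = 1e-4)
  ev <- sort(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, sort(c((s^2 + 1e-4)^(-1 / 2), 1e-4^(-1 / 2))))
  # symmetric PD for random W
  Wr <- matrix(rnorm(12), 3)
  Vr <- update_majorizer(Wr)
  expect_equal(Vr, t(Vr))
  expect_gt(min(eigen(Vr, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("theta follows inverse residuals and stays on the simplex", {
  expect_equal(update_theta(rep(3, 4)), rep(0.25, 4))
  expect_equal(update_theta(c(1, 2)), c(2 / 3, 1 / 3), tolerance = 1e-9)
  r <- runif(7)
  th <- update_theta(r)
  expect_equal(sum(th), 1)
  expect_equal(update_theta(rev(r)), rev(th))
})

test_that("lambda is a softmin of the smoothness traces", {
  # identical traces: uniform
  Xb <- matrix(rnorm(6), 3, 2)
  L <- normalized_laplacian(matrix(c(0, 1, 1, 0), 2))
  doms <- list(list(X_block = Xb, laplacian = L),
               list(X_block = Xb, laplacian = L))
  lam <- update_lambda(rnorm(3), doms, mu = 1)
  expect_equal(lam, c(0.5, 0.5))
  # traces (0, mu): weights (1/(1+e^-1), e^-1/(1+e^-1))
  expect_equal(localdg:::softmin_weights(c(0, 2), 2),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  # huge temperature: entropy dominates, uniform limit
  expect_equal(localdg:::softmin_weights(c(0, 5, 9), 1e9), rep(1 / 3, 3),
               tolerance = 1e-6)
  expect_equal(sum(localdg:::softmin_weights(runif(5), 0.3)), 1)
})

test_that("closed-form model updates are stationary points (finite differences)", {
  inst <- make_binary_instance(21, d = 3, n = 8)
  hyper <- small_control(alpha = 0.8, beta = 1.2, mu = 1, jitter = 0)
  doms <- build_all_local_domains(inst$X, inst$y, hyper$k1, hyper$k2,
                                  hyper$k_graph)
  dm <- doms[[2]]
  Xv <- dm$X_block; Lv <- dm$laplacian
  theta_v <- 0.3; lambda_v <- 0.4
  V <- update_majorizer(withr::with_seed(1, matrix(rnorm(3 * 4, sd = 0.5), 3)),
                        1e-6)
  f <- withr::with_seed(2, rnorm(8))
  fv <- withr::with_seed(3, rnorm(ncol(Xv)))
  w_tilde <- withr::with_seed(4, rnorm(3))

  # local model: gradient of the w_v-dependent terms (trace norm majorized,
  # bias eliminated through the centering matrix)
  wv <- update_local_model(Xv, fv, w_tilde, theta_v, V, hyper)
  Jw <- function(w) {
    r <- drop(crossprod(Xv, w)) - fv
    theta_v^hyper$r * sum((r - mean(r))^2) + hyper$alpha * sum(w^2) +
      sum((drop(crossprod(Xv, w - w_tilde)))^2) +
      hyper$beta * drop(t(w) %*% V %*% w)
  }
  expect_lt(sqrt(sum(num_grad(Jw, wv)^2)), 1e-6)

  # global model: gradient with the local model profiled out (envelope form)
  Q <- q_matrix(Xv, theta_v, V, hyper)
  wt <- update_global_model(inst$X, f, Xv, fv, Q, theta_v, lambda_v, Lv, hyper)
  Jt <- function(wt_try) {
    w <- update_local_model(Xv, fv, wt_try, theta_v, V, hyper)
    r <- drop(crossprod(Xv, w)) - fv
    g <- drop(crossprod(inst$X, wt_try)) - f
    theta_v^hyper$r * sum((r - mean(r))^2) + hyper$alpha * sum(w^2) +
      sum((drop(crossprod(Xv, w - wt_try)))^2) +
      lambda_v * drop(t(wt_try) %*% (Xv %*% Lv %*% t(Xv)) %*% wt_try) +
      sum((g - mean(g))^2) + hyper$beta * (drop(t(w) %*% V %*% w) +
                                             sum(wt_try^2))
  }
  expect_lt(sqrt(sum(num_grad(Jt, wt)^2)), 1e-6)
})

test_that("pseudo-label updates are stationary on their subspaces", {
  inst <- make_binary_instance(31, d = 3, n = 8)
  hyper <- small_control(alpha = 0.8, beta = 1.2, mu = 1, jitter = 0)
  doms <- build_all_local_domains(inst$X, inst$y, hyper$k1, hyper$k2,
                                  hyper$k_graph)
  dm <- doms[[1]]
  Xv <- dm$X_block; Lv <- dm$laplacian; k <- ncol(Xv)
  theta_v <- 0.35; lambda_v <- 0.25
  V <- update_majorizer(withr::with_seed(6, matrix(rnorm(3 * 4, sd = 0.5), 3)),
                        1e-6)
  Q <- q_matrix(Xv, theta_v, V, hyper)
  A <- a_matrix(inst$X, Xv, Q, lambda_v, Lv, hyper)
  B <- b_matrix(Xv, Q, A, theta_v, hyper)

  # B annihilates constants: the null space the bias absorbs
  expect_lt(max(abs(B %*% rep(1, k))), 1e-10)

  # f = 0 propagates to f_v = 0
  expect_equal(update_pseudo_local(inst$X, Xv, numeric(8), Q, A, theta_v,
                                   hyper),
               numeric(k))

  # local pseudo-labels: projected finite-difference stationarity with the
  # models profiled out
  f <- withr::with_seed(7, rnorm(8))
  fv <- update_pseudo_local(inst$X, Xv, f, Q, A, theta_v, hyper)
  Jfv <- function(fv_try) {
    wt <- update_global_model(inst$X, f, Xv, fv_try, Q, theta_v, lambda_v,
                              Lv, hyper)
    w <- update_local_model(Xv, fv_try, wt, theta_v, V, hyper)
    bv <- update_local_bias(w, Xv, fv_try)
    b <- update_global_bias(wt, inst$X, f)
    theta_v^hyper$r * sum((drop(crossprod(Xv, w)) + bv - fv_try)^2) +
      hyper$alpha * sum(w^2) +
      sum((drop(crossprod(Xv, w - wt)))^2) +
      lambda_v * drop(t(wt) %*% (Xv %*% Lv %*% t(Xv)) %*% wt) +
      sum((drop(crossprod(inst$X, wt)) + b - f)^2) +
      hyper$beta * (drop(t(w) %*% V %*% w) + sum(wt^2))
  }
  g <- num_grad(Jfv, fv)
  g_centered <- g - mean(g)          # constants live in the bias
  expect_lt(sqrt(sum(g_centered^2)), 1e-6)

  # global pseudo-labels: full profiled stationarity
  f_hat <- update_pseudo_global(inst$X, Xv, inst$y, Q, A, B, theta_v, hyper)
  Jf <- function(f_try) profiled_objective_f(f_try, inst$X, Xv, Lv, inst$y,
                                             theta_v, lambda_v, V, hyper)
  expect_lt(sqrt(sum(num_grad(Jf, f_hat)^2)), 1e-6)
})

test_that("degenerate closed forms of the global pseudo-label system hold", {
  hyper <- small_control(jitter = 0)
  # n = 1: the centering matrix vanishes and f = y
  X1 <- matrix(1.5, 2, 1); Xv1 <- matrix(0.5, 2, 1)
  V <- diag(2)
  Q <- q_matrix(Xv1, 0.5, V, hyper)
  A <- a_matrix(X1, Xv1, Q, 0.5, matrix(0, 1, 1), hyper)
  B <- b_matrix(Xv1, Q, A, 0.5, hyper)
  expect_equal(update_pseudo_global(X1, Xv1, 3, Q, A, B, 0.5, hyper), 3)

  # all-zero features: M = I + H_n, so mean-zero y gives f = y/2
  n <- 6
  X0 <- matrix(0, 3, n); Xv0 <- matrix(0, 3, 4)
  y <- c(1, -1, 1, -1, 1, -1)
  L0 <- matrix(0, 4, 4)
  Q0 <- q_matrix(Xv0, 0.5, diag(3), hyper)
  A0 <- a_matrix(X0, Xv0, Q0, 0.5, L0, hyper)
  B0 <- b_matrix(Xv0, Q0, A0, 0.5, hyper)
  expect_equal(update_pseudo_global(X0, Xv0, y, Q0, A0, B0, 0.5, hyper),
               y / 2)
  # general y: Sherman-Morrison gives y/2 + mean(y)/2
  y2 <- c(2, 1, 0, 1, 2, 0)
  expect_equal(update_pseudo_global(X0, Xv0, y2, Q0, A0, B0, 0.5, hyper),
               y2 / 2 + mean(y2) / 2)
})

test_that("ridge domination shrinks the corresponding model to zero", {
  inst <- make_binary_instance(41, d = 3, n = 10)
  doms <- build_all_local_domains(inst$X, inst$y, 2, 2, 2)
  dm <- doms[[1]]; Xv <- dm$X_block; Lv <- dm$laplacian
  V <- diag(3)
  fv <- rnorm(ncol(Xv)); f <- rnorm(10); wt <- rnorm(3)

  # f_v = 0, w_tilde = 0 -> w_v = 0 exactly
  expect_equal(update_local_model(Xv, numeric(ncol(Xv)), numeric(3), 0.5, V,
                                  small_control()),
               numeric(3))
  # alpha -> large: ||w_v|| -> 0
  w_big_alpha <- update_local_model(Xv, fv, wt, 0.5, V,
                                    small_control(alpha = 1e8))
  expect_lt(sqrt(sum(w_big_alpha^2)), 1e-5)

  # f = 0, f_v = 0 -> w_tilde = 0; beta -> large: ||w_tilde|| -> 0
  hyper <- small_control()
  Q <- q_matrix(Xv, 0.5, V, hyper)
  expect_equal(update_global_model(inst$X, numeric(10), Xv,
                                   numeric(ncol(Xv)), Q, 0.5, 0.5, Lv, hyper),
               numeric(3))
  hyper_b <- small_control(beta = 1e8)
  Qb <- q_matrix(Xv, 0.5, V, hyper_b)
  wt_big <- update_global_model(inst$X, f, Xv, fv, Qb, 0.5, 0.5, Lv, hyper_b)
  expect_lt(sqrt(sum(wt_big^2)), 1e-5)
})

test_that("matrix square-root majorization inequality holds on random PD pairs", {
  worst <- Inf
  for (seed in 1:100) {
    pair <- withr::with_seed(seed, list(M = rand_pd(4), Vt = rand_pd(4)))
    lhs <- 0.5 * sum(diag(pair$M %*% mat_isqrt(pair$Vt))) -
      sum(diag(mat_sqrt(pair$M)))
    rhs <- 0.5 * sum(diag(pair$Vt %*% mat_isqrt(pair$Vt))) -
      sum(diag(mat_sqrt(pair$Vt)))
    worst <- min(worst, lhs - rhs)
  }
  expect_gt(worst, -1e-8)
})
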