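#' Kernel specification
#'
#' Describes the kernel used by the empirical kernel map, the solver's
#' nonlinear branch and the MMD distance. Families:
#' \describe{
#'   \item{linear}{`K(x, z) = x'z`; the empirical map is the identity.}
#'   \item{gaussian}{`K(x, z) = exp(-sigma ||x - z||^2)` (the default).}
#'   \item{inv_square_distance}{`K(x, z) = 1 / (1 + sigma ||x - z||^2)`.}
#'   \item{laplacian}{`K(x, z) = exp(-sigma ||x - z||)`.}
#'   \item{inv_distance}{`K(x, z) = 1 / (1 + sigma ||x - z||)`.}
#' }
#' `bandwidth = "auto"` resolves `sigma` to `1/d` at evaluation time, `d`
#' being the feature dimension.
#'
#' @param family Kernel family name (see above).
#' @param bandwidth Positive number, or `"auto"` for `sigma = 1/d`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "linear", "inv_square_distance",
                                   "laplacian", "inv_distance"),
                        bandwidth = "auto") {
  family <- match.arg(family)
  if (!identical(bandwidth, "auto")) {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
      abort("`bandwidth` must be \"auto\" or a positive number.",
            class = "localdg_invalid_parameter")
    }
  }
  structure(list(family = family, bandwidth = bandwidth), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  bw <- if (identical(x$bandwidth, "auto")) "auto (1/d)" else format(x$bandwidth)
  cat(sprintf("<kernel_spec> %s kernel, bandwidth %s\n", x$family, bw))
  invisible(x)
}

resolve_bandwidth <- function(spec, d) {
  if (identical(spec$bandwidth, "auto")) 1 / d else spec$bandwidth
}

#' Kernel Gram matrix between two sample blocks
#'
#' @param A,B Numeric matrices with samples as columns, sharing the feature
#'   dimension.
#' @param spec A [kernel_spec()].
#' @return `ncol(A) x ncol(B)` matrix of kernel evaluations.
#' @export
kernel_matrix <- function(A, B, spec = kernel_spec()) {
  stopifnot_matrix(A, "A"); stopifnot_matrix(B, "B")
  if (nrow(A) != nrow(B)) {
    abort("`A` and `B` must share the feature dimension.",
          class = "localdg_shape_error")
  }
  if (spec$family == "linear") return(crossprod(A, B))
  sigma <- resolve_bandwidth(spec, nrow(A))
  D2 <- pairwise_sqdist(A, B)
  switch(spec$family,
    gaussian            = exp(-sigma * D2),
    inv_square_distance = 1 / (1 + sigma * D2),
    laplacian           = exp(-sigma * sqrt(D2)),
    inv_distance        = 1 / (1 + sigma * sqrt(D2)))
}

#' Empirical kernel map
#'
#' Represents query samples by their kernel evaluations against a reference
#' block: column `j` of the result is
#' `(K(x_1, q_j), ..., K(x_n, q_j))` for reference samples `x_i`. For the
#' linear family the map is the identity and `X_query` is returned
#' unchanged.
#'
#' @param X_train Reference block, `d x n`.
#' @param X_query Query block, `d x q`.
#' @param spec A [kernel_spec()].
#' @return `n x q` representation (or `X_query` for the linear family).
#' @export
empirical_kernel_map <- function(X_train, X_query, spec = kernel_spec()) {
  if (spec$family == "linear") {
    stopifnot_matrix(X_query, "X_query")
    return(X_query)
  }
  kernel_matrix(X_train, X_query, spec)
}

#' Stack multiple empirical kernel maps
#'
#' Multiple-kernel representation: the per-kernel maps are stacked on top of
#' each other, so samples represented in `u` kernel spaces of dimension `n`
#' become vectors of dimension `u * n`.
#'
#' @param maps List of `n x q` matrices sharing their dimensions.
#' @return `(u*n) x q` matrix, the vertical stack in list order.
#' @export
mkl_concatenate <- function(maps) {
  if (length(maps) == 0) abort("Need at least one map.",
                               class = "localdg_invalid_parameter")
  for (m in maps) stopifnot_matrix(m, "maps[[i]]")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All maps must share the same dimensions.",
          class = "localdg_shape_error")
  }
  do.call(rbind, maps)
}

#' Multiple-kernel empirical map
#'
#' Convenience wrapper building one empirical kernel map per spec and
#' stacking them with [mkl_concatenate()]. The default four-kernel set pairs
#' the Gaussian kernel with the inverse-square-distance, Laplacian and
#' inverse-distance kernels, all at the `1/d` automatic bandwidth.
#'
#' @inheritParams empirical_kernel_map
#' @param specs List of [kernel_spec()] objects.
#' @return Stacked representation with `length(specs) * ncol(X_train)` rows.
#' @export
mkl_kernel_map <- function(X_train, X_query, specs = mkl_default_specs()) {
  mkl_concatenate(lapply(specs, function(s)
    kernel_matrix(X_train, X_query, s)))
}

#' @rdname mkl_kernel_map
#' @export
mkl_default_specs <- function() {
  list(kernel_spec("gaussian"), kernel_spec("inv_square_distance"),
       kernel_spec("laplacian"), kernel_spec("inv_distance"))
}
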