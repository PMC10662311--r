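#' Save and load fitted models as JSON
#'
#' A fitted [ldg_fit()] model is serialized to a self-describing,
#' versioned JSON container holding the class list, every per-class block
#' (`W`, biases, `theta`, `lambda`, global model, domain membership), the
#' kernel specification and reference block when present, and the control
#' parameters. Objective traces are not persisted.
#'
#' @param model A fitted `ldg_model`.
#' @param path Output path (JSON).
#' @return `ldg_write_model` returns `path` invisibly; `ldg_read_model`
#'   returns an `ldg_model` ready for [predict.ldg_model()].
#' @export
ldg_write_model <- function(model, path) {
  if (!inherits(model, "ldg_model")) abort("Not an ldg_model.",
                                           class = "localdg_invalid_parameter")
  ser_mat <- function(M) {
    if (is.null(M)) NULL else
      list(nrow = nrow(M), ncol = ncol(M), values = as.vector(M))
  }
  ser_bin <- function(bm) {
    list(
      W = ser_mat(bm$W), b_local = bm$b_local, theta = bm$theta,
      lambda = bm$lambda, w_tilde = bm$w_tilde, b_global = bm$b_global,
      d_input = bm$d_input,
      domain_indices = lapply(bm$domains, `[[`, "indices"),
      domain_blocks = lapply(bm$domains, function(d) ser_mat(d$X_block)),
      kernel = lapply(bm$kernel, unclass),
      reference = ser_mat(bm$reference))
  }
  payload <- list(
    format = "localdg-model", version = 1L,
    classes = model$classes,
    feature_names = model$feature_names,
    n = model$n,
    control = unclass_control(model$control),
    binaries = lapply(model$binaries, ser_bin))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

unclass_control <- function(ctrl) {
  out <- unclass(ctrl)
  out$kernel <- lapply(out$kernel, unclass)
  out
}

#' @rdname ldg_write_model
#' @export
ldg_read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  if (!identical(p$format, "localdg-model")) {
    abort("Not a localdg model file.", class = "localdg_format_error")
  }
  ctrl_args <- p$control
  ctrl_args$kernel <- lapply(ctrl_args$kernel, function(ks) {
    kernel_spec(ks$family,
                if (identical(ks$bandwidth, "auto")) "auto"
                else as.numeric(ks$bandwidth))
  })
  control <- do.call(ldg_control, ctrl_args)
  des_mat <- function(x) {
    if (is.null(x) || length(x) == 0) NULL else
      matrix(as.numeric(x$values), as.integer(x$nrow), as.integer(x$ncol))
  }
  des_bin <- function(b) {
    domains <- lapply(seq_along(b$domain_indices), function(i) {
      structure(list(exemplar = b$domain_indices[[i]][1],
                     indices = b$domain_indices[[i]],
                     X_block = des_mat(b$domain_blocks[[i]])),
                class = "local_domain")
    })
    structure(
      list(domains = domains, W = des_mat(b$W),
           b_local = as.numeric(b$b_local), theta = as.numeric(b$theta),
           lambda = as.numeric(b$lambda), w_tilde = as.numeric(b$w_tilde),
           b_global = as.numeric(b$b_global),
           kernel = control$kernel,
           reference = des_mat(b$reference),
           d_input = as.integer(b$d_input)),
      class = "ldg_binary")
  }
  structure(
    list(classes = p$classes,
         binaries = stats::setNames(lapply(p$binaries, des_bin), p$classes),
         control = control, feature_names = p$feature_names,
         n = p$n, label_col = "label", subject_col = "subject"),
    class = "ldg_model")
}
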