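#' Fit a multiclass local domain generalization model
#'
#' Data-frame-first interface: `data` holds one row per sample, a `label`
#' column with the class, a `subject` column with the domain (subject)
#' identifier, and numeric feature columns. One binary one-vs-rest solver
#' ([fit_ldg_binary()]) is fitted per class.
#'
#' @param data Data frame of samples; all columns other than `label` and
#'   `subject` must be numeric features.
#' @param control An [ldg_control()].
#' @param label,subject Names of the label and subject columns.
#' @return Object of class `ldg_model` with one `ldg_binary` fit per class
#'   (in class order), the class levels, feature names, and the control
#'   used. Methods: [predict.ldg_model()], [tidy.ldg_model()],
#'   [glance.ldg_model()], [autoplot.ldg_model()].
#' @examples
#' sim <- simulate_ldg(synthetic_config(n_subjects = 2, d = 3,
#'                                      samples_per_class = 10, seed = 1))
#' fit <- ldg_fit(sim, ldg_control(k1 = 3, k2 = 3, k_graph = 3))
#' predict(fit, sim)
#' @export
ldg_fit <- function(data, control = ldg_control(), label = "label",
                    subject = "subject") {
  ft <- as_feature_table(data, label, subject)
  classes <- levels(ft$y)
  binaries <- lapply(classes, function(cl) {
    y_bin <- ifelse(ft$y == cl, 1, -1)
    fit_ldg_binary(ft$X, y_bin, control)
  })
  names(binaries) <- classes
  structure(
    list(classes = classes, binaries = binaries, control = control,
         feature_names = ft$feature_names, n = ncol(ft$X),
         label_col = label, subject_col = subject),
    class = "ldg_model")
}

#' @export
print.ldg_model <- function(x, ...) {
  cat(sprintf(
    "<ldg_model> %d classes (one-vs-rest), %d training samples, %d features\n",
    length(x$classes), x$n, length(x$feature_names)))
  for (cl in x$classes) {
    bm <- x$binaries[[cl]]
    cat(sprintf("  class %-10s %4d local domains, median %g iterations\n",
                cl, length(bm$domains), median(bm$iterations)))
  }
  invisible(x)
}

#' Predict classes with a fitted model
#'
#' In `"dg"` mode (domain generalization) each one-vs-rest score fuses the
#' local classifiers by their squared importance weights; in `"lda"` mode
#' (local domain adaptation) the unlabeled target features reweight the
#' local classifiers by kernel MMD similarity before fusion. The predicted
#' class maximizes the one-vs-rest score; exact ties go to the earlier
#' class in level order.
#'
#' @param object A fitted [ldg_fit()] model.
#' @param new_data Data frame with the model's feature columns (a label
#'   column, if present, is ignored).
#' @param mode `"dg"` or `"lda"`.
#' @param target Data frame of unlabeled target-domain samples; defaults
#'   to `new_data` itself in `"lda"` mode.
#' @param ... Unused.
#' @return Tibble with `.pred_class` and one `.score_<class>` column per
#'   class.
#' @export
predict.ldg_model <- function(object, new_data, mode = c("dg", "lda"),
                              target = NULL, ...) {
  mode <- match.arg(mode)
  X <- features_matrix(new_data, object$feature_names)
  if (mode == "lda") {
    Xt <- if (is.null(target)) X else
      features_matrix(target, object$feature_names)
    scores <- sapply(object$binaries, function(bm) {
      zeta <- lda_weights(binary_model_psi(bm, Xt))
      predict_lda_score(X, bm, zeta)
    })
  } else {
    if (!is.null(target)) {
      abort("`target` is only used in \"lda\" mode.",
            class = "localdg_invalid_mode")
    }
    scores <- sapply(object$binaries, function(bm) predict_dg_score(X, bm))
  }
  scores <- matrix(scores, ncol = length(object$classes),
                   dimnames = list(NULL, object$classes))
  pred <- object$classes[max.col(scores, ties.method = "first")]
  out <- tibble::tibble(.pred_class = factor(pred, levels = object$classes))
  sc <- tibble::as_tibble(scores)
  names(sc) <- paste0(".score_", object$classes)
  dplyr::bind_cols(out, sc)
}

#' @describeIn ldg_fit Per-domain summary: one row per class and local
#'   domain with the exemplar index, importance weight `theta`, subdomain
#'   weight `lambda`, inner-iteration count and convergence flag.
#' @param x An `ldg_model`.
#' @param ... Unused.
#' @export
tidy.ldg_model <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    bm <- x$binaries[[cl]]
    tibble::tibble(
      class = cl,
      domain = seq_along(bm$domains),
      exemplar = vapply(bm$domains, `[[`, integer(1), "exemplar"),
      size = vapply(bm$domains, function(d) length(d$indices), integer(1)),
      theta = bm$theta,
      lambda = bm$lambda,
      iterations = bm$iterations,
      converged = bm$converged)
  })
}

#' @describeIn ldg_fit One-row model summary: sample count, class and
#'   domain counts, median iterations, final objective, convergence.
#' @export
glance.ldg_model <- function(x, ...) {
  iters <- unlist(lapply(x$binaries, `[[`, "iterations"))
  finals <- vapply(x$binaries, function(bm)
    tail(bm$full_objective_trace[[length(bm$full_objective_trace)]], 1),
    numeric(1))
  tibble::tibble(
    n = x$n,
    n_classes = length(x$classes),
    n_domains = sum(vapply(x$binaries, function(b) length(b$domains),
                           integer(1))),
    median_iterations = median(iters),
    max_iterations = max(iters),
    objective = sum(finals),
    converged = all(unlist(lapply(x$binaries, `[[`, "converged"))))
}

#' @describeIn ldg_fit Objective traces of the inner loops, one thin line
#'   per local domain, faceted by class.
#' @param object An `ldg_model`.
#' @export
autoplot.ldg_model <- function(object, ...) {
  df <- purrr::map_dfr(object$classes, function(cl) {
    bm <- object$binaries[[cl]]
    purrr::map_dfr(seq_along(bm$objective_trace), function(v) {
      tr <- bm$objective_trace[[v]]
      tibble::tibble(class = cl, domain = v,
                     iteration = seq_along(tr) - 1, objective = tr)
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective,
                                   group = .data$domain)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "inner iteration", y = "objective",
                  title = "Per-domain objective traces")
}

# ---- feature-table plumbing ------------------------------------------------

as_feature_table <- function(data, label = "label", subject = "subject") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.",
                                  class = "localdg_format_error")
  for (col in c(label, subject)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` is missing from the feature table.", col),
            class = "localdg_format_error")
    }
  }
  feat <- setdiff(names(data), c(label, subject))
  if (length(feat) == 0) abort("No feature columns found.",
                               class = "localdg_format_error")
  for (fc in feat) {
    if (!is.numeric(data[[fc]])) {
      abort(sprintf("Feature column `%s` is not numeric.", fc),
            class = "localdg_format_error")
    }
    if (anyNA(data[[fc]])) {
      abort(sprintf("Missing value in feature column `%s` (row %d).",
                    fc, which(is.na(data[[fc]]))[1]),
            class = "localdg_format_error")
    }
  }
  y <- data[[label]]
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) abort("Need at least 2 classes.",
                            class = "localdg_format_error")
  subj <- data[[subject]]
  subj <- if (is.factor(subj)) droplevels(subj) else factor(subj)
  X <- t(as.matrix(data[feat]))
  dimnames(X) <- NULL
  list(X = X, y = y, subjects = subj, feature_names = feat)
}

features_matrix <- function(data, feature_names) {
  missing <- setdiff(feature_names, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Feature column(s) missing: %s.",
                  paste(missing, collapse = ", ")),
          class = "localdg_format_error")
  }
  X <- t(as.matrix(data[feature_names]))
  dimnames(X) <- NULL
  X
}
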