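#' Read and write delimited feature tables
#'
#' The on-disk feature-table format is delimited text with a header row:
#' feature columns (any names), a `label` column and a `subject` column;
#' UTF-8, `.` decimal point.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default comma).
#' @return `read_feature_table` returns a validated tibble with `label`
#'   and `subject` as factors; `write_feature_table` returns `path`
#'   invisibly.
#' @export
read_feature_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "localdg_format_error")
  df <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                          progress = FALSE)
  ft <- as_feature_table(df)                      # validates
  out <- tibble::as_tibble(df)
  out$label <- ft$y
  out$subject <- ft$subjects
  out
}

#' @rdname read_feature_table
#' @param data Feature table (data frame with `label` and `subject`).
#' @export
write_feature_table <- function(data, path, delimiter = ",") {
  as_feature_table(data)                          # validates before writing
  readr::write_delim(data, path, delim = delimiter)
  invisible(path)
}

#' Leave-one-subject-out splits
#'
#' One split per subject, ordered by subject identifier: the held-out
#' subject's samples form the test set, all other samples the training
#' set.
#'
#' @param subject_ids Vector of per-sample subject identifiers.
#' @return List of splits, each a list with `subject`, `train` and `test`
#'   index vectors.
#' @export
loso_splits <- function(subject_ids) {
  subj <- as.character(subject_ids)
  ids <- sort(unique(subj))
  if (length(ids) < 2) {
    abort("Leave-one-subject-out needs at least 2 subjects.",
          class = "localdg_protocol_error")
  }
  lapply(ids, function(s) {
    test <- which(subj == s)
    list(subject = s, train = setdiff(seq_along(subj), test), test = test)
  })
}

#' Empirical chance level and its upper confidence bound
#'
#' Repeats uniformly random class predictions over the test labels and
#' summarizes the resulting accuracy distribution: its mean (the empirical
#' chance level) and the upper bound of its two-sided normal-approximation
#' confidence interval (UBCL). A fitted model is conventionally required
#' to beat the UBCL.
#'
#' @param y_test Vector of test labels.
#' @param n_repeats Number of randomized-prediction repeats (at least 100).
#' @param confidence Confidence level of the interval (default 0.95).
#' @return Tibble with `mean_accuracy`, `ubcl`, `sd_accuracy`, `n_repeats`.
#' @export
empirical_chance_level <- function(y_test, n_repeats = 1000,
                                   confidence = 0.95) {
  if (length(y_test) == 0) abort("Empty test labels.",
                                 class = "localdg_protocol_error")
  if (n_repeats < 100) abort("`n_repeats` must be at least 100.",
                             class = "localdg_invalid_parameter")
  y_test <- as.character(y_test)
  classes <- sort(unique(y_test))
  acc <- vapply(seq_len(n_repeats), function(i) {
    mean(sample(classes, length(y_test), replace = TRUE) == y_test)
  }, numeric(1))
  z <- qnorm(1 - (1 - confidence) / 2)
  tibble::tibble(mean_accuracy = mean(acc),
                 ubcl = mean(acc) + z * sd(acc),
                 sd_accuracy = sd(acc),
                 n_repeats = n_repeats)
}

#' Leave-one-subject-out evaluation
#'
#' Fits the multiclass model on all but one subject and predicts the
#' held-out subject, for every subject in turn. In `"lda"` mode the
#' held-out subject's unlabeled features reweight the local classifiers;
#' labels of the held-out subject are never seen by the model.
#'
#' @inheritParams ldg_fit
#' @param mode `"dg"` or `"lda"`.
#' @param chance_repeats Repeats for the per-subject empirical chance
#'   level (0 to skip).
#' @return Tibble of class `ldg_loso`: one row per held-out subject with
#'   `accuracy`, `n_test`, and (when requested) `chance` and `ubcl`.
#'   Summary statistics via [glance.ldg_loso()].
#' @export
ldg_loso <- function(data, control = ldg_control(), mode = c("dg", "lda"),
                     chance_repeats = 0, label = "label",
                     subject = "subject") {
  mode <- match.arg(mode)
  ft <- as_feature_table(data, label, subject)
  splits <- loso_splits(ft$subjects)
  rows <- purrr::map_dfr(splits, function(sp) {
    train <- data[sp$train, , drop = FALSE]
    test <- data[sp$test, , drop = FALSE]
    fit <- ldg_fit(train, control, label, subject)
    pred <- if (mode == "lda") {
      predict(fit, test, mode = "lda", target = test)
    } else {
      predict(fit, test, mode = "dg")
    }
    truth <- as.character(test[[label]])
    out <- tibble::tibble(subject = sp$subject,
                          n_test = length(sp$test),
                          accuracy = mean(as.character(pred$.pred_class) ==
                                            truth))
    if (chance_repeats > 0) {
      ch <- empirical_chance_level(truth, chance_repeats)
      out$chance <- ch$mean_accuracy
      out$ubcl <- ch$ubcl
    }
    out
  })
  class(rows) <- c("ldg_loso", class(rows))
  attr(rows, "mode") <- mode
  rows
}

#' @describeIn ldg_loso One-row summary: mean and standard deviation of
#'   the per-subject accuracies.
#' @param x An `ldg_loso` result.
#' @param ... Unused.
#' @export
glance.ldg_loso <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x),
                 mean_accuracy = mean(x$accuracy),
                 sd_accuracy = sd(x$accuracy),
                 mode = attr(x, "mode"))
}

#' @describeIn ldg_loso Bar chart of per-subject accuracies with the
#'   chance level overlaid when available.
#' @param object An `ldg_loso` result.
#' @export
autoplot.ldg_loso <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$subject, .data$accuracy)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "held-out subject", y = "accuracy",
                  title = "Leave-one-subject-out accuracy")
  if ("ubcl" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$ubcl),
                                 color = "red", shape = 4)
  }
  p
}

#' Subject-stratified grid search
#'
#' Exhaustive search over a hyperparameter grid, scored by p-fold
#' cross-validation where the folds group whole subjects (the closest
#' executable analogue of validating on held-out source subdomains, since
#' no target labels exist in the generalization setting). Configurations
#' whose graph neighborhood is infeasible (`k_graph >= 1 + k1 + k2`) are
#' skipped with a warning. Ties are resolved towards the earlier grid row.
#'
#' @inheritParams ldg_fit
#' @param grid Named list of parameter value vectors ([ldg_control()]
#'   argument names, e.g. `list(alpha = 10^(-2:2), k1 = c(3, 5))`);
#'   crossed exhaustively.
#' @param folds Number of subject folds `p` (default 5, capped by the
#'   subject count; error if larger).
#' @param base Baseline [ldg_control()] supplying the non-searched
#'   parameters.
#' @return List of class `ldg_grid`: `results` (tibble of configurations
#'   with mean fold accuracy, in grid order) and `best` (an
#'   `ldg_control`).
#' @export
ldg_grid_search <- function(data, grid, folds = 5, base = ldg_control(),
                            label = "label", subject = "subject") {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    abort("`grid` must contain non-empty parameter vectors.",
          class = "localdg_invalid_parameter")
  }
  ft <- as_feature_table(data, label, subject)
  ids <- sort(unique(as.character(ft$subjects)))
  if (folds > length(ids)) {
    abort("`folds` cannot exceed the number of subjects.",
          class = "localdg_protocol_error")
  }
  fold_of <- rep_len(seq_len(folds), length(ids))   # round-robin over subjects
  configs <- expand.grid(grid, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  accs <- rep(NA_real_, nrow(configs))
  for (i in seq_len(nrow(configs))) {
    ctrl <- do.call(ldg_control, utils::modifyList(unclass(base),
                                                   as.list(configs[i, , drop = FALSE])))
    if (ctrl$k_graph >= 1 + ctrl$k1 + ctrl$k2) {
      warn(sprintf("Grid row %d skipped: k_graph >= local-domain size.", i),
           class = "localdg_degenerate_config")
      next
    }
    fold_acc <- vapply(seq_len(folds), function(fd) {
      test_subjects <- ids[fold_of == fd]
      test_idx <- which(as.character(ft$subjects) %in% test_subjects)
      fit <- ldg_fit(data[-test_idx, , drop = FALSE], ctrl, label, subject)
      pred <- predict(fit, data[test_idx, , drop = FALSE], mode = "dg")
      mean(as.character(pred$.pred_class) ==
             as.character(data[[label]][test_idx]))
    }, numeric(1))
    accs[i] <- mean(fold_acc)
  }
  results <- tibble::as_tibble(configs)
  results$mean_accuracy <- accs
  if (all(is.na(accs))) {
    abort("No feasible configuration in the grid.",
          class = "localdg_invalid_parameter")
  }
  best_i <- which(accs == max(accs, na.rm = TRUE))[1]
  best <- do.call(ldg_control, utils::modifyList(unclass(base),
                                                 as.list(configs[best_i, , drop = FALSE])))
  structure(list(results = results, best = best, best_index = best_i),
            class = "ldg_grid")
}

#' @export
print.ldg_grid <- function(x, ...) {
  cat(sprintf("<ldg_grid> %d configurations; best row %d (accuracy %.3f)\n",
              nrow(x$results), x$best_index,
              x$results$mean_accuracy[x$best_index]))
  print(x$best)
  invisible(x)
}
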