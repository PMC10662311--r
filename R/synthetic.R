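#' Configuration of the multi-subject synthetic generator
#'
#' The generator emulates the structure the local-domain method assumes of
#' multi-subject biosignal features: a shared class semantics across
#' subjects, multimodal (multi-cluster) class-conditional distributions,
#' and a per-subject covariate shift.
#'
#' Each class `c` is anchored at `class_separation * noise_sigma` times a
#' unit basis direction; its `clusters_per_class` cluster centers are drawn
#' once around that anchor (spread `class_separation * noise_sigma / 4`)
#' and shared by all subjects, so class identity persists across domains.
#' Each subject receives one additive mean-shift vector drawn from an
#' isotropic normal with standard deviation `subject_shift`, and every
#' sample is its cluster center plus the subject shift plus isotropic
#' noise of standard deviation `noise_sigma`. Classes are balanced within
#' each subject.
#'
#' @param n_subjects,n_classes,samples_per_class Counts (per subject for
#'   `samples_per_class`).
#' @param d Feature dimension.
#' @param clusters_per_class Number of modes per class.
#' @param class_separation Distance of the class anchors from the origin,
#'   in units of `noise_sigma`.
#' @param subject_shift Standard deviation of the per-subject mean shift.
#' @param noise_sigma Within-cluster noise standard deviation.
#' @param subject_rotation If `TRUE`, each subject additionally gets a
#'   small random rotation of feature space (a stress-test option; off by
#'   default, where the shift is purely additive).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 4L, n_classes = 3L,
                             samples_per_class = 40L, d = 6L,
                             clusters_per_class = 2L,
                             class_separation = 6, subject_shift = 1,
                             noise_sigma = 1, subject_rotation = FALSE,
                             seed = 1L) {
  counts <- c(n_subjects, n_classes, samples_per_class, d, clusters_per_class)
  if (any(counts < 1)) abort("All counts must be at least 1.",
                             class = "localdg_invalid_parameter")
  if (class_separation < 0 || subject_shift < 0 || noise_sigma < 0) {
    abort("Separation, shift and noise must be nonnegative.",
          class = "localdg_invalid_parameter")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_classes = as.integer(n_classes),
         samples_per_class = as.integer(samples_per_class),
         d = as.integer(d), clusters_per_class = as.integer(clusters_per_class),
         class_separation = class_separation, subject_shift = subject_shift,
         noise_sigma = noise_sigma, subject_rotation = subject_rotation,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Simulate a multi-subject, multimodal feature table
#'
#' @param config A [synthetic_config()].
#' @return Tibble with feature columns `f1..fd`, a `label` factor and a
#'   `subject` factor, one row per sample. The planted cluster centers
#'   (list of `d x clusters` matrices per class) and per-subject shift
#'   vectors (`d x n_subjects`) are attached as attributes `centers` and
#'   `subject_shifts` for moment checks.
#' @export
simulate_ldg <- function(config = synthetic_config()) {
  cf <- config
  withr::with_seed(cf$seed, {
    sep <- cf$class_separation * cf$noise_sigma
    centers <- lapply(seq_len(cf$n_classes), function(c) {
      anchor <- numeric(cf$d)
      anchor[(c - 1) %% cf$d + 1] <- sep
      anchor + matrix(rnorm(cf$d * cf$clusters_per_class, sd = sep / 4),
                      cf$d, cf$clusters_per_class)
    })
    shifts <- matrix(rnorm(cf$d * cf$n_subjects, sd = cf$subject_shift),
                     cf$d, cf$n_subjects)
    rotations <- if (cf$subject_rotation) {
      lapply(seq_len(cf$n_subjects), function(s) {
        qr.Q(qr(diag(cf$d) + matrix(rnorm(cf$d^2, sd = 0.1), cf$d)))
      })
    } else NULL

    rows <- list()
    for (s in seq_len(cf$n_subjects)) {
      for (c in seq_len(cf$n_classes)) {
        cl_id <- sample.int(cf$clusters_per_class, cf$samples_per_class,
                            replace = TRUE)
        base <- centers[[c]][, cl_id, drop = FALSE]
        if (!is.null(rotations)) base <- rotations[[s]] %*% base
        Xs <- base + shifts[, s] +
          matrix(rnorm(cf$d * cf$samples_per_class, sd = cf$noise_sigma),
                 cf$d, cf$samples_per_class)
        df <- tibble::as_tibble(t(Xs), .name_repair = ~ paste0("f", seq_len(cf$d)))
        df$label <- paste0("class", c)
        df$subject <- paste0("s", s)
        rows[[length(rows) + 1]] <- df
      }
    }
    out <- dplyr::bind_rows(rows)
    out$label <- factor(out$label)
    out$subject <- factor(out$subject)
    attr(out, "centers") <- centers
    attr(out, "subject_shifts") <- shifts
    out
  })
}

#' Differential-entropy feature of a band-limited window
#'
#' The standard Gaussian differential entropy of a band-limited signal
#' window, `DE = 0.5 * log(2 * pi * e * var_band)`, where `var_band` is
#' the variance of the window after frequency-mask filtering to `band`.
#' This is the per-band scalar feature commonly extracted from EEG windows
#' for emotion recognition.
#'
#' @param window Numeric signal vector, length at least 8.
#' @param band Frequency interval `c(low, high)` in Hz, within Nyquist.
#' @param sample_rate Sampling rate in Hz.
#' @return Scalar differential entropy (natural log units).
#' @export
differential_entropy_feature <- function(window, band = c(0, sample_rate / 2),
                                         sample_rate = 128) {
  n <- length(window)
  if (n < 8) abort("Window must contain at least 8 samples.",
                   class = "localdg_invalid_parameter")
  if (band[1] < 0 || band[2] > sample_rate / 2 || band[1] >= band[2]) {
    abort("`band` must lie within [0, Nyquist] with band[1] < band[2].",
          class = "localdg_invalid_parameter")
  }
  freqs <- (seq_len(n) - 1) * sample_rate / n
  alias <- pmin(freqs, sample_rate - freqs)
  mask <- alias >= band[1] & alias <= band[2]
  spec <- fft(window)
  spec[!mask] <- 0
  filtered <- Re(fft(spec, inverse = TRUE)) / n
  v <- var(filtered)
  if (v <= .Machine$double.eps * max(1, mean(window^2))) {
    abort("Signal has no variance in the requested band.",
          class = "localdg_degenerate_signal")
  }
  0.5 * log(2 * pi * exp(1) * v)
}
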