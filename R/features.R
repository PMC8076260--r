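#' Sliding-window variability indices and the 40-feature rows
#'
#' For every beat with at least 14 followers, the coefficient of
#' variation of each `C_n` (`CV_n`, percent) and the dispersion of each
#' phase angle (`P_n_SD`, degrees) are computed over that beat and the
#' following 14 beats. Together with the window's first-beat `C_n` and
#' `P_n` this yields the 40-dimensional feature row
#' `[C1..C10, CV1..CV10, P1..P10, P1_SD..P10_SD]` used by the
#' classifier.
#'
#' Phase dispersion near the ±180° branch cut would be inflated by a
#' naive linear SD, so phases are first unwrapped within the window by
#' cutting the circle at its largest angular gap (minimal-arc
#' unwrapping); whenever the phases span less than 180° this equals the
#' ordinary linear SD.
#'
#' @name features
NULL

# Unwrap a set of angles (degrees) by cutting the circle at the largest
# gap, so the values lie on a contiguous arc; returns values shifted by
# multiples of 360.
unwrap_gap <- function(p) {
  if (length(p) < 2L) return(p)
  o <- order(p)
  ps <- p[o]
  gaps <- c(diff(ps), ps[1] + 360 - ps[length(ps)])
  cut <- which.max(gaps)
  if (cut < length(ps)) {
    # values above the cut belong below: shift them down by 360
    shift <- rep(0, length(ps))
    shift[(cut + 1L):length(ps)] <- -360
    ps <- ps + shift
  }
  out <- numeric(length(p))
  out[o] <- ps
  out
}

# Circular-aware SD in degrees (sample SD of gap-cut unwrapped values).
phase_sd <- function(p) sd(unwrap_gap(p))

#' Windowed variability indices
#'
#' @param beat_series data.frame of per-beat indices from
#'   [beat_indices()] (columns C1..C10, P1..P10), in beat order.
#' @param window window length in beats (default 15).
#' @param n_max number of harmonics.
#' @param phase_sd_mode `"degrees"` (default) or `"percent"`
#'   (SD / |circular mean| × 100).
#' @param cv_mean_epsilon windows whose `C_n` mean magnitude falls below
#'   this are rejected (CV undefined); default 1e-9.
#' @return data.frame with one row per window: `window_start_beat`,
#'   CV1..CV10, P1_SD..P10_SD. Window w covers beats w .. w+window-1;
#'   the number of rows is `nrow(beat_series) - window + 1`.
#' @export
windowed_variability <- function(beat_series, window = 15, n_max = 10,
                                 phase_sd_mode = c("degrees", "percent"),
                                 cv_mean_epsilon = 1e-9) {
  phase_sd_mode <- match.arg(phase_sd_mode)
  nb <- nrow(beat_series)
  if (nb < window)
    stop(sprintf("need at least %d beats, got %d: subject excluded",
                 window, nb))
  cn <- as.matrix(beat_series[, paste0("C", 1:n_max), drop = FALSE])
  pn <- as.matrix(beat_series[, paste0("P", 1:n_max), drop = FALSE])
  nw <- nb - window + 1L
  cv <- matrix(NA_real_, nw, n_max)
  psd <- matrix(NA_real_, nw, n_max)
  for (w in seq_len(nw)) {
    rows <- w:(w + window - 1L)
    for (n in seq_len(n_max)) {
      m <- mean(cn[rows, n])
      if (abs(m) < cv_mean_epsilon) {
        # CV undefined; row is dropped (with a message) in assemble_features
        cv[w, n] <- NA_real_
      } else {
        cv[w, n] <- sd(cn[rows, n]) / m * 100
      }
      up <- unwrap_gap(pn[rows, n])
      s <- sd(up)
      if (phase_sd_mode == "percent") {
        mu <- abs(mean(up))
        s <- if (mu < 1e-12) NA_real_ else s / mu * 100
      }
      psd[w, n] <- s
    }
  }
  colnames(cv) <- paste0("CV", 1:n_max)
  colnames(psd) <- paste0("P", 1:n_max, "_SD")
  data.frame(window_start_beat = seq_len(nw), cv, psd, check.names = FALSE)
}

#' Assemble 40-feature rows
#'
#' One row per window: `C_n` and `P_n` from the window's first beat,
#' `CV_n` and `P_n_SD` from the window. Rows with non-finite values are
#' dropped with a message.
#'
#' @param beat_series per-beat indices ([beat_indices()] output).
#' @param windows [windowed_variability()] output for the same series
#'   (computed if `NULL`).
#' @param n_max number of harmonics.
#' @param window window length (only used when `windows` is `NULL`).
#' @return data.frame: subject_id, label, severity, channel,
#'   window_start_beat, then the 40 canonical feature columns
#'   `C1..C10, CV1..CV10, P1..P10, P1_SD..P10_SD`.
#' @export
assemble_features <- function(beat_series, windows = NULL, n_max = 10,
                              window = 15) {
  if (is.null(windows))
    windows <- windowed_variability(beat_series, window = window, n_max = n_max)
  first <- beat_series[windows$window_start_beat, , drop = FALSE]
  out <- data.frame(
    subject_id = first$subject_id, label = first$label,
    severity = first$severity, channel = first$channel,
    window_start_beat = windows$window_start_beat,
    first[, paste0("C", 1:n_max), drop = FALSE],
    windows[, paste0("CV", 1:n_max), drop = FALSE],
    first[, paste0("P", 1:n_max), drop = FALSE],
    windows[, paste0("P", 1:n_max, "_SD"), drop = FALSE],
    check.names = FALSE, row.names = NULL)
  fc <- feature_columns(n_max)
  finite <- apply(as.matrix(out[, fc]), 1L, function(r) all(is.finite(r)))
  if (any(!finite))
    message(sum(!finite), " row(s) with non-finite features dropped")
  out[finite, , drop = FALSE]
}

#' Canonical feature column names
#' @param n_max number of harmonics.
#' @return character vector of the 4 * n_max feature names in canonical
#'   order.
#' @export
feature_columns <- function(n_max = 10) {
  c(paste0("C", 1:n_max), paste0("CV", 1:n_max),
    paste0("P", 1:n_max), paste0("P", 1:n_max, "_SD"))
}

#' Fit a Z-score normalization model on training rows
#'
#' @param rows data.frame or matrix holding (at least) the feature
#'   columns; restrict to training-subject rows to avoid leakage.
#' @param columns feature columns to normalize (default the 40 canonical
#'   ones).
#' @return an object of class `normalization_model` with per-feature
#'   `mean` and `sd`.
#' @export
normalize_fit <- function(rows, columns = feature_columns()) {
  X <- as.matrix(as.data.frame(rows)[, columns, drop = FALSE])
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd)
  bad <- which(!(sg > 0))
  if (length(bad) > 0L)
    stop("constant feature(s): ", paste(columns[bad], collapse = ", "))
  structure(list(mean = mu, sd = sg, columns = columns),
            class = "normalization_model")
}

#' Apply a fitted normalization model
#'
#' Uses the stored training parameters only (no re-fit).
#'
#' @param model a [normalize_fit()] model.
#' @param rows rows to transform.
#' @return `rows` with the feature columns replaced by their Z-scores.
#' @export
normalize_apply <- function(model, rows) {
  stopifnot(inherits(model, "normalization_model"))
  rows <- as.data.frame(rows)
  X <- as.matrix(rows[, model$columns, drop = FALSE])
  X <- sweep(sweep(X, 2L, model$mean), 2L, model$sd, "/")
  rows[, model$columns] <- X
  rows
}
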