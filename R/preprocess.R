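#' Baseline-drift removal: high-order Chebyshev high-pass
#'
#' Slow baseline wander (thermal drift, very-low-frequency interference)
#' is removed before segmentation with an 11th-order type-I Chebyshev
#' high-pass filter at 0.01 Hz. At a 1024 Hz sampling rate the poles of
#' this filter sit so close to z = 1 that a direct-form transfer
#' function is numerically unusable, so the filter is designed
#' analytically (Chebyshev low-pass prototype, low-pass-to-high-pass
#' transform, bilinear transform with prewarping) and realized as a
#' cascade of second-order sections, which is stable in double
#' precision.
#'
#' @name preprocess
NULL

#' High-pass filter specification
#'
#' @param order filter order (default 11).
#' @param cutoff_hz cutoff frequency in Hz (default 0.01).
#' @param ripple_db passband ripple in dB (default 0.5).
#' @param mode `"zero_phase"` (forward-backward; no group delay, squared
#'   magnitude response) or `"one_pass"` (causal).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 11, cutoff_hz = 0.01, ripple_db = 0.5,
                        mode = c("zero_phase", "one_pass")) {
  mode <- match.arg(mode)
  stopifnot_scalar(order, "order", lower = 1)
  stopifnot_scalar(cutoff_hz, "cutoff_hz", lower = 1e-12)
  stopifnot_scalar(ripple_db, "ripple_db", lower = 1e-6)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 ripple_db = ripple_db, mode = mode),
            class = "filter_spec")
}

#' Design the realized high-pass filter
#'
#' Chebyshev type-I analog low-pass prototype with the requested
#' passband ripple, transformed to high-pass at the (prewarped) cutoff
#' and discretized with the bilinear transform. Returned as cascaded
#' biquad sections (all zeros at z = 1, so the DC gain is exactly 0).
#'
#' @param spec a [filter_spec()].
#' @param sampling_rate_hz sampling rate in Hz; the cutoff must be below
#'   Nyquist.
#' @return an object of class `sos_filter`: list with `sos` (list of
#'   `list(b, a)` biquads), `gain`, and the design parameters.
#' @export
design_highpass <- function(spec = filter_spec(), sampling_rate_hz = 1024) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- sampling_rate_hz
  if (spec$cutoff_hz >= fs / 2) stop("cutoff must be below Nyquist")
  n <- spec$order
  eps <- sqrt(10^(spec$ripple_db / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  p_lp <- complex(real = -sinh(mu) * sin(theta),
                  imaginary = cosh(mu) * cos(theta))
  # prototype gain: |H(j0)| = 1 (odd order) or 1/sqrt(1+eps^2) (even)
  K <- Re(prod(-p_lp)) * if (n %% 2 == 0) 1 / sqrt(1 + eps^2) else 1
  wc <- 2 * fs * tan(pi * spec$cutoff_hz / fs)       # prewarped
  p_hp <- wc / p_lp                                  # LP -> HP
  k_hp <- K / Re(prod(-p_lp))                        # n zeros at s = 0
  fs2 <- 2 * fs                                      # bilinear
  pd <- (fs2 + p_hp) / (fs2 - p_hp)
  kd <- k_hp * Re(prod(fs2 - rep(0 + 0i, n)) / prod(fs2 - p_hp))
  if (any(Mod(pd) >= 1))
    stop("unstable realization at the requested order/cutoff; ",
         "reduce the order or raise the cutoff")
  # pair conjugate poles into biquads (zeros all at z = 1)
  ord <- order(abs(Im(pd)), decreasing = TRUE)
  pd <- pd[ord]
  used <- rep(FALSE, n)
  sos <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    if (abs(Im(pd[i])) > 1e-13) {
      j <- which(!used & seq_len(n) != i &
                   abs(pd - Conj(pd[i])) < 1e-9)[1]
      if (is.na(j)) stop("internal error: unpaired complex pole")
      used[c(i, j)] <- TRUE
      sos[[length(sos) + 1L]] <- list(b = c(1, -2, 1),
                                      a = c(1, -2 * Re(pd[i]), Mod(pd[i])^2))
    } else {
      used[i] <- TRUE
      sos[[length(sos) + 1L]] <- list(b = c(1, -1, 0),
                                      a = c(1, -Re(pd[i]), 0))
    }
  }
  structure(list(sos = sos, gain = kd, spec = spec,
                 sampling_rate_hz = fs),
            class = "sos_filter")
}

#' @export
print.sos_filter <- function(x, ...) {
  cat(sprintf("<sos_filter> order %d Chebyshev-I high-pass, cutoff %g Hz @ %g Hz, %d sections, %s\n",
              x$spec$order, x$spec$cutoff_hz, x$sampling_rate_hz,
              length(x$sos), x$spec$mode))
  invisible(x)
}

#' Frequency response of a realized filter
#'
#' Evaluates the transfer function of the biquad cascade on a frequency
#' grid. For `mode = "zero_phase"` the reported magnitude is squared
#' (the effective forward-backward response) and the phase is zero.
#'
#' @param filt an [design_highpass()] result.
#' @param freq_hz frequencies at which to evaluate (Hz).
#' @param effective if `TRUE` (default) report the response of the
#'   filter as applied (squared magnitude under zero-phase); if `FALSE`
#'   report the single-pass transfer function.
#' @return data.frame with `freq_hz`, `magnitude`, `gain_db`.
#' @export
filter_response <- function(filt, freq_hz, effective = TRUE) {
  stopifnot(inherits(filt, "sos_filter"))
  w <- 2 * pi * freq_hz / filt$sampling_rate_hz
  z1 <- exp(-1i * w)
  H <- rep(complex(real = filt$gain), length(w))
  for (s in filt$sos)
    H <- H * (s$b[1] + s$b[2] * z1 + s$b[3] * z1^2) /
      (s$a[1] + s$a[2] * z1 + s$a[3] * z1^2)
  mag <- Mod(H)
  if (effective && filt$spec$mode == "zero_phase") mag <- mag^2
  data.frame(freq_hz = freq_hz, magnitude = mag,
             gain_db = ifelse(mag > 0, 20 * log10(mag), -Inf))
}

# Run the biquad cascade once, causally, over a numeric vector.
sos_pass <- function(filt, x) {
  y <- x * filt$gain
  for (s in filt$sos) {
    # MA part (convolution) then AR part (recursive); both C-level
    v <- stats::filter(c(0, 0, y), s$b, method = "convolution", sides = 1)
    v <- as.numeric(v)[3:(length(y) + 2)]
    if (any(s$a[2:3] != 0))
      v <- as.numeric(stats::filter(v, -s$a[2:3], method = "recursive"))
    y <- v
  }
  y
}

#' Apply the high-pass filter to a recording
#'
#' Zero-phase mode (default) subtracts the signal mean, extends both
#' ends by odd reflection, runs the cascade forward and backward, and
#' trims the extension; this suppresses the start-up transient that a
#' causal pass exhibits and preserves beat timing. One-pass mode applies
#' the cascade causally once.
#'
#' @param recording a [pulse_recording()].
#' @param spec a [filter_spec()], or an already designed [design_highpass()]
#'   filter for the recording's sampling rate.
#' @param transient_s length (seconds) of the edge region flagged as a
#'   filter transient at each end. Defaults: 0 for zero-phase (the
#'   reflection padding absorbs the transient), `2 / cutoff_hz` for
#'   one-pass. Flags are attached as attribute `"transient_mask"`.
#' @param pad_s odd-reflection padding length in seconds (zero-phase
#'   mode), capped at the recording length.
#' @return the filtered [pulse_recording()] (same length and metadata),
#'   with attributes `transient_mask` (logical) and `filter` (the
#'   realized filter). Ground-truth attributes (`feet`, `beat_lengths`,
#'   `spec`) are carried over if present.
#' @export
apply_filter <- function(recording, spec = filter_spec(), transient_s = NULL,
                         pad_s = 2) {
  stopifnot(inherits(recording, "pulse_recording"))
  filt <- if (inherits(spec, "sos_filter")) spec
  else design_highpass(spec, recording$sampling_rate_hz)
  if (!isTRUE(all.equal(filt$sampling_rate_hz, recording$sampling_rate_hz)))
    stop("filter was designed for a different sampling rate")
  fs <- recording$sampling_rate_hz
  x <- recording$samples
  n <- length(x)
  warmup <- 3L * (2L * length(filt$sos) + 1L)
  if (n <= warmup)
    stop(sprintf("recording too short for filtering: %d samples <= warm-up %d",
                 n, warmup))
  mode <- filt$spec$mode
  if (mode == "zero_phase") {
    mu <- mean(x)
    xc <- x - mu
    np <- min(n - 1L, as.integer(round(pad_s * fs)))
    pre <- 2 * xc[1] - xc[(np + 1L):2L]
    post <- 2 * xc[n] - xc[(n - 1L):(n - np)]
    ext <- c(pre, xc, post)
    y <- sos_pass(filt, ext)
    y <- rev(sos_pass(filt, rev(y)))
    y <- y[(np + 1L):(np + n)]
    if (is.null(transient_s)) transient_s <- 0
  } else {
    y <- sos_pass(filt, x)
    if (is.null(transient_s)) transient_s <- 2 / filt$spec$cutoff_hz
  }
  if (any(!is.finite(y))) stop("filter produced non-finite output")
  out <- recording
  out$samples <- y
  nt <- min(n, as.integer(round(transient_s * fs)))
  mask <- rep(FALSE, n)
  if (nt > 0L) {
    mask[seq_len(nt)] <- TRUE
    mask[(n - nt + 1L):n] <- TRUE
  }
  attr(out, "transient_mask") <- mask
  attr(out, "filter") <- filt
  for (a in c("feet", "beat_lengths", "spec"))
    if (!is.null(attr(recording, a))) attr(out, a) <- attr(recording, a)
  out
}
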