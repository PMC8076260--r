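#' Per-beat harmonic analysis
#'
#' Each beat of `k` samples is expanded in a truncated Fourier series;
#' the coefficients are
#' \deqn{A_n = \frac{2}{k} \sum_{s=0}^{k-1} x_s \cos(2\pi n s/k), \quad
#'       B_n = \frac{2}{k} \sum_{s=0}^{k-1} x_s \sin(2\pi n s/k),}
#' so `A0` equals twice the beat mean. Harmonic amplitudes are
#' `Amp_n = sqrt(A_n^2 + B_n^2)` (with `Amp0 = |A0|`), phase angles
#' `P_n = atan2(B_n, A_n)` in degrees on (-180, 180], and the amplitude
#' proportions are `C_n = Amp_n / Amp0 * 100` for n = 1-10.
#'
#' After high-pass filtering the per-beat mean can approach zero, which
#' destabilizes the `C_n` ratios; the default `baseline_mode =
#' "min_zero"` therefore subtracts the beat minimum before the
#' transform, guaranteeing a positive DC term. Mode `"none"` applies
#' the transform to the raw beat and is the mode under which a
#' noise-free synthetic beat reproduces its generating template exactly.
#'
#' @name spectral
NULL

#' Fourier coefficients of one beat
#'
#' @param pulse a `pulse_segment` (from [extract_pulses()]) or a bare
#'   numeric vector of beat samples.
#' @param n_max highest harmonic (default 10).
#' @param baseline_mode `"min_zero"` (subtract the beat minimum first;
#'   default) or `"none"`.
#' @return an object of class `harmonic_spectrum`: `A` (A0..An),
#'   `B` (B0..Bn, with B0 = 0), `k`, `baseline_mode`.
#' @export
fourier_coefficients <- function(pulse, n_max = 10,
                                 baseline_mode = c("min_zero", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  x <- if (inherits(pulse, "pulse_segment")) pulse$samples else as.numeric(pulse)
  k <- length(x)
  if (k < 2 * n_max + 2)
    stop(sprintf("beat too short: k = %d < %d needed for %d harmonics",
                 k, 2 * n_max + 2, n_max))
  if (baseline_mode == "min_zero") x <- x - min(x)
  X <- fft(x)[1:(n_max + 1)]
  A <- 2 * Re(X) / k
  B <- -2 * Im(X) / k
  B[1] <- 0
  structure(list(A = A, B = B, k = k, n_max = n_max,
                 baseline_mode = baseline_mode),
            class = "harmonic_spectrum")
}

#' Amplitudes and phase angles of a harmonic spectrum
#'
#' Adds `Amp_n = sqrt(A_n^2 + B_n^2)` and the phase angle `P_n`,
#' computed with the two-argument arctangent of `(B_n, A_n)` and
#' reported in degrees on (-180, 180]. A vanishing harmonic
#' (`Amp_n = 0`) gets `P_n = 0` by convention and is flagged.
#'
#' @param spectrum a [fourier_coefficients()] result.
#' @return the spectrum with `Amp` (Amp0..Ampn), `P` (P1..Pn, degrees)
#'   and `P_degenerate` (logical flags) added.
#' @export
amp_phase <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  spectrum$Amp <- sqrt(spectrum$A^2 + spectrum$B^2)
  a <- spectrum$A[-1]; b <- spectrum$B[-1]
  p <- atan2(b, a) * 180 / pi
  degen <- (a == 0 & b == 0)
  p[degen] <- 0
  spectrum$P <- wrap_deg(p)
  spectrum$P_degenerate <- degen
  spectrum
}

#' Amplitude proportions (Cn) of one beat
#'
#' @param spectrum an [amp_phase()]-completed spectrum (plain
#'   [fourier_coefficients()] output is completed automatically).
#' @param epsilon degenerate-DC guard: `Amp0` at or below this value is
#'   rejected (beat excluded upstream). Default `1e-9 * max(Amp)`.
#' @return an object of class `pulse_indices`: `C` (C1..Cn, percent),
#'   `P` (P1..Pn, degrees), `k`.
#' @export
amplitude_proportions <- function(spectrum, epsilon = NULL) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  if (is.null(spectrum$Amp)) spectrum <- amp_phase(spectrum)
  amp0 <- spectrum$Amp[1]
  if (is.null(epsilon)) epsilon <- 1e-9 * max(spectrum$Amp)
  if (!is.finite(amp0) || amp0 <= epsilon)
    stop("degenerate beat: Amp0 <= epsilon (DC term vanishes)")
  structure(list(C = spectrum$Amp[-1] / amp0 * 100, P = spectrum$P,
                 k = spectrum$k, baseline_mode = spectrum$baseline_mode),
            class = "pulse_indices")
}

#' Per-beat harmonic index table for a recording
#'
#' Convenience wrapper: cuts the recording at the given feet and returns
#' one row per analyzable beat with C1..C10 and P1..P10. Beats whose DC
#' term degenerates are skipped with a message.
#'
#' @param recording a [pulse_recording()] (normally filtered).
#' @param feet a [detect_feet()] annotation or integer foot indices.
#' @param n_max highest harmonic.
#' @param baseline_mode see [fourier_coefficients()].
#' @return data.frame: subject_id, channel, label, severity, beat_index,
#'   start_index, k, C1..C10, P1..P10.
#' @export
beat_indices <- function(recording, feet, n_max = 10,
                         baseline_mode = c("min_zero", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  segs <- extract_pulses(recording, feet)
  rows <- vector("list", length(segs))
  skipped <- 0L
  for (i in seq_along(segs)) {
    pi_ <- tryCatch(
      amplitude_proportions(amp_phase(
        fourier_coefficients(segs[[i]], n_max, baseline_mode))),
      error = function(e) NULL)
    if (is.null(pi_)) { skipped <- skipped + 1L; next }
    row <- c(beat_index = i, start_index = segs[[i]]$start_index,
             k = segs[[i]]$k, stats::setNames(pi_$C, paste0("C", 1:n_max)),
             stats::setNames(pi_$P, paste0("P", 1:n_max)))
    rows[[i]] <- row
  }
  if (skipped > 0L) message(skipped, " degenerate beat(s) skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no analyzable beats")
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(subject_id = recording$subject_id, channel = recording$channel,
             label = recording$label, severity = recording$severity,
             out, check.names = FALSE)
}
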