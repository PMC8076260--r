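#' Beat segmentation by foot detection
#'
#' All spectral quantities are defined per pulse, between consecutive
#' foot points (diastolic minima marking beat onset). The detector
#' locates systolic upstrokes as maxima of the smoothed first difference
#' above an adaptive threshold with a refractory period, then walks back
#' to the preceding waveform minimum and refines it with a local
#' quadratic fit on the raw signal (robust to sensor noise at high
#' sampling rates).
#'
#' @name segmentation
NULL

#' Detect beat feet (onsets)
#'
#' @param recording a (filtered) [pulse_recording()].
#' @param min_period_s,max_period_s admissible beat period bounds in
#'   seconds; upstrokes closer than `min_period_s` to the previous
#'   accepted one are treated as spurious (e.g. dicrotic dips).
#' @param smooth_s moving-average smoothing width (seconds) used for
#'   candidate detection.
#' @param refine_halfwidth_s half-width (seconds) of the quadratic-fit
#'   window used to refine each foot on the raw signal.
#' @param min_feet minimum number of feet for the recording to be
#'   analyzable (the 15-beat window rule needs at least 16).
#' @param exclude_transient drop feet falling in the filter-transient
#'   mask attached by [apply_filter()], if present.
#' @return an object of class `foot_annotation`: list with `indices`
#'   (1-based, strictly increasing), `method`, `params`.
#' @export
detect_feet <- function(recording, min_period_s = 0.4, max_period_s = 2.0,
                        smooth_s = 0.015, refine_halfwidth_s = 0.04,
                        min_feet = 16, exclude_transient = TRUE) {
  stopifnot(inherits(recording, "pulse_recording"))
  fs <- recording$sampling_rate_hz
  x <- recording$samples
  n <- length(x)
  w <- max(3L, as.integer(round(smooth_s * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  sx <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sx[is.na(sx)] <- x[is.na(sx)]
  d <- diff(sx)
  pos <- d[d > 0]
  if (length(pos) < 10L || diff(range(x)) <= 0)
    stop("fewer than ", min_feet, " feet found: recording rejected as unanalyzable")
  thr <- 0.5 * as.numeric(quantile(pos, 0.98))
  cand <- which(d >= thr)
  if (length(cand) == 0L)
    stop("fewer than ", min_feet, " feet found: recording rejected as unanalyzable")
  # group contiguous candidates into upstroke events, keep steepest point
  grp <- cumsum(c(1L, diff(cand) > as.integer(0.05 * fs)))
  ups <- vapply(split(cand, grp), function(ix) ix[which.max(d[ix])], integer(1))
  ups <- sort(unname(ups))
  # refractory: greedily keep upstrokes at least min_period_s apart
  minp <- as.integer(min_period_s * fs)
  keep <- integer(0)
  for (u in ups) {
    if (length(keep) == 0L || u - keep[length(keep)] >= minp) keep <- c(keep, u)
  }
  ups <- keep
  # foot: walk back from each upstroke to the preceding minimum of a
  # lightly smoothed copy, then refine with a quartic fit (the valley is
  # asymmetric, so a quadratic vertex is biased toward the flat side)
  rh <- max(4L, as.integer(round(refine_halfwidth_s * fs)))
  wr <- max(3L, as.integer(round(0.011 * fs)))
  if (wr %% 2L == 0L) wr <- wr + 1L
  rs <- as.numeric(stats::filter(x, rep(1 / wr, wr), sides = 2))
  rs[is.na(rs)] <- x[is.na(rs)]
  back <- as.integer(0.5 * minp) + rh
  feet <- integer(0)
  for (u in ups) {
    lo <- max(1L, u - back)
    # nearest valley: walk down the upstroke's left flank to the last
    # non-positive smoothed slope (ignores noise dips further back in
    # the flat diastolic tail)
    nz <- which(d[lo:max(lo, u - 1L)] <= 0)
    c0 <- if (length(nz) > 0L) lo + nz[length(nz)] - 1L
    else lo + which.min(rs[lo:u]) - 1L
    a <- max(1L, c0 - rh); b <- min(n, c0 + rh)
    tt <- (a:b) - c0
    yy <- rs[a:b]
    foot <- c0
    if (length(tt) > 8L) {
      cf <- stats::lm.fit(cbind(1, tt, tt^2, tt^3, tt^4), yy)$coefficients
      if (all(is.finite(cf))) {
        g <- seq(-rh, rh, by = 0.25)
        pv <- cf[1] + cf[2] * g + cf[3] * g^2 + cf[4] * g^3 + cf[5] * g^4
        foot <- c0 + as.integer(round(g[which.min(pv)]))
      }
    }
    # snap to the nearby smoothed minimum (removes the fit's residual
    # sub-sample bias on clean signals)
    foot <- min(max(foot, 1L), n)
    a2 <- max(1L, foot - 2L); b2 <- min(n, foot + 2L)
    foot <- a2 + which.min(rs[a2:b2]) - 1L
    feet <- c(feet, min(max(foot, 1L), n))
  }
  feet <- sort(unique(feet))
  # enforce period bounds between consecutive feet
  if (length(feet) > 1L) {
    ok <- c(TRUE, diff(feet) >= minp)
    feet <- feet[ok]
  }
  mask <- attr(recording, "transient_mask")
  if (exclude_transient && !is.null(mask)) feet <- feet[!mask[feet]]
  if (length(feet) < min_feet)
    stop("fewer than ", min_feet, " feet found: recording rejected as unanalyzable")
  structure(list(indices = feet, method = "slope-threshold+quadratic-foot",
                 params = list(min_period_s = min_period_s,
                               max_period_s = max_period_s,
                               smooth_s = smooth_s,
                               refine_halfwidth_s = refine_halfwidth_s)),
            class = "foot_annotation")
}

#' @export
print.foot_annotation <- function(x, ...) {
  cat(sprintf("<foot_annotation> %d feet (%s)\n", length(x$indices), x$method))
  invisible(x)
}

#' Cut a recording into per-beat segments
#'
#' Half-open convention: segment i covers samples
#' `[foot_i, foot_{i+1})`, so `k` equals the inter-foot interval and the
#' Fourier sums run over `s = 0, ..., k-1`. Concatenating all segments
#' reproduces the recording span between the first and last foot
#' exactly.
#'
#' @param recording a [pulse_recording()].
#' @param feet a [detect_feet()] annotation, or an integer vector of
#'   foot indices (e.g. generator ground truth).
#' @param min_samples segments shorter than this are dropped (with a
#'   message); default 32.
#' @return list of `pulse_segment` objects: `samples`, `k`,
#'   `start_index`, `subject_id`, `channel`.
#' @export
extract_pulses <- function(recording, feet, min_samples = 32) {
  stopifnot(inherits(recording, "pulse_recording"))
  ix <- if (inherits(feet, "foot_annotation")) feet$indices else as.integer(feet)
  if (length(ix) < 2L) stop("need at least 2 feet to extract a pulse")
  if (any(diff(ix) <= 0)) stop("foot indices must be strictly increasing")
  n <- length(recording$samples)
  if (ix[1] < 1L || ix[length(ix)] > n) stop("foot indices out of range")
  segs <- vector("list", length(ix) - 1L)
  dropped <- 0L
  for (i in seq_len(length(ix) - 1L)) {
    k <- ix[i + 1L] - ix[i]
    if (k < min_samples) { dropped <- dropped + 1L; next }
    segs[[i]] <- structure(
      list(samples = recording$samples[ix[i]:(ix[i + 1L] - 1L)],
           k = k, start_index = ix[i],
           subject_id = recording$subject_id,
           channel = recording$channel),
      class = "pulse_segment")
  }
  if (dropped > 0L)
    message(dropped, " segment(s) shorter than ", min_samples,
            " samples dropped")
  segs[!vapply(segs, is.null, logical(1))]
}
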