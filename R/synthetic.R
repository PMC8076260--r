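#' Synthetic arterial pulse waveforms with ground truth
#'
#' The generator builds quasi-periodic recordings from a truncated
#' 10-harmonic Fourier series per beat, with beat-period jitter,
#' beat-to-beat template jitter, slow sinusoidal baseline drift and
#' additive sensor noise. Every recording carries ground-truth foot
#' (beat-onset) indices and the generating template, so segmentation and
#' spectral extraction can be tested against known truth.
#'
#' Conventions. A beat of `k` samples with template amplitude
#' proportions `c_n` (percent) and phases `phi_n` (degrees) is
#' \deqn{x_s = d + \sum_{n=1}^{10} 2 d \frac{c_n}{100}
#'       \cos(2\pi n s/k - \phi_n \pi/180), \quad s = 0,\dots,k-1,}
#' where `d` is `dc_level`. Under the analysis-side definitions
#' (`A0 = 2·mean`, `Amp0 = |A0|`, `Cn = Ampn/Amp0·100`) this makes the
#' extracted `Cn`/`Pn` equal the template exactly for a noise-free beat
#' analyzed over its exact period with `baseline_mode = "none"`. Phases
#' are defined at the beat foot: every synthesized beat is circularly
#' rotated so that the minimum of its 10-harmonic waveform falls at
#' sample 0, i.e. the foot *is* the diastolic minimum.
#'
#' @name synthetic
NULL

# Canonical harmonic templates, derived once from a two-component
# (systolic + dicrotic lobe) pulse shape with geometric harmonic decay,
# rotated so the waveform minimum is at the foot. The PPG template has
# weaker high-harmonic content than the BPW one.
.template_defaults <- list(
  BPW = list(
    amp = c(50.0000, 22.0768, 19.6886, 8.0233, 6.0289,
            4.0169, 2.3738, 1.4739, 0.8681, 0.4928),
    phase = c(134.0949, 110.2507, 172.6910, -151.3954, -137.2840,
              -100.7305, -72.9488, -44.9601, -15.8649, 12.6696)
  ),
  PPG = list(
    amp = c(47.0000, 29.5422, 14.4441, 5.6566, 3.1167,
            1.2632, 0.5058, 0.1806, 0.0581, 0.0168),
    phase = c(146.3724, 141.4658, -142.8908, -117.9903, -73.0371,
              -31.6922, 7.8081, 48.4310, 88.6133, 128.8223)
  )
)

#' Harmonic beat template
#'
#' @param dc_level positive DC amplitude (signal units); equals the
#'   analysis-side `Amp0` of a noise-free beat.
#' @param amp_proportions 10 non-negative harmonic amplitude proportions
#'   (percent of `Amp0`).
#' @param phases 10 phase angles in degrees; wrapped to (-180, 180].
#' @return an object of class `harmonic_template`.
#' @export
harmonic_template <- function(dc_level = 1,
                              amp_proportions = .template_defaults$BPW$amp,
                              phases = .template_defaults$BPW$phase) {
  stopifnot_scalar(dc_level, "dc_level", lower = 1e-12)
  if (length(amp_proportions) != 10L || any(!is.finite(amp_proportions)) ||
      any(amp_proportions < 0))
    stop("`amp_proportions` must be 10 finite non-negative values")
  if (length(phases) != 10L || any(!is.finite(phases)))
    stop("`phases` must be 10 finite values (degrees)")
  structure(list(dc_level = dc_level,
                 amp_proportions = as.numeric(amp_proportions),
                 phases = wrap_deg(as.numeric(phases))),
            class = "harmonic_template")
}

#' Default channel template
#'
#' @param channel `"BPW"` or `"PPG"`.
#' @param dc_level DC amplitude.
#' @return a [harmonic_template()].
#' @export
default_template <- function(channel = c("BPW", "PPG"), dc_level = 1) {
  channel <- match.arg(channel)
  d <- .template_defaults[[channel]]
  harmonic_template(dc_level, d$amp, d$phase)
}

#' Synthesize one beat from a harmonic template
#'
#' Returns the truncated Fourier series of the template over
#' `period_samples` samples, rotated (if `align_foot`) so the waveform
#' minimum is at sample 0. Deterministic.
#'
#' @param template a [harmonic_template()].
#' @param period_samples beat length in samples (>= 32 so 10 harmonics
#'   sit below the Nyquist index).
#' @param align_foot rotate the beat so its minimum is at sample 0.
#' @return numeric vector of `period_samples` values; the realized phase
#'   vector (after rotation) is attached as attribute `"phases"`.
#' @export
synth_pulse <- function(template, period_samples, align_foot = TRUE) {
  stopifnot(inherits(template, "harmonic_template"))
  stopifnot_scalar(period_samples, "period_samples", lower = 1)
  k <- as.integer(period_samples)
  if (k < 32L)
    stop("period too short: need >= 32 samples so 10 harmonics fit below Nyquist")
  s <- 0:(k - 1L)
  d <- template$dc_level
  amp <- 2 * d * template$amp_proportions / 100
  ph <- template$phases * pi / 180
  # k x 10 basis; x = d + basis %*% amp
  x <- rep(d, k)
  for (n in 1:10)
    x <- x + amp[n] * cos(2 * pi * n * s / k - ph[n])
  phases <- template$phases
  if (align_foot) {
    shift <- which.min(x) - 1L
    if (shift > 0L) {
      x <- c(x[(shift + 1L):k], x[1:shift])
      phases <- wrap_deg(phases - (1:10) * shift / k * 360)
    }
  }
  attr(x, "phases") <- phases
  x
}

#' Subject specification for the generator
#'
#' @param subject_id opaque id string.
#' @param label `"AD"` or `"control"`.
#' @param severity `"none"`, `"mild"`, `"moderate"` or `"severe"`.
#' @param template a [harmonic_template()].
#' @param mean_heart_period_s mean beat period in seconds, in \[0.4, 2\].
#' @param period_jitter_cv lognormal coefficient of variation of the
#'   beat period (fraction).
#' @param template_jitter_cv beat-to-beat template jitter: multiplicative
#'   Gaussian noise (sd as a fraction) on amplitude proportions and
#'   additive Gaussian noise of sd `100 * template_jitter_cv` degrees on
#'   phases.
#' @param drift_amplitude amplitude of the sinusoidal baseline drift
#'   (signal units).
#' @param drift_frequency_hz drift frequency, below the 0.01 Hz
#'   high-pass cutoff.
#' @param noise_sd additive white-noise sd (signal units).
#' @param channel `"BPW"` or `"PPG"`.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id = "S1", label = c("control", "AD"),
                         severity = c("none", "mild", "moderate", "severe"),
                         template = default_template("BPW"),
                         mean_heart_period_s = 0.85,
                         period_jitter_cv = 0.03,
                         template_jitter_cv = 0.02,
                         drift_amplitude = 0.3,
                         drift_frequency_hz = 0.004,
                         noise_sd = 0.01,
                         channel = c("BPW", "PPG")) {
  label <- match.arg(label)
  severity <- match.arg(severity)
  channel <- match.arg(channel)
  stopifnot(inherits(template, "harmonic_template"))
  stopifnot_scalar(mean_heart_period_s, "mean_heart_period_s", 0.4, 2.0)
  stopifnot_scalar(period_jitter_cv, "period_jitter_cv", 0)
  stopifnot_scalar(template_jitter_cv, "template_jitter_cv", 0)
  stopifnot_scalar(drift_amplitude, "drift_amplitude", 0)
  stopifnot_scalar(drift_frequency_hz, "drift_frequency_hz", 0, 0.01 - 1e-12)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  structure(list(subject_id = as.character(subject_id), label = label,
                 severity = severity, template = template,
                 mean_heart_period_s = mean_heart_period_s,
                 period_jitter_cv = period_jitter_cv,
                 template_jitter_cv = template_jitter_cv,
                 drift_amplitude = drift_amplitude,
                 drift_frequency_hz = drift_frequency_hz,
                 noise_sd = noise_sd, channel = channel),
            class = "subject_spec")
}

#' Raw recording container
#'
#' @param samples numeric vector of signal values (no missing values).
#' @param sampling_rate_hz sampling rate, default 1024.
#' @param channel,subject_id,label,severity metadata.
#' @return an object of class `pulse_recording`.
#' @export
pulse_recording <- function(samples, sampling_rate_hz = 1024,
                            channel = "BPW", subject_id = "S1",
                            label = "unknown", severity = "none") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("recording needs at least 2 samples")
  if (any(!is.finite(samples))) stop("recording contains missing/non-finite values")
  stopifnot_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 channel = channel, subject_id = as.character(subject_id),
                 label = label, severity = severity),
            class = "pulse_recording")
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat(sprintf("<pulse_recording> %s [%s/%s/%s]: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel, x$label, x$severity,
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Synthesize a labeled recording with ground-truth foot indices
#'
#' Concatenates jittered, foot-aligned beats, adds sinusoidal baseline
#' drift and white sensor noise. Bit-identical output for identical
#' `(spec, duration_s, seed)`.
#'
#' @param spec a [subject_spec()].
#' @param duration_s recording duration in seconds.
#' @param seed integer seed.
#' @param sampling_rate_hz sampling rate (default 1024 Hz).
#' @return a [pulse_recording()] with attributes: `feet` (1-based sample
#'   indices of each complete beat's onset), `beat_lengths` (samples per
#'   beat), `spec` (the generating subject specification).
#' @export
synth_recording <- function(spec, duration_s = 180, seed = 1,
                            sampling_rate_hz = 1024) {
  stopifnot(inherits(spec, "subject_spec"))
  stopifnot_scalar(duration_s, "duration_s", lower = 1e-9)
  fs <- sampling_rate_hz
  n <- as.integer(round(duration_s * fs))
  with_seed(seed, {
    cv <- spec$period_jitter_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(spec$mean_heart_period_s) - sdlog^2 / 2
    beats <- list(); feet <- integer(); klens <- integer()
    pos <- 0L
    # anchor value: jittered beats are shifted so each beat's diastolic
    # minimum equals the subject template's, keeping the assembled trace
    # continuous at the beat junctions (beat-to-beat shape jitter would
    # otherwise leave small steps there)
    anchor <- if (spec$template_jitter_cv > 0)
      min(synth_pulse(spec$template,
                      max(32L, as.integer(round(spec$mean_heart_period_s * fs)))))
    else NULL
    repeat {
      period <- if (cv > 0) rlnorm(1, meanlog, sdlog) else spec$mean_heart_period_s
      k <- max(32L, as.integer(round(period * fs)))
      tpl <- spec$template
      if (spec$template_jitter_cv > 0) {
        tj <- spec$template_jitter_cv
        amp <- pmax(0, tpl$amp_proportions * (1 + rnorm(10, 0, tj)))
        ph <- tpl$phases + rnorm(10, 0, 100 * tj)
        tpl <- harmonic_template(tpl$dc_level, amp, ph)
      }
      x <- synth_pulse(tpl, k, align_foot = TRUE)
      if (!is.null(anchor)) x <- x - min(x) + anchor
      if (pos + k > n) {             # final partial beat, truncated
        if (n - pos > 0L) beats[[length(beats) + 1L]] <- x[1:(n - pos)]
        break
      }
      beats[[length(beats) + 1L]] <- as.numeric(x)
      feet <- c(feet, pos + 1L)
      klens <- c(klens, k)
      pos <- pos + k
    }
    samples <- unlist(beats, use.names = FALSE)
    if (length(samples) < n) samples <- c(samples, rep(spec$template$dc_level,
                                                       n - length(samples)))
    # ground-truth feet: the diastolic minima of the clean assembled
    # waveform. Under beat-to-beat jitter the junction valley's true
    # minimum can sit a few samples off the concatenation boundary, so
    # each foot is refined to the local argmin around its boundary.
    wref <- max(1L, as.integer(round(0.04 * fs)))
    feet <- vapply(feet, function(b) {
      lo <- max(1L, b - wref); hi <- min(length(samples), b + wref)
      lo + which.min(samples[lo:hi]) - 1L
    }, integer(1))
    tvec <- (0:(n - 1L)) / fs
    if (spec$drift_amplitude > 0) {
      drift_phase <- runif(1, 0, 2 * pi)
      samples <- samples + spec$drift_amplitude *
        sin(2 * pi * spec$drift_frequency_hz * tvec + drift_phase)
    }
    if (spec$noise_sd > 0) samples <- samples + rnorm(n, 0, spec$noise_sd)
    rec <- pulse_recording(samples, fs, spec$channel, spec$subject_id,
                           spec$label, spec$severity)
    attr(rec, "feet") <- feet
    attr(rec, "beat_lengths") <- klens
    attr(rec, "spec") <- spec
    rec
  })
}

#' Cohort configuration
#'
#' Describes a synthetic study cohort: cell sizes, the between-subject
#' template distribution and the group effect added to AD subjects'
#' templates.
#'
#' @param n_per_group named integer vector of subjects per cell; names
#'   from `control`, `AD`, `mild`, `moderate`, `severe` (the three
#'   severity names imply label `AD`; `AD` alone means severity `none`).
#' @param effect_amp additive offsets (percentage points) applied to AD
#'   subjects' template amplitude proportions, length 10.
#' @param effect_phase additive offsets (degrees) applied to AD
#'   subjects' template phases, length 10.
#' @param severity_scale multipliers applied to the effect for the three
#'   AD severity grades.
#' @param template_mean,template_sd between-subject distribution of
#'   amplitude proportions (percent): subject templates are drawn as
#'   `N(template_mean, template_sd)` truncated at 0.
#' @param phase_sd between-subject sd of template phases (degrees).
#' @param dc_cv between-subject lognormal CV of `dc_level`.
#' @param period_mean_s,period_sd_s,period_range_s between-subject
#'   distribution of the mean heart period (truncated normal); the
#'   default range keeps 3-min beat counts within 180-250.
#' @param duration_s recording length per subject (seconds).
#' @param channel `"BPW"` or `"PPG"`.
#' @param sampling_rate_hz sampling rate.
#' @param seed master seed for the cohort.
#' @param ... overrides passed to [subject_spec()] (jitter/noise/drift).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(control = 20, AD = 20),
                          effect_amp = rep(0, 10),
                          effect_phase = rep(0, 10),
                          severity_scale = c(mild = 0.5, moderate = 1, severe = 1.5),
                          template_mean = NULL,
                          template_sd = NULL,
                          phase_sd = 3,
                          dc_cv = 0.1,
                          period_mean_s = 0.85, period_sd_s = 0.06,
                          period_range_s = c(0.73, 0.99),
                          duration_s = 180,
                          channel = c("BPW", "PPG"),
                          sampling_rate_hz = 1024,
                          seed = 1, ...) {
  channel <- match.arg(channel)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("`n_per_group` must be a named vector")
  ok <- c("control", "AD", "mild", "moderate", "severe")
  if (!all(names(n_per_group) %in% ok))
    stop("`n_per_group` names must be among: ", paste(ok, collapse = ", "))
  if (any(n_per_group < 1)) stop("every used group cell needs >= 1 subject")
  if (is.null(template_mean)) template_mean <- .template_defaults[[channel]]$amp
  if (is.null(template_sd)) template_sd <- 0.10 * template_mean
  if (length(template_mean) != 10L || length(template_sd) != 10L ||
      any(template_sd < 0))
    stop("template distribution needs 10 means and 10 non-negative SDs")
  if (length(effect_amp) != 10L || length(effect_phase) != 10L)
    stop("group effects must have 10 entries")
  structure(list(n_per_group = n_per_group, effect_amp = as.numeric(effect_amp),
                 effect_phase = as.numeric(effect_phase),
                 severity_scale = severity_scale,
                 template_mean = template_mean, template_sd = template_sd,
                 phase_sd = phase_sd, dc_cv = dc_cv,
                 period_mean_s = period_mean_s, period_sd_s = period_sd_s,
                 period_range_s = period_range_s,
                 duration_s = duration_s, channel = channel,
                 sampling_rate_hz = sampling_rate_hz, seed = seed,
                 subject_args = list(...)),
            class = "cohort_config")
}

#' Group effect expressed in pooled-SD units
#'
#' Convenience: sets the generator's group effect — additive offsets on
#' AD subjects' template amplitude proportions *and* phases for the
#' chosen harmonics — to the given multiple of the respective
#' between-subject SDs.
#'
#' @param config a [cohort_config()].
#' @param sd_units effect magnitude in pooled-SD units.
#' @param harmonics harmonic numbers to shift (default 2:4).
#' @return the config with `effect_amp` and `effect_phase` set.
#' @export
cohort_effect <- function(config, sd_units, harmonics = 2:4) {
  stopifnot(inherits(config, "cohort_config"))
  ea <- rep(0, 10); ep <- rep(0, 10)
  ea[harmonics] <- sd_units * config$template_sd[harmonics]
  ep[harmonics] <- sd_units * config$phase_sd
  config$effect_amp <- ea
  config$effect_phase <- ep
  config
}

#' Generate a labeled synthetic cohort
#'
#' Draws one subject template per subject from the configured
#' distribution (AD subjects get the group effect, scaled by severity),
#' then synthesizes one recording per subject.
#'
#' @param config a [cohort_config()].
#' @return an object of class `pulse_cohort`: list with `recordings`
#'   (list of [pulse_recording()] with ground-truth attributes),
#'   `manifest` (data.frame: subject_id, label, severity) and `truth`
#'   (per-subject generating parameters).
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cells <- names(config$n_per_group)
  subj <- data.frame(label = character(), severity = character(),
                     stringsAsFactors = FALSE)
  for (cell in cells) {
    nc <- config$n_per_group[[cell]]
    lab <- if (cell == "control") "control" else "AD"
    sev <- if (cell %in% c("mild", "moderate", "severe")) cell else "none"
    subj <- rbind(subj, data.frame(label = rep(lab, nc),
                                   severity = rep(sev, nc)))
  }
  subj$subject_id <- sprintf("S%03d", seq_len(nrow(subj)))
  recs <- vector("list", nrow(subj))
  truth <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    sseed <- derive_seed(config$seed, paste0("subject", i))
    sp <- with_seed(sseed, {
      amp <- pmax(0, rnorm(10, config$template_mean, config$template_sd))
      ph <- wrap_deg(rnorm(10, .template_defaults[[config$channel]]$phase,
                           config$phase_sd))
      if (subj$label[i] == "AD") {
        sc <- if (subj$severity[i] %in% names(config$severity_scale))
          config$severity_scale[[subj$severity[i]]] else 1
        amp <- pmax(0, amp + sc * config$effect_amp)
        ph <- wrap_deg(ph + sc * config$effect_phase)
      }
      dc <- if (config$dc_cv > 0) rlnorm(1, log(1) - log(1 + config$dc_cv^2) / 2,
                                         sqrt(log(1 + config$dc_cv^2))) else 1
      mp <- min(max(rnorm(1, config$period_mean_s, config$period_sd_s),
                    config$period_range_s[1]), config$period_range_s[2])
      do.call(subject_spec,
              c(list(subject_id = subj$subject_id[i], label = subj$label[i],
                     severity = subj$severity[i],
                     template = harmonic_template(dc, amp, ph),
                     mean_heart_period_s = mp, channel = config$channel),
                config$subject_args))
    })
    recs[[i]] <- synth_recording(sp, config$duration_s,
                                 seed = derive_seed(config$seed, paste0("rec", i)),
                                 sampling_rate_hz = config$sampling_rate_hz)
    truth[[i]] <- sp
  }
  names(recs) <- subj$subject_id
  names(truth) <- subj$subject_id
  structure(list(recordings = recs,
                 manifest = subj[, c("subject_id", "label", "severity")],
                 truth = truth, config = config),
            class = "pulse_cohort")
}

#' @export
print.pulse_cohort <- function(x, ...) {
  cat(sprintf("<pulse_cohort> %d subjects (%s), %g s @ %g Hz, channel %s\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$label)),
                            table(x$manifest$label)), collapse = ", "),
              x$config$duration_s, x$config$sampling_rate_hz,
              x$config$channel))
  invisible(x)
}
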