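# Shared fixtures, built in code at test time.

# Direct-summation Fourier oracle: plain O(k * n) loops, independent of
# the fft-based implementation path.
oracle_fourier <- function(x, n_max = 10) {
  k <- length(x)
  A <- numeric(n_max + 1)
  B <- numeric(n_max + 1)
  for (n in 0:n_max) {
    sa <- 0
    sb <- 0
    for (s in 0:(k - 1)) {
      sa <- sa + x[s + 1] * cos(2 * pi * n * s / k)
      sb <- sb + x[s + 1] * sin(2 * pi * n * s / k)
    }
    A[n + 1] <- 2 * sa / k
    B[n + 1] <- 2 * sb / k
  }
  B[1] <- 0
  list(A = A, B = B)
}

# A small noise-free subject (no jitter/drift/noise) for exact checks.
clean_spec <- function(...) {
  subject_spec(period_jitter_cv = 0, template_jitter_cv = 0,
               drift_amplitude = 0, noise_sd = 0, ...)
}

# Random but valid harmonic template.
random_template <- function(seed) {
  set.seed(seed)
  harmonic_template(dc_level = runif(1, 0.5, 2),
                    amp_proportions = runif(10, 0, 40),
                    phases = runif(10, -179, 180))
}

# A quick two-subject feature table with a controllable mean shift,
# bypassing the waveform pipeline (for classifier/feature unit tests).
toy_features <- function(n_subj_per_class = 6, rows_per_subj = 30,
                         shift = 0, seed = 1) {
  set.seed(seed)
  fc <- feature_columns()
  out <- list()
  id <- 0
  for (lab in c("control", "AD")) {
    for (s in seq_len(n_subj_per_class)) {
      id <- id + 1
      mu <- rnorm(40, 0, 1) + if (lab == "AD") shift else 0
      X <- matrix(rnorm(rows_per_subj * 40, 0, 1), rows_per_subj, 40) +
        matrix(mu, rows_per_subj, 40, byrow = TRUE)
      df <- data.frame(subject_id = sprintf("T%02d", id), label = lab,
                       severity = "none", channel = "BPW",
                       window_start_beat = seq_len(rows_per_subj))
      df[, fc] <- X
      out[[id]] <- df
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
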