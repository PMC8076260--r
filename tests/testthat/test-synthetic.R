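test_that("synth_pulse handles the degenerate and single-harmonic cases", {
  flat <- harmonic_template(1.3, rep(0, 10), rep(0, 10))
  expect_equal(synth_pulse(flat, 64, align_foot = FALSE),
               rep(1.3, 64), ignore_attr = TRUE)

  one <- harmonic_template(2, c(100, rep(0, 9)), rep(0, 10))
  x <- synth_pulse(one, 128, align_foot = FALSE)
  # constant term plus a single cosine of one full cycle, max at sample 0
  expect_equal(which.max(x), 1L)
  s <- 0:127
  expect_equal(as.numeric(x), 2 + 2 * 2 * cos(2 * pi * s / 128),
               tolerance = 1e-12)

  expect_error(synth_pulse(flat, 20), "32 samples")
})

test_that("synth_pulse round-trips through spectral extraction", {
  for (seed in 1:5) {
    tpl <- random_template(seed)
    x <- synth_pulse(tpl, 64 + 17 * seed, align_foot = FALSE)
    idx <- amplitude_proportions(amp_phase(
      fourier_coefficients(x, baseline_mode = "none")))
    expect_equal(idx$C, tpl$amp_proportions, tolerance = 1e-9)
    nz <- tpl$amp_proportions > 1e-6
    expect_lt(max(abs(pulsespec:::wrap_deg(idx$P[nz] - tpl$phases[nz]))), 1e-9)
  }
})

test_that("synth_recording is deterministic and annotates every complete beat", {
  spc <- clean_spec(mean_heart_period_s = 1.0)
  rec <- synth_recording(spc, 180, seed = 5)
  # duration / period beats, +-1 for the trailing partial beat
  expect_true(abs(length(attr(rec, "feet")) - 180) <= 1)
  expect_equal(length(rec$samples), 180 * 1024)

  rec2 <- synth_recording(spc, 180, seed = 5)
  expect_identical(rec$samples, rec2$samples)
  expect_identical(attr(rec, "feet"), attr(rec2, "feet"))

  rec3 <- synth_recording(spc, 180, seed = 6)
  expect_identical(rec$samples, rec3$samples)  # no randomness left when clean
})

test_that("with no jitter each inter-foot segment equals the synthesized beat", {
  spc <- clean_spec(mean_heart_period_s = 0.5)
  rec <- synth_recording(spc, 10, seed = 1)
  feet <- attr(rec, "feet")
  k <- attr(rec, "beat_lengths")[1]
  beat <- as.numeric(synth_pulse(spc$template, k))
  segs <- extract_pulses(rec, feet)
  for (sg in segs) expect_equal(sg$samples, beat)
})

test_that("synth_cohort produces the configured cells and retains ground truth", {
  cfg <- cohort_config(n_per_group = c(control = 3, mild = 2, severe = 1),
                       duration_s = 20, seed = 3)
  ch <- synth_cohort(cfg)
  expect_equal(nrow(ch$manifest), 6)
  expect_equal(sum(ch$manifest$label == "AD"), 3)
  expect_equal(sort(unique(ch$manifest$severity[ch$manifest$label == "AD"])),
               c("mild", "severe"))
  expect_length(ch$recordings, 6)
  expect_s3_class(ch$truth[[1]], "subject_spec")
  expect_error(cohort_config(n_per_group = c(control = 0, AD = 3)), ">= 1")
})

test_that("beat counts under default cohort settings stay within 180-250 per 3 min", {
  cfg <- cohort_config(n_per_group = c(control = 4, AD = 4), seed = 9)
  ch <- synth_cohort(cfg)
  for (rec in ch$recordings) {
    nb <- length(attr(rec, "feet"))
    expect_gte(nb, 180)
    expect_lte(nb, 250)
  }
})

test_that("group effect shifts extracted C3 by the injected amount", {
  # parameter recovery: +5 percentage points on C3, extraction through
  # ground-truth feet without filtering (generator correctness check)
  eff <- rep(0, 10); eff[3] <- 5
  cfg <- cohort_config(n_per_group = c(control = 30, AD = 30),
                       effect_amp = eff, duration_s = 30,
                       drift_amplitude = 0, seed = 17)
  ch <- synth_cohort(cfg)
  m <- sapply(names(ch$recordings), function(id) {
    b <- extract_indices(ch$recordings[[id]], fspec = NULL, feet = "truth",
                         baseline_mode = "none")
    mean(b$C3)
  })
  lab <- ch$manifest$label[match(names(m), ch$manifest$subject_id)]
  diff_c3 <- mean(m[lab == "AD"]) - mean(m[lab == "control"])
  expect_lt(abs(diff_c3 - 5), 1)   # within 20 % of the injected 5 points

  # null configuration: difference within 3 SEM
  cfg0 <- cohort_config(n_per_group = c(control = 30, AD = 30),
                        duration_s = 30, drift_amplitude = 0, seed = 18)
  ch0 <- synth_cohort(cfg0)
  m0 <- sapply(names(ch0$recordings), function(id) {
    b <- extract_indices(ch0$recordings[[id]], fspec = NULL, feet = "truth",
                         baseline_mode = "none")
    mean(b$C3)
  })
  lab0 <- ch0$manifest$label[match(names(m0), ch0$manifest$subject_id)]
  d0 <- mean(m0[lab0 == "AD"]) - mean(m0[lab0 == "control"])
  sem <- sqrt(var(m0[lab0 == "AD"]) / 30 + var(m0[lab0 == "control"]) / 30)
  expect_lt(abs(d0), 3 * sem)
})

test_that("recordings round-trip through the CSV + JSON sidecar format", {
  dir <- withr::local_tempdir()
  spc <- subject_spec(subject_id = "X9", label = "AD", severity = "mild")
  rec <- synth_recording(spc, 5, seed = 2)
  p <- file.path(dir, "x9.csv")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$subject_id, "X9")
  expect_equal(back$label, "AD")
  expect_identical(attr(back, "feet"), attr(rec, "feet"))

  cfg <- cohort_config(n_per_group = c(control = 2, AD = 2), duration_s = 5,
                       seed = 4)
  ch <- synth_cohort(cfg)
  write_cohort(ch, file.path(dir, "cohort"))
  ch2 <- read_cohort(file.path(dir, "cohort"))
  expect_equal(ch2$manifest$subject_id, ch$manifest$subject_id)
  expect_equal(ch2$recordings[[1]]$samples, ch$recordings[[1]]$samples,
               tolerance = 1e-12)
})
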