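test_that("realized high-pass has zero DC gain and the specified band behaviour", {
  filt <- design_highpass(filter_spec(), 1024)
  r <- filter_response(filt, c(0, 0.001, 0.01, 1, 10), effective = FALSE)
  expect_equal(r$magnitude[1], 0)                    # high-pass definition
  expect_lt(r$gain_db[2], -40)                       # deep stopband at 0.001 Hz
  # cutoff and passband within the configured 0.5 dB ripple of unity
  expect_gt(r$gain_db[3], -0.5 - 1e-5)
  expect_true(all(abs(r$gain_db[4:5]) <= 0.5 + 1e-5))
  # stable poles
  for (s in filt$sos) {
    roots <- polyroot(rev(s$a[s$a != 0 | c(TRUE, TRUE, FALSE)]))
    expect_true(all(Mod(roots) < 1))
  }
})

test_that("SOS design agrees with an independent filter-design oracle", {
  skip_if_not_installed("signal")
  # low order and a high cutoff, where the direct-form (b, a) design of
  # signal::cheby1 is numerically sound and provides an independent path
  fs <- 1024
  ref <- signal::cheby1(4, 0.5, 20 / (fs / 2), type = "high")
  mine <- design_highpass(filter_spec(order = 4, cutoff_hz = 20), fs)
  f <- c(0.5, 2, 5, 10, 20, 50, 200, 450)
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  pw <- -(seq_along(ref$b) - 1)
  href <- vapply(seq_along(z), function(i)
    abs(sum(ref$b * z[i]^pw) / sum(ref$a * z[i]^pw)), numeric(1))
  hmine <- filter_response(mine, f, effective = FALSE)$magnitude
  expect_equal(hmine, href, tolerance = 1e-9)
})

test_that("filtering rejects DC, is linear, and attenuates per the realized response", {
  spc <- clean_spec()
  rec <- synth_recording(spc, 30, seed = 1)
  fs <- rec$sampling_rate_hz

  const <- pulse_recording(rep(3.7, 30 * fs), fs)
  out <- apply_filter(const)
  expect_lt(max(abs(out$samples)), 3.7 * 1e-6)

  # linearity on the same filter
  ra <- pulse_recording(rec$samples, fs)
  rb <- pulse_recording(rev(rec$samples), fs)
  fa <- apply_filter(ra)$samples
  fb <- apply_filter(rb)$samples
  mixed <- pulse_recording(2.5 * ra$samples - 1.25 * rb$samples, fs)
  fm <- apply_filter(mixed)$samples
  expect_equal(fm, 2.5 * fa - 1.25 * fb, tolerance = 1e-9)

  # two-tone: passband tone preserved, stopband tone removed
  tt <- (0:(180 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * tt) + 2 * sin(2 * pi * 0.005 * tt)
  f <- apply_filter(pulse_recording(x, fs))$samples
  # the 11th-order filter rings for tens of seconds at stopband-edge
  # frequencies, so judge the steady-state core only
  core <- f[(60 * fs):(120 * fs)]
  tone1 <- sin(2 * pi * 1 * tt)[(60 * fs):(120 * fs)]
  resid <- core - tone1
  # 1 Hz amplitude preserved within ripple; 0.005 Hz tone strongly reduced
  expect_lt(sqrt(mean(resid^2)), 0.05 * sqrt(mean(tone1^2)))
})

test_that("filter output is finite and length-preserving; short input is rejected", {
  spc <- subject_spec()
  rec <- synth_recording(spc, 60, seed = 2)
  out <- apply_filter(rec)
  expect_length(out$samples, length(rec$samples))
  expect_true(all(is.finite(out$samples)))
  expect_identical(out$subject_id, rec$subject_id)
  expect_error(apply_filter(pulse_recording(rnorm(10), 1024)), "too short")
})

test_that("one-pass mode flags edge transients, zero-phase does not delay feet", {
  spc <- clean_spec()
  rec <- synth_recording(spc, 30, seed = 3)
  one <- apply_filter(rec, filter_spec(mode = "one_pass"))
  expect_true(any(attr(one, "transient_mask")))
  zp <- apply_filter(rec)
  expect_false(any(attr(zp, "transient_mask")))
  # zero-phase: feet of the filtered signal coincide with ground truth
  ft <- detect_feet(zp)$indices
  gt <- attr(rec, "feet")
  d <- vapply(gt, function(g) min(abs(ft - g)), numeric(1))
  expect_lt(max(d), 3)
})
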