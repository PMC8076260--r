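test_that("fourier_coefficients matches hand-computable cases", {
  # constant beat: only the DC coefficient survives
  sp <- fourier_coefficients(rep(2.5, 64), baseline_mode = "none")
  expect_equal(sp$A[1], 5)                     # A0 = twice the mean
  expect_lt(max(abs(sp$A[-1])), 1e-12)
  expect_lt(max(abs(sp$B)), 1e-12)

  k <- 96; s <- 0:(k - 1)
  sp1 <- fourier_coefficients(cos(2 * pi * s / k), baseline_mode = "none")
  expect_equal(sp1$A[2], 1, tolerance = 1e-12)
  expect_lt(max(abs(sp1$B)), 1e-12)
  expect_lt(max(abs(sp1$A[-2])), 1e-12)

  sp2 <- fourier_coefficients(0.5 + 0.3 * sin(2 * pi * s / k),
                              baseline_mode = "none")
  expect_equal(sp2$A[1], 1, tolerance = 1e-12)
  expect_equal(sp2$B[2], 0.3, tolerance = 1e-12)
  expect_lt(abs(sp2$A[2]), 1e-12)

  expect_error(fourier_coefficients(rnorm(20), n_max = 10), "too short")
})

test_that("fft path agrees with the direct-summation oracle on random beats", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- rnorm(40 + sample(200, 1), sd = 2) + 3
    sp <- fourier_coefficients(x, baseline_mode = "none")
    or <- oracle_fourier(x)
    expect_equal(sp$A, or$A, tolerance = 1e-10)
    expect_equal(sp$B, or$B, tolerance = 1e-10)
  }
})

test_that("min_zero baseline mode subtracts the beat minimum before the transform", {
  set.seed(1)
  x <- rnorm(128) - 5                    # negative-mean beat (post-filter)
  sp <- fourier_coefficients(x)
  or <- oracle_fourier(x - min(x))
  expect_equal(sp$A, or$A, tolerance = 1e-10)
  expect_gt(sp$A[1], 0)
})

test_that("amp_phase implements the two-argument arctangent convention", {
  sp <- structure(list(A = c(1, 3, 1, -1, 0), B = c(0, 4, 1, 0, 0),
                       k = 64, n_max = 4, baseline_mode = "none"),
                  class = "harmonic_spectrum")
  sp <- amp_phase(sp)
  expect_equal(sp$Amp, c(1, 5, sqrt(2), 1, 0))
  expect_equal(sp$P[1], 53.13010235, tolerance = 1e-7)  # 3-4-5 triangle
  expect_equal(sp$P[2], 45)
  expect_equal(sp$P[3], 180)            # quadrant case: (-1, 0)
  expect_equal(sp$P[4], 0)              # degenerate harmonic, flagged
  expect_true(sp$P_degenerate[4])
  expect_true(all(sp$P > -180 & sp$P <= 180))
})

test_that("amplitude proportions are direct ratios and scale invariant", {
  sp <- structure(list(A = c(2, 1, rep(0, 9)), B = rep(0, 11),
                       k = 64, n_max = 10, baseline_mode = "none"),
                  class = "harmonic_spectrum")
  idx <- amplitude_proportions(sp)
  expect_equal(idx$C, c(50, rep(0, 9)))

  tpl <- random_template(3)
  x <- synth_pulse(tpl, 150, align_foot = FALSE)
  i1 <- amplitude_proportions(amp_phase(fourier_coefficients(x, baseline_mode = "none")))
  i2 <- amplitude_proportions(amp_phase(fourier_coefficients(3.7 * x, baseline_mode = "none")))
  expect_equal(i1$C, i2$C, tolerance = 1e-12)
  expect_equal(i1$P, i2$P, tolerance = 1e-12)

  # degenerate DC rejected
  expect_error(amplitude_proportions(amp_phase(
    fourier_coefficients(sin(2 * pi * 0:63 / 64), baseline_mode = "none"))),
    "degenerate")
})

test_that("rotating the beat start shifts phases by n*d/k*360 degrees", {
  tpl <- random_template(5)
  k <- 200
  x <- synth_pulse(tpl, k, align_foot = FALSE)
  d <- 17
  xr <- c(x[(d + 1):k], x[1:d])
  p0 <- amplitude_proportions(amp_phase(fourier_coefficients(x, baseline_mode = "none")))
  pr <- amplitude_proportions(amp_phase(fourier_coefficients(xr, baseline_mode = "none")))
  expected <- pulsespec:::wrap_deg(p0$P - (1:10) * d / k * 360)
  expect_lt(max(abs(pulsespec:::wrap_deg(pr$P - expected))), 1e-8)
  expect_equal(pr$C, p0$C, tolerance = 1e-10)
})

test_that("beat_indices produces one labeled row per analyzable beat", {
  spc <- subject_spec(subject_id = "B1", label = "AD", severity = "moderate")
  rec <- synth_recording(spc, 30, seed = 6)
  b <- beat_indices(rec, attr(rec, "feet"))
  expect_equal(nrow(b), length(attr(rec, "feet")) - 1)
  expect_true(all(c("C1", "C10", "P1", "P10", "k") %in% names(b)))
  expect_true(all(b$label == "AD"))
  expect_true(all(b$C1 >= 0))
})
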