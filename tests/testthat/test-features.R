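test_that("windowed variability matches brute-force recomputation on every window", {
  set.seed(11)
  nb <- 60
  beats <- data.frame(matrix(abs(rnorm(nb * 10, 20, 5)), nb, 10))
  names(beats) <- paste0("C", 1:10)
  ph <- matrix(runif(nb * 10, -170, 170), nb, 10)
  colnames(ph) <- paste0("P", 1:10)
  beats <- cbind(beats, ph)
  w <- windowed_variability(beats, window = 15)
  expect_equal(nrow(w), nb - 14)
  for (wi in seq_len(nrow(w))) {          # exhaustive, not sampled
    rows <- wi:(wi + 14)
    for (n in 1:10) {
      cv_ref <- sd(beats[rows, paste0("C", n)]) /
        mean(beats[rows, paste0("C", n)]) * 100
      expect_equal(w[wi, paste0("CV", n)], cv_ref, tolerance = 1e-12)
      p <- beats[rows, paste0("P", n)]
      if (diff(range(p)) < 180)           # no wrap: plain linear SD
        expect_equal(w[wi, paste0("P", n, "_SD")], sd(p), tolerance = 1e-12)
    }
  }
})

test_that("constant beat series yields zero variability", {
  beats <- data.frame(matrix(5, 20, 20))
  names(beats) <- c(paste0("C", 1:10), paste0("P", 1:10))
  w <- windowed_variability(beats)
  expect_equal(nrow(w), 6)
  expect_true(all(as.matrix(w[, -1]) == 0))
})

test_that("phase dispersion is immune to the +-180 degree branch cut", {
  # phases clustered around the cut: +/-178 with 4 degrees spread
  beats <- data.frame(matrix(20, 15, 10))
  names(beats) <- paste0("C", 1:10)
  set.seed(2)
  raw <- 178 + rnorm(15, 0, 2)            # spills past 180
  wrapped <- pulsespec:::wrap_deg(raw)
  for (n in 1:10) beats[[paste0("P", n)]] <- wrapped
  w <- windowed_variability(beats)
  expect_equal(w$P1_SD, sd(raw), tolerance = 1e-9)   # same as unwrapped SD
  expect_lt(w$P1_SD, 5)                    # a naive linear SD would be ~180
})

test_that("fewer than 15 beats excludes the subject", {
  beats <- data.frame(matrix(runif(14 * 20, 10, 30), 14, 20))
  names(beats) <- c(paste0("C", 1:10), paste0("P", 1:10))
  expect_error(windowed_variability(beats), "at least 15")
})

test_that("assemble_features lays out the 40 columns in canonical order", {
  spc <- subject_spec(subject_id = "F1")
  rec <- synth_recording(spc, 30, seed = 7)
  b <- beat_indices(rec, attr(rec, "feet"))
  f <- assemble_features(b)
  expect_equal(nrow(f), nrow(b) - 14)
  fc <- feature_columns()
  expect_identical(names(f)[-(1:5)], fc)
  # column C1 equals the window's first beat; CV1 the window statistic
  expect_equal(f$C1[1], b$C1[1])
  expect_equal(f$C1[3], b$C1[3])
  w <- windowed_variability(b)
  expect_equal(f$CV1, w$CV1)
  # minimal case: exactly 15 beats -> one row
  f1 <- assemble_features(b[1:15, ])
  expect_equal(nrow(f1), 1)
  expect_true(all(is.finite(as.matrix(f1[, fc]))))
})

test_that("Z-score normalization fits on training rows only and round-trips", {
  f <- toy_features(seed = 5)
  train_ids <- sprintf("T%02d", 1:8)
  tr <- f[f$subject_id %in% train_ids, ]
  nm <- normalize_fit(tr)
  trn <- normalize_apply(nm, tr)
  X <- as.matrix(trn[, feature_columns()])
  expect_lt(max(abs(colMeans(X))), 1e-9)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-9)

  # model parameters are independent of test rows
  nm_all <- normalize_fit(f)
  expect_false(isTRUE(all.equal(nm$mean, nm_all$mean)))

  # a row at the training mean maps to zero
  row0 <- tr[1, ]
  row0[, feature_columns()] <- as.list(nm$mean)
  z <- normalize_apply(nm, row0)
  expect_lt(max(abs(as.numeric(z[, feature_columns()]))), 1e-12)

  # applying with the stored model is not a silent re-fit
  twice <- normalize_apply(nm, trn)
  expect_false(isTRUE(all.equal(twice[, "C1"], trn[, "C1"])))

  # constant feature rejected with the column named
  bad <- tr
  bad$CV3 <- 1
  expect_error(normalize_fit(bad), "CV3")

  # JSON round-trip
  p <- file.path(withr::local_tempdir(), "norm.json")
  write_normalization(nm, p)
  back <- read_normalization(p)
  expect_equal(back$mean, nm$mean, tolerance = 1e-12)
  expect_equal(back$sd, nm$sd, tolerance = 1e-12)
})
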