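test_that("LPC recovers planted autoregressive coefficients", {
  # AR(2) with conjugate poles at radius 0.95, 300 Hz for an 8 kHz rate
  set.seed(101)
  x <- as.numeric(stats::arima.sim(list(ar = c(1.8479, -0.9025)), 8000))
  fit <- lpc_fit(x, order = 2L, taper = "rectangular")
  expect_equal(fit$coefficients, c(1.8479, -0.9025), tolerance = 0.02)
  expect_true(fit$stable)
  # agreement with the direct normal-equations oracle on the same frame
  expect_equal(fit$coefficients, lpc_oracle(x, 2L), tolerance = 1e-10)
})

test_that("LPC on white noise finds no structure", {
  set.seed(102)
  x <- rnorm(4096)
  fit <- lpc_fit(x, order = 8L, taper = "rectangular")
  expect_lt(max(abs(fit$coefficients)), 0.1)
  # prediction-error power ~ input variance (rectangular taper)
  expect_equal(fit$gain^2 / length(x), var(x), tolerance = 0.1)
  expect_equal(fit$coefficients, lpc_oracle(x, 8L), tolerance = 1e-8)
})

test_that("degenerate frames are rejected", {
  expect_error(lpc_fit(rep(0, 100), 8L), "degenerate")
  expect_error(lpc_fit(rep(3.2, 100), 8L), "degenerate")
  expect_error(lpc_fit(rnorm(8), 8L), "exceed")
})

test_that("planted pole pairs convert to the expected formants", {
  fit <- planted_fit(0.95, 300, rate = 8000)
  fm <- formants_from_fit(fit, 8000)
  expect_equal(nrow(fm), 1)
  expect_equal(fm$frequency, 300, tolerance = 1e-6)

  fit2 <- planted_fit(c(0.98, 0.90), c(300, 1200), rate = 8000)
  fm2 <- formants_from_fit(fit2, 8000)
  expect_equal(fm2$frequency, c(300, 1200), tolerance = 1e-6)
  # envelope-evaluation oracle: amplitude = gain / |A(e^{iw})|
  a <- fit2$coefficients
  env <- function(f_hz) {
    w <- 2 * pi * f_hz / 8000
    1 / Mod(1 - sum(a * exp(-1i * w * seq_along(a))))
  }
  expect_equal(fm2$amplitude, c(env(300), env(1200)), tolerance = 1e-6)
  expect_gt(fm2$amplitude[1], fm2$amplitude[2])
})

test_that("real roots and sub-floor radii yield no formants", {
  # A(z) with all-real roots: product of (1 - r z^-1) terms
  coefs <- poly_from_poles(c(0.9, -0.8, 0.5, -0.3))
  fit <- structure(list(coefficients = -coefs[-1], gain = 1, order = 4L,
                        stable = TRUE), class = "lpc_fit")
  expect_equal(nrow(formants_from_fit(fit, 8000)), 0)

  weak <- planted_fit(0.5, 900, rate = 8000)        # below the 0.7 floor
  expect_equal(nrow(formants_from_fit(weak, 8000)), 0)
  expect_equal(nrow(formants_from_fit(weak, 8000, radius_floor = 0.4)), 1)
})

test_that("tracking a stationary tone stays on the tone", {
  set.seed(103)
  rec <- make_tone(440, duration = 20, rate = 8000, noise = 0.01)
  tr <- track_formants(rec)
  expect_equal(tr$n_frames, 625)
  grid_step <- 8000 / 256
  hit <- abs(tr$freqs[, 1] - 440) <= grid_step
  expect_gte(mean(hit, na.rm = TRUE), 0.95)
  # invariants: frequencies strictly inside (0, rate/2), rows sorted
  expect_true(all(tr$freqs > 0 & tr$freqs < 4000, na.rm = TRUE))
  sorted_ok <- apply(tr$freqs, 1, function(r) !is.unsorted(r[!is.na(r)]))
  expect_true(all(sorted_ok))
})

test_that("formant frequencies are gain-invariant", {
  set.seed(104)
  rec <- make_tone(600, duration = 1, rate = 8000, noise = 0.05)
  rec5 <- pcg_recording(rec$samples * 5, 8000)
  tr1 <- track_formants(rec)
  tr5 <- track_formants(rec5)
  # per-recording peak normalization makes the whole track identical
  expect_equal(tr1$freqs, tr5$freqs)
  expect_equal(tr1$amps, tr5$amps)
})

test_that("degenerate frames keep their rows with absent markers", {
  set.seed(105)
  x <- c(rnorm(256), rep(0, 512), rnorm(256))
  tr <- track_formants(pcg_recording(x, 8000))
  expect_equal(tr$n_frames, 4)
  expect_equal(tr$n_degenerate, 2)
  expect_true(all(is.na(tr$freqs[2:3, ])))
  expect_false(all(is.na(tr$freqs[1, ])))
})

test_that("formant estimates sharpen with frame length on an AR process", {
  set.seed(106)
  x <- as.numeric(stats::arima.sim(list(ar = c(1.8479, -0.9025)), 8192))
  err_for <- function(len) {
    frames <- matrix(x[seq_len((length(x) %/% len) * len)], nrow = len)
    errs <- apply(frames, 2, function(fr) {
      fm <- formants_from_fit(lpc_fit(fr, 2L, taper = "rectangular"), 8000)
      if (nrow(fm) == 0) return(NA_real_)
      abs(fm$frequency[1] - 300)
    })
    mean(errs, na.rm = TRUE)
  }
  expect_lt(err_for(512), err_for(128))
})

test_that("formant tracks round-trip through the text format", {
  set.seed(107)
  rec <- make_tone(440, duration = 0.5, rate = 8000, noise = 0.3)
  tr <- track_formants(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_formant_track(tr, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("time_s", "f1_hz", "f2_hz", "f3_hz", "f4_hz",
                         "a1", "a2", "a3", "a4"))
  back <- read_formant_track(path)
  expect_equal(back$freqs, tr$freqs, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$amps, tr$amps, tolerance = 1e-6, ignore_attr = TRUE)
})
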