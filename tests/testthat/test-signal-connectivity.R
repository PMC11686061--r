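test_that("FFT line filter zeroes contaminated lines and nothing else", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone63 <- sin(2 * pi * 63 * t)
  y <- fft_line_filter(tone63, fs, line_freqs = 63)
  expect_lt(sum(y^2), 1e-10 * sum(tone63^2))

  x <- rnorm(4000)
  expect_equal(fft_line_filter(x, fs, line_freqs = numeric(0)), x)

  mix <- sin(2 * pi * 10 * t) + sin(2 * pi * 63 * t)
  y <- fft_line_filter(mix, fs, line_freqs = 63)
  amp10 <- function(v) {
    2 * Mod(fft(v))[which.min(abs((seq_along(v) - 1) * fs / length(v) - 10))] /
      length(v)
  }
  expect_lt(abs(amp10(y) - 1), 0.01)

  expect_warning(fft_line_filter(x, fs, line_freqs = c(10, 20, 30, 40, 50, 63)),
                 "five")
  expect_error(fft_line_filter(x, fs, line_freqs = 600), "Nyquist")
})

test_that("zero-phase bandpass preserves in-band tones without delay", {
  fs <- 1000
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- bandpass(x, band_spec("alpha", 8, 12), fs)
  mid <- 1001:2000
  expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
  # no phase shift: cross-correlation peak at zero lag
  cc <- stats::ccf(x[mid], y[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("out-of-band attenuation matches the two-pass response", {
  fs <- 1000
  band <- band_spec("alpha", 8, 12)
  f_test <- 4 * band$hi
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f_test * t)
  y <- bandpass(x, band, fs)
  measured <- max(abs(y[4001:6000]))

  # closed-form two-pass magnitude from the designed transfer function
  flt <- dbsconnect:::butter_band(band, fs)
  H <- function(f) {
    z <- exp(1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^-(seq_along(flt$b) - 1)) /
          sum(flt$a * z^-(seq_along(flt$a) - 1)))
  }
  expect_lt(abs(measured - H(f_test)^2), 1e-3)

  # and against the analog Butterworth magnitude (order-2 prototype),
  # loosely, since the bilinear transform warps high frequencies
  wl <- 2 * pi * band$lo; wh <- 2 * pi * band$hi; w <- 2 * pi * f_test
  xi <- (w^2 - wl * wh) / (w * (wh - wl))
  analog_two_pass <- 1 / (1 + xi^4)
  expect_lt(abs(measured - analog_two_pass) / analog_two_pass, 0.3)
})

test_that("filtering twice changes an in-band tone within the ripple bound", {
  fs <- 1000
  band <- band_spec("beta", 12, 30)
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  y1 <- bandpass(x, band, fs)
  y2 <- bandpass(y1, band, fs)
  mid <- 2001:4000
  a1 <- max(abs(y1[mid])); a2 <- max(abs(y2[mid]))
  flt <- dbsconnect:::butter_band(band, fs)
  z <- exp(1i * 2 * pi * 20 / fs)
  Hmag <- Mod(sum(flt$b * z^-(seq_along(flt$b) - 1)) /
                sum(flt$a * z^-(seq_along(flt$a) - 1)))
  bound <- abs(1 - Hmag^2)    # per-extra-two-pass relative change
  expect_lt(abs(a2 - a1) / a1, bound * 1.05 + 1e-6)
})

test_that("epoching cuts 3 s trials and drops edge events", {
  fs <- 1000
  cont <- matrix(rnorm(2 * 40000), 2, 40000)
  ons <- seq(2, 29, by = 3)
  ep <- epoch(cont, ons, fs)
  expect_length(ep$trials, 10)
  expect_true(all(vapply(ep$trials, ncol, 0L) == 3000))
  expect_equal(ep$onset_sample, 1000)

  expect_message(ep2 <- epoch(cont, c(0.5, 5), fs), "dropped")
  expect_length(ep2$trials, 1)
  expect_equal(ep2$n_dropped, 1)
})

test_that("crop window selects 200-600 ms under the 0-based convention", {
  fs <- 1000
  trial <- matrix(seq_len(3000), 1, 3000)   # values = 1-based sample index
  w <- crop_window(trial, fs, onset_sample = 1000)
  expect_equal(ncol(w), 400)
  # 0-based samples 1200..1599 are 1-based 1201..1600
  expect_equal(as.numeric(w), 1201:1600)

  trial500 <- matrix(seq_len(1500), 1, 1500)
  w500 <- crop_window(trial500, 500, onset_sample = 500)
  expect_equal(ncol(w500), 200)

  # onset at trial start: 0-based samples 200..599
  w0 <- crop_window(trial, fs, onset_sample = 0)
  expect_equal(as.numeric(w0), 201:600)

  expect_error(crop_window(matrix(0, 1, 100), fs, onset_sample = 1000),
               "window")
})

test_that("PLI reaches its analytic limits", {
  n <- 400
  phi <- runif(n, -pi, pi)
  # constant pi/2 offset: all signs equal
  expect_equal(pli(rbind(phi, phi - pi / 2), input = "phase")[1, 2], 1)
  # identical channels: sign(0) = 0
  expect_equal(pli(rbind(phi, phi), input = "phase")[1, 2], 0)
  # independent uniform phases: folded-normal scale sqrt(2/(pi*n))
  set.seed(21)
  vals <- replicate(50, {
    pli(matrix(runif(2 * n, -pi, pi), 2, n), input = "phase")[1, 2]
  })
  expect_true(all(vals < 0.15))
  expect_lt(abs(mean(vals) - sqrt(2 / (pi * n))), 0.02)
})

test_that("PLI matches the scalar definition oracle", {
  set.seed(8)
  ph <- matrix(runif(4 * 200, -pi, pi), 4, 200)
  m <- pli(ph, input = "phase")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(m[i, j], oracle_pli_pair(ph[i, ], ph[j, ]), tolerance = 1e-12)
    expect_equal(m[i, j], m[j, i])
  }
  expect_equal(diag(m), rep(0, 4))
})

test_that("PLI is invariant to positive channel rescaling", {
  set.seed(9)
  x <- matrix(rnorm(3 * 500), 3, 500)
  x <- t(apply(x, 1, function(r) bandpass(r, band_spec("beta", 12, 30), 250)))
  m1 <- pli(x)
  m2 <- pli(x * c(0.01, 5, 300))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("a zero-variance channel yields zero edges with a warning", {
  x <- rbind(rnorm(300), 0, rnorm(300))
  expect_warning(m <- pli(x), "zero-variance")
  expect_true(all(m[2, ] == 0) && all(m[, 2] == 0))
})

test_that("average_fc is the element-wise mean and keeps invariants", {
  set.seed(10)
  one <- devectorize_edges(runif(6), 4)
  expect_equal(average_fc(list(one))$values, one)
  two <- devectorize_edges(runif(6), 4)
  avg <- average_fc(list(one, two))
  expect_equal(avg$values, (one + two) / 2)
  expect_equal(avg$n_trials_averaged, 2)

  mats <- lapply(1:30, function(i) devectorize_edges(runif(6), 4))
  out <- average_fc(mats)$values
  expect_true(dbsconnect:::validate_fc(out))
  expect_error(average_fc(list()), "no matrices")
})

test_that("the pipeline recovers a planted alpha-band lag on edge (3,7)", {
  fs <- 250
  b <- band_spec("alpha", 8, 12)
  ts <- generate_coupled_timeseries(
    data.frame(i = 3, j = 7, lag = pi / 3), n_rois = 8, n_trials = 1,
    fs = fs, trial_len = 60, band = b, snr = 5, seed = 12)
  # one long coupled recording with oddball-like event spacing
  cont <- ts$trials[[1]]
  ons <- seq(2, 56, by = 2.2)
  fc <- roi_timeseries_to_fc(cont, data.frame(onset_s = ons, type = "target"),
                             fs, bands = list(b))
  m <- fc$alpha$values
  expect_equal(sort(arrayInd(which.max(m), dim(m))[1, ]),
               c(3, 7), ignore_attr = TRUE)
  expect_equal(fc$alpha$n_trials_averaged, length(ons))
})

test_that("band-limited noise yields no standout edges and modest PLI", {
  # independent narrowband sources: PLI has a positive bias from phase
  # autocorrelation (largest in narrow low bands), but no edge should stand
  # out and the high gamma level stays moderate
  fs <- 500
  set.seed(13)
  cont <- matrix(rnorm(5 * 30 * fs), 5, 30 * fs)
  ons <- seq(2, 27, by = 1.1)
  b <- band_spec("hgamma", 50, 100)
  fc <- roi_timeseries_to_fc(cont, data.frame(onset_s = ons, type = "target"),
                             fs, bands = list(b))
  vals <- vectorize_edges(fc$hgamma$values)
  expect_lt(mean(vals), 0.3)
  expect_lt(max(vals), 0.6)
})

test_that("too few target trials triggers the cohort-level warning", {
  fs <- 250
  cont <- matrix(rnorm(2 * 20 * fs), 2, 20 * fs)
  expect_warning(
    roi_timeseries_to_fc(cont, data.frame(onset_s = c(5, 9), type = "target"),
                         fs, bands = list(band_spec("alpha", 8, 12))),
    "trial")
})

test_that("both DBS conditions are required and share line settings", {
  fs <- 250
  rec <- list(continuous = matrix(rnorm(2 * 20 * fs), 2, 20 * fs),
              events = data.frame(onset_s = seq(2, 17.3, by = 0.7),
                                  type = "target"))
  expect_error(timeseries_to_fc(list(ON = rec), fs), "OFF")
  out <- timeseries_to_fc(list(ON = rec, OFF = rec), fs,
                          bands = list(band_spec("alpha", 8, 12)),
                          line_freqs = 50)
  expect_named(out, "alpha")
  expect_named(out$alpha, c("ON", "OFF"))
  expect_equal(out$alpha$ON$values, out$alpha$OFF$values)  # same input, same settings
})
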