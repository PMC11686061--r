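#' Frequency band definition
#'
#' @param name Band label.
#' @param lo,hi Band edges in Hz, 0 <= lo < hi.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(lo >= 0, lo < hi)
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' Canonical EEG frequency bands
#'
#' delta 0.1-4, theta 4-8, alpha 8-12, beta 12-30, low gamma 30-50 and
#' high gamma 50-100 Hz.
#'
#' @return Named list of six [band_spec()] objects.
#' @export
canonical_bands <- function() {
  list(delta  = band_spec("delta", 0.1, 4),
       theta  = band_spec("theta", 4, 8),
       alpha  = band_spec("alpha", 8, 12),
       beta   = band_spec("beta", 12, 30),
       lgamma = band_spec("lgamma", 30, 50),
       hgamma = band_spec("hgamma", 50, 100))
}

#' FFT spectral-line filter
#'
#' Removes narrowband contamination (DBS stimulation-artifact residues) by
#' zeroing all FFT bins within `bin_halfwidth` of each listed line frequency,
#' together with their conjugate-symmetric mirrors, then inverse
#' transforming. With an empty line list the round trip is the identity.
#'
#' @param x Single-channel numeric vector.
#' @param fs Sampling rate in Hz.
#' @param line_freqs Frequencies to suppress (Hz), each below Nyquist. More
#'   than five lines triggers a warning (heavier suppression suggests the
#'   recording should be reviewed instead).
#' @param bin_halfwidth Half-width of the zeroed notch in Hz (default 0.5).
#' @return Filtered real vector, same length as `x`.
#' @export
fft_line_filter <- function(x, fs, line_freqs, bin_halfwidth = 0.5) {
  n <- length(x)
  if (length(line_freqs) == 0) return(x)
  if (any(line_freqs >= fs / 2)) stop("line frequency at or above Nyquist")
  if (length(line_freqs) > 5) {
    warning("more than five spectral lines suppressed (", length(line_freqs),
            ")")
  }
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n               # bin center frequencies
  freqs_folded <- pmin(freqs, fs - freqs)          # distance-from-DC, mirrored
  kill <- rep(FALSE, n)
  for (f in line_freqs) {
    kill <- kill | abs(freqs_folded - f) <= bin_halfwidth
  }
  X[kill] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

# order-2 zero-phase Butterworth bandpass design; stability asserted
butter_band <- function(band, fs) {
  if (band$lo >= fs / 2) stop("band entirely above Nyquist")
  if (band$hi >= fs / 2) stop("band upper edge at or above Nyquist")
  flt <- signal::butter(2, c(band$lo, band$hi) / (fs / 2), type = "pass")
  if (max(Mod(polyroot(rev(flt$a)))) >= 1) {
    stop("unstable bandpass design for band ", band$name)
  }
  flt
}

#' Zero-phase bandpass filtering
#'
#' Order-2 Butterworth (12 dB/octave) applied forward and backward
#' ([signal::filtfilt()]), so the passband is traversed twice and no phase
#' shift is introduced.
#'
#' @param x Numeric vector, or matrix with one channel per row.
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, band, fs) {
  flt <- butter_band(band, fs)
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(flt, row)))
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Epoch continuous data around stimulus onsets
#'
#' Cuts 3-second trials running from `pre` seconds before to `post` seconds
#' after each stimulus. Events too close to the recording edges for a full
#' trial are dropped with a message.
#'
#' @param continuous Channels x samples matrix.
#' @param onsets_s Stimulus onset times in seconds from recording start.
#' @param fs Sampling rate in Hz.
#' @param pre,post Seconds before/after onset (defaults 1 and 2).
#' @return List with `trials` (list of channels x samples matrices),
#'   `onset_sample` (number of pre-stimulus samples in each trial, i.e. the
#'   0-based sample index of the stimulus), `n_dropped`.
#' @export
epoch <- function(continuous, onsets_s, fs, pre = 1, post = 2) {
  stopifnot(is.matrix(continuous))
  n <- ncol(continuous)
  n_pre <- round(pre * fs)
  n_post <- round(post * fs)
  onset_idx <- round(onsets_s * fs)         # 0-based sample of each onset
  keep <- onset_idx - n_pre >= 0 & onset_idx + n_post <= n
  if (any(!keep)) {
    message(sum(!keep), " event(s) dropped: insufficient support at edges")
  }
  trials <- lapply(onset_idx[keep], function(o0) {
    continuous[, (o0 - n_pre + 1):(o0 + n_post), drop = FALSE]
  })
  list(trials = trials, onset_sample = n_pre, n_dropped = sum(!keep))
}

#' Crop a trial to the post-stimulus analysis window
#'
#' Selects the samples in \[0.2 s, 0.6 s) after stimulus onset — the 400 ms
#' motor-cognitive processing window — under a 0-based half-open sample
#' convention: at 1 kHz with onset at sample 1000 of a 3000-sample trial,
#' samples 1200..1599 are returned.
#'
#' @param trial Channels x samples matrix (one epoch).
#' @param fs Sampling rate in Hz.
#' @param onset_sample 0-based sample index of stimulus onset within the
#'   trial (= number of pre-stimulus samples).
#' @param from,to Window in seconds after onset (defaults 0.2 and 0.6).
#' @return Channels x round((to-from)*fs) matrix.
#' @export
crop_window <- function(trial, fs, onset_sample, from = 0.2, to = 0.6) {
  stopifnot(is.matrix(trial))
  a0 <- onset_sample + round(from * fs)     # 0-based, inclusive
  b0 <- onset_sample + round(to * fs)       # 0-based, exclusive
  if (a0 < 0 || b0 > ncol(trial)) {
    stop("analysis window [", from, ", ", to, ") s not contained in trial")
  }
  trial[, (a0 + 1):b0, drop = FALSE]
}

#' Analytic signal via the FFT half-spectrum method
#'
#' @param x Real numeric vector.
#' @return Complex vector whose argument is the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# wrap angles into (-pi, pi]
wrap_phase <- function(a) {
  w <- a %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Phase-lag index matrix
#'
#' PLI between every channel pair: the absolute time-average of the sign of
#' the wrapped instantaneous phase difference, with sign(0) = 0 so that
#' exactly zero-lag (volume-conduction-like) coupling contributes nothing.
#' Values lie in \[0,1\]; 1 means a constant nonzero lag, 0 means symmetric
#' or zero lag.
#'
#' @param window Channels x samples matrix. With `input = "signal"` (default)
#'   phases are taken from the analytic signal of each row; with
#'   `input = "phase"` rows are instantaneous phases already.
#' @param input `"signal"` or `"phase"`.
#' @return Symmetric zero-diagonal matrix of PLI values. Channels with zero
#'   variance get all-zero edges, with a warning.
#' @export
pli <- function(window, input = c("signal", "phase")) {
  input <- match.arg(input)
  stopifnot(is.matrix(window), ncol(window) >= 2)
  p <- nrow(window)
  if (input == "signal") {
    flat <- apply(window, 1, stats::var) < .Machine$double.eps
    phases <- matrix(0, p, ncol(window))
    for (i in seq_len(p)) {
      if (!flat[i]) phases[i, ] <- Arg(analytic_signal(window[i, ]))
    }
    if (any(flat)) {
      warning("zero-variance channel(s): ",
              paste(which(flat), collapse = ", "), "; their edges set to 0")
    }
  } else {
    phases <- window
    flat <- rep(FALSE, p)
  }
  out <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    js <- (i + 1):p
    d <- phases[js, , drop = FALSE] -
      matrix(phases[i, ], length(js), ncol(phases), byrow = TRUE)
    out[i, js] <- abs(rowMeans(sign(wrap_phase(d))))
  }
  if (any(flat)) {
    out[flat, ] <- 0
    out[, flat] <- 0
  }
  out <- out + t(out)
  diag(out) <- 0
  out
}

#' Average FC matrices across trials
#'
#' @param matrices Non-empty list of equally sized symmetric matrices.
#' @return List with `values` (element-wise mean) and `n_trials_averaged`.
#' @export
average_fc <- function(matrices) {
  if (length(matrices) == 0) stop("no matrices to average")
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) stop("matrices differ in shape")
  list(values = Reduce(`+`, matrices) / length(matrices),
       n_trials_averaged = length(matrices))
}

#' ROI time series to per-band PLI matrices, one subject and condition
#'
#' The full single-condition chain: optional FFT line filtering of the
#' continuous data, epoching into 3 s trials, per-band zero-phase filtering,
#' analytic-signal phases on the full trial (avoiding Hilbert edge artifacts
#' inside the window), cropping phases to the 200-600 ms window, per-trial
#' PLI, and trial averaging.
#'
#' @param continuous Channels x samples matrix of source-space ROI activity.
#' @param events Data frame with columns `onset_s` and `type`.
#' @param fs Sampling rate in Hz.
#' @param bands List of [band_spec()] (default [canonical_bands()]).
#' @param line_freqs DBS-artifact line frequencies to zero, or NULL.
#' @param target_type Event type analyzed (default `"target"`); a condition
#'   with fewer than `min_trials` such trials triggers a warning.
#' @param min_trials Warning threshold for the retained trial count
#'   (default 20).
#' @return Named list over bands; each element a list with `values`
#'   (ROI x ROI PLI matrix) and `n_trials_averaged`.
#' @export
roi_timeseries_to_fc <- function(continuous, events, fs,
                                 bands = canonical_bands(),
                                 line_freqs = NULL,
                                 target_type = "target",
                                 min_trials = 20) {
  stopifnot(is.matrix(continuous), all(c("onset_s", "type") %in% names(events)))
  if (!is.null(line_freqs) && length(line_freqs)) {
    continuous <- t(apply(continuous, 1, fft_line_filter, fs = fs,
                          line_freqs = line_freqs))
  }
  onsets <- events$onset_s[events$type == target_type]
  ep <- epoch(continuous, onsets, fs)
  if (length(ep$trials) < min_trials) {
    warning("only ", length(ep$trials), " ", target_type,
            " trial(s) retained (< ", min_trials, ")")
  }
  if (length(ep$trials) == 0) stop("no usable trials")
  out <- list()
  for (b in bands) {
    per_trial <- lapply(ep$trials, function(tr) {
      filt <- bandpass(tr, b, fs)
      phases <- t(apply(filt, 1, function(row) Arg(analytic_signal(row))))
      win <- crop_window(phases, fs, ep$onset_sample)
      pli(win, input = "phase")
    })
    out[[b$name]] <- average_fc(per_trial)
  }
  out
}

#' ON/OFF recordings to per-band, per-condition FC matrices
#'
#' Applies [roi_timeseries_to_fc()] to both DBS conditions of one subject
#' with identical line-filter settings, as artifact lines identified in the
#' ON recording must be replicated in the OFF recording.
#'
#' @param recordings Named list with elements `ON` and `OFF`, each a list
#'   holding `continuous` (channels x samples) and `events` (data frame).
#' @param fs Sampling rate in Hz.
#' @param bands,line_freqs,target_type,min_trials Passed through.
#' @return Nested list `fc[[band]][[condition]]`.
#' @export
timeseries_to_fc <- function(recordings, fs, bands = canonical_bands(),
                             line_freqs = NULL, target_type = "target",
                             min_trials = 20) {
  if (!all(c("ON", "OFF") %in% names(recordings))) {
    stop("both ON and OFF recordings are required")
  }
  per_cond <- lapply(recordings[c("ON", "OFF")], function(rec) {
    roi_timeseries_to_fc(rec$continuous, rec$events, fs, bands = bands,
                         line_freqs = line_freqs, target_type = target_type,
                         min_trials = min_trials)
  })
  out <- list()
  for (b in bands) {
    out[[b$name]] <- list(ON = per_cond$ON[[b$name]],
                          OFF = per_cond$OFF[[b$name]])
  }
  out
}
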