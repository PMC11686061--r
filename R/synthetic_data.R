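#' Synthetic cohort specification
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' study conditions of the analysis: a 43-subject cohort, 90 AAL ROIs, six
#' canonical bands, ON/OFF condition pairs, MDS-UPDRS improvement scores
#' spread over \[-41, -9\] with the optimal-responder threshold at -18, a
#' motor-subnetwork pattern in the high gamma band whose OFF-state prominence
#' scales with motor improvement and which increases under DBS ON, a sparse
#' multi-band ON-OFF connectivity profile planted in optimal responders only,
#' and a whole-brain ON-state pattern tied to one cognition score.
#'
#' @param n_subjects Cohort size (default 43).
#' @param roi_labels ROI label vector; must contain the 14 motor labels
#'   (default [aal90_labels()], 90 ROIs).
#' @param bands Named list of [band_spec()] (default [canonical_bands()]).
#' @param planted_motor_loading Length-91 non-negative pattern over the motor
#'   subnetwork's edges (row-major upper triangle, cortical-first ordering);
#'   default: weak cortico-cortical block (0.15) against strong subcortical
#'   and cortico-subcortical connections (1), unit-normalized.
#' @param motor_effect_size Scale of the OFF-state motor pattern prominence
#'   gradient across subjects (default 3).
#' @param motor_on_increase Uniform ON-OFF increment along the motor loading,
#'   all subjects (default 0.6).
#' @param motor_band Band carrying the motor plantings (default "hgamma").
#' @param profile_edges Data frame (`band`, `i`, `j`, `direction`) of planted
#'   ON-OFF profile edges for optimal responders; default
#'   [default_profile_edges()]: two edges per band except delta.
#' @param profile_effect_size Per-edge ON-OFF shift magnitude (default 0.15).
#' @param cognition_pattern Unit-norm whole-brain edge pattern, or NULL to
#'   draw one from the seed.
#' @param cognition_effect_size Scale of the ON-state cognition pattern
#'   (default 4).
#' @param cognition_band Band carrying the cognition planting (default
#'   "hgamma").
#' @param noise_sd Additive Gaussian edge noise per condition (default 0.02).
#' @param updrs_diff_range Range of UPDRS_diff = UPDRS ON - OFF; both
#'   negative, default c(-41, -9).
#' @param responder_threshold Optimal-responder cut: diff < threshold
#'   (default -18).
#' @param age_mean,age_sd,p_female Demographic generators (defaults 61, 7,
#'   14/43).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 43,
                        roi_labels = aal90_labels(),
                        bands = canonical_bands(),
                        planted_motor_loading = default_motor_loading(),
                        motor_effect_size = 3,
                        motor_on_increase = 0.6,
                        motor_band = "hgamma",
                        profile_edges = NULL,
                        profile_effect_size = 0.15,
                        cognition_pattern = NULL,
                        cognition_effect_size = 4,
                        cognition_band = "hgamma",
                        noise_sd = 0.02,
                        updrs_diff_range = c(-41, -9),
                        responder_threshold = -18,
                        age_mean = 61, age_sd = 7, p_female = 14 / 43,
                        seed = 1L) {
  p <- length(roi_labels)
  motor <- motor_roi_set(roi_labels)
  stopifnot(n_subjects >= 2, p >= 15,
            length(planted_motor_loading) == 91,
            all(planted_motor_loading >= 0),
            motor_effect_size >= 0, motor_on_increase >= 0,
            profile_effect_size >= 0, cognition_effect_size >= 0,
            noise_sd >= 0,
            updrs_diff_range[1] < updrs_diff_range[2],
            updrs_diff_range[2] < 0)
  if (!motor_band %in% names(bands)) stop("motor_band not in band set")
  if (!cognition_band %in% names(bands)) stop("cognition_band not in band set")
  if (is.null(profile_edges)) {
    profile_edges <- default_profile_edges(roi_labels, names(bands))
  }
  if (nrow(profile_edges)) {
    stopifnot(all(c("band", "i", "j", "direction") %in% names(profile_edges)),
              all(profile_edges$band %in% names(bands)),
              all(profile_edges$i >= 1), all(profile_edges$j <= p),
              all(profile_edges$i != profile_edges$j),
              all(profile_edges$direction %in% c(-1, 1)))
    key <- paste(profile_edges$band, pmin(profile_edges$i, profile_edges$j),
                 pmax(profile_edges$i, profile_edges$j))
    if (anyDuplicated(key)) stop("duplicate (band, edge) in profile_edges")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), roi_labels = roi_labels,
    roi_count = p, bands = bands, motor_rois = motor,
    planted_motor_loading = planted_motor_loading / sqrt(sum(planted_motor_loading^2)),
    motor_effect_size = motor_effect_size,
    motor_on_increase = motor_on_increase, motor_band = motor_band,
    profile_edges = profile_edges, profile_effect_size = profile_effect_size,
    cognition_pattern = cognition_pattern,
    cognition_effect_size = cognition_effect_size,
    cognition_band = cognition_band,
    noise_sd = noise_sd, updrs_diff_range = updrs_diff_range,
    responder_threshold = responder_threshold,
    age_mean = age_mean, age_sd = age_sd, p_female = p_female,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Default planted motor-subnetwork loading
#'
#' Two-module pattern over the 91 within-subnetwork connections (cortical
#' regions first): cortico-cortical edges weighted 0.15, subcortical and
#' cortico-subcortical edges 1; unit-normalized.
#'
#' @return Numeric length-91 vector.
#' @export
default_motor_loading <- function() {
  em <- edge_index_map(14)
  cortical <- motor_cortical_positions()
  w <- ifelse(em[, "i"] %in% cortical & em[, "j"] %in% cortical, 0.15, 1)
  w / sqrt(sum(w^2))
}

#' Default planted connectivity-profile edges
#'
#' Two non-motor edges per band in every band except delta (the reported
#' responder profile spans all bands but delta), one increasing and one
#' decreasing under DBS ON, chosen deterministically among the first
#' non-motor ROIs.
#'
#' @param roi_labels Full ROI label vector.
#' @param band_names Band names in use.
#' @return Data frame with columns `band`, `i`, `j`, `direction`.
#' @export
default_profile_edges <- function(roi_labels, band_names) {
  motor <- motor_roi_set(roi_labels)
  nonmotor <- setdiff(seq_along(roi_labels), motor$indices)
  bands_used <- setdiff(band_names, "delta")
  if (length(nonmotor) < 2) {
    stop("need at least two non-motor ROIs for the default profile; supply ",
         "profile_edges explicitly")
  }
  pairs <- utils::combn(nonmotor, 2)
  np <- ncol(pairs)
  rows <- do.call(rbind, lapply(seq_along(bands_used), function(k) {
    idx <- unique(((2 * k - 2):(2 * k - 1)) %% np + 1)  # cycle through pairs
    data.frame(band = bands_used[k],
               i = pairs[1, idx], j = pairs[2, idx],
               direction = c(1, -1)[seq_along(idx)])
  }))
  rownames(rows) <- NULL
  rows
}

#' Oddball paradigm event sequence
#'
#' Randomized order of target, frequent and distractor stimuli with fixed
#' stimulus duration and interstimulus interval; the default counts
#' (30/140/30, 200 ms, 4 s) give a 200-stimulus, 14-minute task with 15%
#' targets.
#'
#' @param n_target,n_frequent,n_distractor Stimulus counts.
#' @param stim_dur Stimulus duration in seconds (default 0.2).
#' @param isi Interstimulus interval in seconds (default 4).
#' @param seed Integer seed for the order randomization.
#' @return Data frame `onset_s`, `type`; onsets strictly increasing with
#'   spacing `stim_dur + isi`.
#' @export
generate_paradigm <- function(n_target = 30, n_frequent = 140,
                              n_distractor = 30, stim_dur = 0.2, isi = 4,
                              seed = 1L) {
  stopifnot(n_target >= 0, n_frequent >= 0, n_distractor >= 0)
  types <- c(rep("target", n_target), rep("frequent", n_frequent),
             rep("distractor", n_distractor))
  n <- length(types)
  if (n == 0) return(data.frame(onset_s = numeric(0), type = character(0)))
  set.seed(seed)
  types <- sample(types)
  data.frame(onset_s = (seq_len(n) - 1) * (stim_dur + isi), type = types)
}

#' Synthetic subject metadata
#'
#' Demographics, MDS-UPDRS III ON/OFF scores and five neuropsychological
#' T-scores. UPDRS_diff is drawn as uniform integers over the configured
#' range; UPDRS OFF as uniform integers in \[30, 70\]; ages normal; T-scores
#' N(50, 10). One channel (Stroop interference) later carries the planted
#' cognition effect; the others stay pure noise.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame, one row per subject: `id`, `age`, `gender`,
#'   `updrs_on`, `updrs_off`, `updrs_diff`, `responder`, and five `t_*`
#'   columns.
#' @export
generate_metadata <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  rng <- spec$updrs_diff_range
  diff <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
  off <- sample(30:70, n, replace = TRUE)
  tests <- c("t_digit_span", "t_word_list_1", "t_word_list_2",
             "t_stroop_interference", "t_mattis_total")
  meta <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
    gender = ifelse(stats::runif(n) < spec$p_female, "F", "M"),
    updrs_on = off + diff,
    updrs_off = off,
    updrs_diff = diff,
    responder = diff < spec$responder_threshold)
  for (tn in tests) meta[[tn]] <- round(stats::rnorm(n, 50, 10), 1)
  meta
}

#' Generate a synthetic FC cohort with planted effects
#'
#' For each subject, band and condition, builds a PLI-like edge vector as a
#' shared Beta(2,5) subject baseline plus independent Gaussian noise per
#' condition, then plants three effects: (1) in the motor band, the OFF and
#' ON states gain the motor loading scaled by `motor_effect_size` times the
#' subject's normalized motor improvement (so better responders show the
#' pattern more prominently even OFF), and the ON state an additional uniform
#' `motor_on_increase` along the loading; (2) on the profile edges, optimal
#' responders' ON state shifts by `direction * profile_effect_size`; (3) in
#' the cognition band, the ON state gains the whole-brain cognition pattern
#' scaled by the subject's standardized Stroop-interference T-score. Entries
#' are clipped to \[0,1\] and symmetrized.
#'
#' Ground truth (planted loadings, profile, labels) is returned alongside the
#' data and is never consumed by analysis functions.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `subjects` (each
#'   carrying metadata fields plus `fc[[band]][[condition]]` matrices),
#'   `metadata` (data frame), `ground_truth`, `spec`, `clip_fraction`.
#' @export
generate_fc_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- generate_metadata(spec)
  p <- spec$roi_count
  n_edges <- p * (p - 1) / 2
  n <- spec$n_subjects

  # motor loading lifted from the 91 subnetwork edges into full edge indexing
  midx <- spec$motor_rois$indices
  em14 <- edge_index_map(14)
  motor_full <- numeric(n_edges)
  motor_edge_pos <- edge_index(midx[em14[, "i"]], midx[em14[, "j"]], p)
  motor_full[motor_edge_pos] <- spec$planted_motor_loading

  # counter-based sub-seed expansion: multiplicative mixing keeps streams of
  # nearby master seeds disjoint, so cohorts simulated under consecutive
  # seeds are statistically independent
  mix_seed <- function(counter) {
    as.integer((as.numeric(spec$seed) * 48271 +
                  as.numeric(counter) * 1000003) %% 2147483629)
  }

  # whole-brain cognition pattern (unit norm), drawn from the seed if absent;
  # the default is supported off the motor subnetwork's edges so each planted
  # effect remains attributable to its own analysis stage
  if (is.null(spec$cognition_pattern)) {
    set.seed(mix_seed(499L))
    cogpat <- stats::rnorm(n_edges)
    cogpat[motor_edge_pos] <- 0
    cogpat <- cogpat / sqrt(sum(cogpat^2))
  } else {
    stopifnot(length(spec$cognition_pattern) == n_edges)
    cogpat <- spec$cognition_pattern / sqrt(sum(spec$cognition_pattern^2))
  }

  rng <- spec$updrs_diff_range
  u <- (rng[2] - meta$updrs_diff) / (rng[2] - rng[1])   # 1 = best improvement
  si <- meta$t_stroop_interference
  z <- (si - mean(si)) / stats::sd(si)
  optimal <- meta$updrs_diff < spec$responder_threshold

  prof <- spec$profile_edges
  prof_pos <- if (nrow(prof)) edge_index(prof$i, prof$j, p) else integer(0)

  subjects <- vector("list", n)
  clipped <- 0; total <- 0
  for (s in seq_len(n)) {
    set.seed(mix_seed(1000L + s))        # per-subject sub-seed
    fc <- list()
    for (bn in names(spec$bands)) {
      base <- stats::rbeta(n_edges, 2, 5)
      off <- base + stats::rnorm(n_edges, 0, spec$noise_sd)
      on <- base + stats::rnorm(n_edges, 0, spec$noise_sd)
      if (bn == spec$motor_band) {
        off <- off + spec$motor_effect_size * u[s] * motor_full
        on <- on + spec$motor_effect_size * u[s] * motor_full +
          spec$motor_on_increase * motor_full
      }
      if (optimal[s] && nrow(prof)) {
        rows <- prof$band == bn
        if (any(rows)) {
          on[prof_pos[rows]] <- on[prof_pos[rows]] +
            prof$direction[rows] * spec$profile_effect_size
        }
      }
      if (bn == spec$cognition_band) {
        on <- on + spec$cognition_effect_size * z[s] * cogpat
      }
      clipped <- clipped + sum(off < 0 | off > 1) + sum(on < 0 | on > 1)
      total <- total + 2 * n_edges
      off <- pmin(pmax(off, 0), 1)
      on <- pmin(pmax(on, 0), 1)
      fc[[bn]] <- list(ON = devectorize_edges(on, p),
                       OFF = devectorize_edges(off, p))
    }
    rec <- as.list(meta[s, setdiff(names(meta), "responder")])
    rec$fc <- fc
    subjects[[s]] <- rec
  }
  clip_fraction <- clipped / total
  if (clip_fraction > 0.2) {
    warning(sprintf("planted effects clip %.1f%% of edges", 100 * clip_fraction))
  }
  structure(list(
    subjects = subjects, metadata = meta,
    ground_truth = list(responder = optimal,
                        motor_loading_subnet = spec$planted_motor_loading,
                        motor_loading_full = motor_full,
                        profile_edges = prof,
                        cognition_pattern = cogpat),
    spec = spec, clip_fraction = clip_fraction),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d ROIs, bands: %s\n",
              x$spec$n_subjects, x$spec$roi_count,
              paste(names(x$spec$bands), collapse = ", ")))
  invisible(x)
}

#' Stack a cohort's FC matrices as an edge matrix
#'
#' @param cohort A cohort (synthetic or loaded).
#' @param band Band name.
#' @param condition `"ON"` or `"OFF"`.
#' @return subjects x edges numeric matrix (row-major upper-triangle edges).
#' @export
cohort_edge_matrix <- function(cohort, band, condition = c("ON", "OFF")) {
  condition <- match.arg(condition)
  rows <- lapply(cohort$subjects, function(s) {
    m <- s$fc[[band]][[condition]]
    if (is.null(m)) stop("subject ", s$id, " lacks ", band, "/", condition)
    vectorize_edges(m)
  })
  do.call(rbind, rows)
}

#' Age/gender covariate matrix from metadata
#'
#' @param metadata Data frame with `age` and `gender` columns.
#' @return Numeric matrix with columns `age` and `gender` (0 = M, 1 = F).
#' @export
covariate_matrix <- function(metadata) {
  cbind(age = metadata$age, gender = as.numeric(metadata$gender == "F"))
}

#' Coupled narrowband oscillator time series
#'
#' Signal-level fixture generator for the PLI stage: every ROI is a
#' narrowband oscillator obtained by bandpass filtering white noise; ROI
#' pairs listed in `pair_lags` share one analytic generator with a constant
#' phase offset (PLI 1 for nonzero lag, 0 for zero lag), all other ROIs are
#' independent. White measurement noise is added at the given SNR (signal sd
#' over noise sd; `Inf` for noiseless).
#'
#' @param pair_lags Data frame `i`, `j`, `lag` (radians); each ROI may appear
#'   in at most one coupled pair.
#' @param n_rois Number of ROIs.
#' @param n_trials Number of trials.
#' @param fs Sampling rate (Hz); must be at least twice the band's upper edge.
#' @param trial_len Trial length in seconds.
#' @param band A [band_spec()].
#' @param snr Signal-to-noise amplitude ratio (default Inf).
#' @param seed Integer seed.
#' @return List with `trials` (list of ROI x samples matrices), `fs`, `band`.
#' @export
generate_coupled_timeseries <- function(pair_lags, n_rois, n_trials, fs,
                                        trial_len, band, snr = Inf,
                                        seed = 1L) {
  stopifnot(fs >= 2 * band$hi)
  involved <- c(pair_lags$i, pair_lags$j)
  if (anyDuplicated(involved)) stop("each ROI may join at most one pair")
  stopifnot(all(involved >= 1), all(involved <= n_rois))
  set.seed(seed)
  n_samp <- round(trial_len * fs)
  flt <- butter_band(band, fs)
  narrowband <- function() {
    # generate longer and trim to dodge filter edge transients
    pad <- n_samp
    x <- signal::filtfilt(flt, stats::rnorm(n_samp + 2 * pad))
    x[(pad + 1):(pad + n_samp)]
  }
  trials <- lapply(seq_len(n_trials), function(tr) {
    out <- matrix(0, n_rois, n_samp)
    for (r in seq_len(n_rois)) out[r, ] <- narrowband()
    if (nrow(pair_lags)) {
      for (k in seq_len(nrow(pair_lags))) {
        a <- analytic_signal(out[pair_lags$i[k], ])
        out[pair_lags$i[k], ] <- Re(a)
        out[pair_lags$j[k], ] <- Re(a * exp(-1i * pair_lags$lag[k]))
      }
    }
    if (is.finite(snr)) {
      sig_sd <- stats::sd(as.numeric(out))
      out <- out + matrix(stats::rnorm(length(out), 0, sig_sd / snr),
                          n_rois, n_samp)
    }
    out
  })
  list(trials = trials, fs = fs, band = band)
}
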