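# Seeded multi-subject synthetic sEMG cohort generator.
#
# Each subject walks through a repeating cycle of activity classes (gait
# phases). Per channel, a band-limited (20-450 Hz) unit-variance stochastic
# carrier is amplitude-modulated by a class- and channel-specific smooth
# activation envelope; subject individuality enters through per-channel
# gains, a channel-mixing matrix standing in for electrode shift, an
# envelope timing shift, and per-class activation scales. These knobs
# create a controllable source/target distribution gap for adaptation
# experiments.

#' Synthetic cohort configuration
#'
#' @param n_subjects number of subjects (>= 2: source + target).
#' @param n_channels sEMG channels (default 9: the lower-limb muscle
#'   montage).
#' @param fs sampling rate in Hz (default 1000).
#' @param n_classes activity classes C (default 4: the gait phases heel
#'   strike, foot flat, heel off, toe off).
#' @param trial_seconds recorded duration per subject (default 20).
#' @param segment_ms mean duration of one class segment (default 350).
#' @param segment_jitter relative per-segment duration jitter (default
#'   0.2; the shortest possible segment must still hold one window).
#' @param gain_sigma sd of per-channel log-normal subject gains
#'   (amplifier/skin-impedance differences; largely removed by per-channel
#'   peak normalization downstream).
#' @param channel_weight_sigma sd of the per-subject log-normal jitter on
#'   the class-by-channel activation weights (anatomical differences in
#'   muscle recruitment; the main driver of the cross-subject gap that
#'   survives normalization).
#' @param shift_sigma_ms sd of the subject envelope timing shift.
#' @param mixing_strength upper bound of the electrode-shift channel
#'   mixing coefficient.
#' @param envelope_scale_sigma sd of per-class log-normal activation
#'   scales.
#' @param noise_floor additive white-noise sd (signal carriers have unit
#'   variance before modulation).
#' @param class_sequence optional integer vector of class ids defining
#'   the repeating cycle (default `0:(C-1)`).
#' @param seed cohort seed; all subject profiles and signals derive from
#'   it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 4L, n_channels = 9L, fs = 1000,
                          n_classes = 4L, trial_seconds = 20,
                          segment_ms = 350, segment_jitter = 0.2,
                          gain_sigma = 0.35, channel_weight_sigma = 0.5,
                          shift_sigma_ms = 15, mixing_strength = 0.35,
                          envelope_scale_sigma = 0.25,
                          noise_floor = 0.05, class_sequence = NULL,
                          seed = 1L) {
  if (n_subjects < 2L) stop_("need at least 2 subjects (source + target)")
  if (any(c(gain_sigma, channel_weight_sigma, shift_sigma_ms,
            mixing_strength, envelope_scale_sigma, noise_floor) < 0))
    stop_("variability scales must be >= 0")
  if (is.null(class_sequence)) class_sequence <- seq_len(n_classes) - 1L
  if (any(class_sequence < 0L | class_sequence >= n_classes))
    stop_("class_sequence refers to a class id >= n_classes")
  if (segment_ms * (1 - segment_jitter) < 200)
    stop_("shortest segment (%g ms) must be >= one 200 ms window",
          segment_ms * (1 - segment_jitter))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels), fs = fs,
                 n_classes = as.integer(n_classes),
                 trial_seconds = trial_seconds, segment_ms = segment_ms,
                 segment_jitter = segment_jitter, gain_sigma = gain_sigma,
                 channel_weight_sigma = channel_weight_sigma,
                 shift_sigma_ms = shift_sigma_ms,
                 mixing_strength = mixing_strength,
                 envelope_scale_sigma = envelope_scale_sigma,
                 noise_floor = noise_floor,
                 class_sequence = as.integer(class_sequence),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Cohort-level class-by-channel activation pattern: each class activates a
# smooth bump of channels (distinct muscle synergies), on a small baseline
# so every channel carries some signal.
class_channel_weights <- function(C, nch) {
  W <- matrix(0.1, C, nch)
  pos <- seq_len(nch)
  for (c in seq_len(C)) {
    mu <- (c - 0.5) * nch / C + 0.5
    W[c, ] <- 0.1 + exp(-(pos - mu)^2 / (2 * (nch / (C + 1))^2))
  }
  W
}

#' Draw a subject profile
#'
#' @param cfg a [cohort_config()].
#' @param subject_index 1-based subject number.
#' @return a `subject_profile` list: `subject_id`, positive
#'   `channel_gains`, a `C x n_channels` matrix `weight_jitter` of
#'   subject-specific multiplicative perturbations of the class
#'   activation weights, row-stochastic `mixing` matrix,
#'   `envelope_shift_ms`, per-class `envelope_scale`, `noise_floor`, and
#'   the subject's signal `seed`.
#' @export
subject_profile <- function(cfg, subject_index) {
  with_seed_(derive_seed(cfg$seed, "profile", subject_index), {
    nch <- cfg$n_channels
    gains <- exp(stats::rnorm(nch, 0, cfg$gain_sigma))
    wj <- matrix(exp(stats::rnorm(cfg$n_classes * nch, 0,
                                  cfg$channel_weight_sigma)),
                 cfg$n_classes, nch)
    alpha <- stats::runif(1, 0, cfg$mixing_strength)
    dir <- sample(c(-1L, 1L), 1L)
    M <- diag(1 - alpha, nch)
    for (ch in seq_len(nch))
      M[ch, ((ch - 1L + dir) %% nch) + 1L] <- M[ch, ((ch - 1L + dir) %% nch) + 1L] + alpha
    structure(list(
      subject_id = sprintf("S%02d", subject_index),
      channel_gains = gains, weight_jitter = wj, mixing = M,
      envelope_shift_ms = stats::rnorm(1, 0, cfg$shift_sigma_ms),
      envelope_scale = exp(stats::rnorm(cfg$n_classes, 0,
                                        cfg$envelope_scale_sigma)),
      noise_floor = cfg$noise_floor,
      seed = derive_seed(cfg$seed, "signal", subject_index)),
      class = "subject_profile")
  })
}

# Band-limited (20-450 Hz) unit-variance stochastic carrier.
bandlimited_carrier <- function(n, fs) {
  b <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  x <- signal::filtfilt(b, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate one subject's recording
#'
#' @param profile a [subject_profile()].
#' @param cfg the [cohort_config()] the profile was drawn from.
#' @return a labeled [emg_recording()] of `trial_seconds` duration.
#' @export
generate_subject <- function(profile, cfg) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(cfg, "cohort_config"))
  if (any(cfg$class_sequence >= cfg$n_classes))
    stop_("class_sequence refers to a class id >= n_classes")
  fs <- cfg$fs
  n <- round(cfg$trial_seconds * fs)
  nch <- cfg$n_channels
  Wcls <- class_channel_weights(cfg$n_classes, nch)
  with_seed_(profile$seed, {
    # class segments: repeating cycle with per-segment duration jitter
    labels <- integer(0)
    env <- numeric(0)
    floor_ <- 0.1
    while (length(labels) < n) {
      for (cls in cfg$class_sequence) {
        len <- round(cfg$segment_ms * fs / 1000 *
                       stats::runif(1, 1 - cfg$segment_jitter,
                                    1 + cfg$segment_jitter))
        u <- (seq_len(len) - 0.5) / len
        labels <- c(labels, rep(cls, len))
        env <- c(env, floor_ + (1 - floor_) * sin(pi * u)^2)
      }
    }
    labels <- labels[seq_len(n)]
    env <- env[seq_len(n)]
    # subject timing shift (edge-held lag/lead)
    sh <- round(profile$envelope_shift_ms * fs / 1000)
    if (sh != 0) {
      idx <- pmin(pmax(seq_len(n) - sh, 1L), n)
      env <- env[idx]
    }
    # channel amplitudes: subject-perturbed class pattern x per-class
    # subject scale x envelope
    Wsub <- Wcls * profile$weight_jitter
    A <- Wsub[labels + 1L, , drop = FALSE] *
      rep(profile$envelope_scale[labels + 1L], nch)   # n x nch
    X <- matrix(0, nch, n)
    for (ch in seq_len(nch))
      X[ch, ] <- A[, ch] * env * bandlimited_carrier(n, fs)
    X <- profile$mixing %*% (profile$channel_gains * X)
    if (profile$noise_floor > 0)
      X <- X + profile$noise_floor * matrix(stats::rnorm(nch * n), nch)
    emg_recording(X, fs = fs, subject_id = profile$subject_id,
                  labels = labels, trial_id = "sim")
  })
}

#' Generate a full synthetic cohort
#'
#' @param cfg a [cohort_config()].
#' @return a list with `recordings` (one labeled [emg_recording()] per
#'   subject) and `manifest` (the config and every subject profile, for
#'   introspection and serialization).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, trial_seconds = 3))
#' cohort$recordings[[1]]
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  profiles <- lapply(seq_len(cfg$n_subjects), subject_profile, cfg = cfg)
  recordings <- lapply(profiles, generate_subject, cfg = cfg)
  list(recordings = recordings,
       manifest = list(config = cfg, profiles = profiles))
}

#' Standard preprocessing + segmentation for one recording
#'
#' Convenience pipeline: band-limit (20-450 Hz), normalize each channel
#' by its peak, and segment into 200 ms windows with a 25 ms increment.
#'
#' @param rec an [emg_recording()].
#' @param window_ms,increment_ms segmentation parameters.
#' @return a [window_set()].
#' @export
prepare_windows <- function(rec, window_ms = 200, increment_ms = 25) {
  rec <- bandlimit_filter(rec)
  rec <- normalize_by_peak(rec)
  segment_windows(rec, window_ms = window_ms, increment_ms = increment_ms)
}
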