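#' Generate a synthetic EEG recording for one mental state
#'
#' Simulates band-limited oscillatory channels whose pairwise phase
#' coupling follows a [state_profile()]. Coupling is realized by mixing
#' shared band-limited sources into groups of channels: a global source
#' (all channels, weight = the profile's `other` coupling), left- and
#' right-ROI sources, and a frontal-occipital source, each weighted by
#' the amount the profile's class coupling exceeds the background. Every
#' channel receives its group sources with a fixed channel-specific
#' phase offset (so phase differences are non-zero constants and PLI,
#' which is blind to zero-lag coupling, can detect them), plus an
#' independent band-limited oscillator and broadband white noise.
#'
#' @param profile a [state_profile()] or the name of a shipped profile.
#' @param montage a [montage_spec()].
#' @param duration recording length in seconds (>= 4).
#' @param fs sampling rate in Hz (>= 60; default 250).
#' @param seed integer seed; identical arguments give bit-identical
#'   recordings.
#' @return An [eeg_recording()] with `condition = profile$name`.
#' @examples
#' rec <- generate_state_recording("resting", duration = 8, seed = 1)
#' dim(rec$data)
#' @export
generate_state_recording <- function(profile, montage = default_montage(),
                                     duration = 60, fs = 250, seed) {
  if (is.character(profile)) profile <- state_profiles(profile)
  stopifnot(inherits(profile, "state_profile"),
            inherits(montage, "montage_spec"))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  if (duration < 4) stop("duration must be >= 4 s (got ", duration, ")")
  if (fs < 60) stop("fs must be >= 60 Hz (got ", fs, ")")

  ch <- montage$channel_names
  nch <- length(ch)
  n <- round(duration * fs)
  rois <- shipped_rois(montage)
  groups <- list(
    global = ch,
    left   = intersect(ch, rois$left_frontotemporal),
    right  = intersect(ch, rois$right_frontotemporal),
    fo     = ch[montage$lobe_of %in% c("frontal", "occipital")]
  )
  bands <- eeg_bands()
  band_amp <- c(low = 1.0, high = 0.6)

  set.seed(seed)
  x <- matrix(0, nch, n, dimnames = list(ch, NULL))
  for (bn in names(bands)) {
    b <- bands[[bn]]
    cpl <- profile$coupling[bn, ]
    # sqrt maps coupling to source amplitude: the PLI response to a
    # shared source of amplitude a against unit background grows slowly
    # at small a, and sqrt keeps weak couplings detectable while
    # preserving the class ordering. Increments are taken on the sqrt
    # scale so a pair's total shared amplitude is sqrt(class coupling).
    amps <- c(global = sqrt(cpl[["other"]]),
              left   = sqrt(cpl[["within_left"]]) - sqrt(cpl[["other"]]),
              right  = sqrt(cpl[["within_right"]]) - sqrt(cpl[["other"]]),
              fo     = sqrt(cpl[["frontal_occipital"]]) - sqrt(cpl[["other"]]))
    shared <- matrix(0, nch, n)
    shared_amp <- numeric(nch)
    for (g in names(groups)) {
      if (amps[[g]] <= 0) next
      members <- groups[[g]]
      s <- fft_bandpass(stats::rnorm(n), b$f_lo, b$f_hi, fs)
      psi <- drop(analytic_signal(s / stats::sd(s)))
      m <- length(members)
      # golden-ratio scramble keeps the offsets spread over [0.45, 2.7]
      # while decorrelating the pairwise offset difference from channel
      # order, so no pair class is systematically favored
      theta <- if (m > 1) 0.45 + 2.25 * ((seq_len(m) * 0.6180339887) %% 1)
               else 1.5
      for (k in seq_along(members)) {
        i <- match(members[k], ch)
        shared[i, ] <- shared[i, ] +
          amps[[g]] * (cos(theta[k]) * Re(psi) - sin(theta[k]) * Im(psi))
        shared_amp[i] <- shared_amp[i] + amps[[g]]
      }
    }
    own <- fft_bandpass(matrix(stats::rnorm(n * nch), n, nch),
                        b$f_lo, b$f_hi, fs)
    own <- t(own) / apply(own, 2, stats::sd)
    own_amp <- pmax(0.25, 1 - shared_amp)
    x <- x + band_amp[[bn]] * (shared + own_amp * own)
  }
  x <- x + profile$noise_sd * matrix(stats::rnorm(n * nch), nch, n)
  eeg_recording(10 * x, fs, montage, condition = profile$name)
}

#' Generate a labeled two-group synthetic cohort
#'
#' Produces `n_per_group` independent recordings per state, with
#' per-subject seeds derived deterministically from the master seed.
#'
#' @param profile_a,profile_b [state_profile()]s or shipped profile
#'   names.
#' @param n_per_group subjects per group (>= 2).
#' @inheritParams generate_state_recording
#' @return List of `2 * n_per_group` [eeg_recording()]s; each carries
#'   its `condition` and a `subject_id` like `"fatigue_03"`.
#' @export
generate_cohort <- function(profile_a, profile_b, n_per_group = 13,
                            montage = default_montage(),
                            duration = 60, fs = 250, seed) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  if (n_per_group < 2)
    stop("n_per_group must be >= 2 (group statistics are undefined below that)")
  if (is.character(profile_a)) profile_a <- state_profiles(profile_a)
  if (is.character(profile_b)) profile_b <- state_profiles(profile_b)
  set.seed(seed)
  sseeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  recs <- vector("list", 2L * n_per_group)
  k <- 0L
  for (prof in list(profile_a, profile_b)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      r <- generate_state_recording(prof, montage, duration, fs,
                                    seed = sseeds[k])
      r$subject_id <- sprintf("%s_%02d", prof$name, i)
      recs[[k]] <- r
    }
  }
  recs
}
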