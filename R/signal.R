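#' Frequency band definition
#'
#' The analysis uses two bands: a low band pooling the theta and alpha
#' rhythms (4-13 Hz) and a high band covering beta (14-30 Hz). The
#' delta rhythm is excluded by design (it is tied to sleep and deep
#' anesthesia, not task states).
#'
#' @param name band label, conventionally `"low"` or `"high"`.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("band edges must satisfy 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Default analysis bands
#' @return Named list with `low` (4-13 Hz) and `high` (14-30 Hz)
#'   [band_definition()]s.
#' @export
eeg_bands <- function() {
  list(low = band_definition("low", 4, 13),
       high = band_definition("high", 14, 30))
}

# Zero-phase band-pass applied in the frequency domain with the squared
# magnitude response of an order-`order` Butterworth band-pass (the
# squared magnitude is what a forward-backward IIR pass realizes). The
# signal is reflection-padded before the FFT to suppress circular
# wrap-around. `x` is samples x channels (a matrix) or a vector.
fft_bandpass <- function(x, f_lo, f_hi, fs, order = 8) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- min(n, ceiling(2 * fs))
  xp <- rbind(x[pad:1, , drop = FALSE], x, x[n:(n - pad + 1), , drop = FALSE])
  np <- nrow(xp)
  f <- (seq_len(np) - 1) * fs / np
  f <- pmin(f, fs - f)                       # fold to [0, fs/2]
  hp <- (f / f_lo)^(2 * order)
  gain <- (hp / (1 + hp)) / (1 + (f / f_hi)^(2 * order))
  y <- Re(stats::mvfft(stats::mvfft(xp) * gain, inverse = TRUE)) / np
  y <- y[(pad + 1):(pad + n), , drop = FALSE]
  if (vec) drop(y) else y
}

# Analytic signal by the FFT method: zero out negative frequencies,
# double positive ones. `x` is samples x channels; returns a complex
# matrix of the same shape.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Preprocess a recording
#'
#' Removes the per-channel mean and applies a zero-phase 1-45 Hz
#' broadband filter. Ocular-artifact correction is intentionally out of
#' scope (it requires subject-specific EOG handling); inputs are assumed
#' artifact-clean or simulated.
#'
#' @param recording an [eeg_recording()].
#' @param f_lo,f_hi broadband edges in Hz.
#' @return A filtered [eeg_recording()].
#' @export
preprocess <- function(recording, f_lo = 1, f_hi = 45) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (f_hi >= recording$fs / 2)
    stop("broadband upper edge must be below the Nyquist frequency")
  x <- sweep(recording$data, 1, rowMeans(recording$data))
  y <- t(fft_bandpass(t(x), f_lo, f_hi, recording$fs))
  eeg_recording(y, recording$fs, recording$montage,
                recording$condition, recording$subject_id)
}

#' Band-pass filter a recording
#'
#' Zero-phase band-pass with a squared eighth-order Butterworth
#' magnitude response (flat passband, > 20 dB attenuation one octave
#' outside the edges).
#'
#' @param recording an [eeg_recording()].
#' @param band a [band_definition()].
#' @return A band-limited [eeg_recording()] carrying the band in
#'   attribute `"band"`.
#' @export
bandpass <- function(recording, band) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(band, "band_definition"))
  if (band$f_hi >= recording$fs / 2)
    stop("band edge ", band$f_hi, " Hz is not below Nyquist (fs = ",
         recording$fs, " Hz)")
  y <- t(fft_bandpass(t(recording$data), band$f_lo, band$f_hi, recording$fs))
  out <- eeg_recording(y, recording$fs, recording$montage,
                       recording$condition, recording$subject_id)
  attr(out, "band") <- band
  out
}

#' Instantaneous phase and amplitude
#'
#' Computes the analytic signal of each (already band-limited) channel
#' by the Hilbert transform; the instantaneous phase is its angle, the
#' instantaneous amplitude its modulus. The first and last second are
#' flagged as edge samples and excluded from downstream PLI estimation
#' (the analytic transform is unreliable there).
#'
#' @param recording a band-limited [eeg_recording()] (output of
#'   [bandpass()]).
#' @param edge_seconds length of each flagged edge (default 1 s).
#' @return An object of class `phase_array`: list with `phase`
#'   (channels x samples, radians in (-pi, pi\]), `amplitude`
#'   (nonnegative envelope), `fs`, `band`, `edge_samples`.
#' @export
instantaneous_phase <- function(recording, edge_seconds = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  sds <- apply(recording$data, 1, stats::sd)
  if (any(sds == 0))
    stop("phase undefined for constant channel(s): ",
         paste(rownames(recording$data)[sds == 0], collapse = ", "))
  psi <- analytic_signal(t(recording$data))
  structure(
    list(phase = t(Arg(psi)),
         amplitude = t(Mod(psi)),
         fs = recording$fs,
         band = attr(recording, "band"),
         condition = recording$condition,
         channel_names = recording$montage$channel_names,
         edge_samples = round(edge_seconds * recording$fs)),
    class = "phase_array"
  )
}

#' Split a recording into epochs
#'
#' Contiguous fixed-length windows; the trailing partial window is
#' dropped.
#'
#' @param recording an [eeg_recording()].
#' @param length epoch length in seconds (default 4).
#' @param overlap fractional overlap between consecutive epochs in
#'   \[0, 1) (default 0).
#' @return List of [eeg_recording()] epochs.
#' @export
epoch <- function(recording, length = 4, overlap = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  dur <- ncol(recording$data) / recording$fs
  if (length > dur)
    stop("epoch length (", length, " s) exceeds recording duration (",
         dur, " s)")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  step <- length * (1 - overlap)
  starts <- seq(0, dur - length, by = step)
  lapply(starts, function(s) {
    idx <- seq.int(round(s * recording$fs) + 1,
                   round(s * recording$fs) + round(length * recording$fs))
    eeg_recording(recording$data[, idx, drop = FALSE], recording$fs,
                  recording$montage, recording$condition,
                  recording$subject_id)
  })
}
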