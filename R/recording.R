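#' Multichannel EEG recording
#'
#' Container for a channels-by-samples EEG matrix with its sampling rate
#' and montage. Row order of `data` follows `montage$channel_names`.
#'
#' @param data numeric matrix, one row per channel (microvolts).
#' @param fs sampling rate in Hz; must exceed twice the highest band
#'   edge analysed (>= 60 Hz).
#' @param montage a [montage_spec()] whose channels match `nrow(data)`.
#' @param condition optional state label (e.g. `"fatigue"`).
#' @param subject_id optional identifier.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, montage = default_montage(),
                          condition = NULL, subject_id = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(montage$channel_names))
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$channel_names), " channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs < 60)
    stop("fs must be a single number >= 60 Hz")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  rownames(data) <- montage$channel_names
  structure(
    list(data = data, fs = fs, montage = montage,
         condition = condition, subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$condition)) cat(" [", x$condition, "]", sep = "")
  if (!is.null(x$subject_id)) cat(" subject ", x$subject_id, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
duration.eeg_recording <- function(x, ...) ncol(x$data) / x$fs

#' Recording duration in seconds
#' @param x an `eeg_recording`.
#' @param ... unused.
#' @export
duration <- function(x, ...) UseMethod("duration")
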