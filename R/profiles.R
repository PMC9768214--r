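#' Mental-state coupling profile
#'
#' A state profile parameterizes the synthetic generator: for each
#' frequency band (low = theta/alpha, high = beta) and each channel-pair
#' class it gives a target phase-coupling strength in \[0, 1\]. Pair
#' classes are `within_left` / `within_right` (both channels inside the
#' corresponding fronto-centro-temporal ROI), `frontal_occipital`
#' (spanning those two lobes) and `other` (everything else, i.e. the
#' global background coupling).
#'
#' Coupling for the structured classes must be at least the `other`
#' (background) value in the same band, because the generator realizes
#' structured coupling additively on top of the global background.
#'
#' @param name profile label.
#' @param coupling 2 x 4 numeric matrix, rows `low`/`high`, columns
#'   `within_left`, `within_right`, `frontal_occipital`, `other`, all in
#'   \[0, 1\].
#' @param asymmetry signed right-minus-left coupling offset in \[-1, 1\]
#'   (descriptive; derived from the coupling matrix for shipped
#'   profiles).
#' @param noise_sd broadband white-noise amplitude relative to the
#'   oscillatory components (default 1).
#'
#' @return An object of class `state_profile`.
#' @seealso [state_profiles()]
#' @export
state_profile <- function(name, coupling, asymmetry = 0, noise_sd = 1) {
  classes <- c("within_left", "within_right", "frontal_occipital", "other")
  coupling <- as.matrix(coupling)
  if (!identical(dim(coupling), c(2L, 4L)))
    stop("coupling must be a 2 x 4 matrix (bands x pair classes)")
  dimnames(coupling) <- list(c("low", "high"), classes)
  if (any(coupling < 0 | coupling > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (any(coupling[, classes[1:3]] < coupling[, "other"]))
    stop("structured coupling must be >= background ('other') coupling")
  if (abs(asymmetry) > 1) stop("asymmetry must lie in [-1, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name, coupling = coupling,
                 asymmetry = asymmetry, noise_sd = noise_sd),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat("<state_profile> ", x$name, " (noise_sd ", x$noise_sd,
      ", asymmetry ", x$asymmetry, ")\n", sep = "")
  print(round(x$coupling, 3))
  invisible(x)
}

#' Shipped mental-state profiles
#'
#' Six coupling profiles emulating the evoked states contrasted in the
#' analysis: `resting`, `fatigue` (dense global low-band coupling),
#' `attentive` (strong frontal-occipital coupling), `inattentive`
#' (weak coupling overall), `positive` (right-hemisphere dominance) and
#' `negative` (left-hemisphere dominance). Coupling magnitudes are
#' package calibration choices; the *contrasts* between profiles mirror
#' the qualitative connectivity differences the states are known for.
#'
#' @param name optional profile name; if given, that single profile is
#'   returned instead of the full list.
#' @return A named list of [state_profile()] objects, or one profile.
#' @examples
#' state_profiles("fatigue")
#' @export
state_profiles <- function(name = NULL) {
  cp <- function(low, high) rbind(low = low, high = high)
  profs <- list(
    resting = state_profile(
      "resting",
      cp(c(0.35, 0.25, 0.15, 0.05), c(0.30, 0.22, 0.14, 0.05))),
    fatigue = state_profile(
      "fatigue",
      cp(c(0.80, 0.66, 0.56, 0.45), c(0.48, 0.38, 0.31, 0.24))),
    attentive = state_profile(
      "attentive",
      cp(c(0.30, 0.18, 0.60, 0.06), c(0.26, 0.16, 0.45, 0.06))),
    inattentive = state_profile(
      "inattentive",
      cp(c(0.20, 0.12, 0.06, 0.02), c(0.16, 0.10, 0.05, 0.02))),
    positive = state_profile(
      "positive",
      cp(c(0.25, 0.55, 0.14, 0.05), c(0.22, 0.45, 0.12, 0.05)),
      asymmetry = 0.30),
    negative = state_profile(
      "negative",
      cp(c(0.55, 0.25, 0.14, 0.05), c(0.45, 0.22, 0.12, 0.05)),
      asymmetry = -0.30)
  )
  if (is.null(name)) return(profs)
  if (!name %in% names(profs))
    stop("unknown profile '", name, "'; available: ",
         paste(names(profs), collapse = ", "))
  profs[[name]]
}
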