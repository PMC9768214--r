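#' Phase lag index between two phase series
#'
#' PLI is the absolute time-average of the sign of the wrapped phase
#' difference, `|<sign(dphi)>|`. It is 0 for a symmetric
#' phase-difference distribution (including identical signals, since
#' `sign(0) = 0`) and 1 for a perfectly constant-sign lag, and it is
#' insensitive to zero-lag (volume-conduction) coupling by
#' construction. Phase differences are wrapped to (-pi, pi\] before the
#' sign is taken, so a constant small negative lag is not mistaken for a
#' positive one.
#'
#' @param phase_a,phase_b numeric vectors of instantaneous phase
#'   (radians), equal length >= 100 samples, edge samples already
#'   removed.
#' @return Scalar in \[0, 1\].
#' @examples
#' ph <- seq(0, 40 * pi, length.out = 1000)
#' pli_pair(ph, ph - pi / 4)  # constant lag -> 1
#' pli_pair(ph, ph)           # zero lag -> 0
#' @export
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stop("phase series have different lengths (",
         length(phase_a), " vs ", length(phase_b), ")")
  if (length(phase_a) < 100)
    stop("need at least 100 samples for a stable PLI estimate (got ",
         length(phase_a), ")")
  cpp_pli_pair(as.numeric(phase_a), as.numeric(phase_b))
}

#' PLI connectivity matrix
#'
#' Computes the phase lag index between every channel pair of a
#' [instantaneous_phase()] output. Edge-flagged samples are dropped,
#' the remainder is split into epochs, PLI is computed per epoch and
#' pair, and epochs are averaged (set `epoch_length = NULL` to pool all
#' samples into a single estimate instead).
#'
#' @param phases a `phase_array`.
#' @param epoch_length epoch length in seconds (default 4) or `NULL`.
#' @return An object of class `pli_matrix`: list with `values` (N x N
#'   symmetric, zero diagonal, entries in \[0, 1\]), `band`,
#'   `condition`, `n_epochs`, `channel_names`.
#' @export
pli_matrix <- function(phases, epoch_length = 4) {
  stopifnot(inherits(phases, "phase_array"))
  ph <- phases$phase
  if (nrow(ph) < 2) stop("need at least 2 channels for connectivity")
  e <- phases$edge_samples
  keep <- seq.int(e + 1, ncol(ph) - e)
  if (length(keep) < 100)
    stop("too few samples remain after edge exclusion")
  ph <- ph[, keep, drop = FALSE]
  if (is.null(epoch_length)) {
    starts <- 1L
    len <- ncol(ph)
  } else {
    len <- round(epoch_length * phases$fs)
    if (len > ncol(ph))
      stop("epoch_length exceeds the usable (edge-trimmed) duration")
    starts <- seq.int(1L, ncol(ph) - len + 1L, by = len)
  }
  acc <- matrix(0, nrow(ph), nrow(ph))
  for (s in starts)
    acc <- acc + cpp_pli_matrix(ph[, s:(s + len - 1L), drop = FALSE])
  v <- acc / length(starts)
  dimnames(v) <- list(phases$channel_names, phases$channel_names)
  structure(
    list(values = v, band = phases$band, condition = phases$condition,
         n_epochs = length(starts), channel_names = phases$channel_names),
    class = "pli_matrix"
  )
}

#' @export
print.pli_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<pli_matrix> %d channels, %d epoch(s), mean PLI %.3f",
              nrow(x$values), x$n_epochs, mean(off)))
  if (!is.null(x$band)) cat(" [", x$band$name, " band]", sep = "")
  if (!is.null(x$condition)) cat(" [", x$condition, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Average PLI matrices across subjects
#'
#' Element-wise arithmetic mean of connectivity matrices sharing shape
#' and band (the condition-level mean network).
#'
#' @param matrices list of `pli_matrix` objects.
#' @return A `pli_matrix` with `n_epochs` summed.
#' @export
average_pli <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "pli_matrix")))
  dims <- vapply(matrices, function(m) nrow(m$values), integer(1))
  if (length(unique(dims)) != 1) stop("matrices have mixed sizes")
  bands <- vapply(matrices,
                  function(m) if (is.null(m$band)) "" else m$band$name,
                  character(1))
  if (length(unique(bands)) != 1) stop("matrices come from mixed bands")
  v <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  out <- matrices[[1]]
  out$values <- v
  out$n_epochs <- sum(vapply(matrices, `[[`, integer(1), "n_epochs"))
  out
}

# Mean off-diagonal PLI, a convenient scalar density summary.
#' @rdname pli_matrix
#' @param x a `pli_matrix`.
#' @export
mean_pli <- function(x) {
  stopifnot(inherits(x, "pli_matrix"))
  mean(x$values[upper.tri(x$values)])
}
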