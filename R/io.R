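#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds one row per sample and one column per channel (header
#' = channel labels); the sidecar (same path with `.json` appended to
#' the stem) records the sampling rate, condition and subject id.
#'
#' @param recording an [eeg_recording()].
#' @param path CSV file path (the sidecar replaces the extension with
#'   `.json`).
#' @return (Invisibly) the CSV path.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  df <- as.data.frame(t(recording$data))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = recording$fs,
               condition = recording$condition,
               subject_id = recording$subject_id,
               channel_names = recording$montage$channel_names)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname write_recording
#' @param montage montage to attach on read; channels are matched (and
#'   reordered) by label.
#' @export
read_recording <- function(path, montage = default_montage()) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar (", sc, "): sampling rate unknown")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar lacks the sampling rate 'fs'")
  df <- utils::read.csv(path, check.names = FALSE)
  unknown <- setdiff(names(df), montage$channel_names)
  if (length(unknown))
    stop("channel label(s) not in montage: ",
         paste(unknown, collapse = ", "))
  missing_ch <- setdiff(montage$channel_names, names(df))
  if (length(missing_ch))
    stop("montage channel(s) missing from file: ",
         paste(missing_ch, collapse = ", "))
  eeg_recording(t(as.matrix(df[, montage$channel_names])), meta$fs,
                montage,
                condition = meta$condition,
                subject_id = meta$subject_id)
}

#' Write / read a PLI matrix as CSV
#'
#' N x N values with channel-name header and row names; metadata (band,
#' condition, epochs) goes to a JSON sidecar.
#'
#' @param x a [pli_matrix()].
#' @param path CSV file path.
#' @return (Invisibly) the CSV path.
#' @export
write_pli <- function(x, path) {
  stopifnot(inherits(x, "pli_matrix"))
  utils::write.csv(as.data.frame(x$values), path, row.names = TRUE)
  meta <- list(band = if (is.null(x$band)) NULL else unclass(x$band),
               condition = x$condition, n_epochs = x$n_epochs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pli
#' @export
read_pli <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  v <- as.matrix(df)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list()
  band <- if (!is.null(meta$band))
    band_definition(meta$band$name, meta$band$f_lo, meta$band$f_hi)
  else NULL
  structure(list(values = v, band = band, condition = meta$condition,
                 n_epochs = if (is.null(meta$n_epochs)) 1L
                            else meta$n_epochs,
                 channel_names = rownames(v)),
            class = "pli_matrix")
}

#' Heat-map of a PLI matrix
#'
#' Base-graphics image of the connectivity matrix with channels ordered
#' front-to-back (by lobe) or by hemisphere (left, midline, right).
#'
#' @param x a [pli_matrix()].
#' @param montage a [montage_spec()] for the ordering.
#' @param order `"front_to_back"` or `"hemisphere"`.
#' @param ... passed to [graphics::image()].
#' @return (Invisibly) the channel order used.
#' @export
plot_pli <- function(x, montage = default_montage(),
                     order = c("front_to_back", "hemisphere"), ...) {
  stopifnot(inherits(x, "pli_matrix"))
  order <- match.arg(order)
  ch <- montage$channel_names
  ord <- if (order == "front_to_back") {
    lobe_rank <- c(frontal = 1, central = 2, temporal = 3,
                   parietal = 4, occipital = 5)
    ch[order(lobe_rank[montage$lobe_of[ch]])]
  } else {
    hemi_rank <- c(left = 1, midline = 2, right = 3)
    ch[order(hemi_rank[montage$hemisphere_of[ch]])]
  }
  v <- x$values[ord, rev(ord)]
  graphics::image(seq_along(ord), seq_along(ord), v,
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  ...)
  graphics::axis(1, seq_along(ord), ord, las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_along(ord), rev(ord), las = 2, cex.axis = 0.6)
  invisible(ord)
}
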