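#' Electrode montage specification
#'
#' A montage maps each EEG channel label to a cortical lobe and a
#' hemisphere, following the 10-20 naming convention (odd index = left,
#' even = right, trailing "z" = midline). Montages drive the synthetic
#' generator's region-based coupling and the ROI aggregation of nodal
#' metrics.
#'
#' @param channel_names character vector of electrode labels, in the
#'   channel order of the recordings.
#' @param lobe_of named character vector mapping every channel to one of
#'   `"frontal"`, `"central"`, `"parietal"`, `"temporal"`, `"occipital"`.
#' @param hemisphere_of named character vector mapping every channel to
#'   `"left"`, `"right"` or `"midline"`.
#'
#' @return An object of class `montage_spec` with elements
#'   `channel_names`, `lobe_of`, `hemisphere_of`.
#' @seealso [default_montage()]
#' @export
montage_spec <- function(channel_names, lobe_of, hemisphere_of) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("duplicate channel labels in montage")
  lobes <- c("frontal", "central", "parietal", "temporal", "occipital")
  hemis <- c("left", "right", "midline")
  if (!setequal(names(lobe_of), channel_names) ||
      !setequal(names(hemisphere_of), channel_names))
    stop("lobe_of and hemisphere_of must cover exactly the montage channels")
  lobe_of <- lobe_of[channel_names]
  hemisphere_of <- hemisphere_of[channel_names]
  if (!all(lobe_of %in% lobes))
    stop("unknown lobe label: ", paste(setdiff(lobe_of, lobes), collapse = ", "))
  if (!all(hemisphere_of %in% hemis))
    stop("unknown hemisphere label: ",
         paste(setdiff(hemisphere_of, hemis), collapse = ", "))
  structure(
    list(channel_names = channel_names,
         lobe_of = lobe_of,
         hemisphere_of = hemisphere_of),
    class = "montage_spec"
  )
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", length(x$channel_names), " channels\n", sep = "")
  cat("  lobes: ", paste(sprintf("%s=%d", names(table(x$lobe_of)),
                                 table(x$lobe_of)), collapse = " "), "\n")
  invisible(x)
}

#' Default 30-channel 10-20 montage
#'
#' A standard 30-electrode 10-20 layout covering frontal, central,
#' parietal, temporal and occipital regions of both hemispheres. It
#' contains all channels used in the shipped ROI sets (F3, F7, FC1, FC5,
#' C3, T7 on the left; F4, F8, FC2, FC6, C4, T8 on the right).
#'
#' @return A [montage_spec()] with 30 channels.
#' @examples
#' m <- default_montage()
#' m$lobe_of[["O1"]]
#' @export
default_montage <- function() {
  ch <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
          "FC5", "FC1", "FC2", "FC6",
          "T7", "C3", "Cz", "C4", "T8",
          "CP5", "CP1", "CP2", "CP6",
          "P7", "P3", "Pz", "P4", "P8",
          "PO3", "PO4", "O1", "Oz", "O2")
  lobe <- c(Fp1 = "frontal", Fp2 = "frontal", F7 = "frontal", F3 = "frontal",
            Fz = "frontal", F4 = "frontal", F8 = "frontal",
            FC5 = "frontal", FC1 = "frontal", FC2 = "frontal", FC6 = "frontal",
            T7 = "temporal", C3 = "central", Cz = "central", C4 = "central",
            T8 = "temporal",
            CP5 = "parietal", CP1 = "parietal", CP2 = "parietal",
            CP6 = "parietal",
            P7 = "parietal", P3 = "parietal", Pz = "parietal", P4 = "parietal",
            P8 = "parietal",
            PO3 = "occipital", PO4 = "occipital",
            O1 = "occipital", Oz = "occipital", O2 = "occipital")
  hemi_of_label <- function(lab) {
    if (grepl("z$", lab)) return("midline")
    digits <- gsub("[^0-9]", "", lab)
    if (as.integer(digits) %% 2L == 1L) "left" else "right"
  }
  hemi <- vapply(ch, hemi_of_label, character(1))
  montage_spec(ch, lobe, hemi)
}

#' Shipped regions of interest
#'
#' Named channel sets used for ROI aggregation: the left and right
#' fronto-centro-temporal sets used for hemispheric contrasts, and the
#' five lobes of the montage.
#'
#' @param montage a [montage_spec()]; defaults to [default_montage()].
#' @return Named list of character vectors of channel labels.
#' @export
shipped_rois <- function(montage = default_montage()) {
  rois <- list(
    left_frontotemporal  = c("F3", "F7", "FC1", "FC5", "C3", "T7"),
    right_frontotemporal = c("F4", "F8", "FC2", "FC6", "C4", "T8")
  )
  for (lb in unique(unname(montage$lobe_of)))
    rois[[lb]] <- montage$channel_names[montage$lobe_of == lb]
  rois
}

# Class of a channel pair, used both by the generator's coupling model
# and by the structure-recovery diagnostics. A pair is "within_left" /
# "within_right" when both channels lie in the corresponding
# fronto-centro-temporal ROI, "frontal_occipital" when the two channels
# span the frontal and occipital lobes, and "other" otherwise. The ROI
# sets do not contain occipital channels, so the classes are disjoint.
#' Channel-pair coupling class
#'
#' @param ch_a,ch_b channel labels.
#' @param montage a [montage_spec()].
#' @return One of `"within_left"`, `"within_right"`,
#'   `"frontal_occipital"`, `"other"`.
#' @export
pair_class <- function(ch_a, ch_b, montage = default_montage()) {
  rois <- shipped_rois(montage)
  in_l <- c(ch_a, ch_b) %in% rois$left_frontotemporal
  in_r <- c(ch_a, ch_b) %in% rois$right_frontotemporal
  if (all(in_l)) return("within_left")
  if (all(in_r)) return("within_right")
  lb <- montage$lobe_of[c(ch_a, ch_b)]
  if (setequal(lb, c("frontal", "occipital"))) return("frontal_occipital")
  "other"
}
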