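#' Process one recording into a PLI matrix
#'
#' The per-recording chain: preprocess (demean + 1-45 Hz), band-pass,
#' instantaneous phase, epoch-averaged PLI.
#'
#' @param recording an [eeg_recording()].
#' @param band a [band_definition()].
#' @param epoch_length PLI epoch length in seconds (see
#'   [pli_matrix()]).
#' @return A [pli_matrix()].
#' @export
process_recording <- function(recording, band = eeg_bands()$low,
                              epoch_length = 4) {
  recording |>
    preprocess() |>
    bandpass(band) |>
    instantaneous_phase() |>
    pli_matrix(epoch_length = epoch_length)
}

#' Per-subject range-averaged network metrics for a cohort
#'
#' Runs the full per-subject chain (preprocess, band-pass, phase, PLI,
#' sparsity sweep) and returns a tidy data.frame with one row per
#' recording: the range-averaged global metrics plus the hemispheric
#' and lobe ROI means of nodal local efficiency (columns `NE_left`,
#' `NE_right`, `NE_frontal`, ...).
#'
#' @param recordings list of labeled [eeg_recording()]s (e.g. from
#'   [generate_cohort()]).
#' @param band a [band_definition()].
#' @param grid sparsity grid (see [sparsity_sweep()]).
#' @param n_realizations rewired references per sparsity; 0 skips
#'   gamma/lambda/sigma.
#' @param seed integer seed for the reference networks.
#' @param epoch_length PLI epoch length in seconds.
#' @return data.frame, one row per recording.
#' @export
pipeline_metrics <- function(recordings, band = eeg_bands()$low,
                             grid = seq(0.05, 0.40, by = 0.05),
                             n_realizations = 20, seed = 1,
                             epoch_length = 4) {
  stopifnot(length(recordings) >= 1)
  rows <- vector("list", length(recordings))
  for (k in seq_along(recordings)) {
    rec <- recordings[[k]]
    conn <- process_recording(rec, band, epoch_length)
    sw <- sparsity_sweep(conn, grid, n_realizations, seed = seed + k)
    av <- sw$averaged
    roi_h <- roi_aggregate(av$NE_loc, rec$montage, "hemisphere")
    roi_l <- roi_aggregate(av$NE_loc, rec$montage, "lobe")
    rows[[k]] <- data.frame(
      subject_id = if (is.null(rec$subject_id)) paste0("s", k)
                   else rec$subject_id,
      condition = if (is.null(rec$condition)) NA_character_
                  else rec$condition,
      band = band$name,
      C = av$C, L = av$L, gamma = av$gamma, lambda = av$lambda,
      sigma = av$sigma, E_g = av$E_g, E_loc = av$E_loc,
      NE_left = unname(roi_h[["left_frontotemporal"]]),
      NE_right = unname(roi_h[["right_frontotemporal"]]),
      t(vapply(names(roi_l), function(r) roi_l[[r]], numeric(1))) |>
        as.data.frame() |>
        stats::setNames(paste0("NE_", names(roi_l)))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end chain and validates it
#' against the constraints of the owning stages. Round-trips through
#' JSON via [save_config()] / [load_config()].
#'
#' @param profile_a,profile_b names of shipped state profiles.
#' @param n_per_group subjects per group.
#' @param duration,fs simulation length (s) and sampling rate (Hz).
#' @param epoch_length PLI epoch length (s).
#' @param sparsity_grid sparsity fractions in (0, 1\].
#' @param n_random_realizations rewired references per sparsity.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(profile_a = "resting", profile_b = "fatigue",
                            n_per_group = 13, duration = 60, fs = 250,
                            epoch_length = 4,
                            sparsity_grid = seq(0.05, 0.40, by = 0.05),
                            n_random_realizations = 20, seed = 1) {
  state_profiles(profile_a); state_profiles(profile_b)  # validates names
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (duration < 4) stop("duration must be >= 4 s")
  if (fs < 60) stop("fs must be >= 60 Hz")
  if (length(sparsity_grid) == 0 ||
      any(sparsity_grid <= 0 | sparsity_grid > 1))
    stop("sparsity_grid values must lie in (0, 1]")
  if (epoch_length <= 0) stop("epoch_length must be positive")
  if (n_random_realizations < 0) stop("n_random_realizations must be >= 0")
  structure(list(profile_a = profile_a, profile_b = profile_b,
                 n_per_group = n_per_group, duration = duration, fs = fs,
                 epoch_length = epoch_length,
                 sparsity_grid = sparsity_grid,
                 n_random_realizations = n_random_realizations,
                 seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full analysis chain on a simulated cohort
#'
#' Generates a two-state cohort, runs preprocess, band-pass (both
#' bands), instantaneous phase, PLI, the sparsity sweep and the group
#' comparison, and writes all artifacts under `out_dir`: condition-mean
#' PLI matrices (CSV), per-subject metrics (CSV), the comparison table
#' (CSV), and a JSON run manifest holding the full configuration. Runs
#' with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param bands bands to analyse (default both shipped bands).
#' @return (Invisibly) a list with `metrics` (per band), `comparisons`,
#'   `mean_pli` and the config.
#' @export
run_pipeline <- function(config, out_dir = NULL, bands = eeg_bands()) {
  stopifnot(inherits(config, "pipeline_config"))
  recs <- generate_cohort(config$profile_a, config$profile_b,
                          config$n_per_group,
                          duration = config$duration, fs = config$fs,
                          seed = config$seed)
  metrics <- list()
  mean_mats <- list()
  comparisons <- list()
  for (bn in names(bands)) {
    b <- bands[[bn]]
    metrics[[bn]] <- pipeline_metrics(
      recs, b, config$sparsity_grid, config$n_random_realizations,
      seed = config$seed, epoch_length = config$epoch_length)
    for (cond in c(config$profile_a, config$profile_b)) {
      mats <- lapply(Filter(function(r) r$condition == cond, recs),
                     process_recording, band = b,
                     epoch_length = config$epoch_length)
      mean_mats[[paste(bn, cond, sep = "_")]] <- average_pli(mats)
    }
    cmp_metrics <- c("sigma", "gamma", "lambda", "E_g", "E_loc",
                     "NE_left", "NE_right")
    if (config$n_random_realizations == 0)
      cmp_metrics <- setdiff(cmp_metrics, c("sigma", "gamma", "lambda"))
    cmp <- do.call(rbind, lapply(cmp_metrics, function(m)
      compare_conditions(metrics[[bn]], m,
                         c(config$profile_a, config$profile_b))))
    cmp$band <- bn
    comparisons[[bn]] <- cmp
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL
  bundle <- list(config = config, metrics = metrics,
                 comparisons = comparisons, mean_pli = mean_mats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (bn in names(metrics))
      utils::write.csv(metrics[[bn]],
                       file.path(out_dir, paste0("metrics_", bn, ".csv")),
                       row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    for (nm in names(mean_mats))
      write_pli(mean_mats[[nm]],
                file.path(out_dir, paste0("pli_", nm, ".csv")))
    manifest <- list(package = "plinet",
                     version = as.character(utils::packageVersion("plinet")),
                     r_version = R.version.string,
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
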