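#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t with pooled variance and a two-sided p-value
#' on `n_a + n_b - 2` degrees of freedom (the convention used for all
#' group comparisons here; set `welch = TRUE` for the unequal-variance
#' form). Two groups that are constant and equal give `t = 0, p = 1`;
#' constant but unequal groups are rejected as degenerate.
#'
#' @param a,b numeric sample vectors (each n >= 2, finite).
#' @param welch use the Welch form instead of pooled variance.
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  if (welch) {
    res <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(res$statistic), p = res$p.value,
                df = unname(res$parameter)))
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = df))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Cohen's d effect size
#'
#' `(mean_a - mean_b)` divided by the pooled standard deviation (n-1
#' weighting).
#'
#' @param a,b numeric sample vectors (each n >= 2).
#' @return Signed effect size.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation: d is undefined")
  (mean(a) - mean(b)) / sp
}

comparison_result <- function(metric_name, group_names, a, b, welch = FALSE) {
  tt <- two_sample_ttest(a, b, welch)
  d <- if (mean(a) == mean(b)) 0 else cohens_d(a, b)
  data.frame(metric = metric_name,
             group_a = group_names[1], group_b = group_names[2],
             mean_a = mean(a), mean_b = mean(b),
             t = tt$t, p = tt$p, d = d,
             n_a = length(a), n_b = length(b))
}

#' ROI aggregation of nodal values
#'
#' Averages a per-channel vector (typically nodal local efficiency)
#' over regions of interest: the five lobes, the two hemispheric
#' fronto-centro-temporal sets, or custom channel sets.
#'
#' @param nodal_values named numeric vector, one value per channel.
#' @param montage a [montage_spec()].
#' @param grouping `"lobe"`, `"hemisphere"` (the two shipped ROI sets),
#'   or a named list of channel-label vectors.
#' @return Named numeric vector of ROI means.
#' @examples
#' g <- threshold_by_sparsity(diag(0, 30) + 0.5, 0.2)
#' ne <- stats::setNames(runif(30), default_montage()$channel_names)
#' roi_aggregate(ne, grouping = "hemisphere")
#' @export
roi_aggregate <- function(nodal_values, montage = default_montage(),
                          grouping = "lobe") {
  rois <- if (is.list(grouping)) grouping
  else if (identical(grouping, "lobe"))
    shipped_rois(montage)[unique(unname(montage$lobe_of))]
  else if (identical(grouping, "hemisphere"))
    shipped_rois(montage)[c("left_frontotemporal", "right_frontotemporal")]
  else stop("grouping must be 'lobe', 'hemisphere', or a named list")
  unknown <- setdiff(unlist(rois), names(nodal_values))
  if (length(unknown))
    stop("channel(s) not present in nodal values: ",
         paste(unknown, collapse = ", "))
  vapply(rois, function(chs) mean(nodal_values[chs]), numeric(1))
}

scale_grades <- c("very-low", "low", "medium", "high", "very-high")

#' Subjective-scale rating vector
#'
#' Six ordinal indicators, each on a 5-grade scale
#' (`very-low` ... `very-high`), used to label the mental state a
#' participant reports.
#'
#' @param effort,temporal_demand,performance,fatigue_degree,arousal,valence
#'   grades from the 5-level set.
#' @return Named character vector of class `subjective_scale`.
#' @export
subjective_scale <- function(effort, temporal_demand, performance,
                             fatigue_degree, arousal, valence) {
  v <- c(effort = effort, temporal_demand = temporal_demand,
         performance = performance, fatigue_degree = fatigue_degree,
         arousal = arousal, valence = valence)
  bad <- setdiff(v, scale_grades)
  if (length(bad))
    stop("invalid grade(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(scale_grades, collapse = ", "), ")")
  structure(v, class = "subjective_scale")
}

# The state rule table. "/" (NA) matches any grade; "ge-medium" matches
# {medium, high, very-high}. Rows are evaluated in fixed order and the
# first match wins.
state_rules <- function() {
  list(
    attentive   = list(temporal_demand = "medium", arousal = "ge-medium",
                       valence = "medium"),
    inattentive = list(effort = "low", temporal_demand = "low",
                       arousal = "low", valence = "low"),
    fatigue     = list(fatigue_degree = "high", arousal = "low",
                       valence = "medium"),
    positive    = list(performance = "high", arousal = "ge-medium",
                       valence = "high"),
    negative    = list(performance = "low", arousal = "ge-medium",
                       valence = "low")
  )
}

#' Label the mental state of a subjective-scale vector
#'
#' Applies the fixed rule table (attentive, inattentive, fatigue,
#' positive, negative, in that order) and returns the first matching
#' state, or `"unclassified"` when no rule matches. Unconstrained
#' indicators match any grade; threshold constraints ("at least
#' medium") match the upper three grades. When several rules match, the
#' first one wins and the others are reported via `message()`.
#'
#' @param scale a [subjective_scale()].
#' @param quiet suppress the multi-match message.
#' @return A state label or `"unclassified"`.
#' @examples
#' label_state(subjective_scale("medium", "medium", "medium",
#'                              "medium", "high", "medium"))  # attentive
#' @export
label_state <- function(scale, quiet = FALSE) {
  stopifnot(inherits(scale, "subjective_scale"))
  ord <- match(scale, scale_grades)
  names(ord) <- names(scale)
  matches <- vapply(state_rules(), function(rule) {
    all(vapply(names(rule), function(ind) {
      req <- rule[[ind]]
      if (req == "ge-medium") ord[[ind]] >= 3 else scale[[ind]] == req
    }, logical(1)))
  }, logical(1))
  if (!any(matches)) return("unclassified")
  hit <- names(matches)[matches]
  if (length(hit) > 1 && !quiet)
    message("multiple state rules match (", paste(hit, collapse = ", "),
            "); returning the first")
  hit[1]
}

#' Compare a network metric between two conditions
#'
#' Two-sample t-test and Cohen's d on per-subject range-averaged
#' metrics. `cohort_metrics` is a data.frame with one row per subject
#' (e.g. from [pipeline_metrics()]) containing a `condition` column and
#' metric columns.
#'
#' @param cohort_metrics data.frame of per-subject metrics.
#' @param metric metric column to compare (e.g. `"sigma"`, `"E_g"`).
#' @param conditions optional length-2 character vector selecting and
#'   ordering the two groups (difference is a - b); defaults to the two
#'   conditions in order of appearance.
#' @param welch use the Welch t-test.
#' @return One-row data.frame: metric, groups, means, t, p, d, group
#'   sizes.
#' @export
compare_conditions <- function(cohort_metrics, metric, conditions = NULL,
                               welch = FALSE) {
  if (!metric %in% names(cohort_metrics))
    stop("metric '", metric, "' not found in cohort metrics")
  if (is.null(conditions))
    conditions <- unique(cohort_metrics$condition)[1:2]
  if (length(conditions) != 2 || anyNA(conditions))
    stop("need exactly two conditions to compare")
  a <- cohort_metrics[cohort_metrics$condition == conditions[1], metric]
  b <- cohort_metrics[cohort_metrics$condition == conditions[2], metric]
  if (length(a) < 2 || length(b) < 2)
    stop("each condition needs at least 2 subjects (got ",
         length(a), " and ", length(b), ")")
  comparison_result(metric, conditions, a, b, welch)
}

#' Compare behavioral scores before and after training
#'
#' Same machinery as [compare_conditions()] applied to scalar scores;
#' the reported difference (and the signs of t and d) is after minus
#' before.
#'
#' @param before,after numeric score vectors (each n >= 2).
#' @param metric_name label for the output row.
#' @param welch use the Welch t-test.
#' @return One-row data.frame as in [compare_conditions()].
#' @export
compare_scores <- function(before, after, metric_name = "score",
                           welch = FALSE) {
  comparison_result(metric_name, c("after", "before"), after, before, welch)
}
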