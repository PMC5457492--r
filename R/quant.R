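#' Trimmed-mean normalization factor
#'
#' Per-sample scaling factor for pooled-screen counts: the mean of the
#' non-targeting control counts lying within the 10th-90th percentile
#' interval (inclusive; percentiles by linear interpolation). Trimming makes
#' the factor robust to the handful of massively enriched guides seen in
#' positive-selection screens.
#'
#' @param control_counts Non-negative integer counts of the non-targeting
#'   control sgRNAs in one sample.
#' @param lo_pct,hi_pct Trim percentiles (defaults 10 and 90).
#' @return A positive scalar.
#' @export
trimmed_mean_factor <- function(control_counts, lo_pct = 10, hi_pct = 90) {
  if (length(control_counts) == 0) abort("no control counts supplied")
  if (any(control_counts < 0)) abort("control counts must be non-negative")
  if (all(control_counts == 0)) {
    abort("all control counts are zero; normalization factor undefined")
  }
  bounds <- quantile(control_counts, probs = c(lo_pct, hi_pct) / 100,
                     type = 7, names = FALSE)
  kept <- control_counts[control_counts >= bounds[1] &
                           control_counts <= bounds[2]]
  if (length(kept) == 0 || mean(kept) <= 0) {
    abort("trimmed control counts give a non-positive normalization factor")
  }
  mean(kept)
}

#' Per-sample normalization factors
#'
#' @param counts Long count tibble ([read_counts()]).
#' @param control_ids Character vector of non-targeting control sgRNA ids.
#' @inheritParams trimmed_mean_factor
#' @return A tibble with columns `sample_id`, `norm_factor`.
#' @export
norm_factors <- function(counts, control_ids, lo_pct = 10, hi_pct = 90) {
  if (length(control_ids) == 0) abort("control set is empty")
  if (!any(counts$sgrna_id %in% control_ids)) {
    abort("none of the control ids are present in the count table")
  }
  counts |>
    dplyr::filter(.data$sgrna_id %in% control_ids) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(norm_factor = trimmed_mean_factor(.data$count,
                                                       lo_pct, hi_pct),
                     .groups = "drop")
}

#' Log-transformed, control-normalized sgRNA abundance
#'
#' For sample j with trimmed-mean control factor c_j, the abundance of guide
#' i is y_ij = log2(x_ij / c_j + eps). The small constant eps (default 0.05)
#' stabilizes the transform at low counts and keeps zero-count guides finite,
#' so no guide is filtered. A guide at control-typical abundance has y near 0.
#'
#' @inheritParams norm_factors
#' @param epsilon Stabilizing constant added inside the log (default 0.05).
#' @return The count tibble with an added `log_abundance` column; the
#'   normalization factors and `epsilon` are attached as attributes
#'   `norm_factors` and `epsilon`.
#' @export
log_abundance <- function(counts, control_ids, epsilon = 0.05,
                          lo_pct = 10, hi_pct = 90) {
  nf <- norm_factors(counts, control_ids, lo_pct, hi_pct)
  ab <- counts |>
    dplyr::left_join(nf, by = "sample_id") |>
    dplyr::mutate(log_abundance = log2(.data$count / .data$norm_factor +
                                         epsilon)) |>
    dplyr::select(-"norm_factor")
  attr(ab, "norm_factors") <- nf
  attr(ab, "epsilon") <- epsilon
  ab
}

#' Merge biological replicates
#'
#' Replicates are averaged in log-transformed space, per condition.
#'
#' @param ab Abundance tibble from [log_abundance()].
#' @param groups Optional named list mapping condition names to sample ids;
#'   by default the `condition` column groups samples.
#' @return A tibble with columns `sgrna_id`, `condition`, `log_abundance`.
#' @export
merge_replicates <- function(ab, groups = NULL) {
  if (!is.null(groups)) {
    unknown <- setdiff(unlist(groups), as.character(unique(ab$sample_id)))
    if (length(unknown) > 0) {
      abort(paste0("replicate group references unknown sample(s): ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(lengths(groups) == 0)) abort("empty replicate group")
    map <- tibble::tibble(
      sample_id = unlist(groups, use.names = FALSE),
      condition = rep(names(groups), lengths(groups)))
    ab <- ab |>
      dplyr::select(-dplyr::any_of("condition")) |>
      dplyr::inner_join(map, by = dplyr::join_by("sample_id" ==
                                                   "sample_id"))
  }
  ab |>
    dplyr::group_by(.data$sgrna_id, .data$condition) |>
    dplyr::summarise(log_abundance = mean(.data$log_abundance),
                     .groups = "drop")
}

#' Log fold-change between conditions
#'
#' lfc_i = y_i(late) - y_i(early) on replicate-merged log abundances;
#' negative values indicate depletion (fitness cost).
#'
#' @param ab_merged Output of [merge_replicates()].
#' @param early,late Condition labels.
#' @return A tibble with columns `sgrna_id`, `lfc`; the condition pair is
#'   attached as attribute `condition_pair`.
#' @export
log_fold_change <- function(ab_merged, early, late) {
  conds <- unique(ab_merged$condition)
  if (!early %in% conds) abort(paste0("condition not found: ", early))
  if (!late %in% conds) abort(paste0("condition not found: ", late))
  wide <- ab_merged |>
    dplyr::filter(.data$condition %in% c(early, late)) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "log_abundance")
  out <- tibble::tibble(sgrna_id = wide$sgrna_id,
                        lfc = wide[[late]] - wide[[early]])
  out <- out[complete.cases(out), ]
  attr(out, "condition_pair") <- c(early = early, late = late)
  out
}

#' Counts-to-fold-change convenience pipeline
#'
#' Runs [log_abundance()], [merge_replicates()] and [log_fold_change()] with
#' the package defaults.
#'
#' @inheritParams log_abundance
#' @inheritParams log_fold_change
#' @return A fold-change tibble (`sgrna_id`, `lfc`).
#' @export
counts_to_lfc <- function(counts, control_ids, early = "early",
                          late = "late", epsilon = 0.05) {
  counts |>
    log_abundance(control_ids, epsilon = epsilon) |>
    merge_replicates() |>
    log_fold_change(early, late)
}
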