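# Per-nucleus ring intensity scoring and per-condition summaries.

#' Score one nucleus for perinuclear accumulation
#'
#' Computes the mean pixel intensity of the intensity channel over the central
#' (innermost) and perinuclear (outermost) elliptic regions of a ring
#' partition, their ratio, and the accumulation call: a nucleus is classified
#' as accumulating when the perinuclear/central ratio is strictly greater
#' than `cutoff` (default 2) and the nucleus is not excluded. The middle
#' ring's mean is reported for diagnostics but does not enter the statistic.
#'
#' Exclusion reasons: `"aberrant morphology"` (inherited from `fit` when the
#' ellipse does not fit the mask), `"region too small"` (inner or outer region
#' below `min_region_px` pixels), `"zero central intensity"` (undefined
#' ratio). No background subtraction is applied unless `background` is set.
#'
#' @param channel Numeric matrix of pixel intensities.
#' @param partition A [partition_rings()] result, congruent with `channel`.
#' @param fit Optional [ellipse_fit_quality()] result; its `excluded` flag is
#'   inherited.
#' @param cutoff Classification cutoff on the ratio (strict `>`); default 2.
#' @param min_region_px Minimum pixels per scored region; default 10.
#' @param background Optional constant background level subtracted from the
#'   channel before averaging; default `NULL` (no subtraction).
#' @param nucleus_id Identifier copied into the output.
#' @return One-row tibble with columns `nucleus_id`, `mean_inner`,
#'   `mean_middle`, `mean_outer`, `ratio`, `accumulating`, `excluded`,
#'   `exclusion_reason`.
#' @export
score_nucleus <- function(channel, partition, fit = NULL, cutoff = 2,
                          min_region_px = 10, background = NULL,
                          nucleus_id = NA_integer_) {
  stopifnot(inherits(partition, "ring_partition"), cutoff > 0)
  labels <- partition$labels
  if (!identical(dim(channel), dim(labels)))
    abort("channel and partition rasters must have the same dimensions")
  # restrict to the partition's bounding box: labels are 0 elsewhere
  if (!is.null(partition$bbox)) {
    channel <- channel[partition$bbox$rows, partition$bbox$cols, drop = FALSE]
    labels <- labels[partition$bbox$rows, partition$bbox$cols, drop = FALSE]
  }
  if (!is.null(background)) channel <- channel - background
  n <- length(partition$boundaries)
  inner <- channel[labels == 1L]
  outer <- channel[labels == n]
  middle <- if (n == 3L) channel[labels == 2L] else channel[labels > 1L & labels < n]

  excluded <- FALSE
  reason <- ""
  if (!is.null(fit) && fit$excluded) {
    excluded <- TRUE
    reason <- "aberrant morphology"
  } else if (length(inner) < min_region_px || length(outer) < min_region_px) {
    excluded <- TRUE
    reason <- "region too small"
  }

  mean_inner <- if (length(inner)) mean(inner) else NA_real_
  mean_outer <- if (length(outer)) mean(outer) else NA_real_
  mean_middle <- if (length(middle)) mean(middle) else NA_real_

  if (!excluded && isTRUE(mean_inner == 0)) {
    excluded <- TRUE
    reason <- "zero central intensity"
  }
  ratio <- if (isTRUE(mean_inner > 0)) mean_outer / mean_inner else NA_real_
  tibble(
    nucleus_id = nucleus_id,
    mean_inner = mean_inner,
    mean_middle = mean_middle,
    mean_outer = mean_outer,
    ratio = ratio,
    accumulating = !excluded && isTRUE(ratio > cutoff),
    excluded = excluded,
    exclusion_reason = reason
  )
}

#' Fit geometry for every nucleus in a label mask
#'
#' For each nucleus label in `mask`, fits the moments-equivalent ellipse,
#' judges fit quality against the aberrant-morphology threshold, and builds
#' the concentric ring partition. Nuclei whose masks cannot be fitted (empty
#' after cropping, or degenerate) are dropped with a warning.
#'
#' @param mask Integer matrix: 0 = background, each nonzero value one nucleus.
#' @param n_rings,spacing Passed to [partition_rings()].
#' @param jaccard_threshold Passed to [ellipse_fit_quality()].
#' @return Tibble with columns `nucleus_id`, `ellipse`, `partition`, `fit`
#'   (list-columns), `jaccard`, `excluded`.
#' @export
fit_nuclei <- function(mask, n_rings = 3, spacing = "radius",
                       jaccard_threshold = 0.85) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  ids <- sort(unique(mask[mask > 0]))
  if (!length(ids)) abort("empty mask")
  rows <- purrr::map(ids, function(id) {
    m <- mask == id
    ell <- tryCatch(fit_ellipse(m), error = function(e) NULL)
    if (is.null(ell)) {
      warn(sprintf("nucleus %s: could not fit an ellipse; dropped", id))
      return(NULL)
    }
    fq <- ellipse_fit_quality(m, ell, threshold = jaccard_threshold)
    part <- partition_rings(ell, dim(mask), n_rings = n_rings, spacing = spacing)
    tibble(nucleus_id = as.integer(id), ellipse = list(ell),
           partition = list(part), fit = list(fq),
           jaccard = fq$jaccard, excluded = fq$excluded)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) abort("no nucleus could be fitted")
  out
}

#' Score every nucleus of an image
#'
#' End-to-end per-image scoring: [fit_nuclei()] on the label mask, then
#' [score_nucleus()] on the intensity channel for each nucleus.
#'
#' @param channel Numeric intensity matrix.
#' @param mask Label matrix congruent with `channel`.
#' @param cutoff,min_region_px,background Passed to [score_nucleus()].
#' @param n_rings,spacing,jaccard_threshold Passed to [fit_nuclei()].
#' @return Tibble of per-nucleus scores (class `perinuc_scores`), one row per
#'   nucleus.
#' @export
score_image <- function(channel, mask, cutoff = 2, n_rings = 3,
                        spacing = "radius", jaccard_threshold = 0.85,
                        min_region_px = 10, background = NULL) {
  if (!identical(dim(channel), dim(mask)))
    abort("image and mask dimensions differ")
  geo <- fit_nuclei(mask, n_rings = n_rings, spacing = spacing,
                    jaccard_threshold = jaccard_threshold)
  scores <- purrr::pmap(
    list(geo$nucleus_id, geo$partition, geo$fit),
    function(id, part, fq) {
      score_nucleus(channel, part, fit = fq, cutoff = cutoff,
                    min_region_px = min_region_px, background = background,
                    nucleus_id = id)
    }
  ) %>% bind_rows()
  new_perinuc_scores(scores, cutoff = cutoff)
}

new_perinuc_scores <- function(x, cutoff) {
  structure(x, class = c("perinuc_scores", class(tibble())),
            cutoff = cutoff)
}

#' Summarize accumulation calls for one condition
#'
#' Aggregates per-nucleus scores into the per-condition fraction of nuclei
#' classified as accumulating, overall and per biological replicate.
#' Excluded nuclei are omitted from all denominators.
#'
#' @param scores Tibble of [score_nucleus()] rows.
#' @param condition Condition label recorded in the output.
#' @param replicate Optional vector (recycled or same length as rows) or
#'   column name in `scores` giving the biological replicate of each nucleus.
#' @return List of class `condition_summary` with elements `summary` (one-row
#'   tibble: `condition`, `n_included`, `n_excluded`, `fraction_accumulating`)
#'   and `per_replicate` (tibble: `replicate`, `n`, `fraction_accumulating`).
#' @export
summarize_condition <- function(scores, condition = "condition",
                                replicate = NULL) {
  if (!nrow(scores)) abort("no scores supplied")
  if (is.character(replicate) && length(replicate) == 1 &&
      replicate %in% names(scores)) {
    rep_vec <- scores[[replicate]]
  } else if (!is.null(replicate)) {
    rep_vec <- rep_len(replicate, nrow(scores))
  } else {
    rep_vec <- rep("1", nrow(scores))
  }
  included <- !scores$excluded
  n_inc <- sum(included)
  if (n_inc == 0) abort("no scorable nuclei")
  overall <- tibble(
    condition = condition,
    n_included = n_inc,
    n_excluded = sum(!included),
    fraction_accumulating = sum(scores$accumulating[included]) / n_inc
  )
  per_rep <- tibble(replicate = as.character(rep_vec)[included],
                    accumulating = scores$accumulating[included]) %>%
    group_by(.data$replicate) %>%
    summarise(n = dplyr::n(),
              fraction_accumulating = mean(.data$accumulating),
              .groups = "drop")
  structure(list(summary = overall, per_replicate = per_rep),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<condition_summary> %s: %d/%d nuclei accumulating (%.1f%%), %d excluded\n",
    s$condition, round(s$fraction_accumulating * s$n_included), s$n_included,
    100 * s$fraction_accumulating, s$n_excluded))
  if (nrow(x$per_replicate) > 1) {
    cat("  per replicate:",
        paste(sprintf("%s: %.2f", x$per_replicate$replicate,
                      x$per_replicate$fraction_accumulating),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname summarize_condition
#' @param x A `condition_summary`.
#' @param ... Unused.
#' @export
tidy.condition_summary <- function(x, ...) {
  x$per_replicate %>% mutate(condition = x$summary$condition, .before = 1)
}

#' @rdname summarize_condition
#' @export
glance.condition_summary <- function(x, ...) x$summary
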