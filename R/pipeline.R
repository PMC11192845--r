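# File-level pipeline runs: image + mask in, CSV results out.

#' Score an image file for perinuclear accumulation
#'
#' Reads an intensity image and a nucleus label mask, scores every nucleus
#' ([score_image()]), summarizes the condition ([summarize_condition()]),
#' and writes `scores.csv`, `summary.csv` and the resolved configuration to
#' `out_dir` (when given).
#'
#' @param image_path Path to the intensity image (multi-page TIFF or PNG).
#' @param mask_path Path to the label mask.
#' @param out_dir Optional output directory.
#' @param channel Channel name to score; default `"histone"`.
#' @param condition Condition label; default the image file name.
#' @param cutoff,n_rings,jaccard_threshold,min_region_px See
#'   [score_image()].
#' @return List with `scores` (tibble) and `summary` (`condition_summary`).
#' @export
pipeline_score <- function(image_path, mask_path, out_dir = NULL,
                           channel = "histone", condition = NULL,
                           cutoff = 2, n_rings = 3, jaccard_threshold = 0.85,
                           min_region_px = 10) {
  img <- read_image(image_path)
  mask <- read_mask(mask_path)
  ch <- pick_channel(img, channel)
  if (!identical(dim(ch), dim(mask))) abort("image and mask dimensions differ")
  if (is.null(condition)) condition <- tools::file_path_sans_ext(basename(image_path))
  scores <- score_image(ch, mask, cutoff = cutoff, n_rings = n_rings,
                        jaccard_threshold = jaccard_threshold,
                        min_region_px = min_region_px) %>%
    mutate(condition = condition, .before = 1)
  summ <- summarize_condition(scores, condition = condition)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(glance(summ), file.path(out_dir, "summary.csv"))
    write_resolved_config(list(
      command = "score", image = image_path, mask = mask_path,
      channel = channel, condition = condition, cutoff = cutoff,
      n_rings = n_rings, jaccard_threshold = jaccard_threshold,
      min_region_px = min_region_px,
      version = as.character(utils::packageVersion("perinuc"))), out_dir)
  }
  list(scores = scores, summary = summ)
}

#' Count perinuclear spots per nucleus in an image file
#'
#' Detects spots on the spot channel of the whole image, then per nucleus
#' builds the perinuclear region ([perinuclear_region()], optionally refined
#' by the lamin channel) and counts overlapping spots
#' ([count_perinuclear_spots()]). Writes `spot_counts.csv` when `out_dir`
#' is given.
#'
#' @param image_path,mask_path,out_dir As in [pipeline_score()].
#' @param spot_channel,lamin_channel Channel names; `lamin_channel = NULL`
#'   (default) uses the geometric outer ring only.
#' @param dilation_radius Outward dilation of the perinuclear region, px.
#' @param min_sigma,max_sigma,rel_threshold See [detect_spots()].
#' @return List with `spots` (detections) and `counts` (per-nucleus tibble).
#' @export
pipeline_spots <- function(image_path, mask_path, out_dir = NULL,
                           spot_channel = "spots", lamin_channel = NULL,
                           dilation_radius = 2, min_sigma = 1, max_sigma = 3,
                           rel_threshold = 0.1) {
  img <- read_image(image_path)
  mask <- read_mask(mask_path)
  ch <- pick_channel(img, spot_channel)
  if (!identical(dim(ch), dim(mask))) abort("image and mask dimensions differ")
  lam <- if (!is.null(lamin_channel)) pick_channel(img, lamin_channel)
  spots <- detect_spots(ch, min_sigma = min_sigma, max_sigma = max_sigma,
                        rel_threshold = rel_threshold)
  geo <- fit_nuclei(mask)
  counts <- purrr::map2(geo$nucleus_id, geo$partition, function(id, part) {
    region <- perinuclear_region(part, lamin = lam,
                                 dilation_radius = dilation_radius)
    count_perinuclear_spots(spots, region, part$ellipse,
                            margin = dilation_radius / part$ellipse$b,
                            nucleus_id = id)
  }) %>% bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(counts, file.path(out_dir, "spot_counts.csv"))
    readr::write_csv(as_tibble(spots), file.path(out_dir, "spots.csv"))
    write_resolved_config(list(
      command = "spots", image = image_path, mask = mask_path,
      spot_channel = spot_channel, lamin_channel = lamin_channel,
      dilation_radius = dilation_radius, min_sigma = min_sigma,
      max_sigma = max_sigma, rel_threshold = rel_threshold,
      version = as.character(utils::packageVersion("perinuc"))), out_dir)
  }
  list(spots = spots, counts = counts)
}

#' Measure per-nucleus colocalization area between two channels
#'
#' @param image_path,mask_path,out_dir As in [pipeline_score()].
#' @param channel_a,channel_b Channel names; defaults `"histone"` and
#'   `"replication"`.
#' @param threshold_method,fixed_values,pixel_size See [coloc_area()].
#' @return Tibble of per-nucleus [coloc_area()] rows.
#' @export
pipeline_coloc <- function(image_path, mask_path, out_dir = NULL,
                           channel_a = "histone", channel_b = "replication",
                           threshold_method = "otsu", fixed_values = NULL,
                           pixel_size = 1) {
  img <- read_image(image_path)
  mask <- read_mask(mask_path)
  a <- pick_channel(img, channel_a)
  b <- pick_channel(img, channel_b)
  if (!identical(dim(a), dim(mask))) abort("image and mask dimensions differ")
  ids <- sort(unique(mask[mask > 0]))
  if (!length(ids)) abort("empty mask")
  res <- purrr::map(ids, function(id) {
    coloc_area(a, b, mask == id, threshold_method = threshold_method,
               fixed_values = fixed_values, pixel_size = pixel_size,
               nucleus_id = as.integer(id))
  }) %>% bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res, file.path(out_dir, "coloc.csv"))
    write_resolved_config(list(
      command = "coloc", image = image_path, mask = mask_path,
      channel_a = channel_a, channel_b = channel_b,
      threshold_method = threshold_method, pixel_size = pixel_size,
      version = as.character(utils::packageVersion("perinuc"))), out_dir)
  }
  res
}

pick_channel <- function(img, channel) {
  if (is.character(channel)) {
    if (!channel %in% names(img))
      abort(sprintf("channel %s not found (available: %s)", channel,
                    paste(names(img), collapse = ", ")))
    img[[channel]]
  } else {
    img[[as.integer(channel)]]
  }
}
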