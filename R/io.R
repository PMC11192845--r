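# Reading and writing images, masks and configuration files.
#
# Arbitrary-unit intensity rasters are stored in 16-bit TIFF as digital
# numbers 0..65535; readers scale back so a write/read round trip returns
# the rounded intensities.

#' Read a multi-channel intensity image
#'
#' Reads a single- or multi-page TIFF (or a single-channel PNG) into a named
#' list of numeric matrices. Five-page TIFFs written by [generate_dataset()]
#' get the standard channel names (histone, dna, lamin, spots, replication);
#' otherwise pages are named `channel_1`, `channel_2`, ...
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param channel_names Optional character vector overriding channel names.
#' @return Named list of numeric matrices (intensities in digital numbers).
#' @export
read_image <- function(path, channel_names = NULL) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  pages <- read_raster_pages(path)
  nm <- if (!is.null(channel_names)) {
    if (length(channel_names) != length(pages))
      abort("channel_names length does not match the number of channels")
    channel_names
  } else if (length(pages) == length(CHANNEL_ORDER)) {
    CHANNEL_ORDER
  } else {
    paste0("channel_", seq_along(pages))
  }
  setNames(pages, nm)
}

#' Read a nucleus label mask
#'
#' Reads a single-channel TIFF or PNG label image (0 = background, each
#' nonzero gray level one nucleus) and relabels the nuclei as consecutive
#' integers 1..K in increasing gray-level order.
#'
#' @param path File path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("mask file not found: %s", path))
  pages <- read_raster_pages(path)
  if (length(pages) != 1) abort("mask file must contain a single page")
  m <- round(pages[[1]])
  vals <- sort(unique(m[m > 0]))
  out <- matrix(0L, nrow(m), ncol(m))
  if (length(vals)) out[m > 0] <- match(m[m > 0], vals)
  out
}

read_raster_pages <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else if (ext == "png") {
    pages <- list(png::readPNG(path))
  } else {
    abort(sprintf("unsupported image format: .%s", ext))
  }
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first plane of RGB(A)
    p * TIFF_SCALE
  })
}

#' Write intensity channels as a multi-page 16-bit TIFF
#'
#' @param channels Named list of numeric matrices, or a single matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intensity_tiff <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  pages <- lapply(channels, function(ch)
    round(pmin(pmax(ch, 0), TIFF_SCALE)) / TIFF_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a label matrix as a 16-bit TIFF
#'
#' @param labels Integer matrix (0 = background).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > TIFF_SCALE) abort("too many labels for 16-bit storage")
  tiff::writeTIFF(labels / TIFF_SCALE, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a YAML or JSON configuration file
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("unsupported config format: .%s", ext))
  }
}

# write the fully resolved configuration next to a run's outputs
write_resolved_config <- function(config, out_dir, name = "resolved_config.yaml") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, name)
  yaml::write_yaml(config, path)
  invisible(path)
}
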