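# TIFF / CSV / JSON / YAML I/O. Images are 16-bit multi-page TIFFs holding
# integer sample values; tables are plain CSV; models and manifests are JSON.

.write_page <- function(mat, bits = 16L) {
  maxv <- 2^bits - 1
  if (any(mat < 0) || any(mat > maxv))
    stop(sprintf("image values outside the %d-bit range", bits),
         call. = FALSE)
  mat / maxv
}

#' Write a label image and channel stack as multi-page TIFF
#'
#' Page 1 is the label image; subsequent pages are the channels in list
#' order. Values are stored as 16-bit integers, so integer-valued inputs
#' round-trip bit-exactly through [load_label_stack()].
#'
#' @param label Integer matrix of labels.
#' @param channels Named list of numeric matrices (integer-valued,
#'   0..65535).
#' @param path Output `.tif` path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path` invisibly; channel names are recorded in a sidecar JSON
#'   (`<path>.channels.json`) since baseline TIFF has no named pages.
#' @export
write_label_stack <- function(label, channels, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  pages <- c(list(.write_page(label, bits)),
             lapply(channels, .write_page, bits = bits))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  jsonlite::write_json(list(channels = names(channels), bits = bits),
                       paste0(path, ".channels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a label image and channel stack from multi-page TIFF
#'
#' Validates that all pages share dimensions and that the requested channel
#' names resolve; sample values are returned on their original integer
#' scale.
#'
#' @param path TIFF path written by [write_label_stack()] (or any multi-page
#'   TIFF whose first page is the label image).
#' @param channel_names Names for pages 2..k; defaults to the sidecar JSON
#'   written alongside, if present.
#' @return List with `label` (integer matrix), `channels` (named list of
#'   numeric matrices) and `bits`.
#' @export
load_label_stack <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) < 1L) stop("empty TIFF", call. = FALSE)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop(sprintf("TIFF pages disagree in size: %s",
                 paste(vapply(dims, paste, character(1), collapse = "x"),
                       collapse = ", ")), call. = FALSE)
  side <- paste0(path, ".channels.json")
  bits <- 16L
  if (is.null(channel_names) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    channel_names <- meta$channels
    bits <- as.integer(meta$bits %||% 16L)
  }
  nch <- length(pages) - 1L
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch)
    stop(sprintf("%d channel pages but %d channel names", nch,
                 length(channel_names)), call. = FALSE)
  label <- pages[[1]]
  if (any(label != round(label)))
    stop("label page is not integer-typed", call. = FALSE)
  storage.mode(label) <- "integer"
  list(label = label,
       channels = stats::setNames(pages[-1], channel_names),
       bits = bits)
}

#' Write a simulated section bundle to disk
#'
#' Writes `images.tif` (label + channels), `markers.csv`,
#' `ground_truth.csv` and `params.json` into `dir`.
#'
#' @param section Output of [generate_transverse_section()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_section_bundle <- function(section, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_stack(section$label, section$channels,
                    file.path(dir, "images.tif"))
  utils::write.csv(section$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(section$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(section$params),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' not found", path),
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
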