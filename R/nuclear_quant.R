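# Per-nucleus reporter quantification, two-anchor normalization,
# cross-session re-anchoring, fold changes and the ellipse intensity map.

#' Measure per-nucleus intensities and shape descriptors
#'
#' One record per non-zero label of the segmentation: arithmetic mean of each
#' channel's pixels under the label mask, pixel area, centroid, and an
#' ellipse fitted from the second central moments of the binary mask
#' (axis lengths `4 * sqrt(eigenvalue)`, the convention under which a solid
#' ellipse recovers its own axes). Marker-table columns are merged by
#' `cell_id`; records without a marker entry carry `NA` ("unknown") calls.
#'
#' @param label Integer matrix; 0 is background, positive values are nucleus
#'   ids.
#' @param channels Named list of numeric matrices with the dimensions of
#'   `label`.
#' @param markers Optional data.frame keyed by `cell_id`; duplicate ids are
#'   an error.
#' @return A data.frame with one row per nucleus: `cell_id`, `x`, `y`
#'   (0-based centroid, y downward), `area`, `major`, `minor` (full axis
#'   lengths, pixels), `orientation` (radians from +x), one `mean_<name>`
#'   column per channel, and any marker columns. Empty label images give a
#'   zero-row frame.
#' @export
measure_nuclei <- function(label, channels, markers = NULL) {
  stopifnot(is.matrix(label))
  for (ch in channels)
    if (!identical(dim(ch), dim(label)))
      stop("channel dimensions do not match the label image", call. = FALSE)
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a fully named list", call. = FALSE)

  ids <- sort(unique(label[label > 0L]))
  empty <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), major = numeric(0),
                      minor = numeric(0), orientation = numeric(0))
  for (nm in names(channels)) empty[[paste0("mean_", nm)]] <- numeric(0)
  if (length(ids) == 0L) return(empty)

  idx <- which(label > 0L)
  lab <- label[idx]
  H <- nrow(label)
  xs <- (idx - 1L) %/% H          # 0-based column = x
  ys <- (idx - 1L) %% H           # 0-based row = y
  f <- factor(lab, levels = ids)
  area <- as.integer(tabulate(f, length(ids)))
  cx <- tapply(xs, f, mean)
  cy <- tapply(ys, f, mean)
  # second central moments (+1/12 per-pixel term so a single pixel is not
  # degenerate)
  cx <- as.numeric(cx); cy <- as.numeric(cy)
  mxx <- as.numeric(tapply(xs * xs, f, mean)) - cx^2 + 1 / 12
  myy <- as.numeric(tapply(ys * ys, f, mean)) - cy^2 + 1 / 12
  mxy <- as.numeric(tapply(xs * ys, f, mean)) - cx * cy
  tr <- mxx + myy
  det <- sqrt(pmax((mxx - myy)^2 / 4 + mxy^2, 0))
  l1 <- tr / 2 + det
  l2 <- pmax(tr / 2 - det, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  orientation <- 0.5 * atan2(2 * mxy, mxx - myy)

  rec <- data.frame(cell_id = ids, x = as.numeric(cx), y = as.numeric(cy),
                    area = area, major = major, minor = minor,
                    orientation = orientation, row.names = NULL)
  for (nm in names(channels))
    rec[[paste0("mean_", nm)]] <-
      as.numeric(tapply(channels[[nm]][idx], f, mean))

  if (!is.null(markers)) {
    if (!"cell_id" %in% names(markers))
      stop("marker table must have a 'cell_id' column", call. = FALSE)
    if (anyDuplicated(markers$cell_id))
      stop("duplicate cell ids in marker table", call. = FALSE)
    rec <- merge(rec, markers, by = "cell_id", all.x = TRUE, sort = TRUE)
  }
  rec
}

#' Flag excluded-zone and side membership of nucleus records
#'
#' Adds a `region` column (`"included"` / `"excluded_zone"`) from the
#' fractional y-position of each centroid against the excluded bands, and a
#' `side` column (`"electroporated"` for x >= width/2, else
#' `"non_electroporated"`).
#'
#' @param records Output of [measure_nuclei()].
#' @param height,width Section dimensions in pixels.
#' @param excluded_bands List of fractional y-ranges, as in
#'   [section_sim_params()].
#' @return `records` with `region` and `side` columns.
#' @export
flag_regions <- function(records, height, width,
                         excluded_bands = list()) {
  stopifnot(is.numeric(height), is.numeric(width))
  ex <- .in_bands(records$y / height, excluded_bands)
  records$region <- ifelse(ex, "excluded_zone", "included")
  records$side <- ifelse(records$x >= width / 2,
                         "electroporated", "non_electroporated")
  records
}

#' Estimate the neuron-level reporter background
#'
#' The background anchor is the mean raw reporter intensity over
#' neuron (HuCD+) records in included regions: pharmacological Notch
#' blockade drives the reporter down to exactly this level, so it is the
#' operational zero of the signal scale.
#'
#' @param records Nucleus records with `hucd`, `region` and the intensity
#'   column.
#' @param channel Intensity column name (default `"mean_VNP"`).
#' @return The scalar background `b` (a.u.).
#' @export
estimate_background <- function(records, channel = "mean_VNP") {
  sel <- records$hucd %in% TRUE & records$region %in% "included"
  if (!any(sel))
    stop("no HuCD+ included records to estimate the background from",
         call. = FALSE)
  mean(records[[channel]][sel])
}

#' Fit the two-anchor normalization model
#'
#' Anchors: `b`, the mean raw intensity over HuCD+ included records
#' (neuron background), and `m`, the mean over the progenitor anchor set --
#' by default all HuCD- included records, i.e. the undifferentiated
#' population excluding the flagged zones.
#'
#' @param records Nucleus records carrying `hucd`, `region` and the channel.
#' @param channel Intensity column name.
#' @return An object of class `normalization_model` with fields `b`, `m` and
#'   `channel`. Errors if `m <= b` (degenerate anchors).
#' @export
fit_normalization <- function(records, channel = "mean_VNP") {
  b <- estimate_background(records, channel)
  sel <- records$hucd %in% FALSE & records$region %in% "included"
  if (!any(sel))
    stop("no HuCD- included records to anchor the progenitor mean",
         call. = FALSE)
  m <- mean(records[[channel]][sel])
  normalization_model(b, m, channel)
}

#' Construct a normalization model
#'
#' @param b Neuron background anchor (a.u.).
#' @param m Progenitor anchor (a.u.); must exceed `b`.
#' @param channel Intensity column the model applies to.
#' @return An object of class `normalization_model`.
#' @export
normalization_model <- function(b, m, channel = "mean_VNP") {
  if (!is.finite(b) || !is.finite(m) || m <= b)
    stop(sprintf("degenerate anchors: progenitor mean m = %.4g must exceed background b = %.4g",
                 m, b), call. = FALSE)
  structure(list(b = b, m = m, channel = channel),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf("normalization model on %s: background b = %.4g, progenitor anchor m = %.4g\n",
              x$channel, x$b, x$m))
  invisible(x)
}

#' Apply the two-anchor normalization
#'
#' Maps every raw intensity v to `v' = (v - b) / (m - b)`, so the mean over
#' the neuron anchor set is 0 and over the progenitor anchor set 1 (exactly,
#' when the model was fitted on the same records). Individual values may fall
#' outside `[0, 1]` and are deliberately not clipped: the population scatter
#' extends beyond both anchors.
#'
#' @param records Nucleus records.
#' @param model A `normalization_model`.
#' @return `records` with an added `vnp_norm` column.
#' @export
normalize_vnp <- function(records, model) {
  stopifnot(inherits(model, "normalization_model"))
  records$vnp_norm <- (records[[model$channel]] - model$b) /
    (model$m - model$b)
  records
}

#' Cross-session intensity scale factors
#'
#' Imaging sessions differ by detector gain. The per-session reference is the
#' mean reporter intensity, minus the session's optical background, over
#' HuCD+ nuclei of the non-electroporated side -- an internal population
#' untouched by the perturbation whose reporter level is a pure gain readout.
#' Session `s` is rescaled by `f_s = r_1 / r_s` (the first session is the
#' unit), after which `f_s * (v - background_s)` is comparable across
#' sessions.
#'
#' `optical_background` is the non-biological signal floor (camera offset /
#' cell-free region statistic) of each session, not the neuron-level anchor
#' of [fit_normalization()]: the neuron-level signal itself is the reference
#' being equalised here.
#'
#' @param sessions List of nucleus-record data.frames, one per session, each
#'   with `hucd`, `side` and the channel column.
#' @param optical_background Numeric vector of per-session signal floors
#'   (recycled scalar allowed; default 0).
#' @param channel Intensity column name.
#' @return Named numeric vector of scale factors, one per session (first
#'   session = 1). Errors, naming the session, if a session lacks reference
#'   nuclei.
#' @export
cross_session_normalize <- function(sessions, optical_background = 0,
                                    channel = "mean_VNP") {
  stopifnot(is.list(sessions), length(sessions) >= 1L)
  bg <- rep_len(optical_background, length(sessions))
  nm <- names(sessions) %||% paste0("session", seq_along(sessions))
  r <- vapply(seq_along(sessions), function(s) {
    rec <- sessions[[s]]
    sel <- rec$hucd %in% TRUE & rec$side %in% "non_electroporated"
    if (!any(sel))
      stop(sprintf("session '%s' has no HuCD+ non-electroporated reference nuclei",
                   nm[s]), call. = FALSE)
    mean(rec[[channel]][sel]) - bg[s]
  }, numeric(1))
  if (any(r <= 0))
    stop("non-positive session reference after background subtraction",
         call. = FALSE)
  stats::setNames(r[1] / r, nm)
}

#' Fold change of reporter intensity between conditions
#'
#' Ratio of the treated mean to the control mean of background-subtracted
#' intensities (both restricted upstream to HuCD- included records, the
#' undifferentiated population in which the perturbation is read out).
#'
#' @param treated,control Numeric vectors of background-subtracted
#'   intensities.
#' @return The scalar ratio `mean(treated) / mean(control)`. Errors if the
#'   control mean is not positive.
#' @export
fold_change <- function(treated, control) {
  stopifnot(is.numeric(treated), is.numeric(control),
            length(treated) >= 1, length(control) >= 1)
  mc <- mean(control)
  if (mc <= 0)
    stop("control mean is not positive after background subtraction",
         call. = FALSE)
  mean(treated) / mc
}

#' Default palette for the intensity colour-code map
#'
#' Eight equal-width bins over normalized intensity `[-0.2, 1.4]` plus
#' underflow and overflow bins, coloured along a blue-to-red ramp, and a
#' black "excluded" colour for nuclei inside the flagged zones.
#'
#' @param breaks Inner bin boundaries (length >= 2, increasing).
#' @param colors Colours for the `length(breaks) + 1` bins
#'   (under, inner..., over); defaults to a blue-red ramp.
#' @param excluded_color Colour for excluded-zone nuclei.
#' @return An object of class `map_palette`.
#' @export
map_palette <- function(breaks = seq(-0.2, 1.4, length.out = 9),
                        colors = NULL, excluded_color = "black") {
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  nbin <- length(breaks) + 1L
  if (is.null(colors))
    colors <- grDevices::hcl.colors(nbin, "Blue-Red 3")
  stopifnot(length(colors) == nbin)
  structure(list(breaks = breaks, colors = colors,
                 excluded_color = excluded_color), class = "map_palette")
}

#' Bin normalized intensities against a palette
#'
#' Bin 1 is underflow (`v < breaks[1]`); values equal to a boundary fall in
#' the bin above it (`v >= breaks[k]` is in bin `k + 1`); the last bin is
#' overflow.
#'
#' @param v Numeric vector of normalized intensities.
#' @param palette A [map_palette()].
#' @return Integer bin indices in `1..(length(breaks) + 1)`.
#' @export
palette_bin <- function(v, palette) {
  stopifnot(inherits(palette, "map_palette"))
  findInterval(v, palette$breaks) + 1L
}

#' Render the ellipse colour-code intensity map
#'
#' Redraws each nucleus as a filled ellipse at its recorded centroid with its
#' fitted axes and orientation, coloured by the palette bin of its normalized
#' intensity; excluded-zone records are drawn in the excluded colour.
#' Ellipses are painted in ascending `cell_id` order, later draws overwriting
#' earlier ones. Records whose ellipse extends beyond the field are clipped
#' (and counted in the `clipped` attribute), never fatal.
#'
#' @param records Nucleus records with `vnp_norm`, centroid, `major`,
#'   `minor`, `orientation` and optionally `region`.
#' @param height,width Output raster size in pixels.
#' @param palette A [map_palette()].
#' @return An integer H x W matrix of colour indices: 0 background,
#'   `1..nbin` palette bins, `nbin + 1` the excluded colour. Attributes:
#'   `colors` (index -> colour lookup, including `"white"` for background)
#'   and `clipped` (number of partially clipped ellipses).
#' @export
render_intensity_map <- function(records, height, width,
                                 palette = map_palette()) {
  stopifnot(inherits(palette, "map_palette"))
  img <- matrix(0L, height, width)
  nbin <- length(palette$colors)
  ord <- order(records$cell_id)
  clipped <- 0L
  for (i in ord) {
    a <- records$major[i] / 2
    b <- records$minor[i] / 2
    cx <- records$x[i]; cy <- records$y[i]
    if (cx - a < 0 || cx + a > width - 1 || cy - a < 0 || cy + a > height - 1)
      clipped <- clipped + 1L
    idx <- .ellipse_pixels(cx, cy, max(a, 0.5), max(b, 0.5),
                           records$orientation[i], height, width)
    col <- if (!is.null(records$region) &&
               records$region[i] == "excluded_zone") nbin + 1L
           else palette_bin(records$vnp_norm[i], palette)
    img[idx] <- col
  }
  attr(img, "colors") <- c("white", palette$colors, palette$excluded_color)
  attr(img, "clipped") <- clipped
  img
}

#' Write an intensity map to a PNG file
#'
#' @param map Output of [render_intensity_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_map <- function(map, path) {
  cols <- attr(map, "colors")
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, c(nrow(map), ncol(map), 3))
  for (k in 1:3)
    arr[, , k] <- matrix(rgb[k, map + 1L], nrow(map), ncol(map))
  png::writePNG(arr, path)
  invisible(path)
}
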