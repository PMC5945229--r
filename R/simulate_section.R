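# Simulated transverse sections: non-overlapping elliptical nuclei with
# class-conditional reporter intensities and full ground truth.
#
# Pixel convention (used package-wide): 0-based pixel indices, origin at the
# top-left corner, x rightward (columns), y downward (rows). A matrix element
# [r, c] is the pixel (x = c - 1, y = r - 1). Dorsal is the top of the field.

# Linear indices (into an H x W matrix) of the pixels whose centres fall
# inside the ellipse (cx, cy, semi-axes a >= b, orientation theta, radians,
# measured from the +x axis).
.ellipse_pixels <- function(cx, cy, a, b, theta, height, width) {
  x0 <- max(0L, floor(cx - a)); x1 <- min(width - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(height - 1L, ceiling(cy + a))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs, each = length(ys)) - cx
  dy <- rep(ys, times = length(xs)) - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  row <- rep(ys, times = length(xs))[inside] + 1L
  col <- rep(xs, each = length(ys))[inside] + 1L
  (col - 1L) * height + row
}

# Draw per-nucleus means with arithmetic mean m and sd s under the configured
# distribution shape.
.class_draw <- function(n, m, s, dist) {
  if (s == 0) return(rep(m, n))
  if (dist == "normal") return(pmax(stats::rnorm(n, m, s), 0))
  sdlog <- sqrt(log1p((s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

.in_bands <- function(yfrac, bands) {
  hit <- rep(FALSE, length(yfrac))
  for (b in bands) hit <- hit | (yfrac >= b[1] & yfrac < b[2])
  hit
}

#' Simulate a transverse-section label image with ground truth
#'
#' Places `n_nuclei` non-overlapping ellipses by rejection sampling, assigns
#' each a population (cycling progenitor, prospective neuron or neuron),
#' draws its nuclear reporter (VNP) intensity from the class-conditional
#' distribution and paints it, plus pixel noise, into the VNP channel. The
#' DAPI-analogue channel equals the nuclear mask. Channel values are rounded
#' to integers (16-bit detector counts), so written TIFFs round-trip
#' bit-exactly.
#'
#' Marker calls follow the population definitions under cumulative EdU
#' labelling: progenitors are EdU+/HuCD-, prospective neurons EdU-/HuCD-,
#' neurons EdU-/HuCD+. The electroporated side is the right half of the
#' field (x >= width/2); transfection is mosaic within it. Nuclei whose
#' centroid falls in an excluded band (roof-plate / motor-neuron analogue)
#' are flagged and their reporter mean is attenuated by
#' `excluded_vnp_factor`, emulating the low-activity signalling centres those
#' zones are excluded for.
#'
#' @param params A [section_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{label}{integer H x W matrix, 0 = background, nucleus ids 1..n.}
#'     \item{channels}{named list of numeric H x W matrices, `VNP` and `DAPI`.}
#'     \item{truth}{data.frame of per-nucleus ground truth: class, true
#'       intensity parameters, centroid, axes, orientation, zone/side flags.}
#'     \item{markers}{data.frame of the marker-table columns
#'       (`cell_id`, `hucd`, `edu`, `flashtag`, `transfected`, `tuj1`,
#'       `neurog2`) as a downstream pipeline would receive them.}
#'     \item{params}{the echoed parameter object.}
#'   }
#'   Identical `params` (including seed) reproduce the output bit-exactly.
#' @export
generate_transverse_section <- function(params) {
  stopifnot(inherits(params, "section_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    H <- p$height; W <- p$width; n <- p$n_nuclei
    label <- matrix(0L, H, W)
    cx <- cy <- aa <- bb <- th <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(p$max_place_tries)) {
        a <- max(1, stats::rnorm(1, p$radius_mean, p$radius_sd))
        b <- a * stats::runif(1, p$aspect_range[1], p$aspect_range[2])
        x <- stats::runif(1, a, W - 1 - a)
        y <- stats::runif(1, a, H - 1 - a)
        t <- stats::runif(1, 0, pi)
        idx <- .ellipse_pixels(x, y, a, b, t, H, W)
        if (length(idx) && all(label[idx] == 0L)) {
          label[idx] <- i
          cx[i] <- x; cy[i] <- y; aa[i] <- a; bb[i] <- b; th[i] <- t
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste0("infeasible packing: placed %d of %d nuclei ",
                            "without overlap (%d retries each)"),
                     placed, n, p$max_place_tries), call. = FALSE)
      placed <- placed + 1L
    }

    classes <- c("progenitor", "prospective_neuron", "neuron")
    cls <- sample(classes, n, replace = TRUE, prob = p$class_props)
    excluded <- .in_bands(cy / H, p$excluded_bands)
    vnp_true <- numeric(n)
    for (k in classes) {
      sel <- cls == k
      vnp_true[sel] <- .class_draw(sum(sel), p$vnp_mean[[k]], p$vnp_sd[[k]],
                                   p$intensity_dist)
    }
    att <- excluded & cls != "neuron"
    vnp_true[att] <- pmax(vnp_true[att] * p$excluded_vnp_factor, p$background)

    vnp <- matrix(round(pmax(stats::rnorm(H * W, 0, p$noise_sd), 0)), H, W)
    for (i in seq_len(n)) {
      idx <- which(label == i)
      vnp[idx] <- round(pmax(vnp_true[i] + stats::rnorm(length(idx), 0,
                                                        p$noise_sd), 0))
    }
    vnp[vnp > 65535] <- 65535
    dapi <- matrix(0, H, W); dapi[label > 0L] <- 1

    side <- ifelse(cx >= W / 2, "electroporated", "non_electroporated")
    hucd <- cls == "neuron"
    edu <- cls == "progenitor"
    transfected <- side == "electroporated" &
      stats::runif(n) < p$transfected_frac
    tuj1 <- hucd | (cls == "prospective_neuron" & stats::runif(n) < 0.15)
    # continuous proneural (Neurog2) intensity: negative in progenitors,
    # low/high in prospective neurons, decaying in neurons
    ng2_class <- rep("negative", n)
    pros <- which(cls == "prospective_neuron")
    hi <- pros[stats::runif(length(pros)) < 0.5]
    ng2_class[pros] <- "low"; ng2_class[hi] <- "high"
    neurog2 <- pmax(stats::rnorm(n, 20, 15), 0)
    neurog2[cls == "neuron"] <- pmax(stats::rnorm(sum(hucd), 40, 20), 0)
    neurog2[ng2_class == "low"] <- stats::rnorm(sum(ng2_class == "low"),
                                                120, 30)
    neurog2[ng2_class == "high"] <- stats::rnorm(sum(ng2_class == "high"),
                                                 260, 40)
    neurog2 <- pmax(neurog2, 0)

    truth <- data.frame(cell_id = seq_len(n), class = cls,
                        x = cx, y = cy, semi_major = aa, semi_minor = bb,
                        orientation = th, vnp_mean_true = vnp_true,
                        excluded_zone = excluded, side = side,
                        neurog2_class = ng2_class,
                        stringsAsFactors = FALSE)
    markers <- data.frame(cell_id = seq_len(n), hucd = hucd, edu = edu,
                          flashtag = FALSE, transfected = transfected,
                          tuj1 = tuj1, neurog2 = round(neurog2, 2),
                          stringsAsFactors = FALSE)
    list(label = label, channels = list(VNP = vnp, DAPI = dapi),
         truth = truth, markers = markers, params = p)
  })
}
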