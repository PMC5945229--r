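# Simulated en-face apical mosaics: a pixel-exact Voronoi tessellation with
# mosaic transfection, apical constriction of differentiating cells and
# junctional intensity painting.

# Nearest-seed label for arbitrary points (xp, yp), looping over seeds so no
# n_pixels x n_seeds matrix is ever formed.
.nearest_seed <- function(xp, yp, sx, sy, eligible = NULL) {
  best <- rep.int(Inf, length(xp))
  lab <- rep.int(NA_integer_, length(xp))
  idx <- if (is.null(eligible)) seq_along(sx) else which(eligible)
  for (s in idx) {
    d <- (xp - sx[s])^2 + (yp - sy[s])^2
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- s
  }
  lab
}

#' Simulate an en-face apical mosaic with ground truth
#'
#' Tessellates the field into `n_cells` apical footprints (discrete Voronoi
#' cells of minimum-separation seed points, giving the fairly regular
#' polygonal packing of a neuroepithelial apical surface), marks a random
#' transfected subset and, within it, a differentiating subset. Differentiating
#' cells are apically constricted: a pixel p of such a cell is retained iff
#' the point `seed + (p - seed)/sqrt(s)` still falls in the cell's Voronoi
#' region, i.e. the footprint is shrunk linearly by `sqrt(s)` so its area
#' scales by the constriction factor `s`; freed pixels are absorbed by the
#' nearest non-differentiating neighbour, so the tessellation remains an
#' exact partition of the field (pixel areas always sum to the field area).
#'
#' The junction channel paints every pixel at which two or more cells meet
#' (8-connectivity) with `junction_background + junction_baseline * f`, where
#' `f` is the smallest junction factor among the cells meeting there
#' (differentiating cells have factor `junction_factor`, all others 1);
#' non-junction pixels carry background only. Pixel noise is added and values
#' are rounded to integer counts.
#'
#' @param params A [mosaic_sim_params()] object.
#' @return A list with elements `label` (integer H x W matrix, cell ids 1..n,
#'   no background), `junction` (numeric H x W matrix), `truth` (per-cell
#'   data.frame: seed position, flags, true constriction and junction factor,
#'   base and final pixel areas) and `params`.
#' @export
generate_apical_mosaic <- function(params) {
  stopifnot(inherits(params, "mosaic_sim_params"))
  p <- params
  if (p$transfected_frac * p$n_cells < 1)
    stop("transfected_frac * n_cells < 1: no transfected cell can be drawn",
         call. = FALSE)
  withr::with_seed(p$seed, {
    H <- p$height; W <- p$width; n <- p$n_cells
    dmin2 <- (p$seed_spacing * sqrt(H * W / n))^2
    sx <- sy <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:500) {
        x <- stats::runif(1, 0, W - 1); y <- stats::runif(1, 0, H - 1)
        if (i == 1L ||
            min((sx[seq_len(i - 1)] - x)^2 + (sy[seq_len(i - 1)] - y)^2) >=
            dmin2) {
          sx[i] <- x; sy[i] <- y; ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place %d seeds at spacing %.1f px (placed %d)",
                     n, sqrt(dmin2), i - 1L), call. = FALSE)
    }

    px <- rep(0:(W - 1), each = H)   # column-major over the H x W matrix
    py <- rep(0:(H - 1), times = W)
    lab <- .nearest_seed(px, py, sx, sy)
    base_area <- tabulate(lab, n)

    transfected <- rep(FALSE, n)
    transfected[sample.int(n, max(1L, round(p$transfected_frac * n)))] <- TRUE
    differentiating <- rep(FALSE, n)
    tr <- which(transfected)
    ndiff <- round(p$diff_frac * length(tr))
    if (ndiff > 0)
      differentiating[sample(tr, ndiff)] <- TRUE

    s <- p$constriction
    if (s < 1 && any(differentiating)) {
      shrink <- 1 / sqrt(s)
      for (i in which(differentiating)) {
        own <- which(lab == i)
        qx <- sx[i] + (px[own] - sx[i]) * shrink
        qy <- sy[i] + (py[own] - sy[i]) * shrink
        keep <- .nearest_seed(qx, qy, sx, sy) == i
        freed <- own[!keep]
        if (length(freed)) {
          host <- if (all(differentiating))
            .nearest_seed(px[freed], py[freed], sx, sy,
                          eligible = seq_len(n) != i)
          else
            .nearest_seed(px[freed], py[freed], sx, sy,
                          eligible = !differentiating)
          lab[freed] <- host
        }
      }
    }
    label <- matrix(lab, H, W)
    area <- tabulate(lab, n)

    jfac <- ifelse(differentiating, p$junction_factor, 1)
    pixfac <- matrix(NA_real_, H, W)
    junction <- matrix(FALSE, H, W)
    own_fac <- matrix(jfac[label], H, W)
    shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    minfac <- own_fac
    for (sh in shifts) {
      dr <- sh[1]; dc <- sh[2]
      r1 <- max(1, 1 + dr):min(H, H + dr)
      c1 <- max(1, 1 + dc):min(W, W + dc)
      r0 <- r1 - dr; c0 <- c1 - dc
      diffm <- label[r1, c1, drop = FALSE] != label[r0, c0, drop = FALSE]
      junction[r1, c1][diffm] <- TRUE
      nb <- own_fac[r0, c0, drop = FALSE]
      cur <- minfac[r1, c1, drop = FALSE]
      take <- diffm & nb < cur
      cur[take] <- nb[take]
      minfac[r1, c1] <- cur
    }
    img <- matrix(p$junction_background, H, W)
    img[junction] <- p$junction_background +
      p$junction_baseline * minfac[junction]
    img <- round(pmax(img + stats::rnorm(H * W, 0, p$noise_sd), 0))
    img[img > 65535] <- 65535

    truth <- data.frame(cell_id = seq_len(n), seed_x = sx, seed_y = sy,
                        transfected = transfected,
                        differentiating = differentiating,
                        constriction = ifelse(differentiating, s, 1),
                        junction_factor = jfac,
                        base_area = base_area, area = area,
                        stringsAsFactors = FALSE)
    list(label = label, junction = img, truth = truth, params = p)
  })
}

#' Simulate a pulse-labelled cohort time course
#'
#' Generates the longitudinal record of a cohort of `n_cells` cells labelled
#' at mitosis (t = 0). Each cell either exits the cycle at t = 0 (probability
#' `exit_frac`), never incorporates EdU and turns neuronal-marker-positive
#' after its differentiation delay, or stays in the cycle, re-enters S phase
#' after a truncated-normal delay and becomes EdU+ from
#' `max(re-entry time, edu_start)` onward (cumulative dosing keeps EdU
#' available from the first dose). Both marker states are cumulative, hence
#' monotone non-decreasing over the observation timepoints.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list with `cohort`, a long-format data.frame
#'   (`cell_id`, `ft`, `timepoint`, `edu`, `hucd`), and `truth`, the
#'   per-cell generative record (`exits`, `reentry_time`, `edu_time`,
#'   `diff_time`), plus the echoed `params`.
#' @export
generate_cohort_timecourse <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    n <- p$n_cells
    exits <- stats::runif(n) < p$exit_frac
    reentry <- pmin(pmax(stats::rnorm(n, p$reentry_mean, p$reentry_sd), 0),
                    p$reentry_max)
    reentry[exits] <- NA_real_
    edu_time <- pmax(reentry, p$edu_start)
    diff_time <- pmax(stats::rnorm(n, p$diff_delay_mean, p$diff_delay_sd), 0)
    diff_time[!exits] <- NA_real_
    tp <- p$timepoints
    cohort <- data.frame(
      cell_id = rep(seq_len(n), each = length(tp)),
      ft = TRUE,
      timepoint = rep(tp, times = n),
      edu = as.vector(vapply(seq_len(n), function(i)
        !exits[i] & edu_time[i] <= tp, logical(length(tp)))),
      hucd = as.vector(vapply(seq_len(n), function(i)
        exits[i] & diff_time[i] <= tp, logical(length(tp)))))
    truth <- data.frame(cell_id = seq_len(n), exits = exits,
                        reentry_time = reentry, edu_time = edu_time,
                        diff_time = diff_time)
    list(cohort = cohort, truth = truth, params = p)
  })
}
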