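# Neighbour-referenced apical metrics on en-face segmentations: adjacency,
# ring-2 neighbour selection, area and junction-intensity ratios, the
# sister-pair filter, the control-median small/large split and the Tuj1
# cross-tabulation.

# For each of the 8 pixel shifts, the (label(p), label(q)) pairs of adjacent
# pixels with differing labels. Returns a data.frame(a, b) of ordered pairs,
# one row per adjacent pixel pair and direction (each unordered pixel pair
# appears twice, once per orientation).
.adjacent_label_pairs <- function(label) {
  H <- nrow(label); W <- ncol(label)
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  a <- integer(0); b <- integer(0)
  for (sh in shifts) {
    dr <- sh[1]; dc <- sh[2]
    r1 <- max(1, 1 + dr):min(H, H + dr)
    c1 <- max(1, 1 + dc):min(W, W + dc)
    r0 <- r1 - dr; c0 <- c1 - dc
    l1 <- label[r1, c1, drop = FALSE]
    l0 <- label[r0, c0, drop = FALSE]
    d <- l1 != l0
    a <- c(a, l0[d]); b <- c(b, l1[d])
  }
  data.frame(a = a, b = b)
}

#' Cell adjacency graph of a labelled segmentation
#'
#' Two cells are adjacent when their footprints meet along at least
#' `min_shared` 8-connected adjacent pixel pairs; a diagonal single-pixel
#' touch contributes one pair and so falls below the default threshold.
#'
#' @param label Integer matrix of cell ids (no background pixels required;
#'   0s, if present, are ignored).
#' @param min_shared Minimum shared-boundary pixel-pair count for an edge
#'   (default 3).
#' @return Data.frame with columns `from`, `to` (`from < to`) and `shared`
#'   (the pair count).
#' @export
build_adjacency <- function(label, min_shared = 3L) {
  pr <- .adjacent_label_pairs(label)
  pr <- pr[pr$a > 0L & pr$b > 0L, , drop = FALSE]
  if (nrow(pr) == 0L)
    return(data.frame(from = integer(0), to = integer(0),
                      shared = integer(0)))
  lo <- pmin(pr$a, pr$b); hi <- pmax(pr$a, pr$b)
  key <- paste(lo, hi)
  cnt <- table(key)
  ft <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  out <- data.frame(from = as.integer(ft[, 1]), to = as.integer(ft[, 2]),
                    shared = as.integer(cnt))
  out <- out[out$shared >= min_shared, , drop = FALSE]
  out[order(out$from, out$to), , drop = FALSE]
}

# adjacency list (id -> integer vector of neighbour ids) from an edge frame
.adj_list <- function(graph, ids) {
  al <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (k in seq_len(nrow(graph))) {
    f <- as.character(graph$from[k]); t <- as.character(graph$to[k])
    al[[f]] <- c(al[[f]], graph$to[k])
    al[[t]] <- c(al[[t]], graph$from[k])
  }
  al
}

#' Select the four reference neighbours of a transfected cell
#'
#' Reference cells are non-transfected cells spaced by one cell row from the
#' focal cell, i.e. at adjacency distance exactly 2. The four candidates with
#' the smallest centroid distance are chosen (ties broken by ascending cell
#' id). If fewer than four ring-2 candidates exist, ring-1 non-transfected
#' cells complete the set and the ring is recorded per neighbour; fewer than
#' four candidates in rings 1-2 combined is an error (the focal cell is
#' excluded from the analysis).
#'
#' @param focal_id Id of the transfected focal cell.
#' @param graph Adjacency edge data.frame from [build_adjacency()].
#' @param cells Per-cell data.frame with `cell_id`, `x`, `y` (centroids) and
#'   `transfected`.
#' @param n_neighbors Number of reference cells (default 4).
#' @return Data.frame `neighbor_id`, `ring` (1 or 2), `centroid_dist`,
#'   ordered as selected.
#' @export
select_neighbors <- function(focal_id, graph, cells, n_neighbors = 4L) {
  fi <- match(focal_id, cells$cell_id)
  if (is.na(fi)) stop("focal cell not found", call. = FALSE)
  if (!cells$transfected[fi] %in% TRUE)
    stop("focal cell is not transfected", call. = FALSE)
  al <- .adj_list(graph, cells$cell_id)
  ring1 <- unique(al[[as.character(focal_id)]])
  ring2 <- setdiff(unique(unlist(al[as.character(ring1)])),
                   c(ring1, focal_id))
  pick <- function(ids, ring) {
    m <- match(ids, cells$cell_id)
    ids <- ids[cells$transfected[m] %in% FALSE]
    if (length(ids) == 0L) return(NULL)
    m <- match(ids, cells$cell_id)
    d <- sqrt((cells$x[m] - cells$x[fi])^2 + (cells$y[m] - cells$y[fi])^2)
    o <- order(d, ids)
    data.frame(neighbor_id = ids[o], ring = ring, centroid_dist = d[o])
  }
  sel <- pick(ring2, 2L)
  if (is.null(sel) || nrow(sel) < n_neighbors)
    sel <- rbind(sel, pick(ring1, 1L))
  if (is.null(sel) || nrow(sel) < n_neighbors)
    stop(sprintf("cell %s: only %d eligible neighbours in rings 1-2 (need %d)",
                 focal_id, if (is.null(sel)) 0L else nrow(sel), n_neighbors),
         call. = FALSE)
  sel[seq_len(n_neighbors), , drop = FALSE]
}

#' Apical area ratio
#'
#' Area of the transfected focal footprint over the mean area of its
#' reference neighbours.
#'
#' @param focal_area Focal apical area (pixels).
#' @param neighbor_areas Areas of the reference neighbours.
#' @return Unitless ratio.
#' @export
apical_area_ratio <- function(focal_area, neighbor_areas) {
  stopifnot(focal_area > 0, all(neighbor_areas > 0))
  focal_area / mean(neighbor_areas)
}

#' Junction intensity ratio
#'
#' Background-corrected mean junctional intensity of the focal cell over the
#' mean of its neighbours' background-corrected junctional intensities. The
#' ratio is invariant to a common gain applied to intensities and background
#' alike.
#'
#' @param focal_intensity Mean pixel intensity within the focal apical
#'   circumference (a.u.).
#' @param neighbor_intensities Neighbour circumference means (a.u.).
#' @param background Image background (a.u.), from a cell-free or
#'   non-junctional region statistic.
#' @return Unitless ratio. Errors if the neighbour denominator is not
#'   positive; warns if the background exceeds any cell's mean (sign flip).
#' @export
junction_intensity_ratio <- function(focal_intensity, neighbor_intensities,
                                     background = 0) {
  if (background >= min(c(focal_intensity, neighbor_intensities)))
    warning("background exceeds a boundary mean; ratio may sign-flip")
  den <- mean(neighbor_intensities - background)
  if (den <= 0)
    stop("neighbour junction denominator <= 0 after background subtraction",
         call. = FALSE)
  (focal_intensity - background) / den
}

#' Measure apical footprints and junctional band intensities
#'
#' Per cell: pixel area, centroid, and the mean junction-channel intensity
#' over the cell's 2-pixel circumference band. The band of cell i comprises
#' the pixels of i that touch another cell (8-connectivity) together with
#' the pixels of other cells touching i: the shared interface is attributed
#' to both of its cells, mirroring junctional staining geometry.
#'
#' @param label Integer matrix of cell ids.
#' @param junction Numeric matrix, junction-marker channel.
#' @param flags Optional data.frame keyed by `cell_id` (e.g. `transfected`,
#'   `tuj1`) merged onto the output.
#' @return Data.frame `cell_id`, `x`, `y`, `area`, `junction_mean`, plus any
#'   flag columns.
#' @export
measure_apical_cells <- function(label, junction, flags = NULL) {
  stopifnot(identical(dim(label), dim(junction)))
  H <- nrow(label)
  ids <- sort(unique(as.integer(label)))
  ids <- ids[ids > 0L]
  f <- factor(label, levels = ids)
  area <- as.integer(tabulate(f, length(ids)))
  idx0 <- seq_along(label) - 1L
  cx <- as.numeric(tapply(idx0 %/% H, f, mean))
  cy <- as.numeric(tapply(idx0 %% H, f, mean))

  # band membership: (cell, pixel) incidences from differing adjacent pairs
  shifts <- list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  W <- ncol(label)
  cell <- integer(0); pix <- integer(0)
  for (sh in shifts) {
    dr <- sh[1]; dc <- sh[2]
    r1 <- max(1, 1 + dr):min(H, H + dr)
    c1 <- max(1, 1 + dc):min(W, W + dc)
    r0 <- r1 - dr; c0 <- c1 - dc
    i1 <- as.vector(outer(r1, (c1 - 1L) * H, `+`))
    i0 <- as.vector(outer(r0, (c0 - 1L) * H, `+`))
    d <- label[i1] != label[i0]
    # pixel p=i1 belongs to the band of its own cell and of the
    # neighbouring cell
    cell <- c(cell, label[i1][d], label[i0][d])
    pix <- c(pix, i1[d], i1[d])
  }
  inc <- unique(data.frame(cell = cell, pix = pix))
  jm <- tapply(junction[inc$pix], factor(inc$cell, levels = ids), mean)
  out <- data.frame(cell_id = ids, x = cx, y = cy, area = area,
                    junction_mean = as.numeric(jm))
  if (!is.null(flags)) {
    if (anyDuplicated(flags$cell_id))
      stop("duplicate cell ids in flags", call. = FALSE)
    out <- merge(out, flags, by = "cell_id", all.x = TRUE, sort = TRUE)
  }
  out
}

#' Filter post-division sister pairs of transfected cells
#'
#' Transfected cells that later divide appear as adjacent transfected pairs;
#' such cells are discarded from single-cell analyses. The operational proxy
#' is ring-1 adjacency between two transfected cells: both members of any
#' such pair are removed (removal is symmetric).
#'
#' @param cells Per-cell data.frame with `cell_id` and `transfected`.
#' @param graph Adjacency edge data.frame.
#' @return `cells` without the paired transfected cells; the number removed
#'   is attached as attribute `n_removed`.
#' @export
pair_filter <- function(cells, graph) {
  tr <- cells$cell_id[cells$transfected %in% TRUE]
  both <- graph$from %in% tr & graph$to %in% tr
  drop <- unique(c(graph$from[both], graph$to[both]))
  out <- cells[!cells$cell_id %in% drop, , drop = FALSE]
  attr(out, "n_removed") <- length(drop)
  out
}

#' Neighbour-referenced ratios for every eligible transfected cell
#'
#' Convenience driver: applies the sister-pair filter, then for each
#' remaining transfected cell selects its reference neighbours and computes
#' the apical area ratio and junction intensity ratio. Cells without enough
#' eligible neighbours are skipped and counted.
#'
#' @param cells Output of [measure_apical_cells()] with a `transfected`
#'   column (and optionally `tuj1`).
#' @param graph Adjacency edge data.frame from [build_adjacency()].
#' @param background Junction-channel background (a.u.).
#' @param apply_pair_filter Run [pair_filter()] first (default TRUE).
#' @return Data.frame with one row per analysed focal cell: `cell_id`,
#'   `area_ratio`, `junction_ratio`, `n_ring1` (number of ring-1 fallback
#'   neighbours used), plus `tuj1` when present. Attributes `n_skipped` and
#'   `n_paired` report exclusions.
#' @export
apical_ratios <- function(cells, graph, background = 0,
                          apply_pair_filter = TRUE) {
  paired <- 0L
  if (apply_pair_filter) {
    cells <- pair_filter(cells, graph)
    paired <- attr(cells, "n_removed")
  }
  focal <- cells$cell_id[cells$transfected %in% TRUE]
  rows <- list(); skipped <- 0L
  for (id in focal) {
    sel <- tryCatch(select_neighbors(id, graph, cells),
                    error = function(e) NULL)
    if (is.null(sel)) { skipped <- skipped + 1L; next }
    fi <- match(id, cells$cell_id)
    ni <- match(sel$neighbor_id, cells$cell_id)
    ar <- apical_area_ratio(cells$area[fi], cells$area[ni])
    jr <- junction_intensity_ratio(cells$junction_mean[fi],
                                   cells$junction_mean[ni], background)
    row <- data.frame(cell_id = id, area_ratio = ar, junction_ratio = jr,
                      n_ring1 = sum(sel$ring == 1L))
    if (!is.null(cells$tuj1)) row$tuj1 <- cells$tuj1[fi]
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), area_ratio = numeric(0),
               junction_ratio = numeric(0), n_ring1 = integer(0))
  attr(out, "n_skipped") <- skipped
  attr(out, "n_paired") <- paired
  out
}

#' Split area ratios at the control median
#'
#' The threshold discriminating small from large apical areas is the median
#' of the control condition's ratios, applied to every condition. Ratios
#' below the threshold are `small`; ratios at or above it are `large`
#' (equality assigned to `large` by convention, the spec of "below the
#' median" vs "above" leaving ties open).
#'
#' @param ratios Numeric vector to label.
#' @param control_ratios Control-condition ratios (non-empty).
#' @return List with `labels` (factor `small`/`large`) and `threshold`.
#' @export
split_small_large <- function(ratios, control_ratios) {
  if (length(control_ratios) == 0L)
    stop("control ratio set is empty", call. = FALSE)
  thr <- stats::median(control_ratios)
  list(labels = factor(ifelse(ratios < thr, "small", "large"),
                       levels = c("small", "large")),
       threshold = thr)
}

#' Cross-tabulate the size split with Tuj1 expression
#'
#' @param labels Factor from [split_small_large()].
#' @param tuj1 Logical Tuj1 calls, same length.
#' @param ratios Optional numeric ratios for the per-group means.
#' @return List with `table` (2 x 2 counts, small/large x Tuj1-/Tuj1+) and,
#'   when `ratios` is given, `mean_ratio` per Tuj1 group.
#' @export
crosstab_tuj1 <- function(labels, tuj1, ratios = NULL) {
  stopifnot(length(labels) == length(tuj1))
  if (anyNA(labels) || anyNA(tuj1))
    stop("every cell needs both a size label and a Tuj1 call", call. = FALSE)
  tab <- table(size = labels, tuj1 = factor(tuj1, levels = c(FALSE, TRUE),
                                            labels = c("Tuj1-", "Tuj1+")))
  out <- list(table = tab)
  if (!is.null(ratios))
    out$mean_ratio <- tapply(ratios, factor(tuj1, levels = c(FALSE, TRUE),
                                            labels = c("Tuj1-", "Tuj1+")),
                             mean)
  out
}
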