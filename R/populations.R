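# Population classification from cumulative-EdU / HuC/D calls, regional
# restriction, differentiation and proliferation rates, and cumulative-
# labelling time-course analysis.

#' Classify cells from cumulative EdU and HuC/D calls
#'
#' Under cumulative S-phase labelling the two binary markers partition the
#' cells: EdU+/HuCD- cells cycled after labelling began (cycling
#' progenitors); EdU-/HuCD- cells exited the cycle but do not yet express
#' neuronal markers (prospective neurons); EdU-/HuCD+ cells are neurons.
#' EdU+/HuCD+ double positives are flagged `inconsistent` and excluded from
#' rates by default.
#'
#' @param edu,hucd Logical vectors (recycled to common length).
#' @param allow_unknown If `FALSE` (default), any `NA` call is an error; if
#'   `TRUE`, such cells are labelled `NA` and a message reports the count.
#' @return Factor with levels `cycling_progenitor`, `prospective_neuron`,
#'   `neuron`, `inconsistent`.
#' @export
classify_population <- function(edu, hucd, allow_unknown = FALSE) {
  n <- max(length(edu), length(hucd))
  edu <- rep_len(as.logical(edu), n)
  hucd <- rep_len(as.logical(hucd), n)
  unknown <- is.na(edu) | is.na(hucd)
  if (any(unknown)) {
    if (!allow_unknown)
      stop(sprintf("%d cell(s) with unknown marker calls (set allow_unknown = TRUE to drop them)",
                   sum(unknown)), call. = FALSE)
    message(sprintf("dropping %d cell(s) with unknown marker calls",
                    sum(unknown)))
  }
  lab <- character(n)
  lab[edu & !hucd] <- "cycling_progenitor"
  lab[!edu & !hucd] <- "prospective_neuron"
  lab[!edu & hucd] <- "neuron"
  lab[edu & hucd] <- "inconsistent"
  lab[unknown] <- NA_character_
  factor(lab, levels = c("cycling_progenitor", "prospective_neuron",
                         "neuron", "inconsistent"))
}

#' Stratify cells by proneural (Neurog2) intensity
#'
#' Cells at or below `t_low` are negative; above `t_low` up to and including
#' `t_high` are low expressors; above `t_high` are high expressors.
#'
#' @param level Numeric intensities (a.u.).
#' @param t_low,t_high Strictly ordered thresholds.
#' @return Factor with levels `negative`, `low`, `high`.
#' @export
classify_neurog2 <- function(level, t_low = 70, t_high = 190) {
  if (!(t_low < t_high)) stop("thresholds must satisfy t_low < t_high",
                              call. = FALSE)
  cut(level, breaks = c(-Inf, t_low, t_high, Inf),
      labels = c("negative", "low", "high"), right = TRUE)
}

#' Restrict records to the dorsal analysis region
#'
#' Progenitors of the ventral motor-neuron domain differentiate much earlier
#' than the rest of the neural tube, so analyses are restricted to the dorsal
#' two-thirds (measured from the dorsal-most pixel, y = 0 at the top). Also
#' drops records flagged as excluded zones when present.
#'
#' @param records Records with a `y` column (0-based pixels).
#' @param height Section height in pixels (required).
#' @param dorsal_frac Retained dorsal fraction (default 2/3); a record is
#'   kept iff `y <= dorsal_frac * height`.
#' @param drop_excluded Also drop `region == "excluded_zone"` records.
#' @return The filtered records.
#' @export
restrict_region <- function(records, height, dorsal_frac = 2 / 3,
                            drop_excluded = TRUE) {
  if (missing(height) || is.null(height) || !is.finite(height))
    stop("section 'height' is required to restrict the dorsal region",
         call. = FALSE)
  keep <- records$y <= dorsal_frac * height
  if (drop_excluded && !is.null(records$region))
    keep <- keep & records$region != "excluded_zone"
  records[keep, , drop = FALSE]
}

.rate <- function(records, marker, exclude_inconsistent) {
  if (is.null(records$transfected))
    stop("records lack a 'transfected' column", call. = FALSE)
  rec <- records
  if (exclude_inconsistent) {
    bad <- rec$edu %in% TRUE & rec$hucd %in% TRUE
    rec <- rec[!bad, , drop = FALSE]
  }
  tr <- rec$transfected %in% TRUE
  if (!any(tr))
    stop("no transfected records: rate undefined", call. = FALSE)
  sum(rec[[marker]][tr] %in% TRUE) / sum(tr)
}

#' Differentiation rate of transfected cells
#'
#' Number of transfected HuCD+ cells over the total number of transfected
#' cells. EdU+/HuCD+ double positives are excluded from numerator and
#' denominator by default (their classification is inconsistent).
#'
#' @param records Records with `transfected` and `hucd` (and `edu` if
#'   `exclude_inconsistent`).
#' @param exclude_inconsistent Drop EdU+/HuCD+ records first (default TRUE).
#' @return Proportion in `[0, 1]`.
#' @export
differentiation_rate <- function(records, exclude_inconsistent = TRUE)
  .rate(records, "hucd", exclude_inconsistent)

#' Proliferation rate of transfected cells
#'
#' Number of transfected EdU+ cells over the total number of transfected
#' cells.
#'
#' @inheritParams differentiation_rate
#' @return Proportion in `[0, 1]`.
#' @export
proliferation_rate <- function(records, exclude_inconsistent = TRUE)
  .rate(records, "edu", exclude_inconsistent)

#' Neighbour differentiation rate
#'
#' For one section: the number of non-transfected HuCD+ cells adjacent to a
#' transfected HuCD+ cell, over the total number of non-transfected cells
#' adjacent to a transfected HuCD+ cell. Counts are pooled over all
#' transfected HuCD+ cells of the section (one ratio per section), and a
#' non-transfected cell adjacent to several such cells is counted once.
#'
#' @param records Records with `cell_id`, `transfected` and `hucd`.
#' @param adjacency Edge data.frame with columns `from`, `to` (cell ids), or
#'   an `igraph` graph whose vertex names are cell ids.
#' @return Proportion in `[0, 1]`. Errors if no transfected HuCD+ cell has a
#'   non-transfected neighbour.
#' @export
neighbor_differentiation_rate <- function(records, adjacency) {
  if (inherits(adjacency, "igraph")) {
    el <- igraph::as_edgelist(adjacency, names = TRUE)
    adjacency <- data.frame(from = as.integer(el[, 1]),
                            to = as.integer(el[, 2]))
  }
  stopifnot(all(c("from", "to") %in% names(adjacency)))
  focal <- records$cell_id[records$transfected %in% TRUE &
                             records$hucd %in% TRUE]
  if (length(focal) == 0L)
    stop("no transfected HuCD+ cell: neighbour rate undefined",
         call. = FALSE)
  e <- rbind(data.frame(a = adjacency$from, b = adjacency$to),
             data.frame(a = adjacency$to, b = adjacency$from))
  nb <- unique(e$b[e$a %in% focal])
  info <- records[match(nb, records$cell_id), , drop = FALSE]
  elig <- info$transfected %in% FALSE
  if (!any(elig))
    stop("transfected HuCD+ cells have no non-transfected neighbours",
         call. = FALSE)
  sum(info$hucd[elig] %in% TRUE) / sum(elig)
}

#' Cumulative-labelling time course and plateau
#'
#' Computes, at each observation timepoint, the EdU+ and HuCD+ fractions of
#' the pulse-labelled (FT+) cohort, and estimates the EdU+ plateau as the
#' mean fraction over timepoints at or after `plateau_onset` (saturating
#' labelling of cycling cells is reached by then). The flatness of the
#' plateau is reported as the maximum pairwise difference among the plateau
#' points.
#'
#' @param cohort Long-format table with `cell_id`, `ft`, `timepoint`, `edu`,
#'   `hucd`; both marker states must be monotone non-decreasing in time per
#'   cell (cumulative labelling), otherwise the table is corrupt and an
#'   error is raised.
#' @param plateau_onset Hours after labelling at which the plateau is read
#'   (default 12).
#' @return A list: `curve` (data.frame `timepoint`, `n`, `edu_frac`,
#'   `hucd_frac`), `plateau_edu`, `plateau_hucd`, `flatness`.
#' @export
cumulative_labeling_curve <- function(cohort, plateau_onset = 12) {
  need <- c("cell_id", "ft", "timepoint", "edu", "hucd")
  stopifnot(all(need %in% names(cohort)))
  co <- cohort[cohort$ft %in% TRUE, , drop = FALSE]
  tp <- sort(unique(co$timepoint))
  if (length(tp) < 2L)
    stop("at least two timepoints are required", call. = FALSE)
  co <- co[order(co$cell_id, co$timepoint), , drop = FALSE]
  for (mk in c("edu", "hucd")) {
    d <- stats::ave(as.integer(co[[mk]]), co$cell_id,
                    FUN = function(v) c(0L, diff(v)))
    if (any(d < 0))
      stop(sprintf("'%s' status decreases over time for some cells: corrupt cumulative table",
                   mk), call. = FALSE)
  }
  n <- as.integer(table(factor(co$timepoint, levels = tp)))
  if (any(n == 0L))
    stop("a timepoint has zero labelled cells", call. = FALSE)
  edu_frac <- as.numeric(tapply(co$edu, factor(co$timepoint, levels = tp),
                                mean))
  hucd_frac <- as.numeric(tapply(co$hucd, factor(co$timepoint, levels = tp),
                                 mean))
  plat <- tp >= plateau_onset
  if (!any(plat))
    stop("no timepoint at or after the plateau onset", call. = FALSE)
  list(curve = data.frame(timepoint = tp, n = n, edu_frac = edu_frac,
                          hucd_frac = hucd_frac),
       plateau_edu = mean(edu_frac[plat]),
       plateau_hucd = mean(hucd_frac[plat]),
       flatness = if (sum(plat) > 1) diff(range(edu_frac[plat])) else 0)
}
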