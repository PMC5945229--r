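# Parameter constructors for the synthetic-data generators. Each constructor
# validates its invariants once, so the generators can assume a well-formed
# object.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(sprintf("'%s' = %g outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

#' Parameters for a simulated transverse neural-tube section
#'
#' Defines the statistical structure of one simulated cryosection image: a
#' field of non-overlapping elliptical nuclei, each assigned to one of the
#' three populations distinguished by cumulative EdU incorporation and HuC/D
#' expression (cycling progenitor, prospective neuron, neuron), with a nuclear
#' Notch-reporter (VNP) channel whose per-nucleus intensity is drawn from that
#' class's distribution plus pixel noise, and a DAPI-analogue channel equal to
#' the nuclear mask.
#'
#' The default intensity parameters place neurons at the background level,
#' progenitors broad and high, and prospective neurons intermediate, so that
#' after two-anchor normalization (neurons at 0, HuC/D-negative cells at 1)
#' the prospective-neuron population has mean close to 0.80 and median close
#' to 0.62. Intensity units are arbitrary; only ratios and normalized values
#' are meaningful downstream.
#'
#' @param height,width Field size in pixels.
#' @param n_nuclei Number of nuclei to place (>= 1).
#' @param radius_mean,radius_sd Mean and sd of the nuclear semi-major axis,
#'   pixels.
#' @param aspect_range Range of the minor/major axis ratio; each nucleus draws
#'   its aspect uniformly from this interval.
#' @param class_props Named proportions for `progenitor`,
#'   `prospective_neuron`, `neuron`; must sum to 1.
#' @param vnp_mean,vnp_sd Named per-class mean/sd of per-nucleus VNP intensity
#'   (a.u.). A neuron mean of `NA` means "equal to `background`".
#' @param background Neuron-level background intensity (a.u.).
#' @param noise_sd Additive per-pixel noise sd (a.u.).
#' @param intensity_dist Shape of the class-conditional per-nucleus intensity
#'   distribution, `"lognormal"` (default) or `"normal"`; parametrised by
#'   arithmetic mean and sd in both cases.
#' @param excluded_bands Named list of fractional y-ranges `c(lo, hi)` flagged
#'   as excluded zones (roof-plate and motor-neuron-domain analogues).
#' @param excluded_vnp_factor Multiplier applied to the VNP mean of
#'   non-neuron nuclei inside excluded bands, emulating the lower reporter
#'   activity of those signalling centres.
#' @param transfected_frac Fraction of nuclei on the electroporated side
#'   (x >= width/2) carrying the transfection reporter.
#' @param max_place_tries Rejection-sampling retries per nucleus before the
#'   generator reports infeasible packing.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return An object of class `section_sim_params`.
#' @seealso [generate_transverse_section()]
#' @export
section_sim_params <- function(height = 256L, width = 256L, n_nuclei = 150L,
                               radius_mean = 5, radius_sd = 0.8,
                               aspect_range = c(0.6, 0.95),
                               class_props = c(progenitor = 0.45,
                                               prospective_neuron = 0.15,
                                               neuron = 0.40),
                               vnp_mean = c(progenitor = 620,
                                            prospective_neuron = 490,
                                            neuron = NA),
                               vnp_sd = c(progenitor = 250,
                                          prospective_neuron = 341,
                                          neuron = 30),
                               background = 100, noise_sd = 5,
                               intensity_dist = c("lognormal", "normal"),
                               excluded_bands = list(
                                 roof_plate = c(0, 0.06),
                                 motor_neuron = c(0.60, 0.78)),
                               excluded_vnp_factor = 0.5,
                               transfected_frac = 0.3,
                               max_place_tries = 200L,
                               seed = 1L) {
  intensity_dist <- match.arg(intensity_dist)
  .check_scalar(height, "height", 8); .check_scalar(width, "width", 8)
  .check_scalar(n_nuclei, "n_nuclei", 1)
  .check_scalar(radius_mean, "radius_mean", 0, strict_lower = TRUE)
  .check_scalar(radius_sd, "radius_sd", 0)
  .check_scalar(background, "background", 0)
  .check_scalar(noise_sd, "noise_sd", 0)
  .check_scalar(transfected_frac, "transfected_frac", 0, 1)
  .check_scalar(excluded_vnp_factor, "excluded_vnp_factor", 0, 1)
  cls <- c("progenitor", "prospective_neuron", "neuron")
  if (!identical(names(class_props), cls))
    stop("'class_props' must be named progenitor, prospective_neuron, neuron")
  if (any(class_props < 0) || any(class_props > 1) ||
      abs(sum(class_props) - 1) > 1e-9)
    stop("'class_props' must lie in [0,1] and sum to 1 (tolerance 1e-9)")
  if (!identical(names(vnp_mean), cls) || !identical(names(vnp_sd), cls))
    stop("'vnp_mean'/'vnp_sd' must be named progenitor, prospective_neuron, neuron")
  if (is.na(vnp_mean[["neuron"]])) vnp_mean[["neuron"]] <- background
  if (any(vnp_mean <= 0) || any(vnp_sd < 0))
    stop("class intensity means must be > 0 and sds >= 0")
  if (length(aspect_range) != 2L || any(aspect_range <= 0) ||
      any(aspect_range > 1) || aspect_range[1] > aspect_range[2])
    stop("'aspect_range' must be an increasing pair in (0, 1]")
  for (b in excluded_bands)
    if (length(b) != 2L || any(b < 0) || any(b > 1) || b[1] >= b[2])
      stop("each excluded band must be an increasing fractional pair in [0, 1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_nuclei = as.integer(n_nuclei),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 aspect_range = aspect_range, class_props = class_props,
                 vnp_mean = vnp_mean, vnp_sd = vnp_sd,
                 background = background, noise_sd = noise_sd,
                 intensity_dist = intensity_dist,
                 excluded_bands = excluded_bands,
                 excluded_vnp_factor = excluded_vnp_factor,
                 transfected_frac = transfected_frac,
                 max_place_tries = as.integer(max_place_tries),
                 seed = as.integer(seed)),
            class = "section_sim_params")
}

#' Parameters for a simulated en-face apical mosaic
#'
#' Defines a space-filling tessellation of the apical surface into `n_cells`
#' footprints, a randomly transfected subset, and a differentiating subset
#' among the transfected whose footprints are contracted toward their seed
#' point (neighbours absorbing the freed area) and whose junctional intensity
#' is reduced by `junction_factor`.
#'
#' @param height,width Field size in pixels.
#' @param n_cells Number of cells in the tessellation (>= 10).
#' @param transfected_frac Fraction of cells carrying the transfection
#'   reporter; `transfected_frac * n_cells` must be >= 1 at generation time.
#' @param diff_frac Fraction of transfected cells that are differentiating.
#' @param constriction Apical-area multiplier for differentiating cells,
#'   in (0, 1].
#' @param junction_factor Junction-marker intensity multiplier for
#'   differentiating cells, in (0, 1].
#' @param junction_baseline Junctional signal above background at unmodified
#'   junctions (a.u.).
#' @param junction_background Non-junctional background intensity (a.u.).
#' @param noise_sd Additive pixel noise sd (a.u.).
#' @param seed_spacing Minimum seed separation as a fraction of
#'   `sqrt(height * width / n_cells)`; larger values give a more regular,
#'   epithelium-like tessellation.
#' @param seed Integer seed.
#' @return An object of class `mosaic_sim_params`.
#' @seealso [generate_apical_mosaic()]
#' @export
mosaic_sim_params <- function(height = 256L, width = 256L, n_cells = 200L,
                              transfected_frac = 0.15, diff_frac = 0.5,
                              constriction = 0.5, junction_factor = 0.5,
                              junction_baseline = 200,
                              junction_background = 50,
                              noise_sd = 4, seed_spacing = 0.6, seed = 1L) {
  .check_scalar(n_cells, "n_cells", 10)
  .check_scalar(transfected_frac, "transfected_frac", 0, 1)
  .check_scalar(diff_frac, "diff_frac", 0, 1)
  .check_scalar(constriction, "constriction", 0, 1, strict_lower = TRUE)
  .check_scalar(junction_factor, "junction_factor", 0, 1)
  .check_scalar(junction_baseline, "junction_baseline", 0)
  .check_scalar(junction_background, "junction_background", 0)
  .check_scalar(noise_sd, "noise_sd", 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 transfected_frac = transfected_frac, diff_frac = diff_frac,
                 constriction = constriction,
                 junction_factor = junction_factor,
                 junction_baseline = junction_baseline,
                 junction_background = junction_background,
                 noise_sd = noise_sd, seed_spacing = seed_spacing,
                 seed = as.integer(seed)),
            class = "mosaic_sim_params")
}

#' Parameters for a simulated pulse-labelled cohort time course
#'
#' Emulates a FlashTag-style experiment: a cohort of cells labelled at
#' mitosis (t = 0), after which cumulative EdU dosing starts at
#' `edu_start` hours and is renewed every `edu_interval` hours, so every cell
#' that re-enters S phase becomes EdU-positive. A fraction `exit_frac` of the
#' cohort exits the cycle at t = 0 and expresses the neuronal marker after
#' its differentiation delay.
#'
#' S-phase re-entry delays are drawn from a normal distribution truncated to
#' `[0, reentry_max]`: re-entry has to precede the next division and the cell
#' cycle at these stages lasts about 12 h, which bounds G1.
#'
#' @param n_cells Cohort size at t = 0.
#' @param exit_frac Probability that a cohort cell exits the cycle at t = 0.
#' @param reentry_mean,reentry_sd Mean/sd (hours) of the S-phase re-entry
#'   delay of cycling cells.
#' @param reentry_max Truncation bound (hours) of the re-entry delay.
#' @param edu_start First EdU dose, hours after labelling.
#' @param edu_interval Interval between doses (hours); doses keep the label
#'   continuously available from `edu_start` onward.
#' @param diff_delay_mean,diff_delay_sd Mean/sd (hours) of the delay between
#'   cycle exit and neuronal-marker onset.
#' @param timepoints Strictly increasing observation times (hours).
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_params`.
#' @seealso [generate_cohort_timecourse()]
#' @export
cohort_sim_params <- function(n_cells = 500L, exit_frac = 0.35,
                              reentry_mean = 8, reentry_sd = 2,
                              reentry_max = 11,
                              edu_start = 3, edu_interval = 4,
                              diff_delay_mean = 14, diff_delay_sd = 4,
                              timepoints = c(4, 8, 12, 16, 20), seed = 1L) {
  .check_scalar(n_cells, "n_cells", 1)
  .check_scalar(exit_frac, "exit_frac", 0, 1)
  .check_scalar(reentry_mean, "reentry_mean", 0)
  .check_scalar(reentry_sd, "reentry_sd", 0)
  .check_scalar(reentry_max, "reentry_max", 0)
  .check_scalar(edu_start, "edu_start", 0)
  .check_scalar(edu_interval, "edu_interval", 0, strict_lower = TRUE)
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing")
  structure(list(n_cells = as.integer(n_cells), exit_frac = exit_frac,
                 reentry_mean = reentry_mean, reentry_sd = reentry_sd,
                 reentry_max = reentry_max,
                 edu_start = edu_start, edu_interval = edu_interval,
                 diff_delay_mean = diff_delay_mean,
                 diff_delay_sd = diff_delay_sd,
                 timepoints = timepoints, seed = as.integer(seed)),
            class = "cohort_sim_params")
}
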