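---
title: "Methods: quantifying Notch-reporter dynamics and apical remodelling in neuroepithelial mosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Notch-reporter dynamics and apical remodelling in neuroepithelial mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimosaic)
```

## The measurement problem

In the embryonic spinal cord, elongated progenitors line the ventricle and
progressively produce neurons. A cell committing to differentiation passes
through a *prospective neuron* stage: it has left the cell cycle but does not
yet express neuronal markers, and it is still apically attached. Two
quantitative readouts characterise this transition:

1. **Nuclear Notch-reporter intensity.** A destabilised nuclear fluorescent
   reporter driven by a Notch target promoter (Hes5) reads out signalling
   activity per cell. Populations are defined by cumulative EdU incorporation
   (labels every cell that passes S phase after dosing begins) and HuC/D
   expression (neurons): EdU+/HuCD− cycling progenitors, EdU−/HuCD−
   prospective neurons, EdU−/HuCD+ neurons.
2. **Apical geometry and junctions.** On en-face views, the apical footprint
   area of a transfected cell and the junctional N-Cadherin signal around its
   circumference are referenced to non-transfected neighbours, giving
   unit-free ratios robust to staining and imaging variation.

`epimosaic` implements both measurement chains, the population and cohort
analyses built on them, the study's statistical comparisons, and a
ground-truthed simulator of the imagery, so that every stage is verifiable by
parameter recovery without the original microscopy data.

## Reporter quantification and the two-anchor normalization

`measure_nuclei()` computes, for every label of a nuclear segmentation, the
arithmetic mean of each channel under the mask, the pixel area, the centroid,
and an ellipse fitted from the second central moments of the binary mask
(axis lengths $4\sqrt{\lambda}$, so a solid ellipse recovers its own axes).
The segmentation is an input: in the original workflow nuclei were outlined
on the DAPI channel, and that step is upstream of this package too. The exact
shape descriptors recorded by the original macros are unspecified;
moments-based ellipses are the standard choice and are validated against
generative shapes in the tests.

Raw intensities are arbitrary units. The scale is fixed by two anchors:

$$ v' = \frac{v - b}{m - b}, $$

where $b$ is the mean raw intensity over HuCD+ (neuron) records — the
operational background, since pharmacological Notch blockade drives the
reporter exactly to this level — and $m$ is the mean over HuCD− records in
included regions. By construction the neuron anchor set has mean $v' = 0$ and
the HuCD− anchor set mean $v' = 1$. Values are **not clipped** to $[0,1]$:
the population scatter genuinely extends beyond both anchors. The transform
is affine-invariant: any gain–offset change of the raw scale leaves every
$v'$ unchanged, which the test suite asserts at $10^{-9}$.

Anchoring choices made where the procedure left room:

- The background is estimated per acquisition session by default (the
  closest reproducible unit to "per experiment"), overridable to per-image.
  Whether the original background was per embryo or per section is not
  stated; the pipeline makes the unit explicit instead of guessing.
- The progenitor anchor set is all HuCD− records outside the flagged zones
  (roof plate, motor-neuron domain), which display genuinely lower Notch
  activity and would otherwise bias the anchor.
- Analyses are restricted to the dorsal two-thirds of the section
  (`restrict_region()`), measured from the dorsal-most tissue pixel — the
  simplest reproducible reading of the rule, with the retained fraction
  exposed as a parameter.

**Cross-session re-anchoring.** When one experiment spans several confocal
sessions, `cross_session_normalize()` equalises gains using the mean
reporter intensity (minus the session's *optical* background) of HuCD+
nuclei on the non-electroporated side as reference, scaling every session to
the first. The optical background here is the camera offset / cell-free
signal floor, passed explicitly — it cannot be the neuron-level anchor $b$,
which would make the reference identically zero. With a pure gain difference
the correction is exact, and the tests verify per-class means agree within
2% after re-scaling of a half-gain session.

**Fold changes** between a perturbed and a control population
(`fold_change()`) are ratios of background-subtracted means over HuCD−
included records. The simulator's constitutive-Notch regime (treated
progenitor excess six times the control excess) is recovered as a fold
change of 6 within Monte-Carlo error.

**The colour-code map** (`render_intensity_map()`) redraws every nucleus as
its fitted ellipse coloured by the palette bin of $v'$, in ascending id
order (later draws overpaint), with excluded-zone records in black. The
original binning is not stated; the default palette uses 8 equal bins over
$[-0.2, 1.4]$ with underflow/overflow bins, and boundary values fall in the
upper bin. Out-of-field ellipses are clipped and counted, never fatal.

## Populations, rates and the cohort analysis

`classify_population()` is the EdU × HuCD contract above; EdU+/HuCD+ double
positives are labelled `inconsistent` and excluded from rates by default.
Biologically such cells can exist (a cell that cycled under cumulative EdU
and then differentiated); the source procedure does not say how they were
treated, so exclusion is this package's explicit, logged default rather than
an inherited rule.

Differentiation and proliferation rates are the HuCD+ and EdU+ fractions of
the transfected population. The neighbour differentiation rate pools counts
within a section — the number of non-transfected HuCD+ cells adjacent to a
transfected HuCD+ cell over all non-transfected cells adjacent to such cells,
each neighbour counted once — because the source defines one ratio per
section, not a mean of per-cell ratios.

`cumulative_labeling_curve()` analyses a pulse-labelled (FlashTag-style)
cohort: per-timepoint EdU+ and HuCD+ fractions among labelled cells, with a
plateau estimate (mean over timepoints ≥ 12 h, the onset by which labelling
of cycling cells saturates; configurable) and a flatness diagnostic. Both
marker states must be monotone non-decreasing per cell — a violation means a
corrupt table and is an error, not a warning.

## Apical metrics

`build_adjacency()` connects cells sharing at least `min_shared = 3`
8-connected boundary pixel pairs, so a diagonal pixel touch is not contact.
The reference set of a transfected cell (`select_neighbors()`) is four
non-transfected cells *one cell row away* — operationalised as adjacency
distance exactly 2, the reading under which immediate neighbours (whose
geometry is directly deformed by the focal cell) are skipped. Where more
than four candidates exist the four nearest by centroid distance are taken,
ties broken by ascending id; if ring 2 cannot supply four, ring-1
non-transfected cells complete the set with the ring recorded per neighbour,
and fewer than four candidates overall excludes the cell with a log count.
The original choice rule among eligible neighbours is unstated;
nearest-centroid with id tie-break is this package's convention.

The apical area ratio is focal area over the mean of the four reference
areas; the junction intensity ratio is the background-corrected mean over
the focal cell's circumference band over the neighbours' mean. The
"apical circumference" is a 2-pixel boundary band (each side of an interface
attributed to both cells), the band width being unstated in the source. Both
ratios are invariant to uniform spatial rescaling and to intensity gain with
co-scaled background.

Transfected progenitors that divide appear as adjacent transfected pairs and
are discarded (`pair_filter()`, symmetric removal); adjacency at one
timepoint is the operational proxy for the visual pair identification used
originally. `split_small_large()` thresholds area ratios at the *control
condition's median* for every condition; equality goes to `large`, since
"small" was defined as below the median. `crosstab_tuj1()` crosses the size
split with early neuronal marker expression.

## Statistics

`compare_two()` and `compare_many()` mirror the study's conventions:
Student t (pooled variance by default, the classic Prism default, Welch
optional) and one-way ANOVA with Tukey HSD for means; Mann-Whitney U and
Kruskal-Wallis with Dunn's post hoc for reporter-intensity distributions.
The Mann-Whitney p-value is exact by **full enumeration** of all
$\binom{n_A+n_B}{n_A}$ rank assignments for combined $n \le 20$ (valid under
ties via midranks), and a tie-corrected normal approximation beyond. Dunn's
test uses the standard rank-sum z with tie correction and a
Bonferroni-family adjustment (switchable to Holm/Šidák/none). Stars follow
the `ns/*/**/***` convention with boundary values mapping to the
less-significant label. Type-I calibration is asserted on null simulations:
two-sided tests at $\alpha = 0.05$ reject in $5\% \pm 2\%$ of repeats.

The unit of analysis (cells vs sections) changes the meaning of every test;
it is the caller's explicit choice of input rows, never inferred.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the analysis is verified against.

**Transverse sections** (`generate_transverse_section()`): non-overlapping
random ellipses (rejection-sampled with a bounded retry count; infeasible
packing fails loudly with the achieved count), class labels drawn from the
population proportions, per-nucleus reporter intensity drawn from the
class-conditional distribution plus pixel noise, a DAPI-analogue channel
equal to the mask, and integer-rounded counts so TIFF round trips are
bit-exact. Raw intensity distributions were never published; the shape is a
config choice (`lognormal` default — fluorescence intensities are
non-negative and right-skewed — with `normal` available). The default
parameters (background 100 a.u.; neurons at background, sd 30; progenitors
lognormal mean 620, sd 250; prospective neurons lognormal mean 490, sd 341;
proportions 0.45/0.15/0.40) were solved analytically so the normalized
prospective-neuron population has mean ≈ 0.80 and median ≈ 0.62 with
progenitors broad and neurons at background — the reported regime of the
system being emulated. Excluded bands (roof-plate and motor-neuron
analogues) carry attenuated reporter activity, which is what motivates their
exclusion from anchors.

**Apical mosaics** (`generate_apical_mosaic()`): a discrete Voronoi
tessellation of minimum-separation seeds (regular enough to resemble an
epithelium; seed spacing 0.6 of the mean inter-cell distance), mosaic
transfection, and constriction of differentiating cells implemented by
linear shrinkage of the footprint toward the seed by $\sqrt{s}$ — so the
area scales by $s$ — with freed pixels absorbed by the nearest
non-differentiating neighbour. The tessellation therefore remains an exact
partition (areas always sum to the field), and neighbours respond to
constriction as in a real epithelium. Junction pixels (where ≥ 2 labels
meet within 8-connectivity) are painted at baseline times the minimum
junction factor of the cells meeting there, which for an ordinary two-cell
junction equals the differentiating cell's factor, making the generative
factor recoverable from the shared band.

**Cohorts** (`generate_cohort_timecourse()`): each labelled cell exits at
t = 0 with probability `exit_frac` (HuCD+ after a normal differentiation
delay, mean 14 h — neuronal marker onset rises between 12 h and 16 h in this
system) or re-enters S phase after a normal delay (mean 8 h, sd 2 h)
truncated to [0, 11 h]: re-entry must precede the next division and the
cycle at these stages is ~12 h. The truncation also makes the all-cycling
regime reach a plateau of exactly 1. EdU is modelled as continuously
available from the first dose (3 h), the dosing interval (4 h) being kept as
schedule metadata — with doses every 4 h the label pool never clears.

What the simulator does *not* emulate: interkinetic nuclear migration,
signalling dynamics, point-spread blur, bleaching, or segmentation error.
Passing recovery tests therefore demonstrates correctness of the
*measurement chain* given a faithful segmentation, not robustness to
upstream imaging artefacts.

## Numerical choices and problem sizes

- All randomness flows from one integer seed per generator call through a
  single RNG, with the global RNG state saved and restored; identical
  parameters reproduce outputs bit-exactly, and the end-to-end pipeline is
  byte-deterministic under a fixed config.
- Coordinates are 0-based, origin top-left, y downward, stated once and used
  everywhere; dorsal is the top of a transverse section.
- The verification suite uses sections of 50–200 nuclei on 96–300 px fields,
  200-cell mosaics on 256 px fields, 500-cell cohorts, 50 Monte-Carlo seeds
  for fold-change recovery and 1,000 null repeats for test calibration —
  sizes chosen to put Monte-Carlo error well inside every asserted
  tolerance while a full run stays in the minutes range.
- Recovery tolerances follow binomial / Monte-Carlo error at those sizes:
  constriction and junction factors within ±0.1 over a 3 × 3 grid of
  generative values, cohort plateau within 2 binomial sd, fold change within
  3 Monte-Carlo se.

## Known limitations

- Nucleus and apical segmentation are inputs, not outputs; no denoising,
  illumination correction, or junction segmentation from raw signal.
- The sister-pair filter is an adjacency proxy at one timepoint; true
  lineage information would identify pairs that have already separated.
- No mixed-effects modelling of the embryo/section hierarchy: tests treat
  the rows they are given as the unit of analysis, as the original
  comparisons did.
- Cross-session scaling assumes a pure gain difference; offset drift beyond
  the supplied optical background is not modelled.
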