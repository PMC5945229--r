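# epimosaic

Quantitative image analysis for mosaic electroporation experiments in the
embryonic neural tube, for developmental biologists measuring Notch-reporter
dynamics and apical-junction remodelling as progenitors commit to
differentiation and delaminate from the ventricular surface.

During early neurogenesis three populations coexist and are distinguished by
cumulative EdU incorporation and HuC/D expression: cycling progenitors
(EdU+/HuCD−), prospective neurons (EdU−/HuCD−, post-mitotic but not yet
expressing neuronal markers) and neurons (EdU−/HuCD+). The package
quantifies, per cell:

- **Nuclear Notch-reporter intensity** from a labelled nucleus segmentation
  plus an intensity channel, normalized with two anchors,

  v' = (v − b) / (m − b),

  where *b* is the mean raw intensity of neurons (the operational
  background: pharmacological Notch blockade drives the reporter exactly to
  this level) and *m* the mean of the HuCD− population — so neurons sit at
  0 and the undifferentiated population at 1. Cross-session gain factors,
  fold changes between conditions and the classic ellipse colour-code map
  are included.
- **Neighbour-referenced apical metrics** on en-face segmentations: the
  apical area ratio (focal transfected cell over the mean of four
  non-transfected cells one cell row away) and the background-corrected
  junction intensity ratio, with the sister-pair filter and the
  control-median small/large split.
- **Rates and cohort kinetics**: differentiation/proliferation rates of the
  transfected population, the pooled neighbour differentiation rate, and
  cumulative-labelling time courses of pulse-labelled cohorts with plateau
  estimation.
- **The matching statistics**: Student t / one-way ANOVA + Tukey for means,
  Mann-Whitney U (exact by full enumeration at small n) /
  Kruskal-Wallis + Dunn for intensity distributions, with the usual star
  convention.

A ground-truthed synthetic-data generator (`generate_transverse_section()`,
`generate_apical_mosaic()`, `generate_cohort_timecourse()`) emulates the
imagery and cohort structure the analysis assumes, so every stage is
verified by generative-parameter recovery.

## Worked example

```r
library(epimosaic)

sec <- generate_transverse_section(section_sim_params(seed = 7))
rec <- measure_nuclei(sec$label, sec$channels, sec$markers)
rec <- flag_regions(rec, 256, 256, sec$params$excluded_bands)

model <- fit_normalization(rec)
print(model)
#> normalization model on mean_VNP: background b = 97.42, progenitor anchor m = 605.4

rec <- normalize_vnp(rec, model)
rec2 <- restrict_region(rec, 256)          # dorsal two-thirds, zones dropped
rec2$population <- classify_population(rec2$edu, rec2$hucd)
table(rec2$population)
#> cycling_progenitor prospective_neuron             neuron       inconsistent
#>                 40                  8                 32                  0

differentiation_rate(rec2)
#> [1] 0.3

compare_many(rec2$vnp_norm, droplevels(rec2$population),
             mode = "nonparametric")
#> Kruskal-Wallis + Dunn: statistic = 57.48, p = 3.304e-13 (***); n = 40, 8, 32
#> pairwise comparisons:
#>              group1             group2         z            p        p_adj stars
#>  cycling_progenitor prospective_neuron 0.7666667 4.432797e-01 1.000000e+00    ns
#>  cycling_progenitor             neuron 7.4664076 8.241378e-14 2.472413e-13   ***
#>  prospective_neuron             neuron 3.7286677 1.924948e-04 5.774843e-04   ***
```

The anchors are recovered from the data (nuclei average ~100 a.u. of
background; the HuCD− population ~605 a.u.), the three populations separate
on normalized reporter intensity exactly as the biology dictates (neurons at
0; prospective neurons intermediate but still far above neurons), and 30% of
transfected cells are HuCD+.

The end-to-end pipeline — simulate/load, measure, normalize, classify,
rates, stats, with a provenance manifest and byte-deterministic outputs — is
`run_pipeline(config, out_dir)`. A thin command-line dispatcher over the
same functions ships at `inst/scripts/epimosaic.R`
(`Rscript epimosaic.R run --config cfg.json --out out/`).

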