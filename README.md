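# plaquemorph

3D morphometry of connexin-43 (Cx43) gap-junction plaques at the
cardiomyocyte intercalated disc (ID), measured from serial block-face
scanning electron microscopy (SBF-SEM) stacks in which Cx43 is labelled
with silver-enhanced nanogold. In each 50 nm section a plaque appears as
two parallel strings of dark 10–20 nm beads, one per apposed membrane.
The package is aimed at cell-biology and cardiac-electrophysiology groups
who quantify junctional remodelling — for example in plakophilin-2
deficient (PKP2cKO) hearts, where the intercellular space widens and
orphan Cx43 hemichannels accumulate.

From a stack it computes, per plaque:

* **area per length** — intercellular area between the bead strings in a
  section divided by the plaque length there (units reduce to nm: the
  mean membrane gap), averaged per plaque over its sections;
* **maximal width** — the supremum of the inter-membrane distance over
  the whole structure, sampled perpendicular to the plaque midline at
  ≤5 nm arc steps;
* **hemiplaques** — runs of ≥3 consecutive beads spanning ≥100 nm on one
  membrane with no opposing bead in register (mutual-nearest arc pairing
  within 0.6× the median bead spacing and ≤120 nm separation), their
  summed length, and the fraction of total plaque length they occupy.

Group comparisons reproduce the standard protocol: Shapiro-Wilk and
(Lilliefors-corrected) Kolmogorov-Smirnov normality gate — normal when
either passes at p > 0.05 — routing to a two-sided pooled-variance
Student's t-test or a Mann-Whitney U test (exact by enumeration when both
n ≤ 8), significance at p < 0.05, min–max box-whisker summaries.

Because raw volumes of this kind are generally unavailable, the package
includes a synthetic SBF-SEM stack generator with complete ground truth
(midlines, gap profiles, bead tables, orphan intervals) emulating control
morphology (narrow constant gap, fully paired strings) and PKP2cKO-like
morphology (bulged gaps up to ~100 nm, orphan runs). Every stage is
validated by parameter recovery against the generator's oracle.

## Worked example

Simulate one KO-like plaque, detect its beads, reconstruct and measure it:

```r
library(plaquemorph)

set.seed(7)
pl <- sample_plaque("pkp2cko", plaque_id = "demo")
r   <- generate_stack(list(pl$spec), pl$geometry, seed = 7)
det <- detect_beads(r$stack)
rec <- reconstruct_plaques(det, pl$geometry)
rec
#> plaque_reconstruction: 1 plaque(s)
#>   P01: 556 detections, 7 analyzable slices

measure_plaques(rec)$per_plaque[, c("avg_area_per_length_nm",
                                    "max_width_nm",
                                    "hemiplaque_fraction_pct")]
#>   avg_area_per_length_nm max_width_nm hemiplaque_fraction_pct
#> 1                  31.13         73.7                       0
truth_metrics(r$truth)$per_plaque[, c("avg_area_per_length_nm",
                                      "max_width_nm",
                                      "hemiplaque_fraction_pct")]
#>   avg_area_per_length_nm max_width_nm hemiplaque_fraction_pct
#> 1                  31.21        73.93                       0
```

The recovered mean gap (31.1 nm) and widest point (73.7 nm) match the
generative truth (31.2 and 73.9 nm) to within a percent; this plaque was
drawn without orphan runs, and none are called. Comparing simulated
cohorts with the gated protocol:

```r
tm <- cohort_truth_metrics(sample_cohort(n_per_group = 8, seed = 42))
compare_groups(tm$avg_area_per_length_nm[tm$genotype == "control"],
               tm$avg_area_per_length_nm[tm$genotype == "pkp2cko"],
               metric = "avg_area_per_length_nm",
               labels = c("control", "pkp2cko"))
#> avg_area_per_length_nm: control vs pkp2cko (n = 8, 8)
#>   normal: TRUE/TRUE -> student_t; statistic = -10.57, p = 4.701e-08 *
```

The full pipeline (simulate → detect → reconstruct → measure → compare)
runs from one configuration object or from the shell:

```r
cfg <- run_config("runs/demo", seed = 1, n_per_group = 4)
run_pipeline(cfg)   # writes TIFFs, detections, reconstruction JSON,
                    # morphometry CSVs, comparison report, manifest
```

```sh
inst/cli/plaquemorph make-fixture --name tiny --dir runs/tiny --seed 1
inst/cli/plaquemorph run-all --config runs/tiny/config.yaml
```

See `vignettes/plaque-morphometry.Rmd` for the model, parameter meanings
and validation design.

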