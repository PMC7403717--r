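# apicalpulse

Quantification of pulsatile apical constriction and ratcheting in
epithelial cells.

During *Drosophila* ventral furrow formation, mesodermal cells shrink their
apical surface through repeated actomyosin contraction pulses. Between
pulses a cell either stabilizes the constricted state (**ratcheting**) or
relaxes back; the balance decides whether pulsation produces net tissue
invagination. `apicalpulse` is for researchers who have per-cell apical-area
time series (e.g. from EDGE segmentation) and need the downstream
quantitative layer:

- **Per-cell dynamics** — gap interpolation, moving-average smoothing, the
  constriction rate `r = -dA/dt` (µm²/min, positive while constricting),
  cubic polynomial detrending, plateau-aware local-extrema pulse detection,
  and the **ratchet statistic**: the mean difference in area between
  consecutive pulsation peaks, in % of initial area per pulse interval
  (negative = ratcheted, ≈0 = relaxing).
- **Cohort analysis** — behaviour categories at 7 min (area ratio < 0.5
  constricted; 0.5–1 impaired; > 1 expanded), short-track exclusion,
  peak-triggered averaging in ±25 s windows, two-stage per-embryo averages.
- **Image operations** — a grid-based confocal surface-projection algorithm
  with height-map extraction, background rules (lowest focal plane;
  mean − SD), apical mean projections, normalized intensity time courses,
  per-cell intensity, cell geometry (area, A-P/D-V anisotropy), Pearson
  colocalization.
- **Statistics** — effect size `d = (x̄₁ − x̄₂)/(2s)` with `s` the dataset's
  maximal SD and the `|d| < 0.5` non-significance rule, pooled t-test,
  one-way ANOVA with Tukey post hoc, fold-change normalization to control.
- **Synthetic data** — pulsatile traces, cohorts, labelled movies and 3D
  surface phantoms with exact ground truth, so the whole pipeline is
  testable without microscope data.

## Worked example

Simulate a knockdown-like cohort, categorize behaviours, and compare peak
constriction rates against a control cohort:

```r
library(apicalpulse)

co <- gen_cohort(cohort_params(
  n_cells = 60,
  class_mix = c(constricted = 0.5, impaired = 0.44, expanded = 0.06),
  seed = 42))
category_fractions(lapply(co, categorize_cell))$fractions
#> constricted    impaired    expanded
#>  0.50000000  0.43333333  0.06666667

kd_like <- co[attr(co, "truth")$class == "impaired"]
ctrl <- gen_cohort(cohort_params(n_cells = 60, class_mix = c(1, 0, 0), seed = 7))
c_ctrl <- mean(sapply(ctrl, mean_peak_rate, "constriction"))
c_kd   <- mean(sapply(kd_like, mean_peak_rate, "constriction"))
sprintf("constriction: control %.1f vs impaired %.1f um^2/min", c_ctrl, c_kd)
#> "constriction: control 10.0 vs impaired 7.4 um^2/min"

fc <- fold_change_rates(c_ctrl, c_kd)
sprintf("fold change %.2f (%d%%)", fc$fold, fc$percent_change_rounded)
#> "fold change 0.73 (-27%)"

ratchet_amplitude(ctrl[[1]])$mean_interpeak_diff
#> -12.1   # % of initial area per pulse interval: strongly ratcheted

cohens_d(sapply(ctrl, mean_peak_rate, "constriction"),
         sapply(kd_like, mean_peak_rate, "constriction"))$d
#> 1.19    # |d| >= 0.5: significant
```

The category fractions reproduce the requested mixture exactly (up to the
60-cell resolution), the recovered group rates sit at the class targets
(9.9 and 7.5 µm²/min at these sample sizes), and the control cell's negative
ratchet statistic says its area steps down with every pulse.

At the printed precision of the reference group statistics, the fold-change
chain is:

```r
fold_change_rates(9.9, 7.5)$fold_rounded            # 0.8  (constriction, -24%)
fold_change_rates(3.2, 5.1)$fold_rounded            # 1.6  (expansion, +60%)
ratio_of_changes(60, -24)                           # 2.5
```

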