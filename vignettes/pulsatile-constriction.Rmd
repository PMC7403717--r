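---
title: "Quantifying pulsatile apical constriction and ratcheting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile apical constriction and ratcheting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apicalpulse)
```

## The measurement problem

During ventral furrow formation in the gastrulating *Drosophila* embryo,
mesodermal cells shrink their apical surface through repeated actomyosin
contraction pulses. Between pulses a cell either stabilizes its newly
constricted state — *ratcheting* — or relaxes back toward its previous area.
Whether the ratchet holds decides whether pulsation translates into net
tissue-scale constriction. `apicalpulse` implements the quantitative layer of
this analysis: given per-cell apical-area time series (produced upstream by a
segmentation tool such as EDGE), it measures pulsation, ratcheting, and
group-level differences, and it ships a synthetic-data generator with exact
ground truth so every stage of the pipeline is testable without microscope
data.

## The per-cell pipeline

For one cell with area samples $A_i$ at times $t_i$ (typical frame interval
3.8 s):

1. **Cleaning** (`interpolate_gaps`): interior missing runs shorter than
   three frames are linearly interpolated; longer runs stay missing; edge
   gaps are trimmed because they have no anchor.
2. **Constriction rate** (`constriction_rate`):
   $r_{i+1/2} = -\dfrac{A_{i+1}-A_i}{t_{i+1}-t_i}\cdot 60$ in
   $\mu m^2/\mathrm{min}$, assigned to interval midpoints, positive while the
   cell constricts. Displayed rates are smoothed with a centered 10-frame
   moving mean (~38 s); pulse detection always uses the unsmoothed rate.
3. **Detrending** (`detrend_area`): a least-squares cubic polynomial captures
   the slow net constriction; the residual is the normalized pulsation
   signal. Residual + trend reconstructs the input to numerical tolerance.
4. **Pulse detection** (`find_local_extrema`, `find_rate_peaks`): strict
   local maxima/minima, with a plateau rule (a flat run strictly above both
   flanks counts once, at its first sample) and endpoints excluded. Rate
   peaks with non-positive values are discarded, so a cell that never
   constricts contributes no constriction peaks.
5. **Ratchet statistic** (`ratchet_amplitude`): extrema are located on the
   detrended residual, then area differences between consecutive maxima (and
   consecutive minima) are evaluated on the *raw* area, averaged per kind,
   and the kind means averaged to one number per cell, in % of initial area
   per pulse interval. Negative values mean the cell area incrementally
   decreases upon pulsation (ratcheting); values near zero mean it relaxes
   back. The differences are taken on raw area deliberately: the statistic
   must retain the trend-borne decrease to separate ratcheted from
   non-ratcheted cells; `on_raw = FALSE` switches to pure-residual
   differences for users who want the trend excluded.
6. **Categorization** (`categorize_cell`): the 3-frame-smoothed area at the
   sample nearest 7 min after onset, divided by the initial area, classifies
   the cell as *constricted* (< 0.5), *impaired* (0.5–1, boundaries
   inclusive: the printed convention "> 1" is strict for expanded), or
   *expanded* (> 1).
7. **Cohort summaries**: `exclude_short_tracks` removes cells tracked less
   than the median minus one SD of tracked durations;
   `peak_triggered_average` overlays ±25 s windows around isolated rate
   peaks (isolated = no same-polarity peak within the half window; truncated
   windows are dropped, not padded); `per_embryo_average` averages cells
   within embryo first and embryos second, so each embryo carries equal
   weight.

## Statistics

With hundreds of cells per group, p-values alone overstate significance, so
group comparisons use the effect size
$d = \dfrac{\bar x_1 - \bar x_2}{2s}$ with $s$ the maximal SD across all
groups of the dataset (`cohens_d`); $|d| < 0.5$ is reported as not
significant. `two_sample_ttest` (pooled variance), `anova_oneway` (with
Tukey–Kramer post hoc), `fold_change_rates` (group mean ÷ control mean,
reported to one decimal; percent changes to the nearest integer) and
`ratio_of_changes` complete the layer. The canonical worked example: mean
peak constriction rates 9.9 → 7.5 µm²/min give fold 0.8 (−24%), expansion
rates 3.2 → 5.1 µm²/min give fold 1.6 (+60% at the printed precision), and
the expansion change is 60/24 = 2.5 times the constriction change.

## Image operations

`surface_project` flattens a curved epithelial surface out of a confocal
stack: the field is tiled into an x/y grid (default 16 px); each tile's
per-slice summed intensity profile locates the surface peak (argmax, ties to
the apical-most slice); the tile height map is Gaussian-smoothed (σ = 1 grid
unit); each tile is mean-projected over the slices overlapping a 3-slice
band centered at the fractional filtered height, with proportional weights
for partially covered slices. To suppress tile-edge artefacts the procedure
runs a second time on a copy padded by half a grid unit per side (padding
filled with each slice's outer-margin mean), which offsets the grid by half
a tile, and the final image is the mean of both passes. We project at the
fractional height directly rather than rounding it first — the fractional
band subsumes the rounded variant and avoids a half-slice quantization of
the surface.

Background rules: `background_lowest_plane` (mean of the deepest slice, for
whole-stack time courses) and `background_mean_minus_sd` (mean − SD of all
voxels, population SD; used before apical mean projections). Subtraction
clamps at zero, since negative intensities are non-physical.
`intensity_timecourse` normalizes each embryo to its initial time point and
linearly interpolates onto a common grid before across-embryo statistics.
`cell_geometry` reports pixel-count areas and an axis-aligned second-moment
anisotropy with the continuous-pixel (+1/12) correction, so an axis-aligned
rectangle scores exactly its side ratio; the upstream tool's exact formula
is not published, so this definition is our own and is stated with the
results it produces.

## The synthetic-data generator

`gen_pulse_trace` builds one cell as
baseline drift (cubic polynomial) + pulse train + Gaussian noise. Each pulse
constricts by amplitude $A$ along a raised-cosine half-wave, then relaxes
along a *normalized* exponential that reaches the retained level exactly at
the cycle end, so a cell with ratchet efficiency $e$ obeys exact
conservation: after $k$ complete pulses the plateau area is
$A_0 - k\,e\,A$. (A raw exponential tail would leave the conservation
identity only approximate; normalizing it makes the generator's ground truth
closed-form.) The reporter channel rises proportionally to every
instantaneous constriction and is flat during expansion, mimicking a
cortical protein recruited during contraction.

Two temporal modes exist. *Plateau mode* (a quiescent lead, complete pulses,
trailing plateau) keeps the closed-form examples exact. *Continuous mode*
(`phase_frac`) runs cycles back-to-back with a phase offset and partial
cycles at the trace ends; cohorts use it because real cells pulse
continuously and, numerically, perfectly flat synthetic plateaus are an
artefact that real traces do not have.

`gen_cohort` draws, per cell, target peak constriction and expansion rates
from class distributions (defaults: constricted 9.9 ± 1.1 / 3.2 ± 0.8,
impaired 7.5 ± 1.2 / 5.1 ± 1.4 µm²/min, matching the measured group
statistics; expanded-cell rates are unreported upstream, so plausible values
5.0 ± 1.5 / 6.0 ± 1.5 are supplied). Because pulses are aligned to the
sampling grid, the discrete peak rates the pipeline will measure are
closed-form functions of the waveform (`peak_rate_per_unit_amplitude`), and
the generator inverts them — including the constant rate contribution of the
class's linear drift — so on noiseless traces the pipeline recovers each
drawn target to ~1e-13. Targets below the waveform's slowest achievable
relaxation are clipped to the nearest achievable rate; with the default
asymmetric cycle this affects well under 1% of draws.

Fixed generator choices, and why:

* **Frame interval 3.8 s** — implied by the 10-frame ≈ 38 s smoothing
  convention of the upstream analysis.
* **Pulse period 76 s** (20 frames) — inside the 60–90 s range typical of
  these cells, and a whole number of frames so calibration is exact.
* **Asymmetric cycle, 35% constricting / 65% relaxing** (cohorts) — the
  measured control expansion rate (3.2 µm²/min) is three times slower than
  the constriction rate (9.9 µm²/min); a half-period relaxation cannot be
  slow enough to realize the slower expansion targets for every cell.
  Standalone traces default to the symmetric 50/50 split.
* **Initial area 41 ± 2 µm²** — a typical ventral-cell apical area.
* **Class traits** (ratchet efficiency and linear drift removing a fraction
  of the initial area by 7 min: constricted 0.57 / 0.46, impaired 0.10 /
  0.10, expanded 0.00 / −0.18) — chosen once by worst-case bound analysis
  over the clipped (±2.5σ) parameter draws so that every cell of a class
  lands strictly inside its category band at the 7-min evaluation and area
  stays positive throughout the default 432-s trace. The drift models the
  unresolved continuous component of constriction, which is exactly what the
  cubic detrending step exists to remove in real data.
* **Cohort noise defaults to zero** — recovery tests are about the method,
  not noise robustness; noise is a parameter (`noise_sd_um2`), and noisy
  traces are exercised separately (detrending, determinism, phantoms).
* **Seeding** — one master seed; per-cell streams derive from a stable hash
  of (seed, embryo, cell), so cohorts are reproducible cell-by-cell
  regardless of generation order.

`gen_surface_phantom` builds stacks with a bright band of known height
(flat, tilted plane, sinusoid, paraboloid). The band's axial profile is the
quartic $w(\delta) = \max(0, 1-(\delta/h)^4)$, $h = (T+1)/2$: strictly
peaked, so the brightest slice is the nearest slice to the truth, yet nearly
flat across the band, so band projections recover close to the full surface
intensity. `gen_labeled_movie` lays non-overlapping rectangular cells whose
pixel areas track prescribed trajectories to within one pixel row, the
fixture for per-cell intensity measurement.

## What the synthetic tests do and do not show

The generator emulates pulsatile kinetics, ratcheting, class mixtures,
reporter recruitment, and surface geometry with exact ground truth — it does
not emulate segmentation errors beyond missing frames, neighbour mechanical
coupling, myosin flows, or camera physics beyond Gaussian blur and noise.
Passing recovery tests therefore demonstrates that the pipeline measures
what it claims on data of known structure; it does not certify segmentation
quality on real movies.

## Numerical choices and degenerate inputs

Problem sizes in the shipped tests and acceptance script are desk-scale:
cohorts of 200–300 cells × ~114 frames, phantoms of 64×64×12 voxels, 5 seeds
per stochastic check. Other conventions: even smoothing windows are reduced
to the next odd size so windows stay centered; boundary smoothing truncates
the window symmetrically rather than padding; argmax ties in the surface
profile resolve to the apical-most slice, deterministically; the detrended
residual is rounded at 1e-9 µm² before extrema detection so float jitter on
degenerate (exactly linear) traces does not masquerade as pulsation;
background subtraction clamps at zero; traces shorter than five measured
frames refuse to detrend; cells without positive peaks are excluded from
rate statistics rather than contributing zeros, mirroring how per-cell means
are pooled upstream.

## Known limitations

The ratchet statistic depends on which signal the consecutive-peak
differences are evaluated on (raw vs residual); both are implemented and the
raw-area reading is the default, but on strongly drifting non-pulsatile
traces it reports the drift, not pulsation — inspect `n_maxima`/`n_minima`
before interpreting. Plain neighbour-scan extrema are noise-sensitive;
for noisy traces pass `smooth_window = 3` to `ratchet_amplitude`. The
blinded-scoring utility randomizes presentation order but cannot enforce
that the key file stays unopened. Anisotropy uses our axis-aligned moment
definition, which differs from principal-axis eccentricity for diagonal
cells.
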