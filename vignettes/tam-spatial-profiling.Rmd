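---
title: "Compartment-resolved TAM spatial profiling: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved TAM spatial profiling: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tamspat)
```

## The analysis this package implements

Tumor-associated macrophages (TAMs) in breast carcinoma are commonly
identified by CD163 (a scavenger receptor) or CD206 (the mannose receptor),
two markers of M2-like polarization that highlight overlapping but distinct
macrophage populations. Digital whole-slide workflows quantify these cells
per tissue compartment: regions of interest (ROIs) are placed on the
section, a tumor-nest mask partitions each ROI into carcinoma and stroma,
and marker-positive cells are counted per compartment and divided by
compartment area. Because peritumoral stroma — not distant stroma — is the
biologically relevant interface, the analyzed stroma is restricted to a
fixed-width band around the tumor nest.

`tamspat` implements this pipeline end to end:

1. **Geometry** (`build_stromal_band()`, `distance_to_tumor()`,
   `assign_compartment()`, `region_areas()`): the 50 µm peritumoral band,
   exact per-cell distances to the tumor-nest boundary, and compartment
   assignment.
2. **Case metrics** (`summarize_rois()`, `aggregate_case()`,
   `dichotomize()`, `four_group()`, `tam_til_ratio()`): the six case-level
   spatial variables (sCD163, tCD163, sCD206, tCD206 densities in
   cells/mm²; mean stromal CD163/CD206 distance in µm), their median-cutoff
   high/low calls, the joint stromal×tumoral four-group label per marker,
   and the four TAM-density-to-stromal-TIL ratio scores.
3. **Association statistics** (`pearson_chi2()`, `trend_chi2()`,
   `fisher_exact()`, `choose_test()`, rank tests): the contingency battery
   used for clinico-pathological tables.
4. **Survival** (`km_estimate()`, `logrank_test()`, `cox_fit()`,
   `backward_stepwise_wald()`): Kaplan–Meier stratification and
   multivariate Cox with backward-stepwise-Wald selection.
5. **Synthetic cohort** (`sim_config()`, `generate_cohort()`): a fully
   seeded generator for geometries, point patterns, clinical covariates and
   proportional-hazards outcomes, because the study-type data this analysis
   consumes (per-patient coordinates, densities, follow-up) are not
   publicly deposited anywhere.
6. **Image front-end** (`render_tile()`, `color_deconvolve()`,
   `detect_cells()`): an optional synthetic H-DAB detection stage with
   known ground truth.

## Geometry

**Coordinates and conventions.** All coordinates are real-valued
micrometres in the slide frame. ROIs are squares of 1.96 mm² (side
`sqrt(1.96e6) = 1400` µm) — the area is the primary quantity; the square
shape is the simplest area-exact choice. Polygon boundaries are closed
sets: a cell exactly on the tumor boundary has distance 0 and is tumoral.
This makes the compartment rule a pure function of the distance field:
tumor ⟺ d = 0, stroma ⟺ 0 < d ≤ band width (inside the ROI), excluded
otherwise, so the partition invariant (every cell in exactly one class)
holds by construction.

**The stromal band.** The analyzed stroma is
`{p ∈ ROI : 0 < d(p, tumor) ≤ w}` with `w = 50` µm by default. There is no
polygon-clipping library in this dependency stack, so rather than
approximating the Euclidean dilation with a buffer polygon the band is
represented *exactly* through the distance field: membership
(`band_contains()`) evaluates the exact point-to-boundary distance
(a compiled kernel computes min distance over boundary segments), and the
band area is obtained by grid quadrature of that exact distance over pixel
centers. With the default 1 µm grid the area of a 50 µm band around a
200 µm disk is within 0.005% of the closed-form annulus; pixel-center
counting error scales as `h^1.5 · sqrt(L)` for grid step `h` and boundary
length `L`, far below the 0.5% the validation demands. The quadrature step
is exposed (`resolution`); 2 µm is used where many ROIs are processed.

**Distances.** A stromal cell's distance is measured to the tumor polygons
of *its own ROI* (whether the study measured within-ROI or whole-slide
distances is not stated; within-ROI is the only option consistent with
ROI-wise export, and it is what `assign_compartment()` uses). Distances are
exact to floating point — the brute-force boundary-resampling oracle at
0.01 µm agrees to < 0.02 µm.

**Degenerate ROIs.** An ROI without a tumor polygon has no band: it is
flagged, excluded from stromal metrics, and the case keeps its remaining
ROIs. A tumor filling the whole ROI gives band area 0, not an error.

**Hotspots.** The study placed two of its five ROIs on visually selected
staining hotspots. `find_hotspots()` provides a deterministic surrogate — a
sliding-window count maximization on a regular grid with smallest-(x, y)
tie-breaking — clearly labelled as invented plumbing, not a reproduction of
the manual selection.

## Case-level metrics

* **Density aggregation** is the unweighted mean of per-ROI densities over
  the ROIs where the compartment exists, matching the description of
  averaging ROI densities; an area-weighted pooled alternative is available
  (`weighting = "area"`).
* **Distance aggregation** is cell-weighted pooling over all stromal cells
  of the marker (the "average distance of TAMs" reading); a per-ROI-mean
  alternative sits behind `distance = "roi"`.
* **Median dichotomization** uses the sample median (midpoint convention
  for even n) with *high ⟺ value > cutoff*: ties at the median go low.
  Densities are continuous so ties are practically absent, but the rule is
  fixed so flags are reproducible. Dichotomizing any strictly monotone
  transform of a variable yields identical flags.
* **Cutoff population.** Whether the study computed medians before or after
  dropping cases without follow-up is not stated. The default computes
  cutoffs on all assessable cases (the analogue of its 220/211 assessable
  sets); restricting the input table first gives the other convention.
* **TAM/sTIL ratios** divide density (cells/mm²) by the stromal-TIL
  percentage; sTIL = 0 gives a missing score (logged), never infinity, and
  the scores are median-dichotomized like every other variable. The ratio
  is scale-equivariant, so its high/low calls are invariant to any common
  rescaling of densities.

## Association statistics

The battery mirrors the conventions that reproduce the published tables:

* **Pearson chi-square without continuity correction** for unordered
  tables. The printed 2×2 p-values (nodal metastasis × sCD206 0.033, Ki67,
  PR, LVI, ER, TIL rows, …) are reproduced exactly at the printed precision
  by the uncorrected statistic and not by the Yates-corrected one.
* **Linear-by-linear trend** `M² = (n−1) r²` (df = 1, integer scores) for
  ordered grade against a binary group. On the printed grade×tCD163 counts
  Pearson gives p ≈ 0.013 while the trend statistic gives 0.0057 ≈ the
  printed 0.006 (and 0.028 for the distance-group grade table), so ordered
  rows route to the trend test in `choose_test()`.
* **Fisher's exact test** (two-sided probability-mass rule) for 2×2 tables
  with any expected count below 5.
* **Rank statistics**: Spearman (mid-ranks, t approximation), Mann–Whitney
  U and Wilcoxon signed-rank with tie-corrected normal approximations and
  no continuity correction. The asymptotic p deviates from the exact
  permutation law by more than 0.01 below roughly n = 25, so oracle
  comparisons are run at n ≈ 30–40 where the stated approximation is the
  appropriate tool.
* **No multiplicity adjustment** anywhere, matching the source analysis;
  every p is reported raw with its test name.
* Two published cells are *not* reproduced by any of these conventions
  (CK14 × tCD206 printed 0.019 vs recomputed 0.013; one distance table
  printed 0.045 vs 0.046). They ship flagged `validated = FALSE` in
  `reference_association_tables()` and are excluded from exact-reproduction
  checks rather than force-matched. The paired stromal-high vs tumoral-high
  comparison is implemented as an uncorrected McNemar test
  (`paired_flag_shift()`) and labelled unvalidated: the underlying
  convention is not recoverable from the published text, and two median
  splits on a *common* assessable set are exactly balanced by construction
  (the comparison is only informative when the two markers' assessable
  subsets differ).

## Survival analysis

Kaplan–Meier estimation, k-group log-rank tests and Cox
proportional-hazards fits are delegated to the `survival` package (Breslow
tie handling by default, the convention of the software family the source
analysis used; Efron behind `ties = "efron"`). The backward-stepwise-Wald
procedure is implemented here: starting from the full model, the term with
the largest Wald p (multi-df block Wald for factor terms) is removed while
that p exceeds `p_remove`, with the full elimination trace recorded. The
default `p_remove = 0.10` follows from the published final model retaining
a covariate at p = 0.058 — under a 0.05 removal rule that row could not
appear in a final step. There is no re-entry step. Complete separation is
reported as a flagged non-converged fit, never silently.

## The synthetic cohort generator

No slide images, coordinates or follow-up data are deposited for the study
this pipeline re-implements, so the generator is a first-class module that
emulates the inputs at their reported operating point. Its defaults *are*
the study conditions, fixed once:

| Parameter | Default | Source of the value |
|---|---|---|
| cases / ROIs per case | 225 / 5 | cohort size and ROI design |
| ROI area / band width | 1.96 mm² / 50 µm | stated constants |
| intensity medians (s163/t163/s206/t206) | 354.1 / 210.8 / 303.2 / 111.6 cells/mm² | reported cohort medians |
| intensity sdlog | 0.915 / 1.07 / 0.775 / 0.96 | reported mean/median ratios of a lognormal |
| latent s–t correlation | 0.75 (CD163), 0.55 (CD206) | reported rank correlations 0.718 / 0.534 |
| cross-marker correlation | 0.51 | reported rank correlations ≈ 0.49 |
| DFS event fraction | 0.141 | reported 23/163 events |
| censoring window | U(95, 143) months | 48-month accrual, max follow-up 143, median ≈ 110 |
| default log-HRs | ln 3.477 (sCD163/sTIL high), ln 2.111 (pN) | reported multivariate hazard ratios |
| grade marginals | 16/124/85 of 225 | reported cohort composition |

**Intensity model.** Case-level true intensities are lognormal with a
shared-factor Gaussian copula: `Z_v = √b·F + √c_m·G_m + √(1−b−c_m)·ε`,
giving within-marker stromal–tumoral correlation `b + c_m` and cross-marker
correlation `b`. Stromal TILs load on the same case factor F, which is what
makes TAM density and sTIL positively associated, as reported. Clinical
covariates modify intensities multiplicatively on the log scale
(`covariate_effects`; by default grade raises tCD163/sCD163 and nodal
metastasis raises sCD206, reproducing the direction of the published
associations); effects are centered at the cohort mean so the configured
medians are preserved. Within-case between-ROI spread is an additional
mean-one lognormal multiplier (`roi_sdlog = 0.25`) — the study reports no
between-ROI variance, so this is an explicitly free parameter.

**Point patterns.** Per ROI and compartment, counts are Poisson with mean
intensity × area and locations uniform in the compartment (rejection
sampling against the exact band predicate). Homogeneity within a
compartment is a deliberate simplification: real TAMs cluster and drift
toward the tumor interface (the study's mean stromal distances of ≈ 23–24
µm are below the ≈ 26 µm a uniform 50 µm band implies). Density tests
passing on this generator therefore validate the *measurement machinery*,
not any spatial-interaction biology; distance metrics on synthetic data sit
slightly above the reported ones and are not used as calibration targets.

**Geometries.** 1–5 disjoint perturbed-ellipse nests (star-shaped, hence
simple polygons) scaled to an exact target area fraction drawn from
0.2–0.6, placed with margins inside the square ROI; infeasible packings
retry with a lower fraction and fewer nests before erroring.

**Outcomes.** DFS times are exponential with log-hazard linear in
configured covariates; overall survival adds an exponential
relapse-to-death delay (mean 24 months), so DFS ≤ OS always. Censoring is
uniform administrative, and the baseline hazard is calibrated by a
deterministic root-solve so the *expected* event fraction equals the
target. Crucially, the hazard acts on the *realized* median-split flags
computed with the same `tam_metrics` code the downstream analysis runs —
the generating covariate and the analyzed covariate coincide, so the
configured HR is recovered without measurement-error attenuation (at
n = 2000 the Cox estimate covers ln 3.477 within its 95% CI in ≥ 90% of
replicates). When correlated ratio scores are all offered to the stepwise
procedure, the selected model splits the signal between them and the
per-score HR attenuates — visible in `analysis/04_survival.R`, and a
faithful property of stepwise selection on collinear scores, not a bug.

**Fidelity levels and determinism.** `level = "cells"` generates full
geometry and coordinates; `level = "case"` draws per-ROI Poisson counts on
simulated areas directly (its mean stromal distances are drawn from a
plausible correlated normal, a synthetic-only shortcut). Problem sizes in
the shipped analyses: 40 cases × 5 ROIs at cell level for the geometry
stages, 1000–2000 cases at case level for calibration and survival runs —
sizes chosen so each stage completes in seconds-to-minutes while keeping
Monte-Carlo error well inside the tolerances tested. All randomness flows
from one master seed through per-case substreams (a stable string hash of
case id), so cohorts are byte-identical across runs and stable under
parallel generation.

## Image front-end

The optional detection stage mirrors a QuPath-style workflow on synthetic
ground truth. Rendering composes per-pixel transmitted intensity by
Beer–Lambert, `I_c = bg_c · 10^(−Σ_s A_s V_{s,c})`, with Gaussian-disc
stain deposits per cell (DAB only for marker-positive cells); the default
stain vectors are the standard published H-DAB pair — the study's own
detection parameters live in an appendix that is not public, so these
defaults make no equivalence claim. Deconvolution computes per-channel
optical density `−log10(max(I,1)/bg)` and inverts the stain matrix by least
squares (negative amounts clipped); in the noise-free float-image case this
is exact to ≈ 1e−13. Detection smooths the amount images (Gaussian, 1 µm),
thresholds (hematoxylin OR DAB), splits touching cells by watershed on the
distance map, filters components by area (8–150 µm²), and calls a cell
DAB-positive when its mean DAB OD reaches 0.3 — all tunables with units in
`detection_params()`, all deterministic. On rendered tiles with 50 known
cells the detector reaches recall and positivity precision ≥ 0.95 (1.00 in
the shipped runs, with and without mild sensor noise).

## Numerical choices and edge rules, collected

* band quadrature grid 1 µm (configurable); band membership uses exact
  distances, so the only discretization anywhere is the area integral;
* boundary cells are tumoral (distance 0); ties at median cutoffs are low;
* hotspot ties break to smallest x then y;
* density with zero/missing area is missing, never zero; sTIL = 0 gives a
  missing ratio; all-equal values dichotomize to all-low with a warning;
* Fisher on a zero margin returns p = 1; Pearson on a zero margin is an
  error directing to collapse or Fisher;
* Cox: gradient-based convergence is survival's default; monotone
  likelihood is flagged `converged = FALSE`; the stepwise never removes the
  last covariate.

## Known limitations

* Uniform-within-compartment point patterns: no clustering, no
  distance-to-interface gradients; synthetic distance metrics are
  structurally flatter than real ones.
* The clinical generator reproduces marginals and first-order association
  directions, not the real joint covariate distribution.
* The four-group and ratio analyses inherit all the usual caveats of
  median dichotomization; the package reproduces the design rather than
  endorsing it.
* The McNemar paired-shift test and the two unreproducible published cells
  are flagged, not resolved.
* No whole-slide-image reading, no learned tumor segmentation (masks are
  inputs), no 3D, no cell–cell interaction statistics.
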