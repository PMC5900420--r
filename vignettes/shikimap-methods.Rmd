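---
title: "Models and methods behind shikimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shikimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shikimap)
```

shikimap estimates shikimic acid accumulation — the biochemical marker
of glyphosate damage — from canopy Vis-NIR reflectance and chlorophyll
fluorescence (ChlF) parameters, and discriminates glyphosate-damaged
wild-type (WT) maize from a tolerant transgenic (TG) line. This
vignette is the package's own account of the models, the synthetic
study it is validated on, the tunable parameters, and the numerical
conventions. Nothing here states an empirical result that the test
suite does not itself compute.

## The regression model

Both data sources feed the same latent-variable regression. For a
centred sample matrix $X$ ($n \times p$) and response $y$ (shikimate,
fresh-weight-style units), NIPALS PLS extracts components
$t_a = X_{a-1} w_a$ with weights $w_a \propto X_{a-1}^\top y_{a-1}$,
deflating $X$ and $y$ after each component. The fitted model is
collapsed to original-scale coefficients, $\hat y = X b + b_0$, and the
test suite asserts that this affine form agrees with the score
recursion to $10^{-10}$ and that the full-rank model equals ordinary
least squares to $10^{-8}$. The component count is chosen by
leave-one-out cross-validation, ties broken toward fewer components
(parsimony). Spectral matrices are mean-centred only — reflectance
shares units across bands, and autoscaling would inflate noise bands;
the ChlF panel is autoscaled because its parameters carry heterogeneous
units. Both behaviours are arguments (`scale`) rather than policy.

Discrimination uses the same machinery on the dummy response
1 = healthy (all TG plants plus WT water controls), 2 = damaged (WT
glyphosate). The decision rule is interval-based: predictions in
$(0.5, 1.5]$ are healthy, $(1.5, 2.5]$ damaged, anything else
unclassified and counted as incorrect. The source procedure says
"between" without fixing the boundaries; we make the intervals
upper-inclusive so the rule is deterministic, and document rather than
debate the measure-zero choice.

## Sample partitioning

SPXY partitioning ranks samples by Kennard–Stone max–min selection on
the joint distance
$d(i,j) = d_X(i,j)/\max d_X + d_y(i,j)/\max d_y$ (both Euclidean). The
first two calibration members are the maximally distant pair; each
subsequent pick maximizes the minimal distance to the chosen set; ties
break toward the lower row index, making the split deterministic and
permutation-equivariant (a property test asserts this). The regression
stage splits 2:1 (216 retained samples → 144/72), the per-day
discriminant stage 3:1 (60 → 45/15).

## Wavelength selection

The successive projections algorithm (SPA) grows, from every starting
band, a chain of minimally collinear bands: at each step all unchosen
columns are projected onto the orthogonal complement of the span of the
chain and the column of maximal residual norm is appended (ties toward
the lower index; a rank-exhausted chain simply stops). Columns are
scaled to unit norm for the projection phase only. Every chain prefix
in `k_min:k_max` is scored by the validation RMSE of an MLR fit, and
the global minimizer wins. SPA is fully deterministic.

Backward refinement then removes, one at a time, the band whose removal
least increases the leave-one-out RMSECV of a PLSR fit, stopping at
`max_drop` removals or when cross-validated R² would fall below a
floor. Inside the pipeline the floor is *relative* — the starting
selection's cross-validated R² minus `refine_q2_slack` (default 0.03) —
because an absolute floor does not transfer across data scales: on an
easy dataset a fixed 0.75 floor lets refinement prune into clear
underfitting (a single visible band can carry calibration R² ≈ 0.87
here while losing ~0.15 of held-out R²), and on a hard dataset it
blocks all pruning. The relative rule matches the procedure's intent:
remove bands while performance stays essentially unchanged. An absolute
floor remains available via `refine_r2_floor`.

## ChlF parameter screening: random frog

Random frog maintains a feature subset $V$; each iteration proposes a
new size from $\mathrm{round}\,\mathcal N(|V|, \max(1, 0.3|V|))$,
builds the candidate by adding the top-ranked entrants from a random
pool of non-members (pool of twice the deficit) or removing the
bottom-ranked members, and accepts with probability 1 when the
candidate's cross-validated RMSE is no worse, else with probability
$0.1 \cdot \mathrm{RMSECV}(V)/\mathrm{RMSECV}(V^*)$. A feature's
selection probability is its fraction of iterations in membership;
features above the 0.4 threshold are retained.

Three numerical choices matter and were made for identifiable reasons:

* **Proposal sd floored at 1.** A purely relative sd degenerates as
  $|V| \to 1$ (round–Normal(1, 0.3) almost never moves), freezing the
  chain; the floor keeps the proposal proper at all sizes.
* **Monte-Carlo cross-validation.** Folds are redrawn every iteration
  and both subsets scored on the same draw. With one fixed partition
  the chain is a deterministic optimizer and, on signal-free data,
  concentrates all probability on whatever subset happens to minimize
  that partition's RMSECV.
* **Subsampled coefficient ranking.** Entrant/leaver ranking uses
  absolute PLS coefficients (autoscaled space) fitted on a random 70%
  subsample, so a feature's rank must be re-earned under resampling;
  only stably ranked features — true signal — persist.

Even so, on *pure-noise* data the sampler's shrink move (drop the
bottom-ranked) structurally protects whichever feature currently ranks
highest, so some feature can retain a high selection probability on
noise; what the null guarantees, and what the tests assert, is that the
identity of that feature is seed-specific — no reproducible spurious
discovery — and that overall probability mass stays near the
`init_size/p` baseline. The inner model is a 3-component PLSR with
5-fold CV (leave-one-out at $10^4$ iterations would dominate runtime);
the pipeline runs 1500 iterations by default and the function's own
default is 10000.

## The synthetic study

The generator is the package's study definition, not a convenience
fixture. Its defaults encode the screening design: genotypes WT/TG ×
treatments water/glyphosate × days {2, 4, 6, 8}, 10 water and 20
glyphosate pots per genotype-day — 120 plants per genotype, 240 total,
of which the pipeline retains 216 (the reported dataset size; the
generator exposes the count rather than guessing why 24 were dropped).

Ground-truth shikimate: WT-glyphosate plants follow
$20 + 15 \cdot \mathrm{day} + \mathcal N(0, 10)$ (day 8 ≈ 140);
TG plants and water controls sit at $\mathcal N(25, 6)$. The day-8
WT/TG ratio therefore comfortably exceeds the 1.4-fold separation the
screening relies on, and concentrations span the 20–150 range that
makes RMSEs of ~8–13 the natural error magnitude. The day effect is
linear with Gaussian noise — the observed time course is monotone and
no finer kinetics are published.

Spectra follow a Beer–Lambert-style construction on a 412-band axis
spanning 427.75–948.49 nm:
$r(\lambda) = s \cdot \mathrm{baseline}(\lambda)\,
e^{-(c_p g_{\mathrm{chl}}(\lambda) + c_w g_{\mathrm{w}}(\lambda))}
+ a + \varepsilon$, clipped to $[0, 1.2]$, with Gaussian absorber bands
for chlorophyll a (675 nm), chlorophyll b (455 nm) and water (950 nm,
the second O–H stretch overtone region), and a baseline with a green
bump and a red edge into the NIR plateau. Three latent channels carry
the stress signal, all declining in shikimate:
pigment $c_p = 2 - 0.012\,\mathrm{shik}$,
water $c_w = 1.5 - 0.006\,\mathrm{shik}$, and a structural scatter
multiplier $s = 1.05 - 0.0015\,\mathrm{shik}$, each with link noise
(sd 0.13 / 0.09 / 0.02) plus per-band noise (sd 0.004). The link-noise
magnitudes are the study's difficulty dial: they set the best
achievable RMSE near 7–10 units, so pipeline R² values land in the
0.8–0.93 range rather than at an uninformative 0.99. A deliberate
modelling point: the NIR reflectance *decrease* under stress cannot
come from the water absorber (losing water *raises* reflectance at
950 nm); it is carried by the structural multiplier, whose decline
dominates the water-absorber effect across 900–948 nm. Both directions
— drier shoulder up, stressed NIR down — hold simultaneously, as the
monotonicity tests verify on a 10-point shikimate grid. This is a
desk-scale latent-linear stand-in, not a radiative-transfer model:
PROSPECT-style leaf optics, view geometry, and specular effects are out
of scope, which is precisely why PLSR's linearity assumption holds
almost exactly here.

The ChlF table has 60 FluorCam-style parameters of which 11 are
informative (Fv/Fm as `QY_max`, NPQ, qL, qP, QY and related
steady-state/light-phase parameters), affine in shikimate with
physiologically signed slopes (quantum yields fall, quenching rises).
Informative parameters share a plant-level physiological noise term
($u \sim \mathcal N(0, 9)$ shikimate-equivalents) on top of independent
parameter noise: all fluorescence parameters read the same underlying
physiological state, so their errors must not average away across the
panel — without the shared term an 11-parameter model would reach
R²p ≈ 0.99, an unrealistic ceiling for fluorescence-based calibration.
The remaining 49 parameters are pure noise around plausible baselines.

Cubes for the imaging stage place per-pixel concentrations
(plant value + spatial noise) through the same deterministic links on a
rosette-shaped canopy mask, over a flat soil background whose NIR/red
ratio (~1.1) stays well below the segmentation threshold (2.0).

What the generator does *not* emulate — and hence what green tests do
not certify about real data: nonlinear leaf optics and canopy geometry,
instrument stray light and wavelength miscalibration, the actual
(unpublished) ChlF parameter intercorrelation structure, day-specific
physiology beyond a linear trend, and any genotype effect other than
through shikimate. Per-day discrimination accuracies reach 100% from
day 4 because the synthetic late-day signal is far cleaner than field
data; the per-day *structure* of the report (the 4 × 2 accuracy table)
is the tested artefact, not those numbers.

## Preprocessing conventions

* **Wavelet step.** Daubechies-6, decomposition level 3, symmetric
  (edge-repeating) extension — coefficients depend on the extension
  convention, so it is fixed. Whether the original procedure's wavelet
  "background removal" denoised or detrended is not determinable from
  its description; both modes are provided (`denoise` soft-thresholds
  details at the universal threshold $\hat\sigma\sqrt{2\ln n}$ with
  $\hat\sigma$ the MAD of level-1 details / 0.6745; `debaseline`
  subtracts the approximation reconstruction), the pipeline defaults to
  `denoise`, and the choice is recorded in the run report
  configuration. The transform is implemented in the package and its
  perfect-reconstruction and filter-bank identities are unit-tested.
* **Band lookup** by nearest wavelength within 1.5 nm (about half the
  2.8 nm instrument resolution); farther requests error rather than
  silently snapping.
* **Segmentation** is NIR/red ratio thresholding (800 nm / 670 nm,
  threshold 2.0) plus largest connected component — the source names no
  method; a band-ratio rule is the standard vegetation contrast and is
  exactly testable against the generator's truth mask.
* **SNV** uses the sample (n−1) standard deviation; **MSC** regresses
  on a reference spectrum (the calibration mean in the pipeline);
  **Savitzky–Golay** delegates to `signal::sgolayfilt`.
* **Outlier screening** is a single pass: fit PLSR on all samples, flag
  |residual| > 3 sd. No criterion is published; one pass at 3 sd flags
  essentially nothing on clean data and reliably catches gross
  reference errors (the injection test shifts one sample by 10 sd).

## Pipeline problem sizes and seeds

`run_pipeline()` executes synth → preprocess → (SPA + refine | random
frog + threshold) → SPXY → PLSR / PLS-DA → metrics → maps, and writes
`report.json`/`report.md` plus the two map PNGs. Every stochastic stage
draws its seed from the master seed through a fixed counter scheme
recorded in the report, so the whole report is a pure function of the
configuration; the same seed reproduces it byte for byte. Desk-scale
defaults chosen for the package's own study: SPA chains up to 20
members inside the pipeline (30 as the function default), random frog
at 1500 iterations inside the pipeline (10000 as the function default),
LV caps 15 (regression) and 8 (discriminant). SPA's validation set is
an SPXY 2:1 sub-split of the calibration set, so the prediction set
never leaks into selection.

Under the null configuration (`null_link_params()`, all effect slopes
zero) the spectral pipeline's held-out R² collapses to ≤ 0.2 (typically
negative). One caveat for the per-day PLS-DA table: classes are 2:1 by
design (40 healthy vs 20 damaged per day), so under the null the
prediction accuracy concentrates near the majority-class fraction, not
0.5; chance-level behaviour is therefore checked on a class-balanced
null discrimination, where accuracy does sit at 0.5 within Monte-Carlo
error.

## Known limitations

* The printed reference equation ships as a fixture
  (`reference_equation_model()`); one of its bands was printed as
  "5343 nm" and is recorded as 534 nm (it appears in the published
  sensitive-wavelength list), flagged in the fixture metadata.
* SPA on the synthetic spectra selects 2–5 bands, not 11–13: the
  generator has three latent channels, so few bands suffice. Selection
  *power* is therefore validated on a sparse-band construction with
  known truth bands, where the collinear-background/independent-signal
  structure SPA exploits is explicit.
* `wavelet_detrend()` supports db6 only — the one wavelet the procedure
  uses; the transform machinery is generic but no other filter is
  exposed.
* ENVI I/O covers the subset the package writes (BIL/BSQ/BIP, float32/
  float64, little-endian, wavelength list); it is not a general ENVI
  reader.
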