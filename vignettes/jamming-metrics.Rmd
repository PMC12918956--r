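---
title: "Quantifying collective dynamics and jamming in epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective dynamics and jamming in epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epijam)
```

## The scientific problem

Crowding epithelial monolayers undergo a jamming transition: a fluid-like,
motile collective gradually arrests into a solid-like sheet. The reverse
fluidization (unjamming) can be driven pharmacologically without loss of
epithelial identity. Characterizing where a tissue sits on this axis requires
a set of complementary observables:

* **V~rms~** — the root-mean-square cell velocity,
  $V_\mathrm{rms} = \sqrt{\langle |v|^2 \rangle}$, with
  $\langle\cdot\rangle$ the spatial average over the field of view. A scalar
  motility measure whose decay-and-plateau time course tracks the jamming
  process.
* **ξ~v~** — the velocity correlation length, the distance over which cell
  velocities stay correlated. Long ξ~v~ means coordinated, pack-like motion.
* **T1 rate (R~T1~)** — the frequency of neighbor exchanges (collapse of a
  shared junction followed by formation of a new junction between two
  previously non-adjacent cells), in events per cell per hour. T1 exchanges
  are the elementary step of tissue flow.
* **Shape metrics** — the dimensionless shape index $q = P/\sqrt{A}$ and the
  aspect ratio; both shift upward as tissues fluidize.
* **Strain rates** — local isotropic (dilation) and deviatoric (shear)
  rates, elevated in fluid tissue.
* **Marker transitions** — junction maturation and nuclear-exit of
  mechanosensitive factors follow sigmoidal time courses whose half-times
  (reported as LogEC50, in hours) order the events of the transition.

The discriminating physics lives in the relation between R~T1~ and
V~rms~. In a **rigid-pack** picture, cells translate in coherent clusters of
size $L_c$ and exchanges happen only at cluster interfaces. The interface
fraction scales as $f_\mathrm{int} \sim 1/L_c \sim 1/V_\mathrm{rms}$ while
the relative speed of neighboring packs scales as
$V_\mathrm{rel} \sim V_\mathrm{rms}$, so
$R_{T1} \sim f_\mathrm{int} V_\mathrm{rel}$ is *independent* of
V~rms~. A genuinely fluid tissue instead shows R~T1~ growing approximately
linearly with V~rms~. `rigid_pack_prediction()` operationalizes the null
(with proportionality constants fixed by one calibration pair — only the
*shape* of the relation is testable), and `rate_speed_test()` provides the
statistical contrast.

## Why synthetic ground truth

The imaging data behind these quantities are not deposited, and headline
effect sizes from any one experiment are not reproducible at desk scale.
Every estimator in this package is therefore validated against seeded
generators whose ground truth is known by construction:

* `generate_rigid_pack()` — cells partitioned into square tiles of diameter
  ≈ `L_c`, each tile sharing one constant velocity of magnitude `v0`
  (random direction), T1 events scripted only on cross-pack junctions at
  `interface_t1_rate` events per interface cell per hour.
* `generate_fluid()` — persistent random walkers at speed `v0`
  (Ornstein–Uhlenbeck heading, persistence time 4 h by default), T1 events
  scripted uniformly over internal junctions at `fluid_t1_gain * v0` events
  per cell per hour, so the ground-truth R~T1~–V~rms~ relation is exactly
  linear with slope `fluid_t1_gain`.
* `generate_crowding_timecourse()` — fluid-style motion whose speed follows
  a stepwise schedule, for testing V~rms~ windowing and onset detection.
* `render_phantom_pair()` — textured image pairs advected by a known
  displacement field, the fixture for PIV.
* `render_fluorescence_phantom()` — cell layouts with junction, cytoplasm,
  nucleus and puncta compartments at known intensities.
* `generate_sigmoid_series()` / `synth_correlated_field()` — noisy
  four-parameter-logistic series and Gaussian random velocity fields with an
  imposed exponential correlation length.

One design decision matters enough to state prominently: **the neighbor
graph is the topology authority, not the instantaneous Voronoi diagram**.
Both monolayer generators tessellate the *initial* centroids (true Voronoi,
periodic by default so there are no window-edge artifacts) and thereafter
evolve the adjacency only through the scripted T1 swaps. Re-tessellating
moving centroids every frame would create unscripted "natural" exchanges on
top of the scripted ones and destroy the exactness of the ground-truth event
list — and these generators are kinematic stand-ins with controlled
statistics, not mechanical models. The cost is that late-frame positions and
the held adjacency drift apart; for the frame counts used here (tens of
frames) this is irrelevant to every statistic the package computes. Scripted
swaps are instantaneous at a frame boundary; a lost pair cannot be re-gained
for `k = 2` frames, quartets within one transition are disjoint, and events
that cannot be placed in a crowded frame are deferred to the next one
(totals stay Poisson). A persistently impossible rate raises an error rather
than silently under-delivering.

What the generators do **not** emulate: junction mechanics (no vertex-model
energy), density-dependent velocity feedback, segmentation errors or
tracking failures, uneven illumination, phase-contrast optics. Passing tests
demonstrate estimator correctness on clean, statistically controlled input —
not robustness to every artifact of real microscopy.

## T1 detection

`detect_t1()` consumes a per-frame sequence of neighbor graphs (from the
generators, or from `build_neighbor_graph()` applied to label masks or
tessellations). For the transition between frames $f-1$ and $f$, a lost edge
A–B is paired with a gained edge C–D when C and D are neighbors of both A
and B on *both* sides of the transition — the quartet stays intact while its
diagonal flips. Requiring the condition on both sides makes detection
exactly invariant under time reversal (losing and gaining pairs swap), which
is a property test in the suite. The lost adjacency must have been stable
for `k` frames and the gained adjacency must persist for `k` frames;
`k = 2` suppresses single-frame segmentation flicker and matches the
generator's scripting discipline. Rosettes (several simultaneous candidate
pairings) are resolved greedily by gained shared-edge length, ties broken by
lowest cell-id pair, making the output invariant under relabeling.

Adjacency itself uses a degeneracy guard: cells are neighbors only if their
shared boundary is at least `eps_edge` = 5% of the mean cell diameter, so
four-fold vertices (zero-length contacts) never count. `t1_rate()` divides
event counts per half-open time bin by the mean *interior* cell count and
the bin width; boundary-flagged cells are excluded from the denominator by
default (including them changes only the denominator, never the event list).
Note the first and last bins of a movie are censored: events completing in
the first or last `k-1` frames cannot satisfy the persistence windows.
Sweep analyses in the tests therefore use interior bins.

The detector is verified two ways: exact event-list equality with a
brute-force adjacency-matrix oracle on random sequences (the oracle shares
no code with the implementation), and perfect precision/recall against the
generators' ground truth.

## PIV

`piv()` is single-pass FFT cross-correlation: each interrogation window
(32 px, 50% overlap by default) is mean-subtracted, zero-padded to twice its
size, and correlated; the correlation is normalized by the number of
overlapping pixels at each lag. The zero-padding removes circular-wrap
artifacts that, on smooth textures, displace the integer peak by whole
pixels; the per-lag normalization removes the triangular bias toward zero
lag. Displacements are only searched within ±w/4 (the generator refuses
larger displacements). Subpixel refinement is a 3-point Gaussian fit per
axis (exact when the texture autocorrelation is Gaussian, as for the
phantom's blurred-noise texture) with a parabolic fallback. A window is
valid when the ratio of the first correlation peak to the highest peak
outside a radius-3 main lobe is at least `peak_ratio_min = 1.5`; on
uncorrelated noise frames the ratio distribution has a long tail whose 90th
percentile sits near 1.37 regardless of the exclusion radius, so 1.5 flags
~98% of noise windows invalid while true-displacement windows (ratios
≥ 2.3) all pass. Against phantom pairs with a known (3.0, −2.0) px shift,
all windows recover the shift within 0.2 px.

Conventions: pixel arrays are y-down (image rows); velocity fields are
converted to physical y-up micrometre coordinates at the boundary, so a
displacement down the image is a negative `vy`. The raw pixel-space
displacement matrices ride along as attributes for diagnostics.

## Velocity correlation and ξ~v~

`velocity_correlation()` computes
$C(r) = \langle \delta v(x)\cdot\delta v(x+r)\rangle / \langle|\delta v|^2\rangle$
with $\delta v$ the mean-subtracted velocity, accumulating all node pairs by
FFT (masked, so invalid nodes contribute nothing) and binning by separation.
The zero-separation pairs form their own first bin, so $C$ at the smallest
bin is exactly 1. The estimator is bit-equivalent (to ~1e−15) to a
brute-force all-pairs sum, which the suite asserts on small grids. ξ~v~ is
the first crossing of $C(r) = 1/e$, linearly interpolated between bin
centres — a parameter-free definition standard in the collective-migration
literature (there is no single canonical formula for ξ~v~, so a
parameter-free convention is preferred). Crossings inside
1.5 grid spacings are flagged `below_resolution`.

Mean subtraction biases $C(r)$ downward by roughly the variance share of
the spatial mean, $O(\xi^2/L^2)$; recovery of an imposed 40 µm correlation
length is therefore tested on a 64 × 64 grid at 10 µm spacing (640 µm field,
comparable to a stitched time-lapse field of view), where the bias is a few
percent — well inside the 15% recovery criterion. On a 320 µm field the same
estimator reads ~20% low, which is worth knowing when comparing absolute
ξ~v~ values across field sizes; comparisons *within* a fixed geometry are
unaffected.

## V~rms~ and strain rates

`vrms()` implements the bare spatial-average formula. Whether a global
drift should be removed first is a reporting convention that varies between
studies, so both
variants are always co-reported (`vrms_raw`, `vrms_drift_corrected`) and
`subtract_mean` only chooses the headline value. `vrms_timecourse()` pools
forward-difference velocities over half-open frame windows.

`strain_rate()` fits the local velocity gradient by least squares over each
node's 3 × 3 neighbourhood (≥ 6 valid nodes, else the node is flagged
invalid), symmetrizes, and reports the dilation rate
$\tfrac12\,\mathrm{tr}\,E$ and the deviatoric magnitude. The default
deviatoric convention is the Frobenius norm of the traceless tensor (simple
shear $v = (\gamma y, 0)$ gives $\gamma/\sqrt2$); the maximum-shear
convention ($\gamma/2$) is available behind a flag. On affine fields the
decomposition is exact to numerical precision, and rigid rotation maps to
exactly zero.

## Shape metrics

The shape index is sometimes loosely written as "perimeter/area", which is
not dimensionless; this package computes the standard jamming-literature
index $q = P/\sqrt A$ (hexagon: 3.7224; circle bound $2\sqrt\pi$) and
offers the literal $P/A$ behind `convention = "p_over_a"`. Aspect ratio is
the axis ratio of the region's second-moment ellipse. Polygon inputs use
exact Green's-theorem moments. Label-mask inputs take area and moments from
pixel counts and the perimeter from the Moore boundary contour smoothed by
a circular Gaussian with a fixed 1.5 px arc scale: the staircase artifact of
digital contours lives at a fixed pixel wavelength, so fixed-pixel smoothing
removes it at every resolution and the estimate converges to the true
perimeter as resolution grows (from below, error ~ px/size; objects under
~10 px radius are underestimated by a few percent — the suite tracks this
convergence on rasterized disks).

## Transition fitting and onset detection

`fit_sigmoid()` fits the four-parameter logistic in its Hill-ratio form
$y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1+(\mathrm{EC50}/t)^{h})$
by multi-start Levenberg–Marquardt, optimizing EC50 on the log scale. This
makes the fit *exactly* equivariant under rescaling of the time axis and
affine maps of the values, both asserted in the suite. The half-time is
reported in hours under the name `logec50_h`, following the convention in
which marker transitions are summarized by their "LogEC50" even on a time
axis; with the reference parameters (bottom 1, top 3, EC50 90 h, hill 8 on
15 points to 150 h) the noiseless fit recovers all parameters to 1e−6, and
at 5% noise the median EC50 error is ~1 h.

`detect_onset()` estimates when motility starts to decline: a continuous
two-segment piecewise-linear fit with the breakpoint found by exhaustive
grid search over interior observed times, a residual-bootstrap CI, and a
partial F-test against the single-line fit so that a flat series is reported
as `no_change_point` rather than an arbitrary breakpoint. The model is
two-segment by design; feeding it a decline that itself plateaus (three
segments) will split the difference between the two elbows, so V~rms~
series should be truncated to the onset neighbourhood when the late plateau
is long. The estimator is exactly invariant under adding a constant.

## The rate–speed contrast

`rate_speed_test()` regresses R~T1~ on V~rms~ over time-aligned pairs and
reports a pairs-bootstrap percentile CI for the slope plus a studentized
(percentile-t) two-sided p-value with heteroskedasticity-robust standard
errors. Rate bins are Poisson-ish counts, so their variance grows with the
mean; plain percentile p-values run ~7% type-I error at α = 0.05 with a few
dozen pairs, while the studentized version sits at ~5% (the suite checks
3–7% over 500 null simulations). On rigid-pack sweeps
(v0 ∈ {5, 10, 20} µm/h, fixed pack size and interface rate) the slope CI
contains 0 in ≥ 90% of runs; on fluid sweeps with gain 0.003 the CI
contains 0.003 and rejects zero in ≥ 90% — together these reproduce, on
ground-truth data, the qualitative contrast between the rigid-pack null and
fluid-like unjamming.

`t1_speed_comparison()` addresses the single-cell version of the question:
are rearranging cells simply the fast ones? It compares central-difference
speeds of each event's quartet against topologically adjacent
non-participating cells at the same frames (Wilcoxon rank-sum). On the fluid
generator, where all cells share one speed statistically, medians agree
within 10% and the test is non-significant; with quartets scripted at twice
ambient speed (`t1_speed_factor = 2`) it detects the difference at
α = 0.01.

## Fluorescence metrics

`compartment_masks()` splits each cell of a label mask into a junction band
(boundary dilated 3 px each side by default — comparable to junctional
signal width at typical magnifications), a nucleus (supplied mask or
centroid disk) and the remaining cytoplasm; the three masks partition the
cell, junction taking precedence. `junction_contrast()` and
`cyto_nuclear_ratio()` are background-corrected mean-intensity ratios,
per-cell-then-averaged by default (pooled pixels behind a flag); the
cytoplasmic-to-nuclear orientation (increasing ratio = nuclear exclusion)
is the default, with the more common inverse behind a flag. Background is the median of a supplied
background region, else the 1st percentile of the image; the method used is
recorded in the output. Corrected means are floored at a small positive
epsilon with a per-cell flag. On noisy phantoms (σ = 5% of cytoplasm level,
background region supplied) pooled ratios stay within 3% of ground truth.

`puncta_density()` band-passes with a difference of Gaussians matched to
the spot scale, keeps local maxima above median + 5 MAD of the band-passed
image (robust to cell-to-cell brightness variation), merges maxima closer
than one spot scale, and reports count and density over the analyzed
region. It is intended for endosome/vesicle-style images — puncta over a
smooth cytoplasmic background. On junction-dominated images the MAD is
inflated by junctional texture; restrict the analysis region or quantify
junction channels with the contrast metrics instead. Detection holds ≥ 90%
recall and precision down to a peak SNR of about 4.

`normalize_to_control()` reports the ratio of group means with a
studentized bootstrap-t CI (delta-method standard error). In coverage
simulations at the sizes used in practice (n = 30 cells per group, 20% CV)
it is the only interval variant that holds the nominal 95% — percentile,
basic and BCa all undercover by one to two points.

## Reproducibility, problem sizes, and IO

Every stochastic function takes an explicit integer seed and restores the
session RNG state on exit; identical configuration plus seed gives
bit-identical output, including end-to-end through `run_pipeline()`, which
writes stage outputs (CSV/JSON) and a manifest with configuration hash and
output checksums. Units are micrometres and hours throughout; all CSVs are
physical y-up coordinates, with pixel-space conversion confined to the
image readers and writers.

The validation suite runs monolayers of 36–100 cells for 16–120 frames,
correlation grids up to 64 × 64, and 50–500 Monte-Carlo replicates per
property — sizes chosen so the full suite completes in minutes on one core
while keeping the binomial noise of each pass-rate well inside its margin.
The same properties are recomputed from scratch, under a caller-supplied
seed, by `scripts/acceptance.R`.

## Known limitations

* Graph-driven topology means generator positions and adjacency decouple
  over long runs; the generators are validation substrates, not tissue
  simulators.
* `detect_t1()` assumes consistent cell ids across frames (tracking is an
  input contract; frames failing 90% id continuity are warned about and
  dropped from rate denominators). No cell linking is provided.
* Single-pass PIV only: no multi-pass or window deformation, displacements
  capped at a quarter window.
* ξ~v~ from the 1/e crossing inherits the finite-field bias of mean
  subtraction (see above).
* Mask-route perimeters underestimate objects smaller than ~10 px radius.
* The whole denominator question for "per cell" rates (all segmented cells
  vs interior cells) is exposed as a flag, defaulting to interior cells.
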