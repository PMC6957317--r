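---
title: "Simulating and analysing nuclear single-molecule tracking data"
author: "nucspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing nuclear single-molecule tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucspt)
```

## The problem

Chromatin-binding proteins such as MeCP2 alternate between diffusing
through the nucleoplasm and binding chromatin, with binding events that
fall into a short-lived, low-affinity class and a long-lived,
high-affinity class. Live-cell single-molecule tracking (SMT) measures
this directly: sparse fluorescent labelling makes individual molecules
countable, fast acquisitions (100 Hz) record the jumps of both mobile
and bound molecules, and slow acquisitions (2 Hz) blur mobile molecules
into the background so that only stably bound molecules remain visible
and their track durations report residence times.

`nucspt` implements the complete measurement chain twice over: a
forward model that generates synthetic recordings with exact ground
truth, and the analysis pipeline that recovers kinetic parameters from
recordings (simulated or real). Because every preset's ground truth is
known, each analysis stage is validated by parameter recovery rather
than by eyeballing.

## The kinetic model

A molecule occupies one of three states: free (diffusion coefficient
$D_{free}$), short-lived bound, or long-lived bound (both with
$D_{bound} \ll D_{free}$). Transitions are Markovian:

* a free molecule binds with rate $k_{on}$, and the event is long-lived
  with probability $f_{long}$;
* bound molecules unbind with rates $1/\tau_{short}$ and
  $1/\tau_{long}$.

Presets are parameterized by what the experiment reports — the
stationary bound occupancy $F_{bound}$, the dwell times and the
long-lived event fraction — and `derive_rates()` converts them to rates
via the stationarity condition

$$k_{on} = \frac{F_{bound}}{(1 - F_{bound})\,E[\tau_b]},
\qquad E[\tau_b] = f_{long}\tau_{long} + (1 - f_{long})\tau_{short}.$$

`preset_catalog()` encodes the studied conditions: wild-type MeCP2 in
cerebellar granule cells ($F_{bound} = 0.55$, $D_{free} = 1$ µm²/s,
$\tau_{short} = 2$ s, $\tau_{long} = 7$ s, $f_{long} = 0.25$), the DNA
methylation mutants (Dnmt3a cKO 0.45, Tet triple cKO 0.60), the
Rett-syndrome MBD mutants, minimal MBD constructs, the reference
factors H2b, NLS, Sox2, TBP and H1.0, and the acute-slice granule vs
Purkinje-cell conditions. Values not constrained by the studied system
(e.g. the H2b long dwell, set to 300 s — effectively permanent on the
observation timescale) are documented defaults chosen once.

## The forward model

`simulate_cell()` propagates molecules inside a 2D disc of radius 3 µm
(granule cells) or 6 µm (Purkinje cells) with a reflecting boundary
(radial mirroring of overshoot, resolved iteratively). State switches
are sampled exactly within frames; a frame containing a switch uses the
time-weighted effective diffusion coefficient for its displacement,
which is accurate because dwell times (seconds) far exceed the 10 ms
frame interval — an assumption we test explicitly by comparing fits on
simulations with sub-frame switching enabled and disabled.

Camera physics:

* **Localization error.** Reported positions add bivariate Gaussian
  noise with $\sigma = 0.035$ µm per coordinate, truncated at vector
  norm $3\sigma$ so that no reported position can lie beyond
  radius $+3\sigma$ (a hard output invariant).
* **Photobleaching.** Per-frame Bernoulli bleaching, 0.04/frame in
  fast mode (high excitation power; mean track ≈ 25 frames, typical of
  100 Hz nuclear SMT) and 0.005/frame in slow mode (low power). As
  molecules bleach, new ones from the labelled pool are activated so
  the emitting density stays at `density_per_um2`, emulating the
  photobleach-to-sparsity protocol.
* **Motion blur (slow mode).** A molecule is detected only if its
  within-exposure motion-blur scale $\sqrt{2 D_{eff} t_{exp}}$ stays
  below `blur_threshold_um` (default 0.2 µm). This deterministic
  criterion keeps every fully bound frame
  ($\sqrt{2 \cdot 0.005 \cdot 0.5} = 0.07$ µm) and rejects any frame
  with more than ~3.5% of the exposure spent free. We deliberately do
  not threshold the realized net displacement: a molecule that diffused
  freely for part of the exposure has smeared its emission over
  hundreds of nanometres regardless of where it ended up, and a
  realized-step threshold either fragments bound tracks (at tight
  thresholds the bound step distribution's tail is clipped ~2% per
  frame, inflating the apparent off-rate far beyond the bleaching
  contribution) or passes partially free frames (at loose thresholds),
  both of which distort residence-time estimates.

Heterochromatin subdomains are generated by thresholding a
Gaussian-smoothed random field (`simulate_chromatin_map()`), with the
blob scale defaulting to 0.8 µm — chromocenter-like domains. Bound
molecules jitter by $\sqrt{4 D_{bound} \tau_{long}} \approx 0.37$ µm
over a long dwell, so region contrasts are only interpretable when
domains are larger than this jitter; the granule-cell analyses here use
1 µm blobs. Region modifiers on a preset (heterochromatin vs
euchromatin $F_{bound}$, $f_{long}$, or a $D_{free}$ multiplier) take
effect only when a map is attached.

## Trajectory linking

`link_tracks()` reconstructs trajectories with the maximum-displacement
gate $r_{max} = \sqrt{4 D_{max} \Delta t} + 3\sigma$; the $3\sigma$
allowance prevents legitimate fast jumps from being truncated by
localization noise and can be set to zero for the bare gate. Fast
tracking uses $D_{max} = 5$ µm²/s, dwell imaging $D_{max} = 0.05$
µm²/s (the dwell gate omits the noise allowance, matching the bare
published gate). Per frame pair, the assignment between open track ends
and new localizations is the optimal bipartite matching (maximum
cardinality, then minimum summed squared displacement), computed with a
Hungarian algorithm and verified against exhaustive enumeration on
small frames. Input row order within a frame cannot affect the result.

## Per-molecule diffusion coefficients

`estimate_D()` fits $MSD(\tau) = 4 D' \tau + b$ by ordinary least
squares over the first 4 lags with a free intercept (which absorbs the
$4\sigma^2$ localization-error offset); the lag count and intercept are
configurable because conventions differ between laboratories. Tracks
shorter than 5 or longer than 150 frames are excluded, fits with
$R^2 < 0.8$ (computed on the fitted window) are filtered out, and
non-positive slopes are floored at $10^{-4}$ µm²/s and flagged so that
log-scale distributions remain defined while flagged molecules stay out
of summary statistics. All bounds are inclusive.

## Two-state jump-length fit

`fit_two_state()` fits the per-cell distribution of jump lengths,
pooled over lags 1–4, with the mixture CDF

$$P(r \le x) = F_b\,C(x; D_b) + (1 - F_b)\,C(x; D_f), \qquad
C(x; D) = 1 - e^{-x^2 / (4 (D n \Delta t + \sigma^2))},$$

by least squares on 200 quantile-spaced CDF points per lag (CDF
fitting is bin-free), with box constraints $D_b \le 0.08$ µm²/s and
$D_f \ge 0.15$ µm²/s, fixed $\sigma$, and five deterministic
multi-starts spanning the constraint box. Localization noise enters
each lag once (noise sits at the two endpoints only), not once per
frame.

Two measurement effects are modelled rather than ignored:

* **Gate truncation.** A lag-$n$ jump survives linking only if each of
  its $n$ steps stayed under $r_{max}$. This both depletes the fast
  component from the pool (by the per-step retention probability to the
  $n$-th power) and clips its largest displacements (the truncated
  per-step variance). The fit conditions its model CDFs accordingly, so
  the reported parameters refer to the underlying population. This is
  the same spirit as Spot-On's correction for detection losses; we do
  not model axial defocalization because the forward model is 2D — the
  one deliberate divergence from published Spot-On, and the reason the
  simulator and fit are assumption-consistent.
* **Jump pooling weights.** Jumps are pooled uncapped by default:
  track lengths are state-dependent (bound tracks end by bleaching,
  mobile tracks additionally by gate breaks), so any per-track cap that
  binds differentially across states depletes one state's jumps and
  biases the bound fraction; a finite cap remains available for
  robustness against rare very long tracks.

## Residence-time analysis

`extract_immobile_tracks()` links slow recordings with the dwell gate;
durations follow the convention $(n_{frames} - 1)\Delta t$, and a
single-frame detection is not a dwell event. `survival_curve()`
computes $S(t)$ on the observed duration grid, renormalized to 1 at the
minimum reportable duration (one frame interval).
`fit_double_exponential()` fits

$$S(t) = (1 - f)\,e^{-(t - t_0)/\tau_{short}} + f\,e^{-(t - t_0)/\tau_{long}},
\qquad \tau_{long} \ge \tau_{short},$$

anchored at $t_0$ (the curve origin), with weights
$\propto \sqrt{N S(t)}$ — the inverse-SD weights implied by binomial
noise on survival fractions — and deterministic multi-starts. Fits
whose two time constants agree within 10% are flagged effectively
single-exponential.

The reported `f_long` is the *event-level* long-lived fraction. Because
a track of $n$ detections requires $n$ fully covered exposures, the
observed durations form an exact two-geometric mixture whose amplitudes
scale the event fractions by $c(\tau) e^{-(t_0 + \Delta t)/\tau}$ with
$c(\tau) = (\tau/\Delta t)(1 - e^{-\Delta t/\tau})$: longer-lived
events are more likely to be observed at all. Inverting this scaling
recovers the event mixture; the raw amplitude is kept as
`f_long_amplitude`. Without the correction a 25% event fraction with
$\tau = 2/7$ s at $\Delta t = 0.5$ s reads as ≈ 30–33%, which would be
a systematic error of the size of the effects under study.

Bleaching is not corrected by default (the analysis convention here);
at the slow-mode default (0.005/frame, 0.01 s⁻¹) it inflates the
apparent off-rate of the 7 s component by ~7%, within the recovery
tolerance. An optional `bleach_correct()` divides by the survival curve
of an effectively permanent binder (e.g. the H2b preset) when stronger
bleaching must be removed.

## Region-stratified analysis

`mask_from_image()` builds heterochromatin masks from an intensity
snapshot (Gaussian smoothing, then Otsu or quantile thresholding,
removal of sub-3-pixel components); `mask_from_map()` uses the
simulator's ground-truth map directly — both paths are exercised in the
tests. Tracks are assigned by majority vote over their localizations
(threshold 0.8, below which a track is `ambiguous`), and the kinetic
fit uses only jumps with both endpoints in-region to avoid
boundary-crossing contamination. Statistical comparisons follow the
field's conventions: two-sample Kolmogorov–Smirnov on pooled
per-molecule values, unpaired two-tailed t-tests or one-way ANOVA with
Bonferroni-adjusted pairwise p-values on per-cell values.

## Study sizes and what the tests show

The recovery analyses simulate 10 cells per fast-mode condition
(3,500 frames at 100 Hz, ~1,200 labelled molecules per cell, emitting
density 0.3 µm⁻² — about 8 concurrent emitters in a 3 µm nucleus) and three
slow-mode replicates of six pooled cells each (4,500 frames at 2 Hz,
density 0.10 µm⁻², giving ≥ 2,000 immobile events per replicate).
Purkinje simulations use radius 6 µm at density 0.12 µm⁻². These sizes
put per-condition standard errors well inside the recovery tolerances
(bound fractions ±5 percentage points, diffusion coefficients ±15%,
residence times ±20%).

The generator reproduces the features the analysis depends on — state
mixtures of Brownian displacements, exponential dwell mixtures, camera
noise, bleaching, motion-blur selection, spatial heterogeneity — but
not every feature of real recordings: no axial dimension or
defocalization, no fluorophore blinking or re-activation, no PSF-level
image formation (the optional spot detector is tested on rendered
Gaussians only), and free diffusion is homogeneous within a region.
Passing recovery tests therefore validates the analysis chain under
the model's assumptions; on real data the unmodelled features (notably
defocalization of fast molecules in thick nuclei) can shift absolute
values even though the comparative structure survives.

## Numerical choices

* Bipartite assignment uses a large finite cost for gated-out pairs, so
  cardinality dominates cost; ties cannot arise with continuous
  coordinates, and inputs are canonically ordered for determinism.
* Both nonlinear fits use L-BFGS-B from fixed multi-starts; the best
  residual wins, making fits deterministic functions of their input.
* Non-positive MSD slopes are floored, not dropped; empty inputs and
  degenerate configurations raise typed errors
  (`missing_columns`, `nonmonotone_frames`, `missing_sidecar`).
* All randomness flows through R's RNG: one `set.seed()` per simulated
  cell, with condition replicates seeded `base_seed + i`.

## A worked example

```{r example, eval = FALSE}
library(nucspt)
cat <- preset_catalog()

cell <- simulate_cell(cat$MeCP2_GC_WT, nucleus_geometry(3),
                      acquisition_config("fast", n_frames = 3500),
                      n_molecules = 1200, seed = 1)
tracks <- link_tracks(cell$localizations,
                      linking_config(D_max = 5, frame_interval_s = 0.01,
                                     localization_sigma_um = 0.035))
fit_two_state(collect_jumps(tracks), sigma = 0.035)
```
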