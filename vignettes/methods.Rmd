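---
title: "Models and methods behind smquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smquant)
```

smquant quantifies single-molecule microscopy of membrane proteins and
amyloid assemblies: diffusion of individual particles from tracking data,
the discrete diffusive states underlying thousands of short trajectories,
nanoscale clustering in super-resolution localization data, cluster
segmentation and co-localization in diffraction-limited images, and the
conversion between monomer-equivalent and particle concentrations of fibril
preparations. This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was open.
Every stage is paired with a synthetic-data generator so that recovery of
known ground truth — not agreement with any particular data set — is the
test of correctness.

## Trajectory simulation

`simulate_trajectories()` draws multi-state Brownian trajectories. A hidden
Markov chain over K diffusive states switches with per-frame probabilities
from a row-stochastic transition matrix; the initial state comes from the
chain's stationary distribution, so simulated ensembles are stationary from
frame one. While in state $s$, each coordinate steps by
$\sqrt{2 D_s \Delta t}\,\eta$ with $\eta \sim \mathcal N(0,1)$. Observed
positions add i.i.d. Gaussian localization noise per coordinate and frame
(default $\sigma = 20$ nm, the typical precision of quantum-dot and
photoactivated-localization tracking at 50 Hz; default
$\Delta t = 20$ ms). Consequently the expected squared single-frame
displacement is $4D\Delta t + 4\sigma^2$, the quantity the tests check
against closed form.

Design choices worth knowing:

* Localization noise is i.i.d. per frame; motion blur within an exposure is
  not modeled.
* Trajectory lengths follow either a fixed length or a shifted geometric
  law (`min + Geom(p)` with the requested mean). Tracking experiments do
  not publish a canonical length law; the geometric choice reproduces the
  heavy preponderance of short tracks seen in photoactivation data, and its
  tail probability is analytic, which the filtering test exploits.
  Defaults (mean 30 frames, minimum 5) emulate a photoactivation
  experiment; quantum-dot-style analyses filter at 15 frames.
* Positions are in µm internally; nm appears only at interfaces
  (localization clouds, images).

What the generator does **not** emulate: blinking/photophysics of the
label, 3D motion projected to 2D, spatially varying mobility within a
cell, and camera gain noise. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated model, not robustness to
every artifact of real recordings.

## Spot detection and trajectory linking

`detect_spots()` finds strict 8-neighborhood local maxima above the image
median plus a threshold and refines each by least-squares fitting of a
pixel-integrated isotropic 2D Gaussian (center, amplitude, offset, width).
Fitting the pixel-integrated model rather than a sampled Gaussian matters:
it is the exact generative model of the renderer, and on clean input the
fit recovers sub-nanometer centers, so residual localization error in
pipeline tests is attributable to noise, not model mismatch. Fits whose
center leaves the fit window are dropped with a warning.

`link_trajectories()` associates detections frame to frame by minimising
the total squared displacement over candidate pairs within `max_disp`
(optimal bipartite assignment per frame pair). Not linking a track costs
`max_disp^2`, the usual gap-cost convention, so a link forms exactly when
it is cheaper than the alternative. The assignment is solved exactly by
branch-and-bound within each connected component of the candidate graph —
components contain only a handful of spots at tracking densities — with a
greedy fallback above 14 tracks per component. Ties resolve by frame, then
joint cost, then localization order, making linking deterministic and
translation invariant. Tracks unmatched for more than `max_gap` frames
(default 2) are closed. The default search radius
$4\sqrt{4 D_{\max} \Delta t}$ covers essentially all Brownian steps at the
configured mobility bound; both knobs are exposed because published
tracking pipelines rarely state them.

## MSD, diffusion coefficient, explored area

`compute_msd()` implements the time-averaged mean squared displacement

$$\mathrm{MSD}(n\,\Delta t) = \frac{1}{N-n} \sum_{i=1}^{N-n}
  (x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2,$$

with gapped trajectories contributing only pairs whose both endpoints
exist. An independent double-loop implementation in the test suite pins
the vectorized version to 1e-12 relative accuracy.

`fit_diffusion_coefficient()` performs ordinary least squares of MSD
against lag over the first `fit_points` lags (2–5, default 4) with a free
intercept, reading $\mathrm{MSD}(t) = 4Dt + 4\sigma_x^2$: the slope gives
$D$, the intercept the one-direction localization accuracy $\sigma_x$.
A known $\sigma_x$ can be supplied to fix the intercept. Negative slopes —
immobile molecules — yield $D = 0$ with a flag rather than an error.

Two numerical facts shape the defaults and tests:

* On short tracks the sampling distribution of the fitted slope is wide
  and its median falls as more (increasingly correlated and noisy) lags
  enter the fit: on 20-frame tracks at $D = 0.1\ \mu m^2/s$,
  $\sigma = 20$ nm, the median fitted D across 1000 tracks is ≈ 0.094–0.099
  with a two-point fit but ≈ 0.089–0.093 with a four-point fit. The
  recovery test therefore fits two points, the least-biased choice in this
  regime, while the package default remains four points, a sensible
  middle ground for the longer (≥ 15 frame) tracks of quantum-dot
  experiments. `fit_points` is always recorded in the returned object.
* The explored-area statistic is the trapezoidal integral of the MSD curve
  over the 0.6–0.9 s lag window, normalized by the 0.3 s window length so
  that a constant MSD returns that constant and the value carries µm²
  units; the raw integral (µm² s) is attached as an attribute since the
  normalization convention is not universal. Trajectories whose curve does
  not cover the window return `NA` flagged with a reason rather than an
  extrapolated number.

`aggregate_estimates()` provides the two population summaries commonly
reported: arithmetic means per group (per movie or per cell) and the
pooled empirical cumulative distribution across trajectories.

## Diffusive-state inference (variational-Bayes HMM)

`infer_diffusive_states()` treats per-frame displacements of many short
trajectories as emissions of a shared hidden Markov chain over K diffusive
states: each displacement component is zero-mean Gaussian with variance
$2 D_k \Delta t$. Priors are conjugate:

* inverse-gamma on each state's per-axis step variance, centered on
  $2 D_{\text{prior}} \Delta t$ with $D_{\text{prior}} = 0.1\ \mu m^2/s$;
* Dirichlet on each transition-matrix row whose mean encodes a
  self-transition probability $1 - 1/n_{\text{dwell}}$ with
  $n_{\text{dwell}} = 50$ frames (1000 ms at 20 ms);
* Dirichlet on the initial-state distribution (symmetric).

Convention fixes only the prior means; strengths default to one
observation-equivalent so the data dominate after a handful of steps. Inference is variational EM: the E-step runs scaled
forward–backward per trajectory under expected-log parameters (the usual
"tilde" parameterization), batched across trajectories ordered by length
so each time step is a single matrix operation over all active tracks; the
M-step updates the conjugate posteriors from expected counts. The
variational lower bound is evaluated every iteration and asserted
non-decreasing to 1e-8 — a violated bound is a bug, not a tolerance issue.
Candidate models K = 1..3 (default maximum) are each fitted from several
seeded initializations (quantile-binned responsibilities with jitter;
restart seeds derive from the master seed by a fixed counter), and the K
with the highest bound wins. States are always reported ascending in D, so
state 1 is the bound/slow state and state K the free/fast state, and all
downstream metrics are invariant to internal label permutations.

Limitations inherited from this model family: localization noise is not
part of the likelihood, so each estimated D carries a $\sigma^2/\Delta t$
floor (≈ 0.02 µm²/s at 20 nm and 20 ms) — recovery tests therefore
simulate with $\sigma = 0$, and real-data users should subtract the floor
or treat slow-state D values as upper bounds; displacements across gap
frames are excluded (gaps split a trajectory into independent segments)
rather than rescaled; and trajectories shorter than
`min_traj_points` (default 2 positions, i.e. one displacement) are
dropped.

`state_metrics()` reports, per state, the posterior-expected occupancy,
the dwell time $\Delta t / (1 - T_{kk})$, and the per-step entry
probability $\sum_{i \ne j} \pi_i T_{ij} / \sum_{i \ne j} \pi_i$ — the
probability that a molecule not currently in state j enters it on the next
step. Because "the proportion of molecules transitioning into a state" is
also readable as the fraction of trajectories that ever visit it, that
fraction is reported alongside; the entry probability is the default
reading. `state_path_metrics()` computes the same quantities by direct
counting on a known state sequence, which is how the unit tests anchor the
definitions.

`compare_conditions()` differences two fitted models state by state
(matched by D rank) and attaches bootstrap percentile intervals obtained
by resampling trajectories and recombining their stored posterior
sufficient statistics. Refitting the full model per replicate would be
prohibitively slow and is not what the interval is for — it quantifies
sampling variability of the summaries at the fitted posterior. The first
replicate is the identity resample, so a single-replicate bootstrap
degenerates to the point estimate, a convenient smoke-test identity.

## STORM cluster analysis

`merge_consecutive_detections()` collapses blink chains — detections of
one molecule in consecutive frames within a merge radius — to their mean
position. Chains tolerate a configurable frame gap (default 1, strictly
consecutive) and radius (default 50 nm); the original acquisition
pipelines do not publish these values, so they are configuration, not
claims. A chain touched in the current frame stays open but cannot accept
a second detection from the same frame.

`dbscan_clusters()` is a standard DBSCAN with two conventions fixed
deliberately: the ε-neighborhood **includes the point itself**, so the
default `min_pts = 20`, `eps = 20` nm reads literally as "minimum 20
detections within a radial distance of 20 nm" (20 coincident points are a
cluster; 19 are noise); and border points reachable from several clusters
go to the cluster of their lowest-indexed core neighbor, which makes
labels independent of point order. Neighborhoods come from grid bucketing
(cells of size ε), and the test suite pins labels to a quadratic-time
reference on planted-cluster clouds. Per-cluster "radius" is the radius of
gyration — the upstream definition is unpublished, and gyration radius is
the convention that makes a uniform ring of radius r report r.
`cluster_metrics()` reports detections/µm², clusters/µm², events per
cluster and the fraction of detections inside clusters.

`render_storm()` renders each localization as a unit-integral
pixel-integrated Gaussian (defaults: 10 nm SD on a 5 nm grid), so the
integrated image equals the localization count.

## Wavelet segmentation and co-localization

`atrous_decompose()` is the undecimated à-trous transform with the
B3-spline kernel [1,4,6,4,1]/16, taps dilated ×2 per level and
whole-sample mirrored borders; detail plane k is the difference of
consecutive smooths, so planes plus residual reconstruct the input exactly
(checked to 1e-10 on random images, and against a naive direct-convolution
oracle on an impulse). `segment_clusters()` thresholds the level-2 plane —
the diffraction-limited spot scale — at `k_sigma` robust standard
deviations (1.4826 × MAD, robust against the bright clusters themselves
inflating the noise estimate), labels 8-connected components and discards
those below `min_area` pixels. The upstream implementation of this
segmentation published neither its scale nor threshold, so both are
configuration with recorded defaults (level 2, k = 2), and absolute
cluster densities from other pipelines are not expected to be reproduced —
recovery of planted spots is the validated property. Because only a
band-pass plane is thresholded, adding a constant to the image leaves the
mask unchanged, the "background-free" property the segmentation exists
for. One practical note encoded in the tests: the thresholded component
captures the central lobe of a spot, whose extent in PSF units depends on
the PSF-to-kernel scale ratio; summed per-cluster intensities are within a
few percent of planted amplitudes when the PSF sigma is near the pixel
scale, and systematically a few percent low for strongly oversampled
spots.

`cluster_stats()` counts components intersecting a region of interest
(stored as a polygon so manually drawn regions stay reproducible) per µm²
and sums per-component intensity on the original image.
`colocalize()` marks a cluster of channel A co-localized when it shares a
pixel with channel B (overlap mode) or when its boundary lies within
150 nm of a B boundary (apposition mode, measured between boundary pixel
centers — centroid distances would misclassify large clusters). Overlap
implies apposition, so the apposition fraction can never be smaller; both
directions (A-in-B and B-in-A) are always reported.

## Fibril particle concentration

The fibril calculator converts between monomer-equivalent and particle
concentrations. From electron-microscopy geometry, a fibril of volume
$V = \pi (d/2)^2 L$ holds
$\lfloor V (1 - w) / (v_{aa} \cdot n_{res}) \rfloor$ monomers with
defaults $v_{aa} = 1.28 \times 10^{-28}\ m^3$ per average residue,
$w = 0.30$ water content and $n_{res} = 381$ residues per Tau-1N3R
monomer. The floor (not round) is deliberate: the reference worked example
reports the 136.5-monomer intermediate as 136. Note that evaluating the
formula at the mean dimensions (35 nm × 18.7 nm) gives
$9.61 \times 10^{-24}\ m^3$, whereas the published worked example prints
$9.51 \times 10^{-24}\ m^3$ for the same inputs; the printed volume is
treated as the authoritative input for the 136-monomer result and the
discrepancy is surfaced here rather than silently resolved. From
sedimentation, `monomers_from_mass()` rounds the particle-to-monomer mass
ratio (5442 kDa / 39.72 kDa → 137); converting sedimentation coefficients
to molar mass is out of scope, as is fitting raw sedimentation boundaries.
The two routes agreeing within one monomer is itself a tested invariant.
`particle_concentration()` divides and only rounds for display: the exact
value is always attached, so the round trip
`particle_concentration × monomers_per_particle = monomer_eq` is exact.
π is used at full precision throughout; truncating it to 4 decimals
changes nothing at display precision.

## Problem sizes and runtime

The validation suite runs at deliberately moderate scale: 1000 simulated
tracks of 20 frames for diffusion recovery, 500 tracks (~30 frames mean)
for two-state HMM recovery, 2000-point localization clouds for the DBSCAN
reference comparison, 64×64 images for segmentation, and 200 planted
cluster pairs for co-localization recovery. These sizes put each recovery
statistic comfortably inside its tolerance band (3 standard errors where a
closed form exists) while the whole suite completes in a few minutes on a
single core; all of them scale linearly if larger ensembles are wanted.
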