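# smquant

Quantification toolkit for single-molecule microscopy of membrane proteins
and amyloid assemblies. It was built for the analysis problem that arises
when fibrillar protein assemblies (e.g. Tau fibrils) cluster at the
neuronal plasma membrane and perturb the lateral organization of membrane
proteins such as the α3-Na⁺/K⁺-ATPase: establishing that story requires,
in one place,

* **diffusion analysis of tracked particles** — time-averaged mean squared
  displacement, MSD(n·Δt) = (N−n)⁻¹ Σᵢ [(xᵢ₊ₙ−xᵢ)² + (yᵢ₊ₙ−yᵢ)²], fitted
  over its first 2–5 points as MSD(t) = 4Dt + 4σₓ², plus the explored-area
  confinement statistic (MSD integrated over the 0.6–0.9 s lag window);
* **diffusive-state inference** from thousands of short trajectories by a
  variational-Bayes hidden Markov model (per-axis displacement variance
  2·D_k·Δt per state, conjugate inverse-gamma/Dirichlet priors, model
  selection over K = 1..3 by the variational lower bound), yielding
  per-state D, occupancy, dwell time and transition probabilities —
  bound/slow vs free/fast states;
* **STORM cluster analysis** — consecutive-frame deduplication, DBSCAN
  with the literal "minimum 20 detections within 20 nm" convention
  (ε-neighborhood includes the point), cluster densities and the fraction
  of detections in clusters, Gaussian rendering at 5 nm pixels;
* **image cluster segmentation** by à-trous B3-spline wavelet
  decomposition (threshold on the spot-scale detail plane), cluster
  density/intensity within a polygonal ROI, and two-channel
  co-localization by mask overlap or ≤ 150 nm boundary apposition;
* **fibril particle concentrations** — monomers per fibril from cylinder
  geometry, ⌊V(1−w)/(v_aa·n_res)⌋, or from sedimentation mass ratios, and
  the monomer-equivalent ↔ particle concentration conversion;
* a **synthetic-data module** (multi-state Brownian trajectories at 50 Hz
  with 20 nm localization noise, STORM clouds with planted clusters and
  blinking re-detections, diffraction-limited images with Poisson noise)
  so every stage is validated by recovery of known ground truth.

Spot detection (pixel-integrated Gaussian fitting) and optimal per-frame
trajectory linking are included as the front end for image stacks.

## Worked example

Simulate 500 short two-state trajectories (D = 0.01 and 0.2 µm²/s,
10-frame mean dwells, 20 ms frames) and recover the states:

```r
library(smquant)

P <- matrix(c(0.9, 0.1,
              0.1, 0.9), 2, 2, byrow = TRUE)
sim <- simulate_trajectories(traj_sim_spec(
  n_traj = 500, frame_interval = 0.02,
  length_law = list(type = "geometric", mean = 30, min = 5),
  D_states = c(0.01, 0.2), transition_matrix = P,
  loc_noise_sigma = 0, seed = 42))

fit <- infer_diffusive_states(sim$tracks, seed = 7)
summary(fit)
#> <diffusive_state_model> K = 2 state(s), dt = 0.02 s
#>   state 1: D = 0.009957 um²/s, occupancy = 48.9%, dwell = 194 ms
#>   state 2: D = 0.2024 um²/s, occupancy = 51.1%, dwell = 200 ms
#> evidence (lower bound) per K: 38464.0, 47184.7, 40008.2
#> transition matrix (per frame):
#>        [,1]   [,2]
#> [1,] 0.8969 0.1031
#> [2,] 0.1000 0.9000
```

Model selection picks K = 2 (highest lower bound), both diffusion
coefficients land within a few percent of truth, and the ~200 ms dwell
times match the simulated 10-frame mean residence. `state_metrics(fit)`
adds per-state entry probabilities; `compare_conditions()` differences two
fitted models with bootstrap intervals.

Per-trajectory diffusion analysis works on the same container:

```r
msd <- compute_msd(split_tracks(sim$tracks)[[1]])
fit_diffusion_coefficient(msd)
#> <diffusion_fit> D = 0.03562 um²/s, sigma_x = 0.02434 um
```

(a single short two-state track mixes both mobilities — which is exactly
why the HMM, not the per-track fit, assigns states).

The fibril calculator reproduces its printed worked example: a
9.51×10⁻²⁴ m³ fibril at 30% water, 1.28×10⁻²⁸ m³ per residue and 381
residues per monomer holds

```r
g <- fibril_geometry(length_m = 35e-9, diameter_m = 18.7e-9)
monomers_from_geometry(9.51e-24, g)
#> [1] 136        (raw 136.5)
particle_concentration(1, 137, signif_digits = 1)
#> [1] 0.007      (exact 0.00729927)
```

i.e. 136 monomers per average fibril, and a 1 µM monomer-equivalent
suspension of 137-monomer particles is 0.007 µM in particles.

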