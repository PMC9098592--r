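---
title: "fMRI-informed EEG source reconstruction: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fMRI-informed EEG source reconstruction: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmripeb)
```

# The model

`fmripeb` solves the EEG inverse problem in the hierarchical Gaussian
(parametric empirical Bayes) form

$$Y = L S + \varepsilon_1, \qquad \varepsilon_1 \sim N(0, h_C I_C),$$
$$S = 0 + \varepsilon_2, \qquad \varepsilon_2 \sim N(0, C_D), \qquad
C_D = \sum_p \gamma_p V_p,$$

with $Y \in \mathbb{R}^{C\times T}$ the EEG, $L \in \mathbb{R}^{C\times V}$
the leadfield, and $S$ the unknown dipole dynamics. Channel noise is
assumed uniform across channels ($h_C I_C$); temporal correlations are
fixed to the identity. Each covariance component $V_p$ encodes one prior
assumption on the sources, and its hyperparameter $\gamma_p$ is
estimated by ReML: the free energy

$$F(\gamma) = -\tfrac{n}{2}\left[\log\det\Sigma(\gamma)
  + \mathrm{tr}\!\left(\Sigma(\gamma)^{-1} \hat S_Y\right)\right] + \text{const},
\qquad \Sigma(\gamma) = \gamma_0 I_C + \sum_p \gamma_p L V_p L^\top,$$

is maximized over log-hyperparameters, and the posterior mean
$\hat S = C_D L^\top \Sigma^{-1} Y_r$ is returned. The free energy is
the model's log-evidence approximation used for model comparison.

Before inversion the data are reduced onto the smallest right-singular
subspace holding a `retain` fraction (default 0.99) of the squared
singular values (`temporal_reduce()`); this suppresses noise while
keeping a temporally continuous estimate, and its rank bounds the number
of source components estimated later.

## Inversion algorithms as component choices

* **MN** — a single identity component: equal variance, no covariance.
* **LORETA** — identity plus the coherence component $K K^\top$ of the
  Green's smoothing kernel (spatially smooth currents).
* **EBB** — one diagonal component with entries
  $w_i = 1/(l_i^\top \hat\Sigma_Y^{-1} l_i)$, the classic beamformer
  power estimate; the sample covariance is ridge-regularized by
  $10^{-6}\,\mathrm{tr}(\hat\Sigma_Y)/C \cdot I$ so short recordings do
  not break the inverse.
* **MSP** — `n_patch` (default 64) rank-1 components
  $K_{\cdot v_j} K_{\cdot v_j}^\top$ on evenly spaced vertices. Patches
  whose hyperparameters fall below $10^{-8}$ of the largest are held at
  that floor rather than greedily pruned; greedy search variants are out
  of scope.

## ReML numerics

Hyperparameters are parameterized as $\gamma_p = e^{\lambda_p}$ for
positivity and optimized by Fisher scoring with step halving: a step is
only accepted if it does not decrease $F$, so the reported free-energy
trace is non-decreasing by construction. Convergence is declared at
$|\Delta F| < 10^{-4}$ (default), with at most 128 iterations. The
Fisher information is ridge-stabilized by $10^{-8}$ of its largest
diagonal entry. Initialization splits the observed channel power equally
across components, scaled by each component's channel-space trace, which
makes the starting point scale-equivariant — doubling the data
quadruples all fitted $\gamma$ (a property the tests check).

# fMRI spatial priors

## Activation maps

Block paradigms become unit boxcars sampled at the TR, convolved with a
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit
dispersions, peak:undershoot ratio 6, 32 s support, unit-peak scaling)
and truncated to the run; an intercept completes the design. OLS is fit
per unit, contrasts are converted to Z through matched t/normal tail
probabilities on the log scale (stable beyond |Z| ~ 8), and maps are
thresholded at voxel Z > 2.5 followed by a 26-connected
minimum-cluster-extent rule. Random-field cluster p-values are
deliberately not implemented; `calibrate_cluster_extent()` chooses an
extent such that at most 5% of supra-threshold clusters on seeded
white-noise volumes of the same grid survive, which is an explicit,
reproducible surrogate for "cluster p < 0.05". Units with residual
variance at numerical-noise level (relative to the data scale) get Z = 0
and a flag, since their t ratios are 0/0 artifacts.

## Resting-state networks

Spatial ICA uses symmetric fixed-point negentropy extraction (logcosh
contrast) on PCA-whitened data with a seeded random orthonormal start;
component maps are z-scored and ordered by explained variance. The
component count is an explicit parameter — no automatic order
estimation. IC maps are binarized two-sidedly at $|Z| \ge 3$: eigenvector
and IC signs are arbitrary, so a one-sided threshold would make the
assignment depend on an arbitrary sign convention. Templates are
assigned mutually exclusively: if each template's best IC is already
distinct that greedy assignment stands; otherwise template orderings are
searched (exhaustively up to 10,000 orderings, seeded random sampling
beyond), each ordering claiming best-remaining ICs sequentially, and the
ordering with the highest mean Dice across all templates wins.

## dFC-state modules

Parcel BOLD is band-passed (second-order Butterworth, 0.01–0.1 Hz,
forward–backward for zero phase) and the instantaneous phase taken from
the analytic signal. The phase-coherence matrix
$C(n,p,t) = \cos(\theta_{n,t} - \theta_{p,t})$ is, algebraically,
$\cos\theta_t \cos\theta_t^\top + \sin\theta_t \sin\theta_t^\top$: a
positive-semidefinite rank-2 matrix with trace $N$, so its leading
eigenvector always explains at least half of the absolute eigenvalue
mass — the tests and the acceptance script verify this bound rather than
assume it. The eigenvector sign is fixed so the majority of elements are
negative (ties: first element non-positive), following the LEiDA
literature; "explained variance" is $\lambda_1 / \sum_i |\lambda_i|$ by
default, configurable to $\lambda_1/\mathrm{tr}$.

The eigenvector series $C_R$ is factorized as $D A$ with unit-norm atoms
(the dFC states) and an $\ell_1$ penalty $\lambda \sum |A|$ on the
weights. The optimizer alternates (i) sparse coding by coordinate
descent run simultaneously across all columns (each coordinate update is
the exact scalar minimizer, so any number of sweeps decreases the
objective) and (ii) per-atom dictionary updates: because the quadratic
in one atom is isotropic, its minimizer on the unit sphere is the
normalized residual correlation $R_j a_j / \|R_j a_j\|$, in closed form.
Both half-steps are exact minimizers of their subproblems, so the
objective is non-increasing — an invariant the tests assert to
$10^{-10}$ relative tolerance. At $\lambda = 0$ the coding step is exact
least squares (QR, pseudo-inverse fallback), reaching machine-precision
factorizations when $k$ matches the rank. Atoms are initialized from
seeded random data columns; default 100 outer iterations with a
$10^{-10}$ relative objective tolerance.

The (k, λ) grid is k = 5..10 and
$\lambda_j = 10^{-(j-1)/10}$, j = 1..10 (1 down to ~0.1259). One grid
point is selected by the single largest absolute Pearson correlation
between any weight time-course and any contrast; within that fit each
contrast picks its most correlated state, and duplicates collapse to one
state. Correlations use HRF-convolved contrast time-courses by default —
BOLD weights are hemodynamically lagged, so a raw boxcar would
systematically underestimate the association; raw boxcars can be passed
explicitly.

Selected states are expanded to connectivity matrices $d_i d_i^\top$
(diagonal zeroed) and partitioned by signed-modularity Louvain with the
asymmetric convention: positive-part modularity weighted by $1/v^+$,
negative part by $1/(v^+ + v^-)$. The optimizer alternates seeded greedy
local moving (from singletons, with moves to fresh communities allowed)
and best-pair community merging, over 10 seeded restarts, keeping the
maximum-Q partition. On small planted graphs this matches exhaustive
partition search (tested to $\Delta Q < 10^{-9}$); the module count is
whatever the optimizer returns — it is not forced. The partition is
invariant to a global sign flip of the state, as it must be, since
$(-d)(-d)^\top = d d^\top$.

## From prior volumes to covariance components

Prior volumes are binarized at > 0, projected to the surface by
nearest-voxel membership, and smoothed with the truncated-exponential
Green's kernel of the binary mesh adjacency $M$:
$K = \sum_{i=0}^{r} (\sigma M)^i / i!$ with $\sigma = 0.6$, $r = 8$,
entries below $10^{-8}$ zeroed. A literal first-order kernel
$\sigma M$ is available behind `literal = TRUE`, but it is a poor
smoother — it has zero diagonal, so it discards the prior's own support;
the exponential form is the construction the first-order expression
abbreviates. The kernel is rescaled symmetrically,
$K \leftarrow D^{-1/2} K D^{-1/2}$ with $D = \mathrm{diag}(K)$, giving
unit diagonal while preserving symmetry (a row-wise maximum rescale
would break symmetry; for this kernel the diagonal is the row maximum,
so the two coincide up to the symmetric split). Each smoothed prior
$q$ yields the rank-1 component $V_p = qq^\top$, normalized to unit
trace so ReML hyperparameters are comparable across priors of different
spatial extent; rank-1 components are stored by their factor and
reconstruct exactly.

Component sets nest: S1 holds the algorithm's intrinsic components; S2
adds one component per RSN (plus one per activation contrast on task
runs); S3 adds one per dFC-state module and exists only for task runs.
Task runs therefore produce 4 x 3 = 12 inversions, resting runs 8.

# Scoring

Reconstructed sources are decomposed by the same spatial ICA
($S^\top = U\, S_{IC}$), capped by the temporal-reduction rank; maps are
z-scored (constant maps are dropped with a warning), transferred to the
volume by nearest-vertex lookup, binarized at $|z| \ge 3$ (mirroring the
RSN threshold; configurable) and scored against targets with
$d = 2N_{ov}/(N_{roi}+N_{sc})$ and $p_{RS} = N_{ov}/N_{roi}$. Per target
the SC maximizing $d$ is kept (ties: lowest component index) and its
$d^*$, $p^*_{RS}$ averaged within map type. Model-level scores are VE
(reported on both reduced and full data; reduced is primary since the
inversion sees reduced data), the free energy, and random-effects
posterior model probabilities obtained by variational updates of a
symmetric Dirichlet prior over model frequencies (a fixed-effects
softmax of summed log-evidence is available behind a flag).

# The synthetic generator

The generator emulates every input at desk scale and is the package's
acceptance surface:

* **Source spaces** — subdivided icospheres (42/162/642/... vertices)
  at 70 mm radius, parcelled by seeded farthest-point sampling plus
  simultaneous region growing (contiguity guaranteed), embedded in a
  voxel grid with a diagonal RAS affine; near-surface voxels carry the
  parcel of their nearest vertex, and the voxel containing each vertex
  is always labelled, so every parcel has vertices and voxels.
* **Leadfields** — seeded Gaussian channel mixing times a three-step
  random-walk smoothing of the mesh adjacency: columns of adjacent
  vertices correlate (checked against random pairs) while rows stay
  full rank. No volume conduction is modelled.
* **EEG** — $Y = L S_{\text{true}} + \varepsilon$ from planted vertex
  patches; noiseless simulation is exact and superposes across disjoint
  scenes.
* **BOLD** — within each block the parcels share one narrow-band
  oscillation (0.05 Hz by default, fresh random phase per block)
  multiplied by the planted state's sign/magnitude pattern, plus white
  noise; states are rescaled to unit maximum magnitude so `snr` is the
  per-parcel amplitude-to-noise ratio. This is the minimal structure
  that makes phase coherence recover the state: parcels with equal signs
  are phase-aligned, opposite signs are in antiphase, so each in-block
  coherence slice is exactly the sign pattern's outer product.
  Optionally, condition-specific parcels receive an additional
  HRF-convolved boxcar response, giving the GLM path real signal.
* **ROIs/templates** — spheres by exact voxel-center distance (the
  bundled `motion_rois()` table carries the eight standard 10 mm
  motion-sensitive ROI definitions), and surrogate network templates as
  contiguous parcel blobs regenerated until all pairwise Dice < 0.2.

What the generator does **not** emulate: hemodynamic variability,
physiological noise, realistic head geometry or volume conduction,
inter-subject variability. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under their own
generative assumptions — not performance on real recordings.

# Study conditions used by tests and the acceptance script

Tests run at V = 162 vertices, C = 24 channels, N = 20–90 parcels, with
BOLD runs of 300–500 samples and EEG segments of 120–600 samples; the
full-pipeline checks use a 12-job task configuration with reduced
dictionary grids (k = 5..6, three penalties). The acceptance script uses
the headline dFC condition: N = 90 parcels, T = 500 samples at TR = 1 s,
planted two-state block design at snr = 2. In the prior-benefit
comparison the channel noise is set to the signal amplitude
(`noise_sd = 1`): with weaker noise the best-match Dice of a 4-voxel
target saturates at 1.0 for both component sets and the comparison
becomes uninformative ties.

# Degenerate inputs and tie-breaks

* Constant BOLD rows are band-passed anyway but flagged degenerate
  (their phases are meaningless).
* All-zero EEG inverts to all-zero sources with undefined scores.
* Empty prior volumes cannot form components and raise errors; ROI
  spheres outside the grid warn and return empty maps.
* Dictionary atoms with unused weights keep their previous value;
  exact ties in best-match scoring resolve to the lowest component
  index; Louvain ties are resolved by the seeded restart with maximal Q.
* VE below 0 (overshooting reconstructions) is clipped to 0 and
  flagged.

# Known limitations

* The Louvain optimizer is greedy; optimality is only guaranteed (and
  tested) on small graphs against exhaustive search.
* The cluster-extent rule is a calibrated surrogate, not random-field
  theory.
* The temporal projector's retained-variance default (0.99) stands in
  for an unspecified rank rule; the achieved rank is always reported.
* Group-level statistics (repeated-measures ANOVA and post-hocs) are
  out of scope by design: `run_all()` exports the long-format results
  table for external statistical software.
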