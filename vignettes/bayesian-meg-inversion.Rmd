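---
title: "Empirical-Bayes MEG source reconstruction: models, priors and the synthetic bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical-Bayes MEG source reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MEG measures, at a few hundred sensors outside the head, the magnetic
field generated by cortical currents.  Recovering the current
distribution $S$ from the sensor data $B$ under the linear forward model

$$B = L\,S + \varsigma$$

is ill-posed: the leadfield matrix $L$ (sensors $\times$ sources) has far
fewer rows than columns, so priors on $S$ decide the solution.  This
package implements four priors inside one parametric empirical-Bayes
machinery, so that the only difference between "algorithms" is the set of
source-covariance components each one brings:

* **MNM** (minimum-norm model): a single global prior, $Q = I$ — all
  sources equiprobable and uncorrelated.
* **EBB** (empirical Bayesian beamformer): a single diagonal prior whose
  entries are LCMV source-power estimates
  $\sigma^2_\theta = (\tilde l_\theta^{\mathsf T} \tilde C^{-1}
  \tilde l_\theta)^{-1}$ computed from the reduced data covariance
  $\tilde C$; no source correlations are assumed.
* **ARD** (automatic relevance determination): a library of $2p$ cortical
  patch components $Q_i = q_i q_i^{\mathsf T}$ (optionally $3p$ with
  bilateral pairs $q_i + \bar q_i$), each with its own hyperparameter;
  components whose scale collapses to the hyperprior expectation are
  pruned.
* **GS** (greedy search): the same library, but hyperparameters attach to
  *sets* of patches; after each ReML pass the top half of the newest set
  (ranked by reconstructed source power) forms a new candidate set, so
  set sizes halve until the free energy stops improving.

All schemes end in the same final stage: a two-hyperparameter ReML
(synthesized source prior + sensor noise) followed by the MAP extractor
$M = Q L^{\mathsf T}(L Q L^{\mathsf T} + \exp(\lambda_0) I)^{-1}$.
Because that stage is identical, the resulting free energies are
directly comparable across schemes.  The synthesized prior is
trace-normalized on entry, so the comparable free energy is exactly
invariant to any positive rescaling of the prior.

## Covariance-component estimation

The estimated sensor covariance is a weighted sum
$C = \sum_i e^{\lambda_i} P_i + e^{\lambda_0} I_u$ of sensor-level
projections $P_i = \tilde L Q_i \tilde L^{\mathsf T}$.  The log-scale
hyperparameters $\lambda$ carry Gaussian hyperpriors with mean
$\eta = -32$ and precision $\Pi = 1/256$: weakly informative, with prior
scale $e^{-32} \approx 0$ and a variance that lets scales travel many
orders of magnitude.  `reml()` maximizes the Laplace free energy

$$F = -\tfrac{\nu}{2}\operatorname{tr}(C^{-1}S)
      -\tfrac{\nu}{2}\log\lvert C\rvert
      -\tfrac{u\nu}{2}\log 2\pi
      -\tfrac12 (\lambda-\eta)^{\mathsf T}\Pi(\lambda-\eta)
      +\tfrac12 \log\lvert \Sigma_\lambda \Pi\rvert$$

by second-order Fisher scoring with Levenberg-style damping (many
near-zero patch hyperparameters make the expected information
ill-conditioned; damping is raised until a step does not decrease $F$).
Patch components are held in factored form ($P_i = f_i f_i^{\mathsf T}$
with $f_i = \tilde L q_i$), which turns the information-matrix traces
into squared inner products and keeps a 129-hyperparameter ARD pass on a
2,562-vertex bench below a second.

Numerical choices, all configurable: convergence at $\Delta F <
10^{-2}$ (absolute) or 512 iterations; $e^{\lambda}$ clipped to
$[e^{-64}, e^{64}]$; Fisher steps capped at 8 log-units per coordinate;
$C$ inverted by Cholesky with escalating jitter only if singular.
Hyperparameter estimation runs on data rescaled to unit mean power —
the MAP extractor is invariant to this, and it keeps $\lambda$ in a sane
range for any input units (the package uses fT and nAm).  Because the
exact update algebra is anchored to nothing but the objective, its
correctness surface is the test suite's exhaustive grid search of $F$ on
small problems, plus parameter-recovery and scale-equivariance
properties.

## Dimension reduction

Spatial modes are eigenvectors of $LL^{\mathsf T}$ with eigenvalues at
least $e^{-16}$ of the mean eigenvalue.  Temporal modes are found in the
DCT domain (orthonormal DCT-II, optionally band-limited) by an SVD of
the coefficient cross-product.

Which temporal eigenmodes to keep is the one genuinely open choice in
this stage.  A plain cumulative-variance cutoff keeps essentially every
mode whenever noise contributes more than a sliver of variance (at
+10 dB the signal holds only ~91% of the variance), and with it the
reduction removes no noise at all.  The package therefore keeps, by
default, the modes that rise significantly above the flat eigenvalue
floor of white noise — floor estimated by the median eigenvalue, with a
Marchenko–Pastur significance margin for the pooled cross-product — and
falls back to the cumulative-variance rule when nothing clears the
floor (the lowest-SNR regime, where no reduction is justified).  With
this rule one or two modes survive at high SNR and the retained modes
stay signal-dominated far below 0 dB.

By default the temporal subspace is estimated from the trial-averaged
(evoked) response.  The simulator replicates the source time courses
over trials, so averaging attenuates noise by $\sqrt{n_{\text{trials}}}$
before the signal subspace is identified; per-trial pooling
(`temporal_from = "trials"`) is the right choice for induced activity
that does not repeat, at the cost of a much higher detection floor.
Trials are reduced individually and enter ReML through the
trial-averaged covariance with effective sample count
$\nu \cdot n_{\text{trials}}$.

## The synthetic bench

Everything runs on generated geometry; no data files are needed.

* **Cortex**: a subdivided icosahedron carrying a seeded, band-limited
  radial folding field, mirror-symmetric about the mid-sagittal plane so
  every left-hemisphere vertex has an exact contralateral partner.  The
  folding amplitude (0.13 of the cortical radius, soft-clipped at two
  standard deviations) was calibrated once so that the default
  configuration — ~10k vertices at a 71 mm cortical radius — has a mean
  inter-vertex spacing of about 5 mm, matching the resolution of the
  anatomical meshes used in this literature; the fold wavelength tracks
  the mesh resolution (5.5 base edges) so every mesh resolves its own
  folds.  Dipole orientations are fixed along the vertex normals, which
  the folding makes genuinely non-radial.
* **Sensors**: a Fibonacci-spiral helmet of point magnetometers on a
  sphere at 1.3 conductor radii, with seeded tangential orientations.
* **Forward model**: the closed-form field of a current dipole in a
  homogeneous conducting sphere.  Radial dipoles are exactly silent, and
  the radial field component equals the Biot–Savart field of the primary
  current alone — the independent oracle the tests use.
* **Patches**: the smoother is the graph heat kernel
  $\exp(s(A - D))$ of the mesh adjacency, evaluated by a
  cancellation-free shifted series and truncated to the 8th-order
  neighborhood, entries below $10^{-4}$ of the column peak zeroed,
  columns rescaled to unit maximum.  At $s = 0.6$ a patch has a FWHM of
  two to three mesh vertices (~8 mm on the bench mesh).  A
  row-normalized variant of the Laplacian was rejected: it concentrates
  all mass on the central vertex at every $s$, which contradicts the
  patch extents this operator is supposed to produce.
* **Patch centers**: farthest-point sampling (geodesic) on the left
  hemisphere, mirrored to the right, giving $p$ per hemisphere (64 on
  the desk-scale bench, 256 at full scale).

## Simulations

Each dataset follows the benchmark design: dipoles at patch centers
(sites pre-selected as the least leadfield-correlated set of 50 among
10,000 random candidates), time courses $\sin(\phi_0 + 2\pi
\,\mathrm{cumsum}(f_t)/f_s)$ with $f_t \sim N(10, 2^2)$ Hz, replicated
over 100 epochs of 0.8 s at 200 Hz; pairwise correlation regimes
(all $|r| > 0.8$ or all $< 0.3$) enforced by rejection sampling; white
sensor noise calibrated so that
$20\log_{10}(\mathrm{RMS_{signal}}/\mathrm{RMS_{noise}})$ hits the
requested dB level, redrawn per trial.  Unit dipole moments throughout.
The instantaneous-frequency parameters and the amplitude-ratio SNR
convention are choices recorded in every dataset's metadata.

What the generator deliberately does *not* emulate: extended (patch-like)
sources, correlated "brain noise", sensor gradiometry, and real cortical
geometry.  Passing tests therefore speak to the correctness and relative
behavior of the schemes under matched white-noise assumptions, not to
absolute performance on real recordings.

## Accuracy metrics

**SAI** (spatial): image local maxima (strict neighbor comparison, ties
to the lower index, peaks below 5% of the top peak dropped) are labeled
true/false positives by their Euclidean distance to the nearest true
dipole at each of 10 log-spaced search sizes (3–30 mm).  Walking peaks
by descending magnitude, the accumulated-magnitude precision curve
$Y = \mathrm{TP_{acc}}/(\mathrm{TP_{acc}}+\mathrm{FP_{acc}})$ is traced
over the fraction of peaks considered and its trapezoidal area is the
SAI: 1 means no false positive outranks the truth, 0 means nothing was
found.  Images are scored per trial and averaged by default; scoring the
evoked image is an option.

**TAI** (temporal): for each search size, the sources within range of a
true dipole explain the reduced data through their rank-one patterns
(reduced leadfield column times reconstructed time-course signature);
$R^2$ is the least-squares variance they explain.  The nested fits make
the $R^2$ curve non-decreasing in the search size by construction,
which is also the property the index's own description demands — a
fixed partial-sum prediction (summing the MAP contributions of the
selected sources without refitting) fails that property on sparse
reconstructions and was rejected for that reason.  $R^2$ is undefined
when only one temporal mode survives; such runs report `NA`.

Cross-scheme statistics follow the benchmark protocol: two-sample
t-tests per condition and SNR with Bonferroni correction across
conditions × SNR levels, and fixed-effects pairwise free-energy
summaries (mean difference, sign counts, fraction of simulations
favoring each scheme).  Random-effects model selection is out of scope.

## Problem sizes

The package distinguishes the full-scale configuration (10,242-vertex
cortex, 275 sensors, 256 patches per hemisphere, 50 simulations per
condition) from the desk-scale bench used by the test suite and the
acceptance script: 2,562 vertices, 120 sensors, 64 patches per
hemisphere, 100 trials per dataset, and 10–20 simulations per operating
point.  These sizes are the package's reference configuration for
reproducible desk runs; every generator parameter is recorded in the
experiment manifest so larger runs are a config change, not a code
change.

## Known limitations

* At −30 dB with 120 sensors the signal eigenvalue sits at the
  covariance detection limit; ARD then sometimes concentrates on a
  neighboring patch (~20 mm away) and minimum-norm peaks wander, so the
  lowest-SNR operating points fall short of what a 275-sensor array
  achieves.
* Minimum-norm depth bias interacts with the folded geometry: deep
  sources displace towards superficial folds by more than they would on
  smoother real cortex, which depresses MNM accuracy at tight search
  sizes even without noise.
* The bilateral-prior machinery assumes mirror symmetry that the
  generated meshes satisfy exactly; on imported meshes the
  nearest-vertex snap may pair imperfectly.
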