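---
title: "Methods: unified processing of multi-acquisition MSI data"
author: "msiunify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unified processing of multi-acquisition MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Mass spectrometry imaging (MSI) records a full mass spectrum at every pixel
of a tissue raster. Turning a series of such acquisitions — for instance,
serial sections through one embryo — into a single analyzable dataset
requires solving three problems that standard single-sample pipelines do
not address:

1. **Peak calling.** The observed m/z of one ion species fluctuates from
   pixel to pixel (mass shift), so a fixed m/z bin either splits a species
   or merges neighbours. Intervals must adapt to where detections actually
   accumulate.
2. **Cross-acquisition matching.** Each acquisition yields its own peak
   list at slightly different m/z positions; peaks representing the same
   molecule must be linked across tens of acquisitions without external
   references.
3. **Batch-effect normalization.** Log-intensity distributions of the same
   molecule in consecutive sections shift for purely technical reasons;
   the shifts factorize into an acquisition term and a molecule term and
   must be removed without erasing biology.

`msiunify` implements all three stages, the image-quality and spatial
statistics around them, and simulators that emulate the relevant degrees
of freedom of real data so each stage can be benchmarked without any
external download.

# Count-based adaptive peak calling

An acquisition is held as a sparse matrix `S[p, m]` of intensities over
pixels `p` and a global m/z grid of half-open bins of width `grid_step`
(default 1e-4 Da, the nominal resolution of orbital-trap data; the grid is
anchored at the acquisition's declared minimum m/z so columns are
comparable across pixels). The caller works on the *detection-frequency
histogram* `f[m] = #{p : S[p, m] > 0}` — counts of pixels, not summed
intensity — smoothed with a Gaussian kernel whose bandwidth should match
the instrument's mass accuracy (default 1e-3 Da; kernel truncated at 4
s.d., renormalized to unit mass).

**Centers.** A threshold sweeps downward from the histogram maximum over
the sorted distinct values; whenever a new contiguous above-threshold run
appears that contains no existing center, the run's argmax bin (ties to
lower m/z) is added. A new run appears exactly when a superlevel-set
component is born, i.e. at a local maximum, so the implementation finds
plateau local maxima directly in linear time; the test suite checks this
equivalence against a literal threshold-sweep oracle. An optional
`min_count` ignores maxima at or below a background level of event
counts.

**Boundaries.** From each center the interval expands outward while the
histogram is non-increasing, *equal values included*: plateaus — including
runs of empty bins — are walked through until the flank of the next mode
rises. Two guards exist: a hard half-width cap (0.5 Da) against runaway
expansion over flat noise, and the same `min_count` background level,
below which expansion stops when set. Adjacent modes meet at their shared
valley bin, which both intervals may contain. We deliberately follow the
non-strict (`>=`) descent rule: with mass-shift distributions that are
right-skewed (a gamma component), the informative tail of a mode decays
through long shallow plateaus that a strict rule would truncate.

Ion images are the row sums of `S` over each interval, each peak's
reference m/z is the most frequent detection (unsmoothed argmax) inside
its interval, and images are TIC-normalized (each pixel divided by its
total) unless asked otherwise.

# Cross-acquisition matching as minimum-cost flow

Each called peak is a node carrying its acquisition and reference m/z.
Candidate edges connect peaks from different acquisitions whose m/z differ
by less than a threshold `t` and whose section indices differ by at most
`k` (default 2) positions in the series; the edge cost is the m/z
distance. Every peak additionally owns start and end terminal edges of
cost `log(L)` (`L` = number of peaks, natural log). The optimum selects
edges so that every node lies on exactly one start-to-end path, minimizing
total cost; each path is a feature.

Given an ordering of the acquisitions, directing edges from earlier to
later acquisition makes the problem a bipartite assignment between
successor and predecessor slots: a matched pair costs its m/z distance and
saves two terminal edges. We solve it exactly by successive shortest
augmenting paths (a minimum-cost-flow method whose solutions are integral
by construction, matching the integrality of the underlying path polytope
that also makes the LP relaxation exact). A Bellman–Ford search handles
the negative reduced costs. An independent checker verifies the degree
and adjacency constraints of every solution, and on small windows the
test suite compares the objective with exhaustive enumeration over all
path decompositions.

The m/z axis is cut into roughly 1-Da windows, with each nominal cut
snapped to the widest detection-free gap within ±0.1 Da so a peak family
is never split. Each window is solved under `n_perm` random acquisition
orderings (the identity order first) and the lowest objective wins; ties
keep the earliest ordering, so results are reproducible given the seed.
The default `t`, when unset, is three times a robust scale estimate of
nearest cross-acquisition peak distances; full-scale analyses should set
`t` explicitly from the known shift scale.

Feature quality diagnostics follow the same logic as the original
analyses: an ambiguity score counting extra same-acquisition peaks inside
a feature's m/z interval; Jaccard/Euclidean consistency of (M, M+1)
isotopolog presence vectors at 1.00336 Da spacing; and nearest-neighbour
annotation against an adduct-expanded reference list (H+, Na+, K+,
H−H2O+, NH4+; tolerance 0.01 Da; among candidates within tolerance the
most abundant reference wins when abundances are given).

# Hierarchical Bayesian batch-effect model

Within one acquisition `a` and compound `c`, detected log intensities are
bimodal: a background mode (noise floor) and a foreground mode (real
signal). The model ties the groups together:

- mixture: `x ~ pi * N(mu1, sigma1) + (1 - pi) * N(mu0, sigma0_c)`
- foreground mean: `mu1[a,c] = mu0[a,c] + gamma_a * lambda_c + delta_c`
- foreground spread: `sigma1[a,c] = Sigma_a + Sigma_c`
- priors: `delta_c ~ N(3, 1)`, `gamma_a, lambda_c ~ U(-2, 2)`,
  `Sigma_a, Sigma_c ~ Exp(s)`, `sigma0_c ~ U(0.05, 0.5)`,
  `mu0[a,c] ~ N(m0, 1)`, mixture weight `~ Beta(0.5, 0.5)`.

The batch effect is the bilinear term `gamma_a * lambda_c`: one
acquisition-wide factor scaled by each compound's susceptibility.
`delta_c` is the compound's intrinsic mode separation. The
hyperparameters are set empirically from naive unconstrained
two-component mixture fits per group (`m0` = median background mean; `s`
= reciprocal mean foreground s.d.; the exponential parameter is treated
as a *rate*). The background mean is fitted per (acquisition, compound)
while the background s.d. is per compound, following the model's
subscripts.

**Fitting.** Latent pixel labels are marginalized analytically, so the
objective is the exact mixture log posterior. Bounded parameters are
mapped to unconstrained coordinates (scaled logistic for the interval
parameters, log for the positive ones) and the posterior including the
transform Jacobians is maximized with Adam using analytic gradients,
warm-started from the naive fits. The mixture weight's logistic map is
compressed to (0.001, 0.999) because the Beta(0.5, 0.5) prior is
unbounded at 0 and 1 and would otherwise pull degenerate groups onto the
boundary. Convergence is declared when the relative change of the log
posterior over 200 steps falls below 1e-6; otherwise the best-seen
parameters are returned with a warning. The bilinear term is only
identified up to scale and sign, so after fitting we fix the gauge:
`sd(gamma) = 1` and `mean(lambda) >= 0`. Ablation variants (`additive`,
`acquisition`-only, `compound`-only displacement) are provided for model
comparison; the additive variants absorb the mean of `gamma` into
`delta`.

**Correction.** The reference distribution of a compound is the mixture
whose parameters are the across-acquisition means of the fitted group
parameters. Each group's transform is the numerical quantile map
`T^{-1} = F_ref^{-1}(G_obs(x))` evaluated on a 2,048-point grid spanning
4 s.d. beyond both supports, kept monotone by construction and linearly
interpolated with clamped extrapolation. Correction is element-wise,
never imputes (the missing pattern of the panel is untouched), and
reduces to the identity where observed and reference distributions agree.
Two deliberately simple baselines are packaged for comparison — per-group
z-scoring and a per-compound location/scale adjuster — labelled as
non-reference implementations.

**Empirical diagnostic.** Before any model fitting, the factorization
hypothesis can be checked from naive fits alone: assuming the background
mode is honest and biology varies smoothly along consecutive sections,
the matrix `M[c,a] = m1 - m0 - delta_hat_c - y_hat_ac` (with `delta_hat`
the across-section mean mode separation and `y_hat` a ±2-section local
trend) isolates the technical shifts. If they factorize, `M` is close to
rank one; the first singular value's energy fraction and its bootstrap
spread (80% of compounds, 50 repetitions) quantify this. The estimator
needs at least 5 sections and, by design, *mistakes* biology for batch
effect when the section order is shuffled — a property the tests assert.

# Spatial screening and image quality

**Moran's I with a TIC-stratified null.** Spatially informative images
are found by comparing observed Moran's I (row-standardized rook weights
on the pixel lattice, tissue-maskable) with a permutation null that
shuffles pixel values only within 8 total-ion-count quantile strata, so
tissue-wide intensity baselines survive the null while molecule-specific
patterns do not. 100 permutations give the null mean and s.d.; the
one-sided z-derived p (structure = positive autocorrelation) is
Bonferroni-adjusted, significant below 0.01. When the null degenerates an
empirical exceedance p `(1 + #{null >= obs}) / (1 + N)` is used.
A limitation worth knowing: with a spatially smooth TIC field and only 8
strata, the within-stratum residual is itself smooth, so the stratified
null retains a little spatial signal and the test is slightly
anti-conservative for images that are pure functions of TIC; the
calibration tests therefore use spatially rough TIC, and real analyses
should not interpret marginal significances near the threshold.

**Image quality.** Three scale-invariant metrics score extracted images:
(i) *spatial chaos* — intensities are cut into 8 equal-count levels and
each level's connected-component count is compared with the
scattered-singleton expectation of noise (1 − components/pixels, averaged
over levels; our own formulation of the level-set idea); (ii) a
*noise-model* test — a Poisson-family GLM of the rescaled image on a grid
of small Gaussian bumps (sigma 2 px, spacing 4 px) against an
intercept-only null, tested as a dispersion-normalized deviance F because
the intensity rescaling leaves the dispersion unknown; (iii) a *power
ratio* — 2D FFT energy below vs above 0.25 of Nyquist (DC excluded),
small for stripe artifacts of line scanning. Pass thresholds are
calibrated on simulated noise images (95th/5th percentiles), a
reproducible surrogate for manual threshold setting. A separate
aggregation diagnostic flags images whose interval collects two or more
detection clusters from the same pixel's spectrum in over 10% of
contributing pixels — the signature of merged quasi-isobars.

# Simulators and what they do (not) show

All simulators are seed-deterministic and carry their full
parameterization in the returned object.

**Spectra.** Theoretical m/z positions lie in a unit range, by default
evenly spaced so that "crowding" is exactly the molecule count per unit
(uniform-random placement is available but admits pairs closer than the
shift scale, which no caller can separate). Every spectrum shifts each
molecule by normal(0, 0.01) plus gamma(shape 0.1, scale 0.04) draws, with
molecule order preserved via per-molecule rejection resampling (a global
sort would silently relabel molecules). Noise spike-ins land uniformly
over the range; SNR is the ratio of total detections to noise detections,
so SNR 10 in a 100-detection spectrum means 90 true signals and 10 noise
signals, with fractional expected counts resolved by a Bernoulli draw.
The caller's score is, per molecule, the mutual information between the
molecule indicator and membership in the molecule's *predicted* interval
(the one capturing the plurality of its detections), normalized by the
indicator entropy and averaged with detection-count weights. For the
reported benchmark we run the caller with bandwidth 0.015 — the
simulation's actual per-detection shift s.d.,
`sqrt(sigma^2 + k * theta^2) = 0.016`, applying the same
bandwidth-equals-mass-accuracy rule used on real data — on a 1e-3 grid,
at 5 molecules per unit and SNR 100 (the favorable-SNR end of the
benchmark), against zero-anchored fixed bins of 0.02 and 0.04.

**Matching.** Multi-section peak lists with per-section normal shifts and
dropout, plus a known correspondence map; an optional minimum separation
produces the "well-separated" regime. Matching quality is pairwise over
cross-section peak pairs (accuracy, precision, recall; precision of an
all-singleton featurization is reported as 1 with a flag). The baseline
is fixed binning at twice the shift s.d.

**Intensity panels.** The ellipsoid phantom places three ellipsoids (two
overlapping) in a 3D volume, assigns each molecule to a subset, draws
lognormal intensities per region with region-level random means, sums
intensities in the overlap (creating a third mode) and sections the
volume. The pattern panel generates smooth Gaussian-filtered random
fields over sections (a synthetic stand-in for ISH reference images),
pushes them through a strictly monotone logistic contrast so histograms
are bimodal like real ion images, min–max rescales each compound to the
[-7, -1] natural-log range of TIC-normalized MALDI data, and labels five
regions from an independent smooth field. Batch distortion draws
`gamma_a`, `lambda_c` from centered normals and pushes every group
through the monotone quantile map that shifts its foreground mode by
`gamma_a * lambda_c` while pinning the background — the generative mirror
of the correction model.

**Evaluation.** Correction quality is RMSE against ground truth after a
q–q slope rescaling (slope only, so scale-free methods are comparable but
uncorrected offsets still count); regional differential testing runs
two-sided Welch t-tests on the pooled pixel values of each region pair
per compound, scores calls against the ground-truth calls (FPR/FNR), and
bootstraps sections of the truth for the attainable lower bound. Note
that per-section distortion corrupts pooled regional distributions —
which is why the test discriminates corrections — whereas tests on
per-section means largely would not.

What passing these benchmarks does *not* show: the simulators emulate
mass-shift statistics, dropout, bimodality and factorized batch effects,
but not isotope envelopes, chemical noise with structured m/z
preferences, detector saturation, spatial autocorrelation of mass shifts,
or non-factorizable batch effects. Results on real data depend on those
too.

# Problem sizes and numerical choices

The packaged benchmarks and tests run at deliberately modest sizes chosen
as the smallest scales at which each property is statistically decidable:
1,000 spectra and 10 replicate simulations for the calling benchmark;
10-section, 15–25 molecule matching sets; panels around 5–8 sections with
12–20 compounds and 400–2,000 pixels per group for the normalization
benchmarks; 16–64 pixel squares for image metrics. The MAP fit defaults
to at most 4,000 Adam steps (learning rate 0.02) with the convergence
rule above; the benchmark fits converge in a few hundred to ~1,500 steps
from the warm start. Degenerate inputs are handled explicitly: empty
acquisitions abort, negative intensities are rejected with a count,
constant images score zero chaos and undefined Moran's I, all-zero pixels
stay zero through TIC normalization, unfitted mixture groups fall back to
single-mode transforms, and strata of size one merge with a neighbour.

# Known limitations

- The caller assumes centroided input; profile-mode data must be
  centroided upstream.
- The matcher's `k`-consecutive constraint breaks a molecule's chain when
  it is missing from more than `k - 1` consecutive sections; the split
  features are correct but lower pairwise recall.
- The normalization model assumes a shared background level and a
  bimodal shape; strongly trimodal groups (overlap regions of the
  phantom) are corrected through their two dominant modes.
- The rank-one diagnostic requires consecutive sections and honest
  background modes; shuffled or non-serial acquisitions inflate it.
- Quantile matching onto the compound reference flattens genuine
  section-to-section differences in the detected (foreground) fraction:
  where that fraction is biology, correction trades it for comparability.
  The Wasserstein-improvement guarantees hold in the regime the model
  assumes (stationary background and detection fraction along the
  series).
- The stratified Moran test's null is mildly anti-conservative for
  smooth TIC fields, as discussed above.
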