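# msiunify

Unified processing of multi-acquisition mass spectrometry imaging (MSI)
data: count-based adaptive peak calling, network-flow matching of peaks
across acquisitions, and hierarchical Bayesian removal of factorized
batch effects — plus image-quality metrics, a TIC-stratified Moran's *I*
screen for spatially informative molecules, and simulators that let every
stage be benchmarked without any external data.

## Who it is for

Labs producing serial-section MALDI-MSI (or similar) datasets — e.g.
spatial lipidomics atlases across many sections — who need one coherent
feature space and comparable intensities across tens of acquisitions.

## The methods in brief

**Adaptive peak calling.** Per acquisition, intensities live in a sparse
pixel × m/z-grid matrix `S[p, m]` (grid step 1e-4 Da by default). The
caller works on the detection-frequency histogram
`f[m] = #{p : S[p, m] > 0}`, Gaussian-smoothed at the instrument's mass
accuracy. A descending-threshold watershed seeds one center per histogram
mode, and each center expands outward while `f` is non-increasing
(plateaus included), so every ion species gets an m/z interval that
follows its actual mass-shift cloud. Ion images are interval row sums,
TIC-normalized per pixel.

**Peak matching.** Peaks from all acquisitions become nodes; candidate
edges connect peaks within `t` Da from acquisitions at most `k = 2`
sections apart, at cost equal to their m/z distance, with start/end
terminal edges priced `log L`. Minimizing total cost subject to every
node lying on exactly one start-to-end path

```
min Σᵢⱼ Xᵢⱼ Cᵢⱼ   s.t.  Xᵢⱼ ∈ {0,1},  Xᵢⱼ ≤ Gᵢⱼ,  Σⱼ Xᵢⱼ = Σᵢ Xᵢⱼ = 1
```

is solved exactly per 1-Da window as a min-cost bipartite assignment
(successive shortest augmenting paths; integral by construction), best of
`n_perm` random acquisition orderings. Paths become features, each with
at most one peak per acquisition.

**Normalization.** Within each (compound `c`, acquisition `a`) group, log
intensities follow a two-Gaussian mixture (background + foreground) whose
foreground mean is `μ¹ = μ⁰ + γ_a·λ_c + δ_c` and spread `σ¹ = Σ_a + Σ_c`:
the batch effect is the bilinear term `γ_a·λ_c`. MAP estimation (Adam on
the marginalized mixture posterior with the model's priors, warm-started
from naive mixture fits) yields per-group mixtures; each group is then
pushed through the monotone quantile map `T⁻¹ = F_ref⁻¹(G_obs(x))` onto
its compound's across-acquisition reference mixture. An empirical
rank-one diagnostic (`estimate_batch_effect_matrix()`) checks the
factorization assumption before you commit to the model.

## Worked example

Simulate mass-shifted spectra (normal σ = 0.01 plus right-skewed gamma
shifts, noise spike-ins at SNR 100), call peaks, and score the result
against the known molecule labels:

```r
library(msiunify)

sim   <- simulate_spectra(n_molecules = 5, n_spectra = 1000, snr = 100, seed = 1)
acq   <- sim_to_acquisition(sim, grid_step = 1e-3)
stack <- call_peaks(acq, bandwidth = 0.015, tic = FALSE)
stack$peaks[, c("peak", "left_mz", "right_mz", "reference_mz")]
#> # A tibble: 5 × 4
#>    peak left_mz right_mz reference_mz
#> 1     1   0        0.23        0.0985
#> 2     2   0.229    0.415       0.300
#> 3     3   0.414    0.619       0.502
#> 4     4   0.618    0.833       0.706
#> 5     5   0.832    1.40        0.900

eval_peak_calling(sim, stack$peaks)$score
#> [1] 0.9733  # weighted mean mutual information, adaptive caller
eval_peak_calling(sim, fixed_bin_intervals(0.04, range(sim$detections$mz)))$score
#> [1] 0.7876  # the fixed-binning baseline on the same data
```

The five called intervals track the five simulated molecules (reference
m/z near the true positions 0.1, 0.3, …, 0.9, right edges stretched by the
skewed shift tails); the mutual-information score says the adaptive
intervals isolate each molecule's detections almost perfectly while 0.04
Da bins lose about a fifth of the attainable information.

Matching peak lists from six simulated serial sections into features:

```r
msim <- simulate_matching(n_sections = 6, n_molecules = 8, shift_sd = 0.002,
                          dropout_rate = 0.05, seed = 2, min_sep = 0.02)
ft   <- match_dataset(msim$peaks, t = 0.008, k = 2, n_perm = 5, seed = 1)
eval_matching(msim, ft)
#>   accuracy precision recall
#> 1        1         1      1
```

Batch-effect correction end to end on a synthetic pattern panel:

```r
pp  <- simulate_pattern_panel(n_compounds = 12, shape = c(20, 20),
                              n_sections = 8, seed = 41)
pp  <- apply_batch_distortion(pp, gamma_sd = 0.7, lambda_sd = 0.7, seed = 42)
res <- normalize_panel(pp$observed, n_steps = 1000, seed = 1)
glance(res$fit)      # fit summary; tidy(res$fit) for the parameter table
autoplot(res$fit)    # log-posterior trace
```

A full pipeline over a directory of acquisitions (call → QC → match →
normalize → spatial screen, with per-stage caching) is
`run_pipeline("pipeline.yaml")`; a thin command-line wrapper lives in
`inst/cli/msiunify.R`.

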