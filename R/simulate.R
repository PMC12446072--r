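#' Simulate mass-shifted spectra with noise spike-ins
#'
#' Theoretical m/z positions are drawn in a unit range; every spectrum
#' observes each molecule at its theoretical position plus a normal shift
#' (s.d. `sigma`) plus a right-skewed gamma shift (shape `k`, scale
#' `theta`), with the molecule order within each spectrum preserved
#' (offending draws are rejection-resampled per molecule rather than
#' sorted, which would silently relabel molecules). Noise detections are
#' spiked in uniformly over the range so that the ratio of total detections
#' to noise detections equals `snr` (an SNR of 10 in a 100-detection
#' spectrum means 90 true signals and 10 noise signals); `snr = Inf` adds
#' none. Noise intensities are log-uniform over the signal intensity range.
#'
#' @param n_molecules molecules per spectrum; molecular crowding is this
#'   count over the unit range.
#' @param n_spectra number of spectra (default 1000).
#' @param sigma normal shift s.d. (default 0.01).
#' @param k,theta gamma shift shape and scale (defaults 0.1, 0.04).
#' @param snr detections-to-noise ratio (> 1, or `Inf`).
#' @param seed RNG seed.
#' @param spacing `"even"` (default) places the theoretical positions
#'   evenly over the unit range so crowding is exactly `n_molecules` per
#'   unit; `"uniform"` draws them uniformly at random (which admits
#'   arbitrarily close, hence unresolvable, pairs).
#' @param max_tries rejection-resampling cap per molecule.
#' @return a `spectra_sim`: list with `detections` (tibble `spectrum`,
#'   `mz`, `intensity`, `molecule` — NA for noise), `positions` (true
#'   molecule m/z) and `params`.
#' @export
simulate_spectra <- function(n_molecules, n_spectra = 1000, sigma = 0.01,
                             k = 0.1, theta = 0.04, snr = 10, seed = 1,
                             spacing = c("even", "uniform"),
                             max_tries = 100) {
  if (!is.infinite(snr) && snr <= 1) abort("snr must exceed 1 (it is the total:noise detection ratio)")
  spacing <- match.arg(spacing)
  set.seed(seed)
  positions <- if (spacing == "even") {
    (seq_len(n_molecules) - 0.5) / n_molecules
  } else {
    sort(runif(n_molecules))
  }
  noise_rate <- if (is.infinite(snr)) 0 else n_molecules / (snr - 1)
  shift <- function(n) rnorm(n, 0, sigma) + rgamma(n, shape = k, scale = theta)
  spectra <- purrr::map(seq_len(n_spectra), function(sp) {
    # expected noise count per spectrum; fractional part drawn Bernoulli
    n_noise <- floor(noise_rate) + rbinom(1, 1, noise_rate - floor(noise_rate))
    obs <- positions + shift(n_molecules)
    tries <- 0
    repeat {
      bad <- which(diff(obs) <= 0)
      if (length(bad) == 0) break
      tries <- tries + 1
      if (tries > max_tries) {
        abort("could not satisfy the m/z order constraint; molecules too crowded for the shift scale")
      }
      redo <- unique(c(bad, bad + 1))
      obs[redo] <- positions[redo] + shift(length(redo))
    }
    sig_int <- exp(rnorm(n_molecules, 0, 1))
    out <- tibble(spectrum = sp, mz = obs, intensity = sig_int,
                  molecule = seq_len(n_molecules))
    if (n_noise > 0) {
      rng <- range(sig_int)
      out <- dplyr::bind_rows(out, tibble(
        spectrum = sp,
        mz = runif(n_noise, min(positions) - 3 * sigma,
                   max(positions) + 3 * sigma),
        intensity = exp(runif(n_noise, log(rng[1]), log(rng[2]))),
        molecule = NA_integer_))
    }
    out
  })
  structure(list(
    detections = dplyr::bind_rows(spectra),
    positions = positions,
    params = list(n_molecules = n_molecules, n_spectra = n_spectra,
                  sigma = sigma, k = k, theta = theta, snr = snr,
                  seed = seed)
  ), class = "spectra_sim")
}

#' View a simulated spectra set as an acquisition
#'
#' Each spectrum becomes one raster pixel so the peak caller can run on the
#' simulation unchanged.
#'
#' @param sim a `spectra_sim`.
#' @param grid_step m/z grid step (default 1e-4).
#' @return an `msi_acquisition`.
#' @export
sim_to_acquisition <- function(sim, grid_step = 1e-4) {
  recs <- sim$detections %>%
    mutate(x = .data$spectrum - 1L, y = 0L) %>%
    select("mz", "intensity", "x", "y")
  load_acquisition(recs, grid_step = grid_step,
                   acquisition_id = "simulated_spectra")
}

#' Fixed-width zero-anchored binning baseline
#'
#' @param width bin width in Da.
#' @param mz_range range to cover.
#' @return tibble of intervals with `peak`, `left_mz`, `right_mz`.
#' @export
fixed_bin_intervals <- function(width, mz_range = c(0, 1)) {
  lo <- floor(mz_range[1] / width) * width
  edges <- seq(lo, mz_range[2] + width, by = width)
  tibble(peak = seq_len(length(edges) - 1),
         left_mz = edges[-length(edges)], right_mz = edges[-1])
}

# assign each detection to an interval; overlaps resolved by nearest center
assign_intervals <- function(mz, intervals) {
  out <- rep(NA_integer_, length(mz))
  centers <- (intervals$left_mz + intervals$right_mz) / 2
  ord <- order(intervals$left_mz)
  for (i in ord) {
    inb <- which(mz >= intervals$left_mz[i] & mz < intervals$right_mz[i])
    new <- inb[is.na(out[inb])]
    out[new] <- intervals$peak[i]
    clash <- inb[!is.na(out[inb]) & out[inb] != intervals$peak[i]]
    if (length(clash) > 0) {
      prev <- match(out[clash], intervals$peak)
      closer <- abs(mz[clash] - centers[i]) < abs(mz[clash] - centers[prev])
      out[clash[closer]] <- intervals$peak[i]
    }
  }
  out
}

# mutual information of two discrete label vectors, natural log
discrete_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / outer(pa, pb)[pos]))
}

#' Score called intervals against simulated molecule labels
#'
#' Scores each true molecule against its prediction: the interval capturing
#' the plurality of the molecule's detections. The per-molecule score is
#' the mutual information between the molecule-membership indicator and the
#' predicted-interval membership indicator over all detections, normalized
#' by the molecule indicator's entropy, so an interval containing exactly
#' the molecule's detections scores 1, while detections the interval misses
#' (splits) and foreign detections it captures (noise, merged neighbours)
#' both cost. The reported score is the detection-count-weighted mean over
#' molecules.
#'
#' @param sim a `spectra_sim`.
#' @param intervals tibble with `peak`, `left_mz`, `right_mz` (from the
#'   adaptive caller's `peaks` table or [fixed_bin_intervals()]).
#' @return list with `score` (weighted mean MI) and `per_molecule` tibble
#'   (`molecule`, `n`, `mi`, `predicted`).
#' @export
eval_peak_calling <- function(sim, intervals) {
  det <- sim$detections
  assigned <- assign_intervals(det$mz, intervals)
  mols <- sort(unique(det$molecule[!is.na(det$molecule)]))
  per <- purrr::map(mols, function(j) {
    is_j <- !is.na(det$molecule) & det$molecule == j
    n_j <- sum(is_j)
    if (n_j == 0) return(NULL)
    tab <- table(assigned[is_j], useNA = "no")
    if (length(tab) == 0) {
      return(tibble(molecule = j, n = n_j, mi = 0, predicted = NA_integer_))
    }
    pred <- as.integer(names(tab)[which.max(tab)])
    in_pred <- !is.na(assigned) & assigned == pred
    h <- discrete_mi(is_j, is_j)  # indicator entropy
    mi <- if (h > 0) discrete_mi(is_j, in_pred) / h else 0
    tibble(molecule = j, n = n_j, mi = mi, predicted = pred)
  }) %>% dplyr::bind_rows()
  list(score = sum(per$mi * per$n) / sum(per$n), per_molecule = per)
}

#' Simulate multi-section peak lists with known correspondences
#'
#' @param n_sections number of serial sections.
#' @param n_molecules molecules shared by the sections.
#' @param shift_sd per-section m/z shift s.d. (Da).
#' @param dropout_rate per-(section, molecule) missing probability.
#' @param seed RNG seed.
#' @param mz_range placement range of the theoretical positions.
#' @param min_sep minimum separation between theoretical positions in Da
#'   (0 = fully random placement; positive values reject draws closer than
#'   this, giving resolvable "well-separated" molecules).
#' @return a `matching_sim`: list with `peaks` (tibble `peak_id`,
#'   `acquisition`, `section`, `mz`, `molecule`), `positions`, `params`.
#' @export
simulate_matching <- function(n_sections, n_molecules, shift_sd = 0.002,
                              dropout_rate = 0.1, seed = 1,
                              mz_range = c(500, 501), min_sep = 0) {
  set.seed(seed)
  positions <- sort(runif(n_molecules, mz_range[1], mz_range[2]))
  if (min_sep > 0) {
    for (tries in 1:200) {
      if (all(diff(positions) >= min_sep)) break
      bad <- which(diff(positions) < min_sep) + 1L
      positions[bad] <- runif(length(bad), mz_range[1], mz_range[2])
      positions <- sort(positions)
    }
    if (any(diff(positions) < min_sep)) {
      abort("could not place molecules at the requested separation")
    }
  }
  peaks <- purrr::map(seq_len(n_sections), function(sec) {
    present <- runif(n_molecules) >= dropout_rate
    tibble(acquisition = sprintf("S%02d", sec), section = sec,
           molecule = which(present),
           mz = positions[present] + rnorm(sum(present), 0, shift_sd))
  }) %>%
    dplyr::bind_rows() %>%
    mutate(peak_id = dplyr::row_number()) %>%
    select("peak_id", "acquisition", "section", "mz", "molecule")
  structure(list(peaks = peaks, positions = positions,
                 params = list(n_sections = n_sections,
                               n_molecules = n_molecules,
                               shift_sd = shift_sd,
                               dropout_rate = dropout_rate, seed = seed,
                               mz_range = mz_range, min_sep = min_sep)),
            class = "matching_sim")
}

#' Pairwise accuracy, precision and recall of a featurization
#'
#' Over all cross-section peak pairs, a pair predicted to share a feature is
#' a true positive when the two peaks truly come from the same molecule.
#' When nothing is grouped, precision is reported as 1 with a flag.
#'
#' @param sim a `matching_sim` (truth).
#' @param features feature assignment: tibble with `peak_id` and `feature`.
#' @return tibble with `accuracy`, `precision`, `recall`,
#'   `precision_defined`.
#' @export
eval_matching <- function(sim, features) {
  truth <- sim$peaks
  df <- truth %>%
    left_join(features[, c("peak_id", "feature")], by = "peak_id")
  cross_pairs <- function(group, section) {
    tab <- table(group)
    tot <- sum(choose(tab, 2))
    same_sec <- sum(choose(table(group, section), 2))
    tot - same_sec
  }
  n <- nrow(df)
  total <- cross_pairs(rep(1, n), df$section)
  pred_pos <- cross_pairs(df$feature, df$section)
  true_pos_all <- cross_pairs(df$molecule, df$section)
  tp <- cross_pairs(paste(df$feature, df$molecule), df$section)
  fp <- pred_pos - tp
  fn <- true_pos_all - tp
  tn <- total - tp - fp - fn
  precision_defined <- pred_pos > 0
  tibble(accuracy = (tp + tn) / total,
         precision = if (precision_defined) tp / pred_pos else 1,
         recall = if (true_pos_all > 0) tp / true_pos_all else 1,
         precision_defined = precision_defined)
}

#' Binning baseline for cross-section matching
#'
#' Groups peaks into fixed bins of width `2 * shift_sd` (two standard
#' deviations of the shift distribution), the conventional alignment-free
#' baseline.
#'
#' @param peaks peak tibble (`peak_id`, `mz`).
#' @param shift_sd the shift scale defining the bin width.
#' @return tibble `peak_id`, `feature`.
#' @export
bin_match_baseline <- function(peaks, shift_sd) {
  width <- 2 * shift_sd
  tibble(peak_id = peaks$peak_id,
         feature = floor(peaks$mz / width))
}

# separable Gaussian blur of a 3D array (reflected edges)
blur3 <- function(arr, sigma = c(2, 2, 1)) {
  sm1 <- function(v, s) {
    if (s <= 0) return(v)
    half <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-half, half), sd = s); kern <- kern / sum(kern)
    n <- length(v)
    reflect <- function(i) {
      i <- ifelse(i < 1, 2 - i, i)
      i <- ifelse(i > n, 2 * n - i, i)
      pmin(pmax(i, 1L), n)
    }
    pad <- v[reflect(seq(1 - half, n + half))]
    as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1):(half + n)]
  }
  for (d in 1:3) {
    arr <- apply(arr, setdiff(1:3, d), sm1, s = sigma[d])
    arr <- aperm(arr, order(c(d, setdiff(1:3, d))))
  }
  arr
}

#' Simulate the three-ellipsoid phantom
#'
#' A 3D volume holds three ellipsoids, two of them partially overlapping.
#' Every molecule is assigned to a nonempty subset of ellipsoids; pixels of
#' an assigned region draw linear intensities from a lognormal whose
#' location is itself drawn per (molecule, ellipsoid), intensities sum in
#' the overlap (creating a third intensity mode), and a low background is
#' present everywhere. 2D sections along the last axis emulate serial
#' sectioning.
#'
#' @param shape volume dimensions `c(nx, ny, n_sections)`.
#' @param n_molecules number of simulated molecules.
#' @param seed RNG seed.
#' @return a `sim_panel`: list with `truth` (long tibble `acquisition`,
#'   `section`, `compound`, `pixel`, `value` in natural-log intensity),
#'   `regions` (tibble `section`, `pixel`, `region`), `params` and
#'   `assignments`.
#' @export
simulate_ellipsoids <- function(shape = c(24, 24, 10), n_molecules = 12,
                                seed = 1) {
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  inside <- function(cx, cy, cz, rx, ry, rz) {
    ((grid$x - cx) / rx)^2 + ((grid$y - cy) / ry)^2 +
      ((grid$z - cz) / rz)^2 <= 1
  }
  e1 <- inside(nx * 0.32, ny * 0.35, nz * 0.5, nx * 0.22, ny * 0.25, nz * 0.42)
  e2 <- inside(nx * 0.5, ny * 0.55, nz * 0.5, nx * 0.24, ny * 0.26, nz * 0.45)
  e3 <- inside(nx * 0.74, ny * 0.68, nz * 0.5, nx * 0.18, ny * 0.2, nz * 0.4)
  ell <- cbind(e1, e2, e3)
  region <- ifelse(e1 & e2, 4L, ifelse(e1, 1L, ifelse(e2, 2L, ifelse(e3, 3L, 0L))))
  assignments <- purrr::map(seq_len(n_molecules), function(m) {
    which(runif(3) < c(0.5, 0.5, 0.4)) %>%
      (function(s) if (length(s) == 0) sample(3, 1) else s)
  })
  truth <- purrr::imap(assignments, function(sel, m) {
    lin <- exp(rnorm(nrow(grid), -6, 0.3))  # background floor
    for (e in sel) {
      mu <- rnorm(1, -3, 0.5)
      lin[ell[, e]] <- lin[ell[, e]] + exp(rnorm(sum(ell[, e]), mu, 0.3))
    }
    tibble(section = grid$z, compound = sprintf("mol%02d", m),
           pixel = (grid$x - 1L) + nx * (grid$y - 1L), value = log(lin))
  }) %>%
    dplyr::bind_rows() %>%
    mutate(acquisition = sprintf("S%02d", .data$section)) %>%
    select("acquisition", "section", "compound", "pixel", "value")
  regions <- tibble(section = grid$z,
                    pixel = (grid$x - 1L) + nx * (grid$y - 1L),
                    region = region)
  structure(list(truth = truth, regions = regions,
                 assignments = assignments,
                 params = list(shape = shape, n_molecules = n_molecules,
                               seed = seed)),
            class = "sim_panel")
}

#' Simulate a pattern panel of smooth ground-truth log intensities
#'
#' Generates smooth spatial patterns (Gaussian-filtered random fields over a
#' sections-by-pixels volume, a synthetic stand-in for in situ hybridization
#' reference images), pushes each field through a strictly monotone logistic
#' contrast curve so the intensity histogram is bimodal (background floor
#' plus expressing foreground, as in real ion images), min-max rescales each
#' compound to the `[-7, -1]` natural-log dynamic range typical of
#' TIC-normalized MALDI-MSI data, and labels five regions by
#' quantile-slicing an independent smooth field. Patterns vary smoothly from
#' section to section, as serial sections of one anatomy do.
#'
#' @param n_compounds number of molecules.
#' @param shape `c(nx, ny)` pixels per section.
#' @param n_sections number of sections.
#' @param seed RNG seed.
#' @param section_sigma Gaussian smoothing scale along the section axis
#'   (in sections). The default 3 makes consecutive sections nearly
#'   identical, as thin serial sections of one anatomy are; biology then
#'   varies smoothly along the series while batch distortions stay abrupt.
#' @param patterns optional list of user-supplied `nx x ny x n_sections`
#'   arrays overriding the built-in generator.
#' @return a `sim_panel` (see [simulate_ellipsoids()]).
#' @export
simulate_pattern_panel <- function(n_compounds = 20, shape = c(24, 24),
                                   n_sections = 8, seed = 1,
                                   section_sigma = 3, patterns = NULL) {
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]
  make_field <- function() {
    fld <- blur3(array(rnorm(nx * ny * n_sections), c(nx, ny, n_sections)),
                 sigma = c(3, 3, section_sigma))
    # strictly monotone logistic contrast: piles mass at a background floor
    # and a foreground plateau, giving the bimodal histogram of real images
    stats::plogis((fld - median(fld)) / (0.35 * sd(fld)))
  }
  if (is.null(patterns)) {
    patterns <- purrr::map(seq_len(n_compounds), function(i) make_field())
  }
  truth <- purrr::imap(patterns, function(fld, m) {
    rng <- range(fld)
    if (diff(rng) < 1e-12) abort("constant pattern rejected")
    val <- -7 + 6 * (fld - rng[1]) / diff(rng)  # min-max to [-7, -1]
    grid <- expand.grid(x = seq_len(nx), y = seq_len(ny),
                        z = seq_len(n_sections))
    tibble(section = grid$z, compound = sprintf("mol%02d", m),
           pixel = (grid$x - 1L) + nx * (grid$y - 1L),
           value = as.vector(val))
  }) %>%
    dplyr::bind_rows() %>%
    mutate(acquisition = sprintf("S%02d", .data$section)) %>%
    select("acquisition", "section", "compound", "pixel", "value")
  regfield <- make_field()
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(n_sections))
  qs <- quantile(regfield, probs = seq(0, 1, length.out = 6))
  regions <- tibble(section = grid$z,
                    pixel = (grid$x - 1L) + nx * (grid$y - 1L),
                    region = cut(as.vector(regfield), breaks = unique(qs),
                                 include.lowest = TRUE, labels = FALSE))
  structure(list(truth = truth, regions = regions,
                 params = list(n_compounds = length(patterns), shape = shape,
                               n_sections = n_sections, seed = seed)),
            class = "sim_panel")
}

#' Distort a ground-truth panel with factorized batch effects
#'
#' Draws acquisition factors `gamma_a` and compound factors `lambda_c` from
#' centered normals and pushes each (compound, acquisition) group through
#' the monotone quantile map that shifts the group's foreground mode by
#' `gamma_a * lambda_c` while leaving the background mode in place — the
#' generative counterpart of the correction model.
#'
#' @param panel a `sim_panel`.
#' @param gamma_sd,lambda_sd factor standard deviations.
#' @param seed RNG seed.
#' @return the `sim_panel` with `observed` (distorted long tibble) and
#'   `distortion` (drawn factors) filled in.
#' @export
apply_batch_distortion <- function(panel, gamma_sd = 0.6, lambda_sd = 0.6,
                                   seed = 1) {
  truth <- panel$truth
  set.seed(seed)
  acqs <- unique(truth$acquisition)
  comps <- unique(truth$compound)
  gam <- rnorm(length(acqs), 0, gamma_sd)
  lam <- rnorm(length(comps), 0, lambda_sd)
  # per-compound mixture description of the truth, for the quantile map
  cfit <- purrr::map(comps, function(cc) {
    fit_gmm2(truth$value[truth$compound == cc], min_pixels = 10)
  })
  names(cfit) <- comps
  obs <- truth
  if (gamma_sd > 0 || lambda_sd > 0) {
    key <- paste(truth$compound, truth$acquisition, sep = "\r")
    for (kk in unique(key)) {
      sel <- which(key == kk)
      cc <- truth$compound[sel[1]]; aa <- truth$acquisition[sel[1]]
      shift <- gam[match(aa, acqs)] * lam[match(cc, comps)]
      p <- cfit[[cc]]
      if (!p$fitted || p$single_mode || abs(shift) < 1e-12) {
        obs$value[sel] <- truth$value[sel] + shift * as.numeric(!p$fitted)
        next
      }
      q <- list(mu0 = p$mu0, mu1 = p$mu1 + shift, sigma0 = p$sigma0,
                sigma1 = p$sigma1, pi = p$pi)
      sup <- range(mix_support(p), mix_support(q))
      xg <- seq(sup[1], sup[2], length.out = 1024)
      Fx <- cummax(mix_cdf(xg, p) + seq_along(xg) * 1e-12)
      Gq <- cummax(mix_cdf(xg, q) + seq_along(xg) * 1e-12)
      u <- approx(xg, Fx, xout = truth$value[sel], rule = 2)$y
      obs$value[sel] <- approx(Gq, xg, xout = pmin(pmax(u, min(Gq)), max(Gq)),
                               ties = "ordered")$y
    }
  }
  panel$observed <- obs
  panel$distortion <- list(
    acquisitions = tibble(acquisition = acqs, gamma = gam),
    compounds = tibble(compound = comps, lambda = lam),
    gamma_sd = gamma_sd, lambda_sd = lambda_sd, seed = seed)
  panel
}

#' One-dimensional Wasserstein-1 distance between samples
#'
#' Mean absolute difference between the two empirical quantile functions on
#' a common probability grid.
#'
#' @param x,y numeric samples.
#' @param n_grid quantile grid size.
#' @return scalar distance.
#' @export
wasserstein1 <- function(x, y, n_grid = 512) {
  p <- (seq_len(n_grid) - 0.5) / n_grid
  mean(abs(quantile(x, p, names = FALSE) - quantile(y, p, names = FALSE)))
}

#' RMSE against ground truth after q-q slope rescaling
#'
#' Because different corrections leave data on different scales, a line is
#' fit to the quantile-quantile relation of corrected versus truth per
#' compound and the corrected values are rescaled by its slope before the
#' root-mean-square error is taken. Improvement is relative to the
#' uncorrected panel treated the same way.
#'
#' @param truth,corrected,uncorrected long panels sharing
#'   (`acquisition`, `compound`, `pixel`).
#' @return list with `per_compound` tibble (`rmse`, `rmse_uncorrected`,
#'   `improvement`) and overall `improvement` (percent).
#' @export
eval_rmse <- function(truth, corrected, uncorrected) {
  key <- c("acquisition", "compound", "pixel")
  j <- truth %>%
    dplyr::inner_join(corrected, by = key, suffix = c("", "_cor")) %>%
    dplyr::inner_join(uncorrected, by = key, suffix = c("", "_unc"))
  qq_rmse <- function(y, x) {
    qs <- (seq_len(256) - 0.5) / 256
    qy <- quantile(y, qs, names = FALSE); qx <- quantile(x, qs, names = FALSE)
    slope <- if (sd(qx) < 1e-12) 1 else stats::cov(qx, qy) / var(qx)
    sqrt(mean((slope * x - y)^2))
  }
  per <- j %>%
    group_by(.data$compound) %>%
    summarise(rmse = qq_rmse(.data$value, .data$value_cor),
              rmse_uncorrected = qq_rmse(.data$value, .data$value_unc),
              .groups = "drop") %>%
    mutate(improvement = 1 - .data$rmse / .data$rmse_uncorrected)
  list(per_compound = per,
       improvement = 100 * (1 - sum(per$rmse) / sum(per$rmse_uncorrected)))
}

#' Regional differential-testing error rates
#'
#' For every compound and pair of regions, a two-sided Welch t-test on the
#' pixel values belonging to each region (pooled across sections) decides a
#' call at level `alpha`; calls on the evaluated panel are scored against
#' calls made on ground truth, giving false-positive and false-negative
#' rates. Section-wise intensity distortions corrupt the pooled regional
#' distributions, which is exactly what this benchmark measures. A
#' bootstrap over sections of the truth gives the attainable lower bound on
#' both rates.
#'
#' @param truth ground-truth panel (long tibble).
#' @param panel evaluated panel (same keys).
#' @param regions tibble `section`, `pixel`, `region`.
#' @param alpha test level.
#' @param n_boot bootstrap repetitions for the lower bound (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return list with `fpr`, `fnr`, `calls` tibble and, when bootstrapped,
#'   `bound` (tibble of bootstrap `fpr`, `fnr`).
#' @export
eval_regional_tests <- function(truth, panel, regions, alpha = 0.05,
                                n_boot = 0, seed = 1) {
  region_values <- function(p) {
    p %>%
      dplyr::inner_join(regions, by = c("section", "pixel")) %>%
      filter(.data$region > 0)
  }
  calls_from <- function(rv, sections = NULL) {
    if (!is.null(sections)) {
      rv <- purrr::imap(sections, function(sc, i) {
        rv[rv$section == sc, , drop = FALSE]
      }) %>% dplyr::bind_rows()
    }
    regs <- sort(unique(rv$region))
    pairs <- t(utils::combn(regs, 2))
    purrr::map(seq_len(nrow(pairs)), function(i) {
      r1 <- pairs[i, 1]; r2 <- pairs[i, 2]
      rv %>%
        filter(.data$region %in% c(r1, r2)) %>%
        group_by(.data$compound) %>%
        summarise(p = tryCatch(
          t.test(.data$value[.data$region == r1],
                 .data$value[.data$region == r2])$p.value,
          error = function(e) 1), .groups = "drop") %>%
        mutate(pair = paste(r1, r2))
    }) %>%
      dplyr::bind_rows() %>%
      mutate(call = .data$p < alpha)
  }
  rv_truth <- region_values(truth)
  truth_calls <- calls_from(rv_truth)
  panel_calls <- calls_from(region_values(panel))
  j <- dplyr::inner_join(truth_calls, panel_calls,
                         by = c("compound", "pair"),
                         suffix = c("_truth", "_panel"))
  n_pos <- sum(j$call_truth); n_neg <- sum(!j$call_truth)
  fpr <- if (n_neg > 0) sum(!j$call_truth & j$call_panel) / n_neg else 0
  fnr <- if (n_pos > 0) sum(j$call_truth & !j$call_panel) / n_pos else 0
  out <- list(fpr = fpr, fnr = fnr, calls = j,
              fnr_defined = n_pos > 0)
  if (n_boot > 0) {
    set.seed(seed)
    secs <- unique(rv_truth$section)
    out$bound <- purrr::map(seq_len(n_boot), function(b) {
      bs <- sample(secs, length(secs), replace = TRUE)
      bc <- calls_from(rv_truth, sections = bs)
      jj <- dplyr::inner_join(truth_calls, bc, by = c("compound", "pair"),
                              suffix = c("_truth", "_boot"))
      np <- sum(jj$call_truth); nn <- sum(!jj$call_truth)
      tibble(fpr = if (nn > 0) sum(!jj$call_truth & jj$call_boot) / nn else 0,
             fnr = if (np > 0) sum(jj$call_truth & !jj$call_boot) / np else 0)
    }) %>% dplyr::bind_rows()
  }
  out
}

#' Build an intensity panel from a simulated panel's detected entries
#'
#' Applies the detection floor of MSI data: entries below `detect_floor`
#' (natural-log scale) are treated as not detected and dropped, since real
#' panels only carry detected, nonzero intensities.
#'
#' @param panel_long long tibble (`acquisition`, `section`, `compound`,
#'   `pixel`, `value`).
#' @param detect_floor log-intensity detection limit (default -Inf: keep
#'   all).
#' @return the filtered tibble.
#' @export
panel_detected <- function(panel_long, detect_floor = -Inf) {
  panel_long %>% filter(.data$value > detect_floor)
}
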