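test_that("spectra simulation honours the SNR bookkeeping and order constraint", {
  # the worked example: SNR 10 with 100 detections = 90 true + 10 noise
  sim <- simulate_spectra(n_molecules = 90, n_spectra = 20, snr = 10,
                          seed = 2)
  per <- sim$detections %>%
    dplyr::group_by(.data$spectrum) %>%
    dplyr::summarise(n_true = sum(!is.na(.data$molecule)),
                     n_noise = sum(is.na(.data$molecule)))
  expect_true(all(per$n_true == 90))
  expect_true(all(per$n_noise == 10))
  # snr = Inf: no noise at all
  sim_inf <- simulate_spectra(n_molecules = 10, n_spectra = 10, snr = Inf,
                              seed = 1)
  expect_equal(sum(is.na(sim_inf$detections$molecule)), 0)
  # within each spectrum the observed true positions preserve molecule order
  ordered <- sim_inf$detections %>%
    dplyr::filter(!is.na(.data$molecule)) %>%
    dplyr::group_by(.data$spectrum) %>%
    dplyr::summarise(ok = all(diff(.data$mz[order(.data$molecule)]) > 0))
  expect_true(all(ordered$ok))
  expect_error(simulate_spectra(5, snr = 0.5), "exceed 1")
})

test_that("mutual-information scoring is exact on canonical cases", {
  sim <- simulate_spectra(n_molecules = 6, n_spectra = 200, snr = Inf,
                          seed = 3)
  # intervals exactly covering each molecule's detections -> score 1
  iv <- sim$detections %>%
    dplyr::filter(!is.na(.data$molecule)) %>%
    dplyr::group_by(.data$molecule) %>%
    dplyr::summarise(left_mz = min(.data$mz) - 1e-9,
                     right_mz = max(.data$mz) + 1e-9) %>%
    dplyr::mutate(peak = .data$molecule)
  expect_equal(eval_peak_calling(sim, iv)$score, 1)
  # random intervals -> near zero
  set.seed(5)
  rnd <- vapply(1:20, function(s) {
    det <- sim$detections
    shuf <- det
    shuf$mz <- sample(det$mz)
    sim_shuf <- sim
    sim_shuf$detections <- shuf
    eval_peak_calling(sim_shuf, iv)$score
  }, numeric(1))
  expect_lt(mean(rnd), 0.05)
  # two molecules merged into one interval: score matches the direct
  # contingency computation
  iv_merged <- tibble::tibble(peak = 1L,
                              left_mz = min(iv$left_mz),
                              right_mz = max(iv$right_mz[2]))
  got <- eval_peak_calling(sim, dplyr::bind_rows(iv_merged, iv[-(1:2), ] %>%
                                                   dplyr::mutate(peak = .data$molecule)))
  expect_lt(got$per_molecule$mi[1], 1)
  det <- sim$detections
  asg <- msiunify:::assign_intervals(det$mz, dplyr::bind_rows(
    iv_merged, iv[-(1:2), ] %>% dplyr::mutate(peak = .data$molecule)))
  a <- !is.na(det$molecule) & det$molecule == 1
  in_pred <- !is.na(asg) & asg == got$per_molecule$predicted[1]
  manual <- msiunify:::discrete_mi(a, in_pred) / msiunify:::discrete_mi(a, a)
  expect_equal(got$per_molecule$mi[1], manual)
})

test_that("matching simulation and its seed determinism behave", {
  sim <- simulate_matching(n_sections = 6, n_molecules = 10,
                           dropout_rate = 0, seed = 4)
  counts <- table(sim$peaks$molecule)
  expect_true(all(counts == 6))
  sim2 <- simulate_matching(n_sections = 6, n_molecules = 10,
                            dropout_rate = 0, seed = 4)
  expect_equal(sim$peaks, sim2$peaks)
  expect_equal(sim$positions, sim2$positions)
})

test_that("pairwise matching metrics agree with brute-force pair counting", {
  sim <- simulate_matching(n_sections = 4, n_molecules = 6, shift_sd = 0.001,
                           dropout_rate = 0.2, seed = 5)
  set.seed(6)
  grouping <- tibble::tibble(peak_id = sim$peaks$peak_id,
                             feature = sample(1:8, nrow(sim$peaks),
                                              replace = TRUE))
  got <- eval_matching(sim, grouping)
  df <- dplyr::left_join(sim$peaks, grouping, by = "peak_id")
  pairs <- t(utils::combn(nrow(df), 2))
  cross <- df$section[pairs[, 1]] != df$section[pairs[, 2]]
  same_feat <- df$feature[pairs[, 1]] == df$feature[pairs[, 2]]
  same_mol <- df$molecule[pairs[, 1]] == df$molecule[pairs[, 2]]
  tp <- sum(cross & same_feat & same_mol)
  fp <- sum(cross & same_feat & !same_mol)
  fn <- sum(cross & !same_feat & same_mol)
  tn <- sum(cross) - tp - fp - fn
  expect_equal(got$accuracy, (tp + tn) / sum(cross))
  expect_equal(got$precision, tp / (tp + fp))
  expect_equal(got$recall, tp / (tp + fn))
  # all-singleton grouping: recall 0, precision reported 1 with flag
  singles <- tibble::tibble(peak_id = sim$peaks$peak_id,
                            feature = seq_len(nrow(sim$peaks)))
  g2 <- eval_matching(sim, singles)
  expect_equal(g2$recall, 0)
  expect_equal(g2$precision, 1)
  expect_false(g2$precision_defined)
})

test_that("the ellipsoid phantom produces the documented mode structure", {
  sp <- simulate_ellipsoids(shape = c(20, 20, 8), n_molecules = 8, seed = 7)
  expect_setequal(unique(sp$regions$region), c(0L, 1L, 2L, 3L, 4L))
  expect_gt(sum(sp$regions$region == 4), 0)  # overlap exists
  # a molecule assigned to exactly one of the overlapping ellipsoids:
  # bimodal (background + one foreground)
  single <- which(vapply(sp$assignments, function(a) identical(a, 1L),
                         logical(1)))[1]
  skip_if(is.na(single), "no single-ellipsoid molecule in this seed")
  v <- sp$truth$value[sp$truth$compound == sprintf("mol%02d", single)]
  dens <- stats::density(v)
  peaks <- sum(diff(sign(diff(dens$y))) == -2)
  expect_gte(peaks, 2)
  sp2 <- simulate_ellipsoids(shape = c(20, 20, 8), n_molecules = 8, seed = 7)
  expect_equal(sp$truth, sp2$truth)
})

test_that("pattern panels hit the [-7, -1] dynamic range and preserve order", {
  pp <- simulate_pattern_panel(n_compounds = 4, shape = c(12, 12),
                               n_sections = 6, seed = 8)
  rng <- pp$truth %>%
    dplyr::group_by(.data$compound) %>%
    dplyr::summarise(lo = min(.data$value), hi = max(.data$value))
  expect_equal(rng$lo, rep(-7, 4))
  expect_equal(rng$hi, rep(-1, 4))
  expect_setequal(unique(pp$regions$region), 1:5)
  expect_error(simulate_pattern_panel(patterns = list(array(1, c(5, 5, 4))),
                                      shape = c(5, 5), n_sections = 4),
               "constant")
})

test_that("batch distortion moves only the foreground mode and is recorded", {
  pp <- simulate_ellipsoids(shape = c(16, 16, 6), n_molecules = 6, seed = 9)
  null <- apply_batch_distortion(pp, gamma_sd = 0, lambda_sd = 0, seed = 1)
  expect_equal(null$observed$value, pp$truth$value)
  dist <- apply_batch_distortion(pp, gamma_sd = 0.8, lambda_sd = 0.8,
                                 seed = 2)
  expect_false(identical(dist$observed$value, pp$truth$value))
  expect_equal(nrow(dist$distortion$acquisitions),
               length(unique(pp$truth$acquisition)))
  # background mode barely moves: compare low quantiles
  q_lo_truth <- quantile(pp$truth$value, 0.2)
  q_lo_obs <- quantile(dist$observed$value, 0.2)
  expect_lt(abs(q_lo_truth - q_lo_obs), 0.15)
  # distortion with the same seed reproduces exactly
  dist2 <- apply_batch_distortion(pp, gamma_sd = 0.8, lambda_sd = 0.8,
                                  seed = 2)
  expect_equal(dist$observed, dist2$observed)
})

test_that("q-q rescaled RMSE evaluates corrections sensibly", {
  pp <- simulate_pattern_panel(n_compounds = 5, shape = c(10, 10),
                               n_sections = 5, seed = 10)
  truth <- pp$truth
  # corrected == truth: zero error, 100% improvement
  shifted <- truth %>% dplyr::mutate(value = .data$value - 0.8)
  out <- eval_rmse(truth, truth, shifted)
  expect_equal(out$per_compound$rmse, rep(0, 5), tolerance = 1e-10)
  expect_equal(out$improvement, 100)
  # corrected == uncorrected: zero improvement
  out2 <- eval_rmse(truth, shifted, shifted)
  expect_equal(out2$improvement, 0)
  # additive offset survives slope-only rescaling as residual error
  expect_gt(out2$per_compound$rmse[1], 0.5)
})

test_that("regional testing calibrates under label permutation and self-comparison", {
  pp <- simulate_pattern_panel(n_compounds = 10, shape = c(14, 14),
                               n_sections = 6, seed = 11)
  truth <- pp$truth
  self <- eval_regional_tests(truth, truth, pp$regions, n_boot = 0)
  expect_equal(self$fpr, 0)
  expect_equal(self$fnr, 0)
  # permuted region labels: FPR near alpha on truly null pairs
  set.seed(12)
  fprs <- vapply(1:8, function(s) {
    set.seed(100 + s)
    reg_perm <- pp$regions
    reg_perm$region <- sample(reg_perm$region)
    perm_truth <- eval_regional_tests(truth, truth, reg_perm, n_boot = 0)
    mean(perm_truth$calls$call_panel)
  }, numeric(1))
  expect_lt(mean(fprs), 0.15)
})
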