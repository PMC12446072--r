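test_that("candidate graph honours the distance, acquisition and span constraints", {
  pk <- tibble::tibble(peak_id = 1:2, acquisition = c("a", "b"),
                       section = 1:2, mz = c(500.000, 500.003))
  g <- build_match_graph(pk, t = 0.01)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$cost, 0.003)
  expect_equal(nrow(build_match_graph(pk, t = 0.002)$edges), 0)
  pk3 <- tibble::tibble(peak_id = 1:3, acquisition = c("a", "b", "c"),
                        section = 1:3, mz = c(500.001, 500.002, 500.003))
  g3 <- build_match_graph(pk3, t = 0.01, k = 1)
  expect_false(any(g3$edges$i == 1 & g3$edges$j == 3))
  # same-acquisition peaks are never candidates
  pk_same <- tibble::tibble(peak_id = 1:2, acquisition = "a", section = 1,
                            mz = c(500.000, 500.0005))
  expect_equal(nrow(build_match_graph(pk_same, t = 0.01)$edges), 0)
  expect_error(build_match_graph(pk, t = 0), "positive")
})

test_that("solve_window matches exhaustive enumeration and satisfies the constraints", {
  # chaining three acquisitions beats isolated paths when distances are small
  pk <- tibble::tibble(peak_id = 1:3, acquisition = c("a", "b", "c"),
                       section = 1:3, mz = c(500.001, 500.0015, 500.002))
  g <- build_match_graph(pk, t = 0.01, k = 2)
  sol <- solve_window(g)
  expect_equal(nrow(sol$edges), 2)
  expect_equal(sol$objective, enumerate_best(g, c("a", "b", "c")),
               tolerance = 1e-12)
  check_match_solution(sol, g)
  # two well-separated ladders stay disjoint
  pk2 <- tibble::tibble(
    peak_id = 1:6, acquisition = rep(c("a", "b", "c"), 2),
    section = rep(1:3, 2), mz = c(500.001, 500.0012, 500.0014,
                                  500.4, 500.4001, 500.4003))
  g2 <- build_match_graph(pk2, t = 0.01, k = 2)
  sol2 <- solve_window(g2)
  feats <- msiunify:::solution_features(sol2, pk2)
  expect_equal(sort(vapply(feats, length, integer(1))), c(3L, 3L))
  expect_equal(sol2$objective, enumerate_best(g2, c("a", "b", "c")),
               tolerance = 1e-12)
  # single peak: start -> peak -> end, objective 2 log(1) = 0
  pk1 <- tibble::tibble(peak_id = 1L, acquisition = "a", section = 1L,
                        mz = 500.5)
  sol1 <- solve_window(build_match_graph(pk1, t = 0.01))
  expect_equal(sol1$objective, 0)
})

test_that("solve_window equals the oracle on random small windows", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(3:7, 1)
    pk <- tibble::tibble(
      peak_id = seq_len(L),
      section = sample(1:4, L, replace = TRUE),
      mz = 500 + runif(L, 0, 0.01)) %>%
      dplyr::mutate(acquisition = paste0("s", .data$section))
    g <- build_match_graph(pk, t = 0.006, k = 2)
    ord <- paste0("s", 1:4)
    sol <- solve_window(g, order = ord)
    check_match_solution(sol, g)
    expect_equal(sol$objective, enumerate_best(g, ord), tolerance = 1e-9)
  }
})

test_that("match_dataset recovers simulated correspondences and is reproducible", {
  # well-separated molecules, mild dropout (deep double-dropout gaps would
  # break chains by the k = 2 span constraint, by design)
  sim <- simulate_matching(n_sections = 10, n_molecules = 15,
                           shift_sd = 0.002, dropout_rate = 0.05, seed = 3,
                           min_sep = 0.02)
  ft <- match_dataset(sim$peaks, t = 4 * 0.002, k = 2, n_perm = 5, seed = 1)
  # no feature holds two peaks from one acquisition
  dup <- ft %>%
    dplyr::count(.data$feature, .data$acquisition) %>%
    dplyr::filter(.data$n > 1)
  expect_equal(nrow(dup), 0)
  # every peak lands in exactly one feature
  expect_equal(sort(ft$peak_id), sort(sim$peaks$peak_id))
  m <- eval_matching(sim, ft)
  expect_gt(m$recall, 0.95)
  expect_gt(m$precision, 0.95)
  ft2 <- match_dataset(sim$peaks, t = 4 * 0.002, k = 2, n_perm = 5, seed = 1)
  expect_equal(ft, ft2)
})

test_that("noiseless matching is perfect for any positive threshold", {
  sim <- simulate_matching(n_sections = 5, n_molecules = 15, shift_sd = 0,
                           dropout_rate = 0, seed = 2)
  ft <- match_dataset(sim$peaks, t = 1e-6, k = 2, n_perm = 2, seed = 1)
  m <- eval_matching(sim, ft)
  expect_equal(m$accuracy, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("ambiguity counts extra same-acquisition peaks in feature intervals", {
  peaks <- tibble::tibble(
    peak_id = 1:5,
    acquisition = c("a", "b", "c", "a", "a"),
    section = c(1, 2, 3, 1, 1),
    mz = c(500.000, 500.001, 500.002, 500.0015, 500.2))
  feats <- tibble::tibble(feature = 1L, peak_id = 1:3,
                          mz = c(500.000, 500.001, 500.002))
  amb <- ambiguity_score(feats, peaks)
  expect_equal(amb$ambiguity, 1L)  # peak 4 is a second 'a' peak inside
  feats_clean <- tibble::tibble(feature = 1L, peak_id = 1:3,
                                mz = c(500.000, 500.0005, 500.0008))
  peaks_clean <- peaks[1:3, ] %>%
    dplyr::mutate(mz = c(500.000, 500.0005, 500.0008))
  expect_equal(ambiguity_score(feats_clean, peaks_clean)$ambiguity, 0L)
})

test_that("isotopolog consistency reproduces closed-form Jaccard distances", {
  ft <- tibble::tibble(
    feature = rep(1:2, each = 3),
    centroid_mz = rep(c(700, 700 + 1.00336), each = 3),
    acquisition = c("a", "b", "c", "a", "b", "c"),
    section = rep(1:3, 2), peak_id = 1:6, mz = 0)
  out <- isotopolog_consistency(ft)
  expect_equal(out$jaccard, 0)
  expect_equal(out$euclidean, 0)
  ft2 <- ft
  ft2$acquisition[4:6] <- c("d", "e", "f")
  out2 <- isotopolog_consistency(ft2)
  expect_equal(out2$jaccard, 1)
  expect_equal(out2$euclidean, sqrt(6))
  # random presence patterns against the direct formula
  set.seed(1)
  acqs <- paste0("s", 1:8)
  pa <- sample(acqs, 5); pb <- sample(acqs, 4)
  ftr <- dplyr::bind_rows(
    tibble::tibble(feature = 1L, centroid_mz = 800, acquisition = pa),
    tibble::tibble(feature = 2L, centroid_mz = 800 + 1.00336,
                   acquisition = pb)) %>%
    dplyr::mutate(section = 1, peak_id = dplyr::row_number(), mz = 0)
  outr <- isotopolog_consistency(ftr)
  expect_equal(outr$jaccard,
               1 - length(intersect(pa, pb)) / length(union(pa, pb)))
})

test_that("annotation picks candidates within tolerance, preferring abundance", {
  ft <- tibble::tibble(feature = 1:3,
                       centroid_mz = c(760.589, 761.620, 780.551),
                       acquisition = "a", section = 1, peak_id = 1:3, mz = 0)
  ref <- tibble::tibble(name = c("PC 34:1", "PC 34:0", "PC 36:4"),
                        mz = c(759.578, 760.590, 779.548),
                        abundance = c(10, 2, 5))
  ann <- annotate_features(ft, ref, adducts = c("[M+H]+" = 1.007276),
                           tol = 0.01)
  expect_equal(ann$name[ann$feature == 1], "PC 34:1")  # 0.004 Da away
  expect_true(is.na(ann$name[ann$feature == 2]))  # > 0.01 from everything
  expect_equal(ann$name[ann$feature == 3], "PC 36:4")
  # two references within tol: the abundant one wins
  ref2 <- tibble::tibble(name = c("lipA", "lipB"),
                         mz = c(760.586 - 1.007276, 760.592 - 1.007276),
                         abundance = c(2, 10))
  ann2 <- annotate_features(ft[1, ], ref2,
                            adducts = c("[M+H]+" = 1.007276), tol = 0.01)
  expect_equal(ann2$name, "lipB")
  # empty reference: everything unannotated
  ann3 <- annotate_features(ft, ref[0, ])
  expect_true(all(is.na(ann3$name)))
})
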