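#' Candidate graph for cross-acquisition peak matching
#'
#' Peaks from different acquisitions are candidate matches when their m/z
#' values differ by less than `t` Da and their sections lie within `k`
#' positions of one another in the series. Matching a pair costs their m/z
#' distance; leaving a peak on its own path costs two terminal edges of
#' `log(L)` each (`L` = number of peaks), so pairs are matched whenever their
#' distance beats that price.
#'
#' @param peaks tibble with columns `peak_id`, `acquisition`, `section`
#'   (integer series position) and `mz`.
#' @param t m/z distance threshold in Da (must be positive).
#' @param k maximum section-index separation for candidate edges.
#' @return a `match_graph`: list with the peak table, the candidate edge
#'   table (`i`, `j` row indices into `peaks`, `cost`) and the terminal edge
#'   cost `log(L)`.
#' @export
build_match_graph <- function(peaks, t, k = 2) {
  if (t <= 0) abort("distance threshold t must be positive")
  peaks <- as_tibble(peaks)
  L <- nrow(peaks)
  edges <- tibble(i = integer(0), j = integer(0), cost = numeric(0))
  if (L > 1) {
    ord <- order(peaks$mz)
    pr <- expand.grid(a = seq_len(L), b = seq_len(L))
    pr <- pr[pr$a < pr$b, , drop = FALSE]
    d <- abs(peaks$mz[pr$a] - peaks$mz[pr$b])
    ok <- d < t &
      peaks$acquisition[pr$a] != peaks$acquisition[pr$b] &
      abs(peaks$section[pr$a] - peaks$section[pr$b]) <= k
    edges <- tibble(i = pr$a[ok], j = pr$b[ok], cost = d[ok])
  }
  structure(list(peaks = peaks, edges = edges,
                 terminal_cost = log(max(L, 1L))),
            class = "match_graph")
}

# Min-cost bipartite matching by successive shortest augmenting paths.
# Rows are out-slots, columns in-slots; edge weights may be negative and
# augmentation stops when no path decreases the total cost, so the result is
# the minimum-cost matching over all cardinalities (optimal for the path-
# decomposition polytope, whose LP relaxation is integral).
min_cost_partial_matching <- function(n_left, n_right, edges) {
  if (nrow(edges) == 0) return(edges[0, ])
  n <- n_left + n_right + 2L
  s <- n_left + n_right + 1L; tt <- s + 1L
  from <- c(rep(s, n_left), edges$i, n_left + seq_len(n_right))
  to <- c(seq_len(n_left), n_left + edges$j, rep(tt, n_right))
  cost <- c(numeric(n_left), edges$cost, numeric(n_right))
  cap <- rep(1L, length(from))
  m <- length(from)
  # add reverse residual arcs
  ffrom <- c(from, to); fto <- c(to, from)
  fcost <- c(cost, -cost); fcap <- c(cap, integer(m))
  repeat {
    # Bellman-Ford shortest path s -> tt on arcs with residual capacity
    dist <- rep(Inf, n); dist[s] <- 0
    parent <- rep(NA_integer_, n)
    act <- fcap > 0L
    af <- ffrom[act]; at <- fto[act]; ac <- fcost[act]; aid <- which(act)
    for (iter in seq_len(n)) {
      relax <- dist[af] + ac < dist[at] - 1e-12
      if (!any(relax)) break
      # sequential relaxation to keep parents consistent
      for (e in which(relax)) {
        if (dist[af[e]] + ac[e] < dist[at[e]] - 1e-12) {
          dist[at[e]] <- dist[af[e]] + ac[e]
          parent[at[e]] <- aid[e]
        }
      }
    }
    if (!is.finite(dist[tt]) || dist[tt] >= -1e-9) break
    v <- tt
    while (v != s) {
      e <- parent[v]
      fcap[e] <- fcap[e] - 1L
      rev_e <- if (e <= m) e + m else e - m
      fcap[rev_e] <- fcap[rev_e] + 1L
      v <- ffrom[e]
    }
  }
  # matched pairs: forward matching arcs with zero remaining capacity
  arc_idx <- n_left + seq_len(nrow(edges))
  used <- fcap[arc_idx] == 0L
  edges[used, , drop = FALSE]
}

#' Solve the matching problem on one m/z window
#'
#' Minimizes the total cost of a path decomposition of the candidate graph:
#' every peak gets exactly one predecessor (a peak from an earlier
#' acquisition in the given order, or the start terminal) and one successor
#' (a later peak or the end terminal). Terminal edges cost `log(L)`.
#' Solved exactly as a minimum-cost bipartite matching between successor and
#' predecessor slots; integrality holds by construction.
#'
#' @param graph a `match_graph`.
#' @param order character vector giving the acquisition order used to direct
#'   edges (defaults to section order).
#' @return a `match_solution`: list with `edges` (selected directed pairs),
#'   `objective` (including terminal edges), and the ordering used.
#' @export
solve_window <- function(graph, order = NULL) {
  pk <- graph$peaks
  L <- nrow(pk)
  if (is.null(order)) {
    order <- unique(pk$acquisition[base::order(pk$section)])
  }
  rank <- match(pk$acquisition, order)
  ed <- graph$edges
  if (nrow(ed) > 0) {
    # direct each candidate edge from earlier to later acquisition in `order`
    swap <- rank[ed$i] > rank[ed$j]
    tmp <- ed$i[swap]; ed$i[swap] <- ed$j[swap]; ed$j[swap] <- tmp
    ed <- ed[rank[ed$i] != rank[ed$j], , drop = FALSE]
  }
  tc <- graph$terminal_cost
  ed$cost <- ed$cost - 2 * tc  # matched pair saves one start and one end edge
  sel <- min_cost_partial_matching(L, L, ed)
  sel$cost <- sel$cost + 2 * tc
  objective <- sum(sel$cost) + tc * 2 * (L - nrow(sel))
  structure(list(edges = sel, objective = objective, order = order,
                 n_peaks = L),
            class = "match_solution")
}

#' Verify the degree and adjacency constraints of a matching solution
#'
#' Independent checker: every selected edge must be a candidate edge, and no
#' peak may have more than one selected predecessor or successor (slack is
#' taken by the terminal edges).
#'
#' @param solution a `match_solution`.
#' @param graph the `match_graph` it was solved on.
#' @return TRUE invisibly; aborts with a message on violation.
#' @export
check_match_solution <- function(solution, graph) {
  ed <- solution$edges
  if (nrow(ed) > 0) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    if (!all(key(ed$i, ed$j) %in% key(graph$edges$i, graph$edges$j))) {
      abort("solution uses an edge absent from the candidate graph")
    }
    if (anyDuplicated(ed$i) || anyDuplicated(ed$j)) {
      abort("a peak has more than one selected successor or predecessor")
    }
    acq <- graph$peaks$acquisition
    if (any(acq[ed$i] == acq[ed$j])) {
      abort("matched peaks share an acquisition")
    }
  }
  invisible(TRUE)
}

# follow selected successor edges into start->...->end paths
solution_features <- function(solution, peaks) {
  L <- nrow(peaks)
  succ <- rep(NA_integer_, L)
  has_pred <- rep(FALSE, L)
  if (nrow(solution$edges) > 0) {
    succ[solution$edges$i] <- solution$edges$j
    has_pred[solution$edges$j] <- TRUE
  }
  starts <- which(!has_pred)
  purrr::map(starts, function(v) {
    path <- integer(0)
    while (!is.na(v)) { path <- c(path, v); v <- succ[v] }
    path
  })
}

#' Match peaks from many acquisitions into one feature space
#'
#' Splits the m/z axis into windows of roughly one Da (cut points snapped to
#' nearby detection-free gaps so no peak family straddles a cut), solves the
#' minimum-cost matching on each window under `n_perm` random acquisition
#' orderings, keeps the best solution per window, and reads features off the
#' start-to-end paths. Every feature holds at most one peak per acquisition.
#'
#' @param peaks tibble with `peak_id`, `acquisition`, `section`, `mz`.
#' @param t m/z distance threshold in Da; when NULL, 3x the median absolute
#'   deviation of nearest cross-section peak distances is used.
#' @param k maximum section separation for candidate edges (default 2).
#' @param n_perm number of random acquisition orderings per window.
#' @param seed RNG seed for the orderings.
#' @return a `feature_table`: tibble with one row per member peak
#'   (`feature`, `centroid_mz`, `acquisition`, `section`, `peak_id`, `mz`),
#'   features sorted by centroid m/z.
#' @export
match_dataset <- function(peaks, t = NULL, k = 2, n_perm = 10, seed = 1) {
  peaks <- as_tibble(peaks)
  if (is.null(t)) t <- 3 * estimate_shift_sd(peaks)
  set.seed(seed)
  cuts <- window_cuts(peaks$mz)
  win <- findInterval(peaks$mz, cuts)
  acqs <- unique(peaks$acquisition[base::order(peaks$section)])
  out <- purrr::map(split(seq_len(nrow(peaks)), win), function(idx) {
    wpk <- peaks[idx, , drop = FALSE]
    g <- build_match_graph(wpk, t = t, k = k)
    best <- NULL
    for (p in seq_len(max(1L, n_perm))) {
      ord <- if (p == 1L) acqs else sample(acqs)
      sol <- solve_window(g, order = ord)
      if (is.null(best) || sol$objective < best$objective - 1e-12) best <- sol
    }
    check_match_solution(best, g)
    paths <- solution_features(best, wpk)
    purrr::imap(paths, function(path, fi) {
      wpk[path, c("peak_id", "acquisition", "section", "mz")]
    }) %>%
      dplyr::bind_rows(.id = "local_feature")
  })
  feats <- dplyr::bind_rows(out, .id = "window") %>%
    mutate(feature_key = paste(.data$window, .data$local_feature)) %>%
    group_by(.data$feature_key) %>%
    mutate(centroid_mz = mean(.data$mz)) %>%
    ungroup() %>%
    arrange(.data$centroid_mz, .data$section) %>%
    mutate(feature = match(.data$feature_key, unique(.data$feature_key))) %>%
    select("feature", "centroid_mz", "acquisition", "section", "peak_id",
           "mz")
  class(feats) <- c("feature_table", class(feats))
  feats
}

# nominal 1-Da cuts snapped to the nearest detection-free gap within +/- 0.1
window_cuts <- function(mz) {
  lo <- floor(min(mz)); hi <- ceiling(max(mz))
  if (lo + 1 > hi - 1) return(lo)
  nominal <- seq(lo + 1, hi - 1, by = 1)
  if (length(nominal) == 0) return(lo)
  smz <- sort(mz)
  snapped <- vapply(nominal, function(ct) {
    near <- smz[smz > ct - 0.1 & smz < ct + 0.1]
    if (length(near) == 0) return(ct)
    pts <- sort(unique(c(ct - 0.1, near, ct + 0.1)))
    gaps <- diff(pts)
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    mids[which.max(gaps)]  # widest detection-free gap near the nominal cut
  }, numeric(1))
  c(lo, snapped)
}

# per-peak mass-shift scale from nearest-neighbour cross-section distances
estimate_shift_sd <- function(peaks) {
  nn <- purrr::map_dbl(seq_len(nrow(peaks)), function(i) {
    other <- peaks$mz[peaks$acquisition != peaks$acquisition[i]]
    if (length(other) == 0) return(NA_real_)
    min(abs(other - peaks$mz[i]))
  })
  stats::mad(nn, na.rm = TRUE) + stats::median(nn, na.rm = TRUE)
}

#' Ambiguity score of matched features
#'
#' For each feature, counts how many extra same-acquisition peaks fall inside
#' the feature's m/z interval (the range of its member m/z values): evidence
#' that the interval spans more than one ion species.
#'
#' @param features a `feature_table`.
#' @param peaks the full peak table the features were matched from.
#' @return tibble with `feature` and `ambiguity` (sum over acquisitions of
#'   peaks beyond the single expected one).
#' @export
ambiguity_score <- function(features, peaks) {
  features %>%
    group_by(.data$feature) %>%
    summarise(lo = min(.data$mz), hi = max(.data$mz), .groups = "drop") %>%
    purrr::pmap(function(feature, lo, hi) {
      inside <- peaks[peaks$mz >= lo & peaks$mz <= hi, , drop = FALSE]
      cnt <- table(inside$acquisition)
      tibble(feature = feature, ambiguity = sum(pmax(0L, cnt - 1L)))
    }) %>%
    dplyr::bind_rows()
}

#' Isotopolog (M, M+1) presence consistency
#'
#' Pairs features whose centroids differ by one neutron substitution
#' (about 1.00336 Da for 13C) and compares their presence patterns across
#' acquisitions: a faithful featurization detects both isotopologs of an
#' abundant compound in the same acquisitions, giving low Jaccard and
#' Euclidean distances between the two binary presence vectors.
#'
#' @param features a `feature_table`.
#' @param delta isotopolog spacing in Da.
#' @param tol matching tolerance on the spacing, Da.
#' @return tibble with one row per (M, M+1) pair: centroids, `jaccard` and
#'   `euclidean` distances between presence vectors.
#' @export
isotopolog_consistency <- function(features, delta = 1.00336, tol = 0.01) {
  acqs <- sort(unique(features$acquisition))
  cent <- features %>%
    group_by(.data$feature) %>%
    summarise(centroid_mz = .data$centroid_mz[1], .groups = "drop")
  presence <- function(f) as.integer(acqs %in%
                                       features$acquisition[features$feature == f])
  pairs <- tidyr::expand_grid(m = cent$feature, m1 = cent$feature) %>%
    mutate(d = cent$centroid_mz[match(.data$m1, cent$feature)] -
             cent$centroid_mz[match(.data$m, cent$feature)]) %>%
    filter(abs(.data$d - delta) < tol)
  if (nrow(pairs) == 0) {
    inform("no isotopolog partners found within tolerance")
    return(tibble(feature_m = integer(0), feature_m1 = integer(0),
                  jaccard = numeric(0), euclidean = numeric(0)))
  }
  purrr::map2(pairs$m, pairs$m1, function(a, b) {
    va <- presence(a); vb <- presence(b)
    un <- sum(va | vb)
    tibble(feature_m = a, feature_m1 = b,
           jaccard = if (un == 0) 0 else 1 - sum(va & vb) / un,
           euclidean = sqrt(sum((va - vb)^2)))
  }) %>% dplyr::bind_rows()
}

#' Default adduct mass offsets (positive mode), Da
#' @export
default_adducts <- function() {
  c("[M+H]+" = 1.007276, "[M+Na]+" = 22.989218, "[M+K]+" = 38.963158,
    "[M+H-H2O]+" = -17.003289, "[M+NH4]+" = 18.033823)
}

#' Annotate feature centroids against a reference m/z list
#'
#' Each feature centroid is compared with every adduct-expanded reference
#' mass; candidates within `tol` Da are considered, and among candidates the
#' most abundant reference wins when abundances are supplied (else the
#' nearest mass). Features without a candidate stay unannotated.
#'
#' @param features a `feature_table`.
#' @param reference tibble with `name`, `mz` and optionally `abundance`.
#' @param adducts named numeric vector of mass offsets (Da).
#' @param tol matching tolerance in Da (default 0.01).
#' @return tibble `feature`, `centroid_mz`, `name`, `adduct`, `delta_mz`
#'   (NA name where unannotated).
#' @export
annotate_features <- function(features, reference,
                              adducts = default_adducts(), tol = 0.01) {
  cent <- features %>%
    group_by(.data$feature) %>%
    summarise(centroid_mz = .data$centroid_mz[1], .groups = "drop")
  if (is.null(reference) || nrow(reference) == 0) {
    return(cent %>% mutate(name = NA_character_, adduct = NA_character_,
                           delta_mz = NA_real_))
  }
  expanded <- tidyr::expand_grid(ref = seq_len(nrow(reference)),
                                 adduct = names(adducts)) %>%
    mutate(mass = reference$mz[.data$ref] + adducts[.data$adduct],
           name = reference$name[.data$ref],
           abundance = if ("abundance" %in% names(reference))
             reference$abundance[.data$ref] else 1)
  purrr::pmap(cent, function(feature, centroid_mz) {
    d <- abs(expanded$mass - centroid_mz)
    cand <- which(d < tol)
    if (length(cand) == 0) {
      return(tibble(feature = feature, centroid_mz = centroid_mz,
                    name = NA_character_, adduct = NA_character_,
                    delta_mz = NA_real_))
    }
    best <- cand[order(-expanded$abundance[cand], d[cand])][1]
    tibble(feature = feature, centroid_mz = centroid_mz,
           name = expanded$name[best], adduct = expanded$adduct[best],
           delta_mz = expanded$mass[best] - centroid_mz)
  }) %>% dplyr::bind_rows()
}
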