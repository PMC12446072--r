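#' Detection-frequency histogram of an acquisition
#'
#' Counts, for every m/z grid column, the number of pixels with a nonzero
#' entry. The peak caller operates on this histogram, not on intensities:
#' mass-shift structure shows up as clusters of detection counts.
#'
#' @param acq an `msi_acquisition`.
#' @return a `freq_histogram`: list with `counts` (integer vector over the
#'   grid), `smoothed` (NULL until [smooth_histogram()] is applied),
#'   `grid_step`, `mz_min`.
#' @export
build_frequency_histogram <- function(acq) {
  stopifnot(inherits(acq, "msi_acquisition"))
  S <- methods::as(acq$S, "CsparseMatrix")
  counts <- diff(S@p)  # nonzeros per column; stored values are > 0
  structure(list(counts = as.numeric(counts), smoothed = NULL,
                 bandwidth = NA_real_, grid_step = acq$meta$grid_step,
                 mz_min = acq$meta$mz_range[1]),
            class = "freq_histogram")
}

#' Smooth a detection-frequency histogram with a Gaussian kernel
#'
#' The bandwidth should reflect the instrument's mass accuracy: detections of
#' one ion species scatter over roughly that scale, so smoothing at it merges
#' them into a single histogram mode without bridging distinct species.
#'
#' @param f a `freq_histogram`.
#' @param bandwidth kernel standard deviation in Da (default 1e-3 Da).
#' @return the histogram with `smoothed` filled in.
#' @export
smooth_histogram <- function(f, bandwidth = 1e-3) {
  stopifnot(inherits(f, "freq_histogram"))
  if (bandwidth <= 0) abort("bandwidth must be positive")
  sigma <- bandwidth / f$grid_step
  if (bandwidth < f$grid_step) {
    warn("bandwidth below grid step: smoothing is near-identity")
  }
  half <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(f$counts)
  padded <- c(numeric(half), f$counts, numeric(half))
  sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
  f$smoothed <- as.numeric(sm[(half + 1):(half + n)])
  f$bandwidth <- bandwidth
  f
}

#' Locate peak centers by descending-threshold watershed
#'
#' Sweeps a threshold from the histogram maximum toward zero; at each level
#' the maximal contiguous runs of bins above the threshold are examined, and
#' every run not yet containing a center contributes one new center, the
#' run's argmax bin (ties broken toward lower m/z). With the threshold
#' schedule taken over the sorted distinct histogram values, this sweep adds
#' a center exactly when a new superlevel-set component is born, i.e. at
#' every local maximum (plateaus counted once); the implementation exploits
#' that equivalence and runs in linear time.
#'
#' @param f a `freq_histogram` with `smoothed` filled (the raw counts are
#'   used when no smoothing was applied).
#' @param min_count background level of event counts: local maxima at or
#'   below it are not seeded (default 0, the printed threshold floor).
#' @return integer vector of 0-based center bins, sorted.
#' @export
find_peak_centers <- function(f, min_count = 0) {
  v <- histogram_values(f)
  n <- length(v)
  if (n == 0 || all(v == 0)) return(integer(0))
  # collapse exact-value plateaus, then test each plateau against neighbours
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])   # -Inf: array edge counts as descent
  right <- c(r$values[-1], -Inf)
  is_max <- r$values > left & r$values > right & r$values > 0 &
    r$values > min_count
  sort(starts[is_max] - 1L)
}

histogram_values <- function(f) {
  stopifnot(inherits(f, "freq_histogram"))
  if (is.null(f$smoothed)) f$counts else f$smoothed
}

#' Expand peak centers into m/z intervals
#'
#' From each center the left and right boundaries walk outward while the
#' histogram keeps descending, equal-value plateaus included, so each
#' interval covers one histogram mode down to its surrounding valleys (or
#' across detection-free stretches until the next mode's flank rises). A
#' hard cap of `max_halfwidth` Da guards against runaway expansion over
#' flat noise, and a positive `min_count` additionally stops expansion when
#' the histogram falls below that background level of event counts.
#' Adjacent intervals may share their single valley bin.
#'
#' @param centers 0-based center bins from [find_peak_centers()].
#' @param f the same `freq_histogram`.
#' @param min_count background detection level below which expansion stops
#'   (default 0: expansion stops only at local minima, the cap, or the
#'   array edges).
#' @param max_halfwidth cap on each side of the interval, in Da.
#' @return tibble with one row per center: `center`, `left`, `right`
#'   (0-based bins, `left <= center <= right`).
#' @export
expand_boundaries <- function(centers, f, min_count = 0, max_halfwidth = 0.5) {
  v <- histogram_values(f)
  n <- length(v)
  cap <- max(1L, floor(max_halfwidth / f$grid_step))
  one <- function(m) {
    i <- m + 1L  # 1-based
    l <- i - 1L
    while (l > 1L && (i - l) < cap && v[l] >= min_count && v[l] >= v[l - 1L]) {
      l <- l - 1L
    }
    l <- max(l, 1L)
    r <- i + 1L
    while (r < n && (r - i) < cap && v[r] >= min_count && v[r] >= v[r + 1L]) {
      r <- r + 1L
    }
    r <- min(r, n)
    c(l - 1L, r - 1L)
  }
  bounds <- vapply(as.integer(centers), one, integer(2))
  tibble(center = as.integer(centers),
         left = bounds[1, ], right = bounds[2, ])
}

#' Integrate called intervals into ion images
#'
#' For every called interval the per-pixel signal is summed across the
#' interval's grid columns, yielding one image per peak. The reference m/z of
#' a peak is the most frequent detection within its interval, i.e. the argmax
#' of the unsmoothed counts.
#'
#' @param acq an `msi_acquisition`.
#' @param boundaries tibble from [expand_boundaries()].
#' @param f optional `freq_histogram` (recomputed when missing) used for the
#'   reference m/z.
#' @return an `ion_image_stack`.
#' @export
extract_images <- function(acq, boundaries, f = NULL) {
  stopifnot(inherits(acq, "msi_acquisition"))
  if (is.null(f)) f <- build_frequency_histogram(acq)
  step <- acq$meta$grid_step
  mz0 <- acq$meta$mz_range[1]
  C <- nrow(boundaries)
  if (C == 0) {
    values <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(nrow(acq$S), 0L))
    peaks <- tibble(peak = integer(0), center = integer(0), left = integer(0),
                    right = integer(0), left_mz = numeric(0),
                    right_mz = numeric(0), reference_mz = numeric(0))
    return(new_ion_image_stack(values, peaks, acq$meta))
  }
  cols <- purrr::map2(boundaries$left, boundaries$right, ~ seq(.x + 1L, .y + 1L))
  values <- do.call(cbind, purrr::map(cols, function(idx) {
    Matrix::rowSums(acq$S[, idx, drop = FALSE])
  }))
  values <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  ref_bin <- purrr::map2_int(boundaries$left, boundaries$right, function(l, r) {
    idx <- seq(l + 1L, r + 1L)
    idx[which.max(f$counts[idx])] - 1L
  })
  peaks <- boundaries %>%
    mutate(
      peak = dplyr::row_number(),
      left_mz = mz0 + .data$left * step,
      right_mz = mz0 + (.data$right + 1L) * step,
      reference_mz = mz0 + (ref_bin + 0.5) * step
    ) %>%
    select("peak", "center", "left", "right", "left_mz", "right_mz",
           "reference_mz")
  new_ion_image_stack(values, peaks, acq$meta)
}

#' Total-ion-content normalization
#'
#' Divides each pixel's image intensities by that pixel's total, so every
#' pixel with signal sums to 1 across peaks. All-zero pixels are left alone.
#'
#' @param stack an `ion_image_stack`.
#' @return the normalized stack.
#' @export
tic_normalize <- function(stack) {
  stopifnot(inherits(stack, "ion_image_stack"))
  tot <- Matrix::rowSums(stack$values)
  scale <- ifelse(tot > 0, 1 / tot, 0)
  stack$values <- Matrix::Diagonal(x = scale) %*% stack$values
  stack$values <- methods::as(stack$values, "CsparseMatrix")
  stack
}

#' Call peaks for one acquisition
#'
#' Convenience wrapper running the full single-acquisition path: frequency
#' histogram, Gaussian smoothing, watershed centers, boundary expansion and
#' image extraction, optionally TIC-normalized.
#'
#' @inheritParams build_frequency_histogram
#' @inheritParams smooth_histogram
#' @inheritParams expand_boundaries
#' @param tic whether to TIC-normalize the extracted images.
#' @return an `ion_image_stack` whose `peaks` table lists the called
#'   intervals.
#' @export
call_peaks <- function(acq, bandwidth = 1e-3, min_count = 0,
                       max_halfwidth = 0.5, tic = TRUE) {
  f <- smooth_histogram(build_frequency_histogram(acq), bandwidth)
  centers <- find_peak_centers(f, min_count = min_count)
  B <- expand_boundaries(centers, f, min_count = min_count,
                         max_halfwidth = max_halfwidth)
  stack <- extract_images(acq, B, f)
  if (tic) stack <- tic_normalize(stack)
  stack
}

#' Presence filter for features across sections
#'
#' Keeps features detected in at least `pixel_frac` of pixels in at least
#' `section_frac` of sections; defaults (15% of pixels, 80% of sections)
#' suit serial-section atlases.
#'
#' @param presence a tibble with columns `feature`, `section`, `pixel_frac`
#'   (fraction of that section's pixels where the feature is nonzero), or a
#'   features-by-sections numeric matrix of pixel fractions.
#' @param pixel_frac,section_frac thresholds.
#' @return tibble with columns `feature` and `keep`.
#' @export
filter_features <- function(presence, pixel_frac = 0.15, section_frac = 0.8) {
  if (is.matrix(presence)) {
    feats <- rownames(presence) %||% as.character(seq_len(nrow(presence)))
    presence <- as_tibble(presence, .name_repair = "minimal") %>%
      mutate(feature = feats) %>%
      tidyr::pivot_longer(-"feature", names_to = "section",
                          values_to = "pixel_frac")
  }
  pf <- pixel_frac
  sf <- section_frac
  presence %>%
    group_by(.data$feature) %>%
    summarise(keep = mean(.data$pixel_frac >= pf) >= sf, .groups = "drop")
}
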