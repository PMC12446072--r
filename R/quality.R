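#' Spatial-chaos score of an ion image
#'
#' Partitions image intensities into `n_levels` equal-count quantile levels
#' and measures, per level, how far the connected-structure sizes depart
#' from the scattered-singleton expectation of noise: a level whose pixels
#' form one blob scores near 1, a level of isolated pixels scores near 0.
#' The score is the mean over occupied levels and is invariant to global
#' intensity scaling. Constant images score 0 (no structure is
#' distinguishable).
#'
#' @param image numeric matrix.
#' @param n_levels number of quantile levels (default 8).
#' @return score in `[0, 1]`.
#' @export
spatial_chaos <- function(image, n_levels = 8) {
  v <- as.vector(image)
  if (length(unique(v)) < 2) return(0)
  qs <- unique(quantile(v, probs = seq(0, 1, length.out = n_levels + 1)))
  lev <- cut(v, breaks = qs, include.lowest = TRUE, labels = FALSE)
  scores <- vapply(sort(unique(lev)), function(l) {
    mask <- matrix(lev == l, nrow(image), ncol(image))
    np <- sum(mask)
    if (np == 0) return(NA_real_)
    nc <- max(EBImage::bwlabel(mask))
    1 - nc / np
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

# grid of small Gaussian bumps spanning the image
bump_basis <- function(shape, sigma = 2, spacing = 4) {
  nr <- shape[1]; nc <- shape[2]
  centers <- expand.grid(r = seq(spacing / 2, nr, by = spacing),
                         c = seq(spacing / 2, nc, by = spacing))
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  X <- vapply(seq_len(nrow(centers)), function(k) {
    as.vector(exp(-((rr - centers$r[k])^2 + (cc - centers$c[k])^2) /
                    (2 * sigma^2)))
  }, numeric(nr * nc))
  X
}

#' Structured-signal test via a Poisson bump-basis GLM
#'
#' Fits a Poisson-family generalized linear model of the (scaled, rounded)
#' image on a grid of small Gaussian bumps spanning the raster and compares
#' it with an intercept-only null by a deviance ratio test. Because the
#' image is rescaled to a fixed count range (making the score invariant to
#' global intensity scaling, at the price of an unknown dispersion), the
#' deviance drop is tested against the full model's estimated dispersion
#' with an F reference rather than a raw chi-square. Images with spatial
#' structure load on the bumps and reject the null; noise does not.
#'
#' @param image non-negative numeric matrix.
#' @param sigma,spacing bump standard deviation and grid spacing in pixels.
#' @return list with `stat` (deviance-ratio F statistic) and `p` (F test
#'   p-value).
#' @export
noise_model_score <- function(image, sigma = 2, spacing = 4) {
  mx <- max(image)
  if (mx <= 0 || sd(as.vector(image)) < 1e-12) return(list(stat = 0, p = 1))
  y <- round(100 * as.vector(image) / mx)
  X <- bump_basis(dim(image), sigma, spacing)
  fit <- tryCatch(
    suppressWarnings(glm(y ~ X, family = stats::quasipoisson())),
    error = function(e) NULL)
  if (is.null(fit)) return(list(stat = 0, p = 1))
  null <- suppressWarnings(glm(y ~ 1, family = stats::quasipoisson()))
  df1 <- max(1, fit$df.null - fit$df.residual)
  df2 <- max(1, fit$df.residual)
  disp <- max(sum(stats::residuals(fit, "pearson")^2) / df2, 1e-8)
  stat <- max(0, null$deviance - fit$deviance) / (df1 * disp)
  list(stat = stat, p = stats::pf(stat, df1, df2, lower.tail = FALSE))
}

#' Low- to high-frequency power ratio of an image
#'
#' 2D FFT energy below a radial-frequency cutoff (fraction of Nyquist,
#' default 0.25) divided by the energy above it, DC excluded. Smooth images
#' give large ratios; stripe artifacts from line-scanning concentrate energy
#' at high frequency and give small ratios. Constant images return `Inf`
#' (all energy at DC).
#'
#' @param image numeric matrix.
#' @param cutoff radial cutoff as a fraction of Nyquist.
#' @return ratio (possibly `Inf`).
#' @export
power_spectrum_ratio <- function(image, cutoff = 0.25) {
  nr <- nrow(image); nc <- ncol(image)
  sp <- Mod(stats::fft(image))^2
  fr <- c(seq(0, floor(nr / 2)), seq(ceiling(nr / 2) - 1, 1)) / floor(nr / 2)
  fc <- c(seq(0, floor(nc / 2)), seq(ceiling(nc / 2) - 1, 1)) / floor(nc / 2)
  rad <- sqrt(outer(fr^2, fc^2, `+`))
  dc <- rad == 0
  low <- sum(sp[!dc & rad < cutoff])
  high <- sum(sp[!dc & rad >= cutoff])
  if (high < 1e-12 * max(low, 1)) return(Inf)
  low / high
}

#' Fraction of ion images aggregating multiple species
#'
#' An image is flagged aggregated when, in more than `pixel_frac` of its
#' contributing pixels, the pixel's detections inside the image's m/z
#' interval fall into two or more clusters separated by empty grid runs of
#' more than `min_gap` bins: a single ion species leaves one detection
#' cluster per spectrum.
#'
#' @param acq the `msi_acquisition` the images came from.
#' @param peaks the `peaks` table of the called stack (needs `left`,
#'   `right` 0-based grid bounds).
#' @param pixel_frac flagging threshold on the fraction of multi-cluster
#'   pixels (default 0.1).
#' @param min_gap cluster separation in grid bins.
#' @return list with `fraction` (of images flagged) and `per_image` tibble.
#' @export
aggregated_fraction <- function(acq, peaks, pixel_frac = 0.1, min_gap = 3) {
  if (nrow(peaks) == 0) return(list(fraction = 0, per_image = tibble()))
  per <- purrr::pmap(peaks[, c("peak", "left", "right")],
                     function(peak, left, right) {
    n_multi <- 0L; n_contrib <- 0L
    sub <- acq$S[, seq(left + 1L, right + 1L), drop = FALSE]
    sub <- methods::as(sub, "TsparseMatrix")
    if (length(sub@i) > 0) {
      by_pixel <- split(sub@j, sub@i)
      n_contrib <- length(by_pixel)
      n_multi <- sum(vapply(by_pixel, function(cols) {
        cols <- sort(cols)
        any(diff(cols) > min_gap)
      }, logical(1)))
    }
    tibble(peak = peak, n_contrib = n_contrib, n_multi = n_multi,
           aggregated = n_contrib > 0 && n_multi / n_contrib > pixel_frac)
  }) %>% dplyr::bind_rows()
  list(fraction = mean(per$aggregated), per_image = per)
}

#' Monte-Carlo calibration of quality thresholds
#'
#' Simulates noise-only images and takes per-metric reference quantiles as
#' pass thresholds: a reproducible surrogate for manual threshold setting.
#'
#' @param shape image shape used for calibration.
#' @param n_sim number of noise images.
#' @param seed RNG seed.
#' @return named list `chaos` (95th noise percentile), `noise_p` (5th
#'   percentile of the noise-model p under noise), `power` (95th noise
#'   percentile of the power ratio).
#' @export
calibrate_qc_thresholds <- function(shape = c(32, 32), n_sim = 50, seed = 1) {
  set.seed(seed)
  mets <- purrr::map(seq_len(n_sim), function(i) {
    img <- matrix(runif(prod(shape)), shape[1], shape[2])
    tibble(chaos = spatial_chaos(img),
           noise_p = noise_model_score(img)$p,
           power = power_spectrum_ratio(img))
  }) %>% dplyr::bind_rows()
  list(chaos = quantile(mets$chaos, 0.95, names = FALSE),
       noise_p = quantile(mets$noise_p, 0.05, names = FALSE),
       power = quantile(mets$power, 0.95, names = FALSE))
}

#' Quality report for a set of ion images
#'
#' Scores every image on the three quality metrics and flags passes against
#' the supplied thresholds (an image passes when it beats all three noise
#' references).
#'
#' @param images named list of numeric matrices.
#' @param thresholds output of [calibrate_qc_thresholds()].
#' @return tibble per image with the three scores and `pass`.
#' @export
qc_report <- function(images, thresholds = calibrate_qc_thresholds()) {
  purrr::imap(images, function(img, nm) {
    nms <- noise_model_score(img)
    tibble(image = nm, chaos = spatial_chaos(img), noise_stat = nms$stat,
           noise_p = nms$p, power = power_spectrum_ratio(img))
  }) %>%
    dplyr::bind_rows() %>%
    mutate(pass = .data$chaos > thresholds$chaos &
             .data$noise_p < thresholds$noise_p &
             .data$power > thresholds$power)
}
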