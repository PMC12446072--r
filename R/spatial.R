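#' Rook-adjacency spatial weights for a pixel lattice
#'
#' Row-standardized rook (4-neighbour) weights over the pixels of a raster,
#' restricted to a tissue mask when given.
#'
#' @param shape integer `c(rows, cols)`.
#' @param mask optional logical matrix of the same shape; FALSE pixels are
#'   excluded.
#' @return list with `W` (sparse row-standardized weight matrix over kept
#'   pixels) and `keep` (linear indices of kept pixels, column-major).
#' @export
rook_weights <- function(shape, mask = NULL) {
  nr <- shape[1]; nc <- shape[2]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  idx <- matrix(NA_integer_, nr, nc)
  keep <- which(mask)
  idx[keep] <- seq_along(keep)
  pairs <- list()
  rc <- arrayInd(keep, c(nr, nc))
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- rc[, 1] + d[1]; c2 <- rc[, 2] + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    pairs[[length(pairs) + 1]] <-
      cbind(idx[keep][ok], idx[cbind(r2[ok], c2[ok])])
  }
  pr <- do.call(rbind, pairs)
  n <- length(keep)
  Wb <- Matrix::sparseMatrix(i = c(pr[, 1], pr[, 2]),
                             j = c(pr[, 2], pr[, 1]),
                             x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(Wb)
  W <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% Wb
  list(W = methods::as(W, "CsparseMatrix"), keep = keep)
}

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I of a pixel image under row-standardized rook weights.
#' With row standardization the statistic reduces to `z' W z / z' z` for the
#' centered values `z`.
#'
#' @param image numeric matrix (or vector when `weights` is supplied).
#' @param weights optional precomputed [rook_weights()] result; computed
#'   from the image shape otherwise.
#' @param mask optional logical tissue mask.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(image, weights = NULL, mask = NULL) {
  if (is.null(weights)) {
    stopifnot(is.matrix(image))
    weights <- rook_weights(dim(image), mask)
  }
  v <- if (is.matrix(image)) image[weights$keep] else image
  z <- v - mean(v)
  denom <- sum(z^2)
  if (denom < 1e-12) abort("Moran's I is undefined for a constant image")
  as.numeric((z %*% (weights$W %*% z)) / denom)
}

#' Null distribution of Moran's I under TIC-stratified permutation
#'
#' Pixels are stratified into quantile bins of their total ion count and
#' values are shuffled only within strata, so the null preserves the
#' TIC-driven baseline structure of the tissue while destroying the
#' molecule-specific pattern. Strata of size 1 are merged with a neighbour.
#'
#' @param image numeric matrix.
#' @param tic numeric matrix of per-pixel total ion counts, same shape.
#' @param n_strata number of TIC-quantile strata (default 8).
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param weights,mask as in [morans_i()].
#' @return numeric vector of `n_perm` Moran's I values.
#' @export
stratified_null <- function(image, tic, n_strata = 8, n_perm = 100,
                            seed = 1, weights = NULL, mask = NULL) {
  if (is.null(weights)) weights <- rook_weights(dim(image), mask)
  v <- image[weights$keep]
  tv <- tic[weights$keep]
  strata <- stratify_tic(tv, n_strata)
  set.seed(seed)
  groups <- split(seq_along(v), strata)
  vapply(seq_len(n_perm), function(i) {
    sv <- v
    for (gidx in groups) sv[gidx] <- sv[sample(gidx)]
    morans_i(sv, weights = weights)
  }, numeric(1))
}

stratify_tic <- function(tv, n_strata) {
  if (n_strata <= 1) return(rep(1L, length(tv)))
  qs <- quantile(tv, probs = seq(0, 1, length.out = n_strata + 1))
  strata <- cut(tv, breaks = unique(qs), include.lowest = TRUE,
                labels = FALSE)
  # merge singleton strata into their lower neighbour
  repeat {
    tab <- table(strata)
    small <- as.integer(names(tab)[tab < 2])
    if (length(small) == 0) break
    inform(sprintf("merging stratum %d (size < 2) with its neighbour", small[1]))
    target <- if (small[1] > min(strata)) small[1] - 1L else small[1] + 1L
    strata[strata == small[1]] <- target
  }
  strata
}

#' Screen images for significant spatial structure
#'
#' For each image the observed Moran's I is compared with its TIC-stratified
#' permutation null via a one-sided z test (structure shows as positive
#' autocorrelation); p-values are Bonferroni-adjusted over the tested set
#' and images with adjusted p below `alpha` are flagged significant. When a
#' null has zero spread the empirical exceedance p `(1 + #{null >= obs}) /
#' (1 + N)` is used instead.
#'
#' @param images named list of numeric matrices (or a single matrix).
#' @param tic total-ion-count matrix shared by the images.
#' @param n_strata,n_perm,seed as in [stratified_null()].
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @param mask optional tissue mask.
#' @return tibble per image: `image`, `observed_i`, `null_mean`, `null_sd`,
#'   `z`, `p_value`, `p_adjusted`, `significant`.
#' @export
spatial_informative_test <- function(images, tic, n_strata = 8,
                                     n_perm = 100, alpha = 0.01, seed = 1,
                                     mask = NULL) {
  if (is.matrix(images)) images <- list(image = images)
  if (is.null(names(images))) names(images) <- seq_along(images)
  weights <- rook_weights(dim(images[[1]]), mask)
  res <- purrr::imap(images, function(img, nm) {
    obs <- morans_i(img, weights = weights)
    null <- stratified_null(img, tic, n_strata = n_strata, n_perm = n_perm,
                            seed = seed, weights = weights)
    mu <- mean(null); sdv <- sd(null)
    if (sdv > 1e-12) {
      z <- (obs - mu) / sdv
      p <- pnorm(z, lower.tail = FALSE)
    } else {
      z <- NA_real_
      p <- (1 + sum(null >= obs)) / (1 + length(null))
    }
    tibble(image = nm, observed_i = obs, null_mean = mu, null_sd = sdv,
           z = z, p_value = p)
  }) %>% dplyr::bind_rows()
  res %>%
    mutate(p_adjusted = pmin(1, .data$p_value * dplyr::n()),
           significant = .data$p_adjusted < alpha)
}
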