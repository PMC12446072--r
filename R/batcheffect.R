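#' Empirical batch-effect matrix and its low-rank diagnostic
#'
#' Ad hoc estimator of foreground-mode intensity shifts that motivates the
#' factorized model. It assumes (i) the observed background mode equals the
#' true background mode and (ii) biology varies smoothly along consecutive
#' sections, so high-frequency deviations of the foreground mode between
#' neighboring sections are technical. For each compound `c` and section
#' `a`, with naive mode estimates `m1`, `m0`:
#' `delta_c = mean_a(m1 - m0)`; the smooth biological trend
#' `y_ac = mean(m1 over sections within 2 of a) - mean(m1 over all other
#' sections)`; and the batch-effect matrix `M_ca = m1 - m0 - delta_c - y_ac`.
#' If distortions factorize as an acquisition term times a compound term,
#' `M` is close to rank one; the fraction of squared singular-value energy
#' captured by the first singular value quantifies this, and a bootstrap
#' over compounds gives its variability.
#'
#' @param fits tibble of naive mixture fits (from [fit_naive_gmms()]`$fits`)
#'   with columns `compound`, `acquisition`, `mu0`, `mu1`; plus a `section`
#'   column or an `ordering` argument.
#' @param ordering optional character vector of acquisitions in section
#'   order (defaults to the order of `section` if present).
#' @param window half-width of the local smoothing window in sections.
#' @param n_boot,boot_frac bootstrap repetitions and compound fraction for
#'   the first-singular-value variance.
#' @param seed RNG seed for the bootstrap.
#' @return a `batch_effect_matrix`: list with `M` (compounds x sections),
#'   `singular_values`, `rank1_fraction`, `boot` (tibble of bootstrap first
#'   singular values) and `norm` (Frobenius norm of `M`).
#' @export
estimate_batch_effect_matrix <- function(fits, ordering = NULL, window = 2,
                                         n_boot = 50, boot_frac = 0.8,
                                         seed = 1) {
  if (is.null(ordering)) {
    if (!"section" %in% names(fits)) {
      abort("supply `ordering` or a `section` column")
    }
    ordering <- fits %>%
      dplyr::distinct(.data$acquisition, .data$section) %>%
      arrange(.data$section) %>%
      dplyr::pull(.data$acquisition)
  }
  A <- length(ordering)
  if (A < 5) abort("need at least 5 consecutive sections for the smoothing window")
  comps <- unique(fits$compound)
  C <- length(comps)
  m1 <- m0 <- matrix(NA_real_, C, A, dimnames = list(comps, ordering))
  ai <- match(fits$acquisition, ordering)
  ci <- match(fits$compound, comps)
  ok <- !is.na(ai) & !is.na(ci) & fits$fitted & !fits$single_mode
  m1[cbind(ci[ok], ai[ok])] <- fits$mu1[ok]
  m0[cbind(ci[ok], ai[ok])] <- fits$mu0[ok]
  keep <- rowSums(is.na(m1)) == 0
  if (sum(keep) < 2) abort("too few compounds with complete mode estimates")
  m1 <- m1[keep, , drop = FALSE]; m0 <- m0[keep, , drop = FALSE]
  delta_hat <- rowMeans(m1 - m0)
  y_hat <- matrix(NA_real_, nrow(m1), A)
  for (a in seq_len(A)) {
    loc <- seq(max(1, a - window), min(A, a + window))
    y_hat[, a] <- rowMeans(m1[, loc, drop = FALSE]) -
      rowMeans(m1[, -loc, drop = FALSE])
  }
  M <- m1 - m0 - delta_hat - y_hat
  sv <- svd(M, nu = 0, nv = 0)$d
  rank1 <- sv[1]^2 / sum(sv^2)
  set.seed(seed)
  nb <- max(2, round(boot_frac * nrow(M)))
  boot <- tibble(rep = seq_len(n_boot),
                 sv1 = purrr::map_dbl(seq_len(n_boot), function(i) {
                   rows <- sample(nrow(M), nb)
                   svd(M[rows, , drop = FALSE], nu = 0, nv = 0)$d[1]
                 }))
  structure(list(M = M, singular_values = sv, rank1_fraction = rank1,
                 boot = boot, norm = sqrt(sum(M^2))),
            class = "batch_effect_matrix")
}

#' @export
print.batch_effect_matrix <- function(x, ...) {
  cat(sprintf(
    "<batch_effect_matrix> %d compounds x %d sections; rank-1 energy %.1f%%; ||M|| = %.3f\n",
    nrow(x$M), ncol(x$M), 100 * x$rank1_fraction, x$norm))
  invisible(x)
}

#' @method glance batch_effect_matrix
#' @export
glance.batch_effect_matrix <- function(x, ...) {
  tibble(n_compounds = nrow(x$M), n_sections = ncol(x$M),
         rank1_fraction = x$rank1_fraction, frobenius_norm = x$norm,
         sv1 = x$singular_values[1], sv1_boot_sd = sd(x$boot$sv1))
}

#' @method autoplot batch_effect_matrix
#' @export
autoplot.batch_effect_matrix <- function(object, ...) {
  df <- as_tibble(object$M, .name_repair = "minimal") %>%
    mutate(compound = rownames(object$M) %||%
             as.character(seq_len(nrow(object$M)))) %>%
    tidyr::pivot_longer(-"compound", names_to = "section",
                        values_to = "shift")
  ggplot(df, aes(.data$section, .data$compound, fill = .data$shift)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "section", y = "compound", fill = "shift") +
    theme_minimal()
}
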