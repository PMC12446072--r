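# Two-component Gaussian mixture helpers shared by the normalization code.
mix_pdf <- function(x, p) {
  p$pi * dnorm(x, p$mu1, p$sigma1) + (1 - p$pi) * dnorm(x, p$mu0, p$sigma0)
}
mix_cdf <- function(x, p) {
  p$pi * pnorm(x, p$mu1, p$sigma1) + (1 - p$pi) * pnorm(x, p$mu0, p$sigma0)
}
mix_support <- function(p, k = 4) {
  c(min(p$mu0 - k * p$sigma0, p$mu1 - k * p$sigma1),
    max(p$mu0 + k * p$sigma0, p$mu1 + k * p$sigma1))
}

#' Naive per-group two-component Gaussian mixture fits
#'
#' Fits an unconstrained two-component mixture to every (compound,
#' acquisition) group of log intensities. These fits seed the hierarchical
#' model and fix its empirical hyperparameters: `m0` (prior center of the
#' background mean) is the median of the fitted background means, and the
#' exponential rate `s` for the spread components is the reciprocal of the
#' mean fitted foreground s.d.
#'
#' @param panel long tibble with columns `acquisition`, `compound`, `pixel`,
#'   `value` (natural-log TIC-normalized intensities of detected entries).
#' @param min_pixels groups with fewer detected pixels are left unfitted.
#' @return list with `fits` (tibble per group: `mu0`, `mu1`, `sigma0`,
#'   `sigma1`, `pi`, `fitted`, `single_mode`), `m0` and `s`.
#' @export
fit_naive_gmms <- function(panel, min_pixels = 50) {
  fits <- panel %>%
    group_by(.data$compound, .data$acquisition) %>%
    summarise(fit = list(fit_gmm2(.data$value, min_pixels)), .groups = "drop") %>%
    tidyr::unnest_wider("fit")
  ok <- fits$fitted & !fits$single_mode
  m0 <- median(fits$mu0[ok], na.rm = TRUE)
  s <- 1 / mean(fits$sigma1[ok], na.rm = TRUE)
  list(fits = fits, m0 = m0, s = s)
}

# EM fit of a 2-Gaussian mixture via mclust, with degenerate fallbacks.
fit_gmm2 <- function(x, min_pixels = 50) {
  na <- list(mu0 = NA_real_, mu1 = NA_real_, sigma0 = NA_real_,
             sigma1 = NA_real_, pi = NA_real_, fitted = FALSE,
             single_mode = FALSE)
  if (length(x) < min_pixels) return(na)
  if (sd(x) < 1e-8) {
    return(list(mu0 = mean(x), mu1 = mean(x), sigma0 = 1e-3, sigma1 = 1e-3,
                pi = 0, fitted = TRUE, single_mode = TRUE))
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu0 = mean(x), mu1 = mean(x), sigma0 = sd(x), sigma1 = sd(x),
                pi = 0, fitted = TRUE, single_mode = TRUE))
  }
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  pr <- fit$parameters$pro
  lo <- which.min(mu); hi <- which.max(mu)
  sep <- abs(mu[hi] - mu[lo]) > 1.5 * min(sg)
  list(mu0 = unname(mu[lo]), mu1 = unname(mu[hi]), sigma0 = unname(sg[lo]),
       sigma1 = unname(sg[hi]), pi = unname(pr[hi]), fitted = TRUE,
       single_mode = !sep)
}

sigmoid <- function(u) 1 / (1 + exp(-u))
logit <- function(p) log(p / (1 - p))

#' MAP fit of the hierarchical batch-effect model
#'
#' Log intensities of each (compound, acquisition) group follow a
#' two-Gaussian mixture whose foreground mean sits at
#' `mu1 = mu0 + gamma_a * lambda_c + delta_c`: the displacement of the
#' foreground mode factorizes into an acquisition effect `gamma_a` and a
#' compound susceptibility `lambda_c`, on top of the compound's intrinsic
#' mode separation `delta_c`. Foreground spread is `sigma1 = Sigma_a +
#' Sigma_c`. Priors: `delta_c ~ N(3, 1)`, `gamma_a, lambda_c ~ U(-2, 2)`,
#' `Sigma ~ Exp(s)`, `sigma0_c ~ U(0.05, 0.5)`, `mu0_ac ~ N(m0, 1)`, mixture
#' weight `~ Beta(0.5, 0.5)`. Latent pixel labels are marginalized
#' analytically; the log posterior is maximized by Adam on unconstrained
#' reparameterized coordinates (log-Jacobian terms included), warm-started
#' from the naive mixture fits.
#'
#' @param panel long tibble (`acquisition`, `compound`, `pixel`, `value`).
#' @param naive optional result of [fit_naive_gmms()]; computed when NULL.
#' @param effect structure of the foreground displacement: `"bilinear"`
#'   (`gamma * lambda`, the full model) or the ablations `"additive"`
#'   (`gamma + lambda`), `"acquisition"` (`gamma` only), `"compound"`
#'   (`lambda` only).
#' @param n_steps maximum Adam steps.
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization jitter.
#' @param tol,patience convergence: stop when the relative change of the log
#'   posterior over `patience` steps drops below `tol`.
#' @return an object of class `msi_hier_fit` with per-acquisition,
#'   per-compound and per-group parameter tables, the log-posterior trace
#'   and a convergence flag.
#' @export
fit_hierarchical_map <- function(panel, naive = NULL,
                                 effect = c("bilinear", "additive",
                                            "acquisition", "compound"),
                                 n_steps = 4000, lr = 0.02, seed = 1,
                                 tol = 1e-6, patience = 200) {
  effect <- match.arg(effect)
  acqs <- unique(panel$acquisition)
  if (length(acqs) < 2) abort("need at least 2 acquisitions")
  comps <- unique(panel$compound)
  A <- length(acqs); C <- length(comps)
  if (is.null(naive)) naive <- fit_naive_gmms(panel)
  m0 <- naive$m0; s_rate <- naive$s
  if (!is.finite(m0)) m0 <- median(panel$value)
  if (!is.finite(s_rate)) s_rate <- 2

  ai <- match(panel$acquisition, acqs)
  ci <- match(panel$compound, comps)
  g <- (ci - 1L) * A + ai  # group id in column-major (A x C) layout
  xv <- panel$value
  ng <- A * C

  # --- initialization from the naive fits ---------------------------------
  set.seed(seed)
  fits <- naive$fits
  fits$ai <- match(fits$acquisition, acqs)
  fits$ci <- match(fits$compound, comps)
  mu0_init <- matrix(m0, A, C)
  pi_init <- matrix(0.5, A, C)
  d_init <- rep(3, C); s0_init <- rep(0.2, C)
  ok <- fits$fitted & !fits$single_mode
  for (r in which(ok)) {
    mu0_init[fits$ai[r], fits$ci[r]] <- fits$mu0[r]
    pi_init[fits$ai[r], fits$ci[r]] <- min(max(fits$pi[r], 0.05), 0.95)
  }
  for (cc in seq_len(C)) {
    rows <- which(ok & fits$ci == cc)
    if (length(rows) > 0) {
      d_init[cc] <- median(fits$mu1[rows] - fits$mu0[rows])
      s0_init[cc] <- min(max(median(fits$sigma0[rows]), 0.06), 0.45)
    }
  }
  sig1_bar <- mean(fits$sigma1[ok])
  if (!is.finite(sig1_bar) || sig1_bar <= 0) sig1_bar <- 0.5

  upar <- list(
    g = rnorm(A, 0, 0.1),                       # gamma in (-2, 2)
    l = rnorm(C, 0, 0.1),                       # lambda in (-2, 2)
    d = d_init,                                 # delta
    Sa = rep(log(sig1_bar / 2), A),             # Sigma_a > 0
    Sc = rep(log(sig1_bar / 2), C),             # Sigma_c > 0
    s0 = logit(pmin(pmax((s0_init - 0.05) / 0.45, 0.02), 0.98)),
    mu0 = mu0_init,                             # A x C
    pi = logit(pi_init)                         # A x C
  )

  shape <- purrr::map(upar, length)
  flatten <- function(p) unlist(p, use.names = FALSE)
  unflatten <- function(v) {
    out <- list(); i <- 1L
    for (nm in names(shape)) {
      out[[nm]] <- v[i:(i + shape[[nm]] - 1L)]
      i <- i + shape[[nm]]
    }
    out$mu0 <- matrix(out$mu0, A, C)
    out$pi <- matrix(out$pi, A, C)
    out
  }

  effect_term <- function(gam, lam) {
    switch(effect,
           bilinear = outer(gam, lam),
           additive = outer(gam, lam, function(a, b) a + b),
           acquisition = matrix(gam, A, C),
           compound = matrix(lam, A, C, byrow = TRUE))
  }

  obj_grad <- function(uv) {
    u <- unflatten(uv)
    sg <- sigmoid(u$g); gam <- -2 + 4 * sg
    sl <- sigmoid(u$l); lam <- -2 + 4 * sl
    del <- u$d
    Sa <- exp(u$Sa); Sc <- exp(u$Sc)
    ss0 <- sigmoid(u$s0); sig0 <- 0.05 + 0.45 * ss0
    mu0 <- u$mu0
    spi <- sigmoid(u$pi); piM <- 0.998 * spi + 0.001
    mu1 <- mu0 + effect_term(gam, lam) + matrix(del, A, C, byrow = TRUE)
    sig1 <- outer(Sa, Sc, `+`)
    sig0M <- matrix(sig0, A, C, byrow = TRUE)

    m1g <- mu1[g]; s1g <- sig1[g]; m0g <- mu0[g]; s0g <- sig0M[g]; pg <- piM[g]
    lN1 <- dnorm(xv, m1g, s1g, log = TRUE)
    lN0 <- dnorm(xv, m0g, s0g, log = TRUE)
    a1 <- log(pg) + lN1; a0 <- log(1 - pg) + lN0
    mx <- pmax(a1, a0)
    lmix <- mx + log(exp(a1 - mx) + exp(a0 - mx))
    r <- exp(a1 - lmix)
    loglik <- sum(lmix)

    # per-observation partials, then group scatter into A x C matrices
    gsum <- function(v) {
      out <- numeric(ng)
      tmp <- rowsum(v, g)
      out[as.integer(rownames(tmp))] <- tmp
      matrix(out, A, C)
    }
    d_mu1 <- gsum(r * (xv - m1g) / s1g^2)
    d_sig1 <- gsum(r * ((xv - m1g)^2 / s1g^3 - 1 / s1g))
    d_mu0l <- gsum((1 - r) * (xv - m0g) / s0g^2)
    d_sig0 <- gsum((1 - r) * ((xv - m0g)^2 / s0g^3 - 1 / s0g))
    d_pi <- gsum((exp(lN1 - lmix) - exp(lN0 - lmix)))

    # priors (uniform supports contribute only via the Jacobians below)
    logprior <- sum(dnorm(del, 3, 1, log = TRUE)) +
      sum(log(s_rate) - s_rate * Sa) + sum(log(s_rate) - s_rate * Sc) +
      sum(dnorm(mu0, m0, 1, log = TRUE)) +
      sum(-0.5 * log(piM) - 0.5 * log(1 - piM)) - ng * lbeta(0.5, 0.5)

    d_mu0 <- d_mu1 + d_mu0l - (mu0 - m0)
    d_del <- colSums(d_mu1) - (del - 3)
    d_gam <- switch(effect,
                    bilinear = as.vector(d_mu1 %*% lam),
                    additive = rowSums(d_mu1),
                    acquisition = rowSums(d_mu1),
                    compound = numeric(A))
    d_lam <- switch(effect,
                    bilinear = as.vector(t(d_mu1) %*% gam),
                    additive = colSums(d_mu1),
                    acquisition = numeric(C),
                    compound = colSums(d_mu1))
    d_Sa <- rowSums(d_sig1) - s_rate
    d_Sc <- colSums(d_sig1) - s_rate
    d_s0 <- colSums(d_sig0)
    d_piM <- d_pi - 0.5 / piM + 0.5 / (1 - piM)

    # chain to unconstrained coordinates; add log-Jacobian value + gradient
    logjac <- sum(log(4) + log(sg) + log(1 - sg)) +
      sum(log(4) + log(sl) + log(1 - sl)) +
      sum(u$Sa) + sum(u$Sc) +
      sum(log(0.45) + log(ss0) + log(1 - ss0)) +
      sum(log(0.998) + log(spi) + log(1 - spi))
    gr <- list(
      g = d_gam * 4 * sg * (1 - sg) + (1 - 2 * sg),
      l = d_lam * 4 * sl * (1 - sl) + (1 - 2 * sl),
      d = d_del,
      Sa = d_Sa * Sa + 1,
      Sc = d_Sc * Sc + 1,
      s0 = d_s0 * 0.45 * ss0 * (1 - ss0) + (1 - 2 * ss0),
      mu0 = d_mu0,
      pi = d_piM * 0.998 * spi * (1 - spi) + (1 - 2 * spi)
    )
    list(value = loglik + logprior + logjac, grad = flatten(gr))
  }

  # --- Adam ascent ---------------------------------------------------------
  v <- flatten(upar)
  mAd <- numeric(length(v)); vAd <- numeric(length(v))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(0)
  best <- -Inf; best_v <- v
  converged <- FALSE
  for (step in seq_len(n_steps)) {
    og <- obj_grad(v)
    trace[step] <- og$value
    if (og$value > best) { best <- og$value; best_v <- v }
    gvec <- og$grad
    mAd <- b1 * mAd + (1 - b1) * gvec
    vAd <- b2 * vAd + (1 - b2) * gvec^2
    mh <- mAd / (1 - b1^step); vh <- vAd / (1 - b2^step)
    v <- v + lr * mh / (sqrt(vh) + eps)
    if (step > patience) {
      rel <- abs(trace[step] - trace[step - patience]) /
        max(1, abs(trace[step]))
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    warn("MAP optimization stopped at n_steps without meeting the convergence tolerance; returning best-seen parameters")
  }
  u <- unflatten(best_v)
  gam <- -2 + 4 * sigmoid(u$g); lam <- -2 + 4 * sigmoid(u$l)
  del <- u$d; Sa <- exp(u$Sa); Sc <- exp(u$Sc)
  sig0 <- 0.05 + 0.45 * sigmoid(u$s0)
  mu0 <- u$mu0; piM <- 0.998 * sigmoid(u$pi) + 0.001

  # gauge fixing: only the displacement term is identified
  if (effect == "bilinear") {
    sdg <- sd(gam)
    if (is.finite(sdg) && sdg > 1e-8) { gam <- gam / sdg; lam <- lam * sdg }
    if (mean(lam) < 0) { gam <- -gam; lam <- -lam }
  } else if (effect %in% c("additive", "acquisition")) {
    mg <- mean(gam); gam <- gam - mg; del <- del + mg
  }
  mu1 <- mu0 + effect_term(gam, lam) + matrix(del, A, C, byrow = TRUE)
  sig1 <- outer(Sa, Sc, `+`)

  has_data <- matrix(FALSE, A, C)
  has_data[unique(g)] <- TRUE
  groups <- tidyr::expand_grid(ci = seq_len(C), ai = seq_len(A)) %>%
    mutate(compound = comps[.data$ci], acquisition = acqs[.data$ai],
           mu0 = mu0[cbind(.data$ai, .data$ci)],
           mu1 = mu1[cbind(.data$ai, .data$ci)],
           sigma0 = sig0[.data$ci],
           sigma1 = sig1[cbind(.data$ai, .data$ci)],
           pi = piM[cbind(.data$ai, .data$ci)],
           has_data = has_data[cbind(.data$ai, .data$ci)]) %>%
    select(-"ci", -"ai")
  structure(list(
    acquisitions = tibble(acquisition = acqs, gamma = gam, Sigma_a = Sa),
    compounds = tibble(compound = comps, lambda = lam, delta = del,
                       Sigma_c = Sc, sigma0 = sig0),
    groups = groups,
    effect = effect, m0 = m0, s = s_rate,
    logpost = trace, converged = converged
  ), class = "msi_hier_fit")
}

#' @export
print.msi_hier_fit <- function(x, ...) {
  cat(sprintf(
    "<msi_hier_fit> %s displacement, %d acquisitions x %d compounds; log-posterior %.2f (%s)\n",
    x$effect, nrow(x$acquisitions), nrow(x$compounds),
    tail(x$logpost, 1), if (x$converged) "converged" else "max steps"))
  invisible(x)
}

#' @method tidy msi_hier_fit
#' @export
tidy.msi_hier_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$acquisitions %>%
      tidyr::pivot_longer(-"acquisition", names_to = "term") %>%
      mutate(level = "acquisition", unit = .data$acquisition) %>%
      select("level", "unit", "term", "value"),
    x$compounds %>%
      tidyr::pivot_longer(-"compound", names_to = "term") %>%
      mutate(level = "compound", unit = as.character(.data$compound)) %>%
      select("level", "unit", "term", "value")
  )
}

#' @method glance msi_hier_fit
#' @export
glance.msi_hier_fit <- function(x, ...) {
  tibble(effect = x$effect, n_acquisitions = nrow(x$acquisitions),
         n_compounds = nrow(x$compounds), log_posterior = tail(x$logpost, 1),
         n_steps = length(x$logpost), converged = x$converged)
}

#' @method autoplot msi_hier_fit
#' @export
autoplot.msi_hier_fit <- function(object, ...) {
  df <- tibble(step = seq_along(object$logpost), log_posterior = object$logpost)
  ggplot(df, aes(.data$step, .data$log_posterior)) +
    geom_line() +
    labs(x = "Adam step", y = "log posterior") +
    theme_minimal()
}

#' Per-compound reference distribution
#'
#' The acquisition-free reference each group is mapped onto: a two-Gaussian
#' mixture whose parameters are the across-acquisition means of the fitted
#' group parameters (restricted to acquisitions where the compound was
#' observed).
#'
#' @param fit an `msi_hier_fit`.
#' @return tibble per compound: `mu0`, `mu1`, `sigma0`, `sigma1`, `pi`.
#' @export
reference_distribution <- function(fit) {
  fit$groups %>%
    filter(.data$has_data) %>%
    group_by(.data$compound) %>%
    summarise(mu0 = mean(.data$mu0), mu1 = mean(.data$mu1),
              sigma0 = mean(.data$sigma0), sigma1 = mean(.data$sigma1),
              pi = mean(.data$pi), .groups = "drop")
}

#' Monotone intensity-correction transforms
#'
#' For every (compound, acquisition) with data, builds the quantile-matching
#' map `T^-1 = F_ref^-1(G_obs(x))` between the fitted observed mixture CDF
#' `G_obs` and the compound's reference CDF `F_ref`, evaluated numerically on
#' a grid spanning 4 s.d. beyond both mixtures' supports and interpolated
#' linearly (clamped outside the grid).
#'
#' @param fit an `msi_hier_fit`.
#' @param reference optional output of [reference_distribution()].
#' @param n_grid grid resolution.
#' @return a `transform_map`: tibble with list-columns `x_grid`, `y_grid`
#'   per (compound, acquisition).
#' @export
build_transforms <- function(fit, reference = NULL, n_grid = 2048) {
  if (is.null(reference)) reference <- reference_distribution(fit)
  obs <- fit$groups %>% filter(.data$has_data)
  out <- purrr::pmap(obs, function(compound, acquisition, mu0, mu1, sigma0,
                                   sigma1, pi, has_data) {
    op <- list(mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
               pi = pi)
    rp <- as.list(reference[reference$compound == compound, ])
    sup_o <- mix_support(op); sup_r <- mix_support(rp)
    xg <- seq(min(sup_o[1], sup_r[1]), max(sup_o[2], sup_r[2]),
              length.out = n_grid)
    Gx <- mix_cdf(xg, op)
    Fr <- mix_cdf(xg, rp)
    # numeric inversion of the reference CDF, kept strictly monotone
    Fr <- cummax(Fr + seq_along(Fr) * 1e-12)
    yg <- approx(x = Fr, y = xg, xout = pmin(pmax(Gx, min(Fr)), max(Fr)),
                 ties = "ordered")$y
    yg <- cummax(yg)
    tibble(compound = compound, acquisition = acquisition,
           x_grid = list(xg), y_grid = list(yg))
  }) %>% dplyr::bind_rows()
  class(out) <- c("transform_map", class(out))
  out
}

#' Apply correction transforms to an intensity panel
#'
#' Element-wise monotone transformation of each (compound, acquisition)
#' group; the missing-entry pattern is untouched (no imputation). Groups
#' without a transform are passed through unchanged with a warning.
#'
#' @param panel long tibble (`acquisition`, `compound`, `pixel`, `value`).
#' @param transforms a `transform_map` from [build_transforms()].
#' @return the panel with `value` replaced by the corrected value.
#' @export
apply_normalization <- function(panel, transforms) {
  key <- paste(panel$compound, panel$acquisition, sep = "\r")
  tkey <- paste(transforms$compound, transforms$acquisition, sep = "\r")
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    warn(sprintf("%d (compound, acquisition) groups have no transform; left unchanged",
                 length(unique(key[is.na(idx)]))))
  }
  out <- panel$value
  for (tk in unique(idx[!is.na(idx)])) {
    sel <- which(idx == tk)
    out[sel] <- approx(transforms$x_grid[[tk]], transforms$y_grid[[tk]],
                       xout = panel$value[sel], rule = 2)$y
  }
  panel$value <- out
  panel
}

#' Correct a panel end to end with the hierarchical model
#'
#' Runs naive fits, the MAP fit, reference construction, transform building
#' and application in one call.
#'
#' @inheritParams fit_hierarchical_map
#' @param ... passed to [fit_hierarchical_map()].
#' @return list with `panel` (corrected), `fit`, `transforms`.
#' @export
normalize_panel <- function(panel, ...) {
  naive <- fit_naive_gmms(panel)
  fit <- fit_hierarchical_map(panel, naive = naive, ...)
  tr <- build_transforms(fit)
  list(panel = apply_normalization(panel, tr), fit = fit, transforms = tr,
       naive = naive)
}

#' Baseline corrections: per-group z-normalization and location/scale
#'
#' Simple non-reference baselines for comparison. `normalize_z()` z-scores
#' each (compound, acquisition) group. `normalize_location_scale()`
#' additionally maps every group back onto its compound's pooled location
#' and scale (a normality-assuming adjuster in the spirit of ComBat, without
#' its empirical-Bayes shrinkage).
#'
#' @param panel long tibble (`acquisition`, `compound`, `pixel`, `value`).
#' @return the panel with corrected `value`.
#' @export
normalize_z <- function(panel) {
  panel %>%
    group_by(.data$compound, .data$acquisition) %>%
    mutate(value = (.data$value - mean(.data$value)) /
             max(sd(.data$value), 1e-8)) %>%
    ungroup()
}

#' @rdname normalize_z
#' @export
normalize_location_scale <- function(panel) {
  panel %>%
    group_by(.data$compound) %>%
    mutate(.m = mean(.data$value), .s = max(sd(.data$value), 1e-8)) %>%
    group_by(.data$compound, .data$acquisition) %>%
    mutate(value = .data$.m + .data$.s *
             (.data$value - mean(.data$value)) / max(sd(.data$value), 1e-8)) %>%
    ungroup() %>%
    select(-".m", -".s")
}
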