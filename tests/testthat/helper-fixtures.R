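# in-code fixtures shared across the suite

# tibble of spectrum records for a tiny synthetic acquisition
make_records <- function(n = 200, mz_range = c(500, 501), shape = c(8, 10),
                         seed = 1) {
  set.seed(seed)
  tibble::tibble(
    mz = runif(n, mz_range[1], mz_range[2]),
    intensity = rexp(n) + 0.01,
    x = sample(0:(shape[1] - 1), n, replace = TRUE),
    y = sample(0:(shape[2] - 1), n, replace = TRUE)
  )
}

# freq_histogram carrying arbitrary values, for algorithm unit tests
make_histogram <- function(values, grid_step = 1) {
  structure(list(counts = values, smoothed = NULL, bandwidth = NA_real_,
                 grid_step = grid_step, mz_min = 0),
            class = "freq_histogram")
}

# literal descending-threshold sweep (printed watershed loop): independent
# oracle for find_peak_centers
sweep_centers_oracle <- function(v) {
  centers <- integer(0)
  runs_above <- function(t) {
    r <- rle(v > t)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  if (all(v == 0)) return(integer(0))
  thresholds <- sort(unique(v), decreasing = TRUE)
  centers <- which.max(v)
  for (t in c(thresholds[-1], 0)) {
    rr <- runs_above(t)
    if (length(rr) == 0) next
    for (q in seq_len(nrow(rr))) {
      idx <- seq(rr[q, 1], rr[q, 2])
      if (!any(centers %in% idx)) {
        centers <- c(centers, idx[which.max(v[idx])])
      }
    }
  }
  sort(centers - 1L)
}

# minimal continuous-layout imzML + ibd writer (64-bit floats), built at
# test time so the repo stays text-only
write_test_imzml <- function(path_stem, spectra) {
  ibd <- paste0(path_stem, ".ibd")
  imzml <- paste0(path_stem, ".imzML")
  con <- file(ibd, "wb")
  offsets <- list()
  pos <- 0
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
    offsets[[i]] <- list(mz_off = pos, n = length(sp$mz))
    pos <- pos + 8 * length(sp$mz)
    writeBin(as.numeric(sp$intensity), con, size = 8, endian = "little")
    offsets[[i]]$int_off <- pos
    pos <- pos + 8 * length(sp$intensity)
  }
  close(con)
  spec_xml <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]; off <- offsets[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d">',
      '<scanList count="1"><scan>',
      '<cvParam accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam accession="MS:1000514" name="m/z array"/>',
      '<cvParam accession="MS:1000523" name="64-bit float"/>',
      '<cvParam accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray><cvParam accession="MS:1000515" name="intensity array"/>',
      '<cvParam accession="MS:1000523" name="64-bit float"/>',
      '<cvParam accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1, i, sp$x, sp$y, off$mz_off, off$n, off$int_off, off$n)
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml">',
    '<run><spectrumList>',
    spec_xml,
    '</spectrumList></run></mzML>'), imzml)
  imzml
}

# small bimodal intensity panel drawn from the hierarchical generative
# model with known factors
make_model_panel <- function(n_acq = 4, n_comp = 8, n_px = 300, seed = 1,
                             gamma = NULL, lambda = NULL, delta = NULL) {
  set.seed(seed)
  # acquisition factors are centered in-sample: only deviations from the
  # shared mean are identifiable as batch effect (the common component is
  # indistinguishable from the compound's mode separation)
  if (is.null(gamma)) { gamma <- rnorm(n_acq, 0, 0.8); gamma <- gamma - mean(gamma) }
  # susceptibilities are predominantly positive and non-negligible, as the
  # observed foreground-mode shifts of real matrix and analyte ions are
  if (is.null(lambda)) lambda <- rnorm(n_comp, 0.8, 0.3)
  if (is.null(delta)) delta <- rnorm(n_comp, 3, 0.5)
  # background modes are stable across acquisitions (a stated premise of
  # the correction model and of its empirical diagnostic)
  mu0 <- matrix(rnorm(n_comp, -6, 0.3), n_acq, n_comp, byrow = TRUE)
  sigma0 <- runif(n_comp, 0.15, 0.3)
  # foreground spread is a compound property here; acquisition-level spread
  # differences would be unremovable-yet-flattened nuisance in the
  # counterfactual comparison
  sigma1 <- outer(rep(0.2, n_acq), rexp(n_comp, 8) + 0.15, `+`) / 2
  # like the backgrounds, detection fractions are a compound property with
  # only mild acquisition-level jitter in serial sections
  pimix <- matrix(runif(n_comp, 0.35, 0.65), n_acq, n_comp, byrow = TRUE) +
    matrix(rnorm(n_acq * n_comp, 0, 0.01), n_acq, n_comp)
  pimix <- pmin(pmax(pimix, 0.05), 0.95)
  rows <- list()
  for (a in seq_len(n_acq)) for (cc in seq_len(n_comp)) {
    mu1 <- mu0[a, cc] + gamma[a] * lambda[cc] + delta[cc]
    z <- runif(n_px) < pimix[a, cc]
    val <- ifelse(z, rnorm(n_px, mu1, sigma1[a, cc]),
                  rnorm(n_px, mu0[a, cc], sigma0[cc]))
    rows[[length(rows) + 1]] <- tibble::tibble(
      acquisition = sprintf("A%02d", a), section = a,
      compound = sprintf("c%02d", cc), pixel = seq_len(n_px) - 1L,
      value = val,
      # paired counterfactual without the batch term: foreground pixels
      # shifted back by gamma_a * lambda_c
      value_truth = val - z * gamma[a] * lambda[cc])
  }
  list(panel = dplyr::bind_rows(rows),
       truth = list(gamma = gamma, lambda = lambda, delta = delta,
                    mu0 = mu0, sigma0 = sigma0, sigma1 = sigma1, pi = pimix))
}

# exhaustive oracle: best total cost over all valid path decompositions,
# i.e. over all subsets of directed candidate edges with in/out degree <= 1
enumerate_best <- function(graph, order) {
  pk <- graph$peaks
  L <- nrow(pk)
  rank <- match(pk$acquisition, order)
  ed <- graph$edges
  if (nrow(ed) > 0) {
    swap <- rank[ed$i] > rank[ed$j]
    tmp <- ed$i[swap]; ed$i[swap] <- ed$j[swap]; ed$j[swap] <- tmp
    ed <- ed[rank[ed$i] != rank[ed$j], , drop = FALSE]
  }
  tc <- graph$terminal_cost
  best <- 2 * tc * L  # all isolated
  m <- nrow(ed)
  if (m > 0) {
    for (mask in 1:(2^m - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (anyDuplicated(ed$i[sel]) || anyDuplicated(ed$j[sel])) next
      obj <- sum(ed$cost[sel]) + 2 * tc * (L - length(sel))
      if (obj < best) best <- obj
    }
  }
  best
}

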