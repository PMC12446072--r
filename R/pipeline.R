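#' Extract one peak image as a raster matrix
#'
#' @param stack an `ion_image_stack`.
#' @param peak peak id (row of `stack$peaks`).
#' @return numeric matrix of shape `raster_shape`.
#' @export
image_matrix <- function(stack, peak) {
  col <- match(peak, stack$peaks$peak)
  if (is.na(col)) abort("unknown peak id")
  v <- as.numeric(stack$values[, col])
  matrix(v, nrow = stack$meta$raster_shape[1],
         ncol = stack$meta$raster_shape[2], byrow = TRUE)
}

#' Assemble a cross-acquisition intensity panel from matched features
#'
#' For every feature and member acquisition, takes the member peak's
#' TIC-normalized image from that acquisition's stack and keeps the natural
#' log of its nonzero (detected) entries.
#'
#' @param stacks named list of `ion_image_stack` objects (TIC-normalized),
#'   names matching the feature table's `acquisition` values.
#' @param features a `feature_table` from [match_dataset()].
#' @return long tibble `acquisition`, `section`, `compound` (feature id),
#'   `pixel`, `value`.
#' @export
panel_from_stacks <- function(stacks, features) {
  purrr::pmap(features[, c("feature", "acquisition", "section", "peak_id")],
              function(feature, acquisition, section, peak_id) {
    st <- stacks[[acquisition]]
    col <- match(peak_id, st$peaks$peak)
    v <- as.numeric(st$values[, col])
    nz <- which(v > 0)
    tibble(acquisition = acquisition, section = section,
           compound = sprintf("f%04d", feature), pixel = nz - 1L,
           value = log(v[nz]))
  }) %>% dplyr::bind_rows()
}

default_pipeline_config <- function() {
  list(
    grid_step = 1e-4, bandwidth = 1e-3, min_count = 0,
    match = list(t = NULL, k = 2, n_perm = 10),
    normalize = list(n_steps = 4000, effect = "bilinear"),
    filter = list(pixel_frac = 0.15, section_frac = 0.8),
    spatial = list(n_perm = 100, n_strata = 8, alpha = 0.01),
    seed = 1
  )
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- defaults[[nm]][[sub]]
      }
    }
  }
  if (is.null(config$acquisitions) || length(config$acquisitions) < 1) {
    abort("config needs at least one acquisition (id, path, section)")
  }
  if (is.null(config$out_dir)) abort("config needs out_dir")
  config
}

stage_hash <- function(...) {
  payload <- paste(utils::capture.output(dput(list(...))), collapse = "\n")
  tf <- tempfile(); writeLines(payload, tf)
  unname(tools::md5sum(tf))
}

run_stage <- function(name, out_dir, hash, outputs, fn) {
  hfile <- file.path(out_dir, sprintf(".stage_%s.hash", name))
  if (file.exists(hfile) && readLines(hfile, n = 1) == hash &&
      all(file.exists(outputs))) {
    inform(sprintf("stage %s: cache hit", name))
    return(FALSE)
  }
  inform(sprintf("stage %s: running", name))
  fn()
  writeLines(hash, hfile)
  TRUE
}

#' Run the full pipeline over a directory of acquisitions
#'
#' Stages, in order: peak calling per acquisition, image quality report,
#' cross-acquisition matching, panel assembly plus batch-effect
#' normalization, and the spatial-information screen. Each stage is cached
#' on a content hash of its inputs and configuration, so re-running an
#' unchanged configuration re-executes nothing and editing one stage's
#' inputs re-runs only that stage onward. The resolved configuration is
#' written next to the outputs.
#'
#' @param config list (or path to a YAML file) with `acquisitions` (list of
#'   `id`, `path`, `section`), `out_dir` and optional stage settings
#'   (defaults: grid step 1e-4 Da, bandwidth 1e-3 Da, matching k 2 with 10
#'   permutations, 8 TIC strata, 100 permutations and adjusted alpha 0.01
#'   for the spatial screen, presence filter 0.15/0.80).
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out, "resolved_config.yaml"))
  acq_files <- purrr::map_chr(config$acquisitions, "path")
  in_hash <- unname(tools::md5sum(acq_files))

  # --- stage 1: peak calling ----------------------------------------------
  img_dirs <- file.path(out, "images",
                        purrr::map_chr(config$acquisitions, "id"))
  h1 <- stage_hash("call", in_hash, config$grid_step, config$bandwidth,
                   config$min_count)
  run_stage("call", out, h1, file.path(img_dirs, "intervals.csv"), function() {
    purrr::walk2(config$acquisitions, img_dirs, function(ac, d) {
      acq <- load_acquisition(ac$path, grid_step = config$grid_step,
                              acquisition_id = ac$id,
                              section_index = ac$section)
      stack <- call_peaks(acq, bandwidth = config$bandwidth,
                          min_count = config$min_count)
      write_images(stack, d)
    })
  })
  stacks <- purrr::map(img_dirs, read_images)
  names(stacks) <- purrr::map_chr(config$acquisitions, "id")

  # --- stage 2: image quality ---------------------------------------------
  qc_path <- file.path(out, "qc.csv")
  h2 <- stage_hash("qc", h1)
  run_stage("qc", out, h2, qc_path, function() {
    thr <- calibrate_qc_thresholds(seed = config$seed)
    qc <- purrr::imap(stacks, function(st, id) {
      imgs <- setNames(purrr::map(st$peaks$peak, ~ image_matrix(st, .x)),
                       paste0(id, "_p", st$peaks$peak))
      qc_report(imgs, thr) %>% mutate(acquisition = id)
    }) %>% dplyr::bind_rows()
    readr::write_csv(qc, qc_path)
  })

  # --- stage 3: matching ---------------------------------------------------
  feat_path <- file.path(out, "features.csv")
  h3 <- stage_hash("match", h1, config$match, config$seed)
  run_stage("match", out, h3, feat_path, function() {
    peaks <- purrr::imap(stacks, function(st, id) {
      tibble(acquisition = id, section = st$meta$section_index,
             peak_id = paste0(id, "_", st$peaks$peak),
             stack_peak = st$peaks$peak, mz = st$peaks$reference_mz)
    }) %>% dplyr::bind_rows()
    feats <- match_dataset(peaks, t = config$match$t, k = config$match$k,
                           n_perm = config$match$n_perm, seed = config$seed)
    readr::write_csv(as_tibble(feats), feat_path)
  })
  features <- readr::read_csv(feat_path, col_types = readr::cols())

  # --- stage 4: panel + normalization -------------------------------------
  panel_path <- file.path(out, "panel_corrected.csv")
  par_path <- file.path(out, "norm_parameters.csv")
  h4 <- stage_hash("normalize", h3, config$normalize,
                   unname(tools::md5sum(feat_path)))
  run_stage("normalize", out, h4, c(panel_path, par_path), function() {
    feats <- features
    # feature-table peak ids are "<acquisition>_<stack peak>"; recover the
    # per-stack peak number for image lookup
    feats$peak_id <- as.integer(sub(".*_", "", as.character(feats$peak_id)))
    panel <- panel_from_stacks(stacks, feats)
    if (length(stacks) >= 2 && length(unique(panel$compound)) >= 2) {
      res <- normalize_panel(panel, effect = config$normalize$effect,
                             n_steps = config$normalize$n_steps,
                             seed = config$seed)
      readr::write_csv(res$panel, panel_path)
      readr::write_csv(tidy(res$fit), par_path)
    } else {
      readr::write_csv(panel, panel_path)
      readr::write_csv(tibble(level = character(0), unit = character(0),
                              term = character(0), value = numeric(0)),
                       par_path)
    }
  })

  # --- stage 5: spatial screen --------------------------------------------
  sp_path <- file.path(out, "spatial.csv")
  h5 <- stage_hash("spatial", h1, config$spatial, config$seed)
  run_stage("spatial", out, h5, sp_path, function() {
    sp <- purrr::imap(stacks, function(st, id) {
      tic <- matrix(Matrix::rowSums(st$values > 0),
                    nrow = st$meta$raster_shape[1], byrow = TRUE)
      imgs <- setNames(purrr::map(st$peaks$peak, ~ image_matrix(st, .x)),
                       paste0(id, "_p", st$peaks$peak))
      imgs <- imgs[purrr::map_lgl(imgs, ~ sd(.x) > 1e-12)]
      if (length(imgs) == 0) return(NULL)
      spatial_informative_test(imgs, tic,
                               n_strata = config$spatial$n_strata,
                               n_perm = config$spatial$n_perm,
                               alpha = config$spatial$alpha,
                               seed = config$seed) %>%
        mutate(acquisition = id)
    }) %>% dplyr::bind_rows()
    readr::write_csv(sp, sp_path)
  })
  invisible(out)
}
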