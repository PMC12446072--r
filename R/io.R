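#' Row-major pixel indexing
#'
#' Maps raster coordinates to a linear pixel index and back. Coordinates and
#' indices are 0-based, matching the on-disk conventions of tabular MSI
#' exports; `x` indexes rows and `y` columns of the raster.
#'
#' @param x,y integer pixel coordinates, 0-based.
#' @param raster_shape integer vector `c(rows, cols)`.
#' @return `pixel_index()` returns the 0-based linear index; `pixel_coords()`
#'   returns a tibble with columns `x` and `y`.
#' @export
pixel_index <- function(x, y, raster_shape) {
  rows <- raster_shape[[1]]; cols <- raster_shape[[2]]
  if (any(x < 0 | x >= rows | y < 0 | y >= cols)) {
    abort("pixel coordinates out of raster bounds")
  }
  as.integer(x) * as.integer(cols) + as.integer(y)
}

#' @rdname pixel_index
#' @param index 0-based linear pixel index.
#' @export
pixel_coords <- function(index, raster_shape) {
  cols <- raster_shape[[2]]
  npix <- raster_shape[[1]] * cols
  if (any(index < 0 | index >= npix)) abort("pixel index out of bounds")
  tibble(x = index %/% cols, y = index %% cols)
}

#' Load one MSI acquisition into the sparse pixel-by-m/z-grid representation
#'
#' Records are `(m/z, intensity, x, y)` tuples. m/z values are discretized
#' onto a global grid anchored at `mz_range[1]` with half-open bins of width
#' `grid_step`: column `m` covers `[mz_min + m*step, mz_min + (m+1)*step)`.
#' Intensities of records falling in the same (pixel, column) cell are summed.
#' Pixels with no recorded signal are kept as all-zero rows: they are real
#' raster positions.
#'
#' @param source a data frame with columns `mz`, `intensity`, `x`, `y`; or a
#'   path to a CSV file with that header; or a path to an imzML file (the
#'   companion `.ibd` is found by extension substitution).
#' @param grid_step width of one m/z grid bin in Da. The default 1e-4 Da
#'   matches the nominal mass resolution of orbital-trap instruments.
#' @param mz_range optional numeric `c(min, max)` anchoring the grid; defaults
#'   to `c(floor(min(mz)), ceiling(max(mz)))` of the data.
#' @param acquisition_id,section_index identity and position of this
#'   acquisition along the section series.
#' @return an object of class `msi_acquisition`: a list with `S` (sparse
#'   `dgCMatrix`, pixels x grid columns) and `meta` (acquisition metadata).
#' @export
load_acquisition <- function(source, grid_step = 1e-4, mz_range = NULL,
                             acquisition_id = "acq", section_index = 1L) {
  if (grid_step <= 0) abort("grid_step must be positive")
  recs <- if (is.data.frame(source)) {
    as_tibble(source)
  } else if (grepl("\\.imzml$", source, ignore.case = TRUE)) {
    read_imzml(source)
  } else {
    read_msi_csv(source)
  }
  if (nrow(recs) == 0) abort("empty acquisition: no spectrum records")
  need <- c("mz", "intensity", "x", "y")
  if (!all(need %in% names(recs))) {
    abort("records need columns mz, intensity, x, y")
  }
  n_rejected <- sum(recs$intensity < 0)
  if (n_rejected > 0) {
    warn(sprintf("rejected %d records with negative intensity", n_rejected))
    recs <- recs[recs$intensity >= 0, , drop = FALSE]
  }
  if (nrow(recs) == 0) abort("empty acquisition after rejecting records")
  if (is.null(mz_range)) {
    mz_range <- c(floor(min(recs$mz)), ceiling(max(recs$mz)))
    if (mz_range[2] <= mz_range[1]) mz_range[2] <- mz_range[1] + grid_step
  }
  if (any(recs$mz < mz_range[1] | recs$mz > mz_range[2])) {
    abort("records outside the declared mz_range")
  }
  n_cols <- as.integer(ceiling((mz_range[2] - mz_range[1]) / grid_step))
  raster_shape <- c(max(recs$x) + 1L, max(recs$y) + 1L)
  col0 <- pmin(floor((recs$mz - mz_range[1]) / grid_step), n_cols - 1L)
  row0 <- pixel_index(recs$x, recs$y, raster_shape)
  keep <- recs$intensity > 0
  S <- Matrix::sparseMatrix(
    i = row0[keep] + 1L, j = as.integer(col0[keep]) + 1L,
    x = recs$intensity[keep],
    dims = c(prod(raster_shape), n_cols)
  )
  meta <- list(
    acquisition_id = acquisition_id,
    section_index = as.integer(section_index),
    raster_shape = as.integer(raster_shape),
    mz_range = as.numeric(mz_range),
    grid_step = grid_step,
    n_rejected = n_rejected
  )
  structure(list(S = S, meta = meta), class = "msi_acquisition")
}

#' @export
print.msi_acquisition <- function(x, ...) {
  cat(sprintf(
    "<msi_acquisition '%s'> %d pixels (%d x %d raster), %d m/z bins of %g Da over [%g, %g]\n",
    x$meta$acquisition_id, nrow(x$S), x$meta$raster_shape[1],
    x$meta$raster_shape[2], ncol(x$S), x$meta$grid_step,
    x$meta$mz_range[1], x$meta$mz_range[2]
  ))
  invisible(x)
}

#' Read the plain tabular MSI dialect
#'
#' A CSV file with header `mz,intensity,x,y`, one detected ion per row.
#'
#' @param path file path.
#' @return a tibble of spectrum records.
#' @export
read_msi_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    mz = readr::col_double(), intensity = readr::col_double(),
    x = readr::col_integer(), y = readr::col_integer()
  ))
}

# imzML cvParam accessions used by the minimal reader
.IMZML_ACC <- list(
  pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  offset = "IMS:1000102", arr_len = "IMS:1000103",
  mz_arr = "MS:1000514", int_arr = "MS:1000515",
  f32 = "MS:1000521", f64 = "MS:1000523"
)

#' Read a (centroided) imzML/ibd acquisition into spectrum records
#'
#' Minimal reader for processed- and continuous-mode imzML with 32- or 64-bit
#' float arrays, the layout written by common MSI converters. Coordinates are
#' converted from imzML 1-based to the package's 0-based convention.
#'
#' @param path path to the `.imzML` file; the `.ibd` binary must sit next to
#'   it with the same stem.
#' @return a tibble of `(mz, intensity, x, y)` records.
#' @export
read_imzml <- function(path) {
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd)) abort(sprintf("companion ibd file not found: %s", ibd))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  con <- file(ibd, "rb")
  on.exit(close(con))
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0) abort("imzML file contains no spectra")
  read_arr <- function(node) {
    cv <- xml2::xml_find_all(node, ".//cvParam")
    acc <- setNames(xml2::xml_attr(cv, "value"), xml2::xml_attr(cv, "accession"))
    what_size <- if (.IMZML_ACC$f64 %in% names(acc)) 8L else 4L
    off <- as.numeric(acc[[.IMZML_ACC$offset]])
    len <- as.integer(acc[[.IMZML_ACC$arr_len]])
    seek(con, where = off, origin = "start")
    readBin(con, what = "double", n = len, size = what_size, endian = "little")
  }
  out <- purrr::map(spectra, function(sp) {
    cv <- xml2::xml_find_all(sp, "./scanList//cvParam")
    acc <- setNames(xml2::xml_attr(cv, "value"), xml2::xml_attr(cv, "accession"))
    x <- as.integer(acc[[.IMZML_ACC$pos_x]]); y <- as.integer(acc[[.IMZML_ACC$pos_y]])
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    is_mz <- purrr::map_lgl(arrays, function(a) {
      .IMZML_ACC$mz_arr %in% xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "accession")
    })
    mz <- read_arr(arrays[is_mz][[1]])
    ints <- read_arr(arrays[!is_mz][[1]])
    tibble(mz = mz, intensity = ints, x = x - 1L, y = y - 1L)
  })
  dplyr::bind_rows(out)
}

#' Persist and reload an ion-image stack
#'
#' The on-disk container is a directory holding `images.mtx` (MatrixMarket
#' sparse pixels-by-peaks matrix), `intervals.csv` (peak id, interval bounds
#' in Da and reference m/z) and `meta.yaml` (acquisition metadata plus a
#' format version). The interval CSV doubles as the human-readable peak list.
#'
#' @param stack an `ion_image_stack` (see [extract_images()]).
#' @param path directory to create or read.
#' @return `read_images()` returns the reconstructed `ion_image_stack`.
#' @export
write_images <- function(stack, path) {
  stopifnot(inherits(stack, "ion_image_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(stack$values, "generalMatrix"), "CsparseMatrix"),
                  file.path(path, "images.mtx"))
  readr::write_csv(stack$peaks, file.path(path, "intervals.csv"))
  meta <- stack$meta
  meta$format_version <- 1L
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_images
#' @export
read_images <- function(path) {
  ivpath <- file.path(path, "intervals.csv")
  if (!file.exists(ivpath)) abort("container is missing its interval table")
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  if (is.null(meta$format_version) || meta$format_version != 1L) {
    abort("unsupported container format version")
  }
  meta$format_version <- NULL
  meta$raster_shape <- as.integer(meta$raster_shape)
  values <- methods::as(Matrix::readMM(file.path(path, "images.mtx")), "CsparseMatrix")
  peaks <- readr::read_csv(ivpath, col_types = readr::cols())
  new_ion_image_stack(values, peaks, meta)
}

new_ion_image_stack <- function(values, peaks, meta) {
  structure(list(values = values, peaks = as_tibble(peaks), meta = meta),
            class = "ion_image_stack")
}

#' @export
print.ion_image_stack <- function(x, ...) {
  cat(sprintf("<ion_image_stack> %d pixels x %d peak images ('%s')\n",
              nrow(x$values), ncol(x$values),
              x$meta$acquisition_id %||% "?"))
  invisible(x)
}

#' Long-format view of an ion image stack
#'
#' @param x an `ion_image_stack`.
#' @param ... unused.
#' @return a tibble with one row per (pixel, peak): `x`, `y`, `peak`,
#'   `reference_mz`, `intensity` (zeros included).
#' @method tidy ion_image_stack
#' @export
tidy.ion_image_stack <- function(x, ...) {
  P <- nrow(x$values)
  coords <- pixel_coords(seq_len(P) - 1L, x$meta$raster_shape)
  dense <- as.matrix(x$values)
  tidyr::expand_grid(peak = x$peaks$peak, pixel = seq_len(P) - 1L) %>%
    arrange(.data$peak) %>%
    mutate(
      x = coords$x[.data$pixel + 1L], y = coords$y[.data$pixel + 1L],
      intensity = as.vector(dense),
      reference_mz = rep(x$peaks$reference_mz, each = P)
    ) %>%
    select("peak", "reference_mz", "x", "y", "intensity")
}

#' @method autoplot ion_image_stack
#' @export
autoplot.ion_image_stack <- function(object, peaks = NULL, ...) {
  df <- tidy.ion_image_stack(object)
  if (!is.null(peaks)) df <- df[df$peak %in% peaks, , drop = FALSE]
  ggplot(df, aes(x = .data$y, y = .data$x, fill = .data$intensity)) +
    geom_raster() +
    facet_wrap(~ .data$peak) +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "intensity") +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
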