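#' Sensor specimens as tibbles
#'
#' A specimen table has one row per specimen and columns `doping`, `angle`,
#' `force`, `pressure`, `current` (the five measured parameters) and `label`
#' (class index 0-4). The doping material is categorical and is encoded as a
#' numeric code before normalization. A specimen whose air pressure was
#' measured as a range instead carries `pressure_low` and `pressure_high`
#' columns; [expand_pressure_range()] turns such rows into one scalar-pressure
#' row per increment step.
#'
#' @name sensor-specimens
NULL

#' Expand air-pressure ranges into individual specimens
#'
#' For every row carrying a pressure range, emits
#' `floor((high - low) / increment) + 1` rows with pressures `low`,
#' `low + increment`, ... and all other fields copied. Rows that already have
#' a scalar `pressure` pass through unchanged. This is the training-set
#' augmentation used for range-valued pressure readings; the default step is
#' 295 Pascal.
#'
#' @param specimens Specimen tibble (see [sensor-specimens]).
#' @param increment Pressure step in Pascal (> 0).
#' @return A tibble in which every row has a scalar `pressure`.
#' @export
expand_pressure_range <- function(specimens, increment = 295) {
  if (increment <= 0) {
    abort("pressure increment must be > 0", class = "dualpathnet_spec_error")
  }
  has_range <- all(c("pressure_low", "pressure_high") %in% names(specimens))
  if (!has_range) {
    assert_columns(specimens, "pressure", "specimen table")
    return(tibble::as_tibble(specimens))
  }
  if (any(specimens$pressure_high < specimens$pressure_low, na.rm = TRUE)) {
    abort("pressure_high must be >= pressure_low", class = "dualpathnet_spec_error")
  }
  rows <- purrr::pmap(specimens, function(...) {
    row <- tibble::as_tibble_row(list(...))
    if (is.na(row$pressure_low)) {
      # scalar-pressure row in a mixed table
      return(dplyr::select(row, -"pressure_low", -"pressure_high"))
    }
    steps <- floor((row$pressure_high - row$pressure_low) / increment)
    pressures <- row$pressure_low + increment * (0:steps)
    out <- row[rep(1, length(pressures)), ]
    out$pressure <- pressures
    dplyr::select(out, -"pressure_low", -"pressure_high")
  })
  dplyr::bind_rows(rows)
}

#' Normalize the five sensor parameters to \[0, 1\]
#'
#' Each of the five parameters is divided, independently of the others, by
#' its maximum absolute value over all specimens (max-scaling; zero is
#' preserved). After normalization every value lies in \[0, 1\] for
#' non-negative inputs, so 1 renders as white in the zone encoding.
#'
#' @param specimens Specimen tibble with scalar pressures (expand ranges
#'   first).
#' @return The tibble with the five parameter columns rescaled; labels and
#'   other columns unchanged.
#' @export
normalize_parameters <- function(specimens) {
  assert_columns(specimens, param_cols, "specimen table")
  if (nrow(specimens) < 1) {
    abort("at least one specimen is required", class = "dualpathnet_spec_error")
  }
  out <- tibble::as_tibble(specimens)
  for (col in param_cols) {
    m <- max(abs(out[[col]]))
    if (m == 0) {
      warn(sprintf("parameter '%s' is zero for all specimens; left as zeros", col))
    } else {
      out[[col]] <- out[[col]] / m
    }
  }
  out
}

#' Five-zone canvas layout
#'
#' Pixel geometry of the five encoding zones on a square canvas. Zones 1-4
#' (doping, angle, force, pressure) are 20x20 squares at the four corners
#' with a 2-pixel margin; zone 5 (the in-air current, the most decisive
#' parameter) is the central 20x20 square. For canvas sizes other than 64 the
#' geometry scales proportionally. Origins are 1-based (R convention).
#'
#' @param canvas Canvas side length in pixels (default 64).
#' @return A `zone_layout`: a tibble with columns `zone`, `row`, `col`,
#'   `height`, `width`, plus a `canvas` attribute.
#' @export
zone_layout <- function(canvas = 64L) {
  canvas <- as.integer(canvas)
  z <- as.integer(round(canvas * 20 / 64))
  margin <- as.integer(round(canvas * 2 / 64))
  ctr <- as.integer(floor((canvas - z) / 2)) + 1L
  far <- canvas - margin - z + 1L
  layout <- tibble(
    zone = 1:5,
    row = c(margin + 1L, margin + 1L, far, far, ctr),
    col = c(margin + 1L, far, margin + 1L, far, ctr),
    height = z, width = z
  )
  attr(layout, "canvas") <- canvas
  validate_zone_layout(layout)
  layout
}

validate_zone_layout <- function(layout) {
  canvas <- attr(layout, "canvas")
  occupied <- matrix(0L, canvas, canvas)
  for (i in seq_len(nrow(layout))) {
    r <- layout$row[i]; c0 <- layout$col[i]
    h <- layout$height[i]; w <- layout$width[i]
    if (r < 1 || c0 < 1 || r + h - 1 > canvas || c0 + w - 1 > canvas) {
      abort("zone extends outside the canvas", class = "dualpathnet_spec_error")
    }
    occupied[r:(r + h - 1), c0:(c0 + w - 1)] <-
      occupied[r:(r + h - 1), c0:(c0 + w - 1)] + 1L
  }
  if (any(occupied > 1L)) {
    abort("zones overlap", class = "dualpathnet_spec_error")
  }
  invisible(layout)
}

zone_mask <- function(layout, zone) {
  canvas <- attr(layout, "canvas")
  m <- matrix(FALSE, canvas, canvas)
  i <- which(layout$zone == zone)
  m[layout$row[i]:(layout$row[i] + layout$height[i] - 1),
    layout$col[i]:(layout$col[i] + layout$width[i] - 1)] <- TRUE
  m
}

#' Encode one normalized specimen as a five-zone grayscale image
#'
#' Builds a `canvas x canvas` matrix whose five zones hold
#' `round(value * 255)` (half-up) for doping, angle, force, pressure and
#' in-air current respectively; the background is 0. A parameter value of 1
#' renders as white. The CNN learns the spatial positions of the zones, so
#' equal gray values in different zones remain distinguishable.
#'
#' @param specimen One-row tibble (or named list) with the five parameters in
#'   \[0, 1\].
#' @param layout A [zone_layout()].
#' @return An integer matrix (rows x cols = canvas x canvas) with values in
#'   0..255.
#' @export
encode_specimen <- function(specimen, layout = zone_layout()) {
  values <- vapply(param_cols, function(col) as.numeric(specimen[[col]][1]), 0)
  if (any(is.na(values)) || any(values < 0) || any(values > 1)) {
    abort("parameter values must lie in [0, 1]; run normalize_parameters() first",
          class = "dualpathnet_spec_error")
  }
  canvas <- attr(layout, "canvas")
  img <- matrix(0L, canvas, canvas)
  for (z in 1:5) {
    i <- which(layout$zone == z)
    img[layout$row[i]:(layout$row[i] + layout$height[i] - 1),
        layout$col[i]:(layout$col[i] + layout$width[i] - 1)] <-
      as.integer(round_half_up(values[z] * 255))
  }
  img
}

#' Encode a specimen table to PNG files plus a label table
#'
#' Writes one 8-bit grayscale PNG per specimen (deterministic names
#' `specimen_%05d.png`, so re-runs are byte-identical) and a `labels.csv`
#' with columns `filename,label`.
#'
#' @param specimens Normalized specimen tibble with a `label` column.
#' @param layout A [zone_layout()].
#' @param out_dir Output directory (created if needed).
#' @return A tibble `(filename, label)`, invisibly also written as
#'   `labels.csv` in `out_dir`.
#' @export
encode_dataset <- function(specimens, layout = zone_layout(), out_dir) {
  assert_columns(specimens, c(param_cols, "label"), "specimen table")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", out_dir),
                   class = "dualpathnet_io_error")
  }
  filenames <- sprintf("specimen_%05d.png", seq_len(nrow(specimens)))
  for (i in seq_len(nrow(specimens))) {
    img <- encode_specimen(specimens[i, ], layout)
    png::writePNG(img / 255, file.path(out_dir, filenames[i]))
  }
  labels <- tibble(filename = filenames, label = as.integer(specimens$label))
  readr::write_csv(labels, file.path(out_dir, "labels.csv"))
  labels
}

#' In-memory image set from a specimen table
#'
#' Encodes each normalized specimen and replicates the grayscale channel to
#' the three input channels the networks expect, returning the tabular image
#' set used by [train_network()].
#'
#' @inheritParams encode_dataset
#' @return A tibble `(id, image, label)` where `image` is a list column of
#'   `canvas x canvas x 3` arrays with values in \[0, 1\].
#' @export
sensor_image_set <- function(specimens, layout = zone_layout()) {
  assert_columns(specimens, c(param_cols, "label"), "specimen table")
  images <- lapply(seq_len(nrow(specimens)), function(i) {
    g <- encode_specimen(specimens[i, ], layout) / 255
    array(g, dim = c(nrow(g), ncol(g), 3))
  })
  tibble(id = sprintf("specimen_%05d", seq_len(nrow(specimens))),
         image = images, label = as.integer(specimens$label))
}

#' Read/write specimen tables
#'
#' Thin CSV wrappers with the column contract of [sensor-specimens].
#'
#' @param path CSV file path.
#' @return `read_specimens()` returns a tibble.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("specimen file not found: ", path), class = "dualpathnet_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_specimens
#' @param specimens Specimen tibble.
#' @export
write_specimens <- function(specimens, path) {
  readr::write_csv(specimens, path)
  invisible(path)
}
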