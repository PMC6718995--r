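#' Default class means for the synthetic sensor generator
#'
#' One row per pollutant class (0-4: acetone, ethanol, chloroform, toluene,
#' methanol), columns = the five parameters. The doping code is the integer
#' encoding of the doping material; angle is in degrees, pressure in Pascal,
#' force and in-air current in instrument units. The magnitudes span
#' realistic sensing ranges and the classes are pairwise well separated,
#' reflecting the premise that specimens measured with different doping
#' materials share little internal correlation.
#'
#' @return A 5 x 5 numeric matrix with parameter column names.
#' @export
default_class_means <- function() {
  m <- rbind(
    c(1, 15, 2.0, 40000, 18),
    c(2, 30, 3.5, 55000, 35),
    c(3, 45, 5.0, 70000, 52),
    c(4, 60, 6.5, 85000, 69),
    c(5, 75, 8.0, 100000, 86)
  )
  colnames(m) <- param_cols
  rownames(m) <- c("acetone", "ethanol", "chloroform", "toluene", "methanol")
  m
}

#' Generate synthetic sensor specimens
#'
#' Gaussian class clusters around per-class parameter means: each parameter
#' is its class mean plus Gaussian noise with standard deviation
#' `noise_sd * scale`, where scale is that parameter's largest class mean;
#' values are clipped at zero. Labels are assigned round-robin over the
#' classes, so `n_specimens = 55` with 5 classes yields 11 per class.
#' Optionally, a symmetric pressure range of half-width
#' `pressure_half_range` is attached to every specimen (columns
#' `pressure_low`/`pressure_high`) for use with [expand_pressure_range()].
#' Deterministic given `seed`.
#'
#' @param n_specimens Number of specimens (default 150, i.e. 30 per class).
#' @param n_classes Number of classes (>= 2; default 5).
#' @param class_means Matrix `n_classes x 5` of parameter means; defaults to
#'   [default_class_means()].
#' @param noise_sd Noise standard deviation as a fraction of each
#'   parameter's scale (default 0.05).
#' @param pressure_half_range Optional half-width (Pascal) of a pressure
#'   range per specimen; `NULL` (default) gives scalar pressures.
#' @param seed Integer seed.
#' @return A specimen tibble (see [sensor-specimens]).
#' @export
gen_sensor_specimens <- function(n_specimens = 150L, n_classes = 5L,
                                 class_means = default_class_means(),
                                 noise_sd = 0.05,
                                 pressure_half_range = NULL, seed = 1L) {
  if (n_classes < 2) abort("need at least 2 classes", class = "dualpathnet_spec_error")
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "dualpathnet_spec_error")
  class_means <- as.matrix(class_means)
  if (nrow(class_means) < n_classes || ncol(class_means) != 5) {
    abort("class_means must be n_classes x 5", class = "dualpathnet_spec_error")
  }
  scales <- apply(abs(class_means[seq_len(n_classes), , drop = FALSE]), 2, max)
  labels <- (seq_len(n_specimens) - 1L) %% n_classes
  withr::with_seed(seed, {
    vals <- class_means[labels + 1L, , drop = FALSE] +
      matrix(rnorm(n_specimens * 5), n_specimens, 5) *
        matrix(noise_sd * scales, n_specimens, 5, byrow = TRUE)
    vals[vals < 0] <- 0
    out <- as_tibble(stats::setNames(as.data.frame(vals), param_cols))
    out$label <- labels
    if (!is.null(pressure_half_range)) {
      out$pressure_low <- pmax(0, out$pressure - pressure_half_range)
      out$pressure_high <- out$pressure + pressure_half_range
      out$pressure <- NULL
    }
    out
  })
}

#' Generate a toy fundus-style image set
#'
#' Small RGB images emulating the structure of graded retinal photographs:
#' a dark background, a bright centered disk, and class-k images carrying
#' `lesion_density[k+1]` small bright spots scattered inside the disk, with
#' spot counts non-decreasing in severity class. These carry the
#' class-dependent signal the preprocessing and training pipelines assume;
#' they make no attempt at anatomical realism. Deterministic given `seed`.
#'
#' @param size Image side length in pixels (>= 32).
#' @param n_per_class Images per class.
#' @param lesion_density Five non-decreasing spot counts for classes 0-4.
#' @param seed Integer seed.
#' @return An image-set tibble `(id, image, label)` with `size x size x 3`
#'   arrays in \[0, 1\].
#' @export
gen_toy_fundus <- function(size = 64L, n_per_class = 10L,
                           lesion_density = c(0L, 3L, 8L, 16L, 30L),
                           seed = 1L) {
  if (size < 32) abort("size must be >= 32", class = "dualpathnet_spec_error")
  if (is.unsorted(lesion_density)) {
    abort("lesion_density must be non-decreasing over classes",
          class = "dualpathnet_spec_error")
  }
  n_classes <- length(lesion_density)
  ctr <- (size + 1) / 2
  radius <- 0.45 * size
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  disk <- (yy - ctr)^2 + (xx - ctr)^2 <= radius^2
  base_rgb <- c(0.75, 0.42, 0.12) # fundus-like hue
  withr::with_seed(seed, {
    rows <- list()
    for (k in seq_len(n_classes) - 1L) {
      for (i in seq_len(n_per_class)) {
        img <- array(0.04, dim = c(size, size, 3))
        for (c in 1:3) {
          ch <- img[, , c]
          ch[disk] <- base_rgb[c]
          img[, , c] <- ch
        }
        n_spots <- lesion_density[k + 1L]
        s <- 0L
        while (s < n_spots) {
          sy <- sample.int(size, 1); sx <- sample.int(size, 1)
          if (!disk[sy, sx]) next
          r <- sample(1:2, 1)
          ys <- max(1, sy - r):min(size, sy + r)
          xs <- max(1, sx - r):min(size, sx + r)
          img[ys, xs, 1] <- 1
          img[ys, xs, 2] <- 0.95
          img[ys, xs, 3] <- 0.75
          s <- s + 1L
        }
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("fundus_c%d_%04d", k, i),
          image = list(img), label = k
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
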