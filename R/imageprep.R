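#' @importFrom stats predict rnorm runif setNames
NULL

dr_class_names <- c("Normal", "Mild NPDR", "Moderate NPDR", "Severe NPDR",
                    "Proliferative DR")

as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (length(dim(img)) != 3) {
    abort("an image must be a matrix or a height x width x channels array",
          class = "dualpathnet_spec_error")
  }
  img
}

#' Resize an image so its shorter edge hits a target
#'
#' Bilinear resize preserving the aspect ratio: the shorter of height/width
#' becomes `target` pixels and the longer edge is scaled proportionally
#' (rounded). Keeping the aspect ratio leaves the eyeball geometry of fundus
#' photographs unaltered; no other enhancement is applied.
#'
#' @param img A `height x width (x channels)` numeric array in \[0, 1\].
#' @param target Target shorter-edge length in pixels (>= 1).
#' @return The resized array.
#' @export
resize_shorter_edge <- function(img, target) {
  img <- as_image_array(img)
  if (target < 1) abort("target must be >= 1", class = "dualpathnet_spec_error")
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < 1 || w < 1) abort("empty image", class = "dualpathnet_spec_error")
  scale <- target / min(h, w)
  new_h <- if (h <= w) as.integer(target) else as.integer(round(h * scale))
  new_w <- if (w < h) as.integer(target) else as.integer(round(w * scale))
  if (new_h == h && new_w == w) return(img)
  # EBImage uses width-first (x, y, c) layout
  ebi <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Grayscale")
  res <- EBImage::resize(ebi, w = new_w, h = new_h, filter = "bilinear")
  out <- aperm(EBImage::imageData(res), c(2, 1, 3))
  array(out, dim = c(new_h, new_w, dim(img)[3]))
}

#' Crop the central square out of an image
#'
#' The output is S x S where S is the shorter edge; the crop window is
#' centered on the long axis with offset `floor((L - S) / 2)`.
#'
#' @param img A `height x width (x channels)` numeric array.
#' @return The cropped array.
#' @export
center_crop_square <- function(img) {
  img <- as_image_array(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- min(h, w)
  off_r <- floor((h - s) / 2)
  off_c <- floor((w - s) / 2)
  img[(off_r + 1):(off_r + s), (off_c + 1):(off_c + s), , drop = FALSE]
}

#' Preprocess an image for a target input resolution
#'
#' Shorter-edge resize to `size` followed by central square crop, the
#' composition used to prepare raw photographs for training.
#'
#' @inheritParams resize_shorter_edge
#' @param size Target square side (64 or 224 in the bundled architectures).
#' @return A `size x size (x channels)` array.
#' @export
prep_image <- function(img, size) {
  center_crop_square(resize_shorter_edge(img, size))
}

#' Per-class counts and percentages of a labeled set
#'
#' Percentages are `100 * count / total`, reported to two decimals with
#' half-up rounding.
#'
#' @param x Either a data frame with a `label` column (class indices 0-4) or
#'   an integer vector of per-class counts for classes `0..length(x)-1`.
#' @param class_names Optional class names; defaults to the five retinopathy
#'   phases when there are five classes.
#' @return A tibble `(class, class_name, n, percentage)`.
#' @export
class_distribution <- function(x, class_names = NULL) {
  if (is.data.frame(x)) {
    assert_columns(x, "label", "label table")
    if (nrow(x) == 0) abort("empty label set", class = "dualpathnet_spec_error")
    labels <- as.integer(x$label)
    classes <- 0:max(max(labels), 4L)
    counts <- vapply(classes, function(k) sum(labels == k), 0L)
  } else {
    counts <- as.integer(x)
    classes <- seq_along(counts) - 1L
  }
  if (sum(counts) == 0) abort("empty label set", class = "dualpathnet_spec_error")
  if (is.null(class_names)) {
    class_names <- if (length(classes) == 5) dr_class_names else as.character(classes)
  }
  tibble(
    class = classes,
    class_name = class_names,
    n = counts,
    percentage = round_half_up(100 * counts / sum(counts), 2)
  )
}

#' Random train/validation split
#'
#' Uniform partition without replacement: `floor(ratio * n)` rows go to the
#' training set and the rest to validation. Deterministic given `seed`;
#' together the two parts are exactly the input.
#'
#' @param set A tibble (one row per sample).
#' @param ratio Training fraction in (0, 1); the conventional value is 0.9.
#' @param seed Integer seed.
#' @return A list with elements `train` and `validation`.
#' @export
split_dataset <- function(set, ratio = 0.9, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) {
    abort("ratio must be in (0, 1)", class = "dualpathnet_spec_error")
  }
  n <- nrow(set)
  if (n < 2) abort("need at least 2 samples to split", class = "dualpathnet_spec_error")
  n_train <- floor(ratio * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = set[sort(idx), ], validation = set[setdiff(seq_len(n), idx), ])
}

#' Read an image file as a \[0, 1\] array
#'
#' @param path PNG/JPEG/TIFF file path.
#' @return A `height x width x channels` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image not found: ", path), class = "dualpathnet_io_error")
  }
  ebi <- EBImage::readImage(path)
  d <- EBImage::imageData(ebi)
  if (length(dim(d)) == 2) d <- array(d, dim = c(dim(d), 1L))
  aperm(d, c(2, 1, 3))
}

#' @rdname read_image
#' @param img Array in \[0, 1\] (grayscale matrix or H x W x C).
#' @export
write_image <- function(img, path) {
  img <- as_image_array(img)
  if (dim(img)[3] == 1) img <- img[, , 1]
  png::writePNG(img, path)
  invisible(path)
}

#' Load an image directory plus label table as an image set
#'
#' @param dir Directory of image files.
#' @param labels Path to a CSV with columns `filename,label`; defaults to
#'   `labels.csv` inside `dir`.
#' @param channels Channel count the images are expanded/collapsed to
#'   (networks expect 3).
#' @return A tibble `(id, image, label)`.
#' @export
load_image_dir <- function(dir, labels = file.path(dir, "labels.csv"),
                           channels = 3L) {
  if (!file.exists(labels)) {
    abort(paste0("label file not found: ", labels), class = "dualpathnet_io_error")
  }
  tab <- readr::read_csv(labels, show_col_types = FALSE)
  assert_columns(tab, c("filename", "label"), "label table")
  images <- lapply(tab$filename, function(f) {
    img <- read_image(file.path(dir, f))
    if (dim(img)[3] == 1 && channels == 3) {
      img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3L))
    }
    img
  })
  tibble(id = tab$filename, image = images, label = as.integer(tab$label))
}

#' Write an in-memory image set to disk
#'
#' @param set Tibble `(id, image, label)`.
#' @param dir Output directory.
#' @return The label tibble `(filename, label)`.
#' @export
write_image_set <- function(set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  filenames <- paste0(sub("\\.png$", "", set$id), ".png")
  for (i in seq_len(nrow(set))) {
    write_image(set$image[[i]], file.path(dir, filenames[i]))
  }
  labels <- tibble(filename = filenames, label = set$label)
  readr::write_csv(labels, file.path(dir, "labels.csv"))
  labels
}
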