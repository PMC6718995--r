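# Shared fixtures, all generated in code.

# A minimal valid architecture for fast network tests.
tiny_spec <- function(input = c(16, 16, 3), classes = 2L) {
  arch_spec("tiny", input, list(
    mod_simple_conv(8, kernel = 3, stride = 1),
    mod_reduction_dual(8),
    mod_normal_dual(4, 4),
    mod_global_pool(),
    mod_flatten(),
    mod_fully_connected(classes),
    mod_softmax()
  ))
}

# Two trivially separable classes: left half bright vs right half bright.
separable_image_set <- function(n_per_class = 12, size = 16, seed = 42) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(2 * n_per_class), function(i) {
      label <- (i - 1L) %% 2L
      img <- array(runif(size * size * 3, 0, 0.1), dim = c(size, size, 3))
      cols <- if (label == 0) 1:(size / 2) else (size / 2 + 1):size
      img[, cols, ] <- img[, cols, ] + 0.8
      tibble::tibble(id = sprintf("img%03d", i), image = list(img), label = label)
    })
    dplyr::bind_rows(rows)
  })
}

# Independent sliding-window oracle for the convolution output width:
# count the placements of a k-wide window on a zero-padded 1-D axis.
slide_count <- function(win, k, p, s) {
  padded <- win + 2 * p
  count <- 0L
  pos <- 1L
  while (pos + k - 1L <= padded) {
    count <- count + 1L
    pos <- pos + s
  }
  count
}
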