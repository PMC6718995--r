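#' Extract pooled activations for an image set
#'
#' Runs each image through the network in evaluation mode and returns the
#' global-average-pooled feature vector (the input of the fully connected
#' classifier). Since every feature is a ReLU activation averaged over its
#' map, all entries are non-negative; a column that is exactly zero for
#' every sample is a "dead" unit whose filter never activated.
#'
#' @param model A trained `dual_cnn`.
#' @param images Image-set tibble `(id, image, label)` or list of arrays.
#' @param labels Optional label vector (taken from the tibble if present).
#' @param ids Optional sample identifiers.
#' @return An activation tibble with columns `f1..fW`, `label`, `id`.
#' @export
extract_activations <- function(model, images, labels = NULL, ids = NULL) {
  if (is.data.frame(images)) {
    labels <- labels %||% images$label
    ids <- ids %||% images$id
  }
  feats <- pooled_features(model, images)
  n <- nrow(feats)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- as_tibble(feats)
  out$label <- if (is.null(labels)) NA_integer_ else as.integer(labels)
  out$id <- ids %||% sprintf("sample_%05d", seq_len(n))
  out
}

activation_matrix <- function(activations) {
  cols <- grep("^f[0-9]+$", names(activations), value = TRUE)
  if (length(cols) == 0) {
    abort("no feature columns (f1..fW) found", class = "dualpathnet_spec_error")
  }
  as.matrix(activations[, cols])
}

#' Census of dead feature units
#'
#' A unit is dead when its pooled activation is exactly zero for every
#' sample ("exactly" is correct here: a post-ReLU average is zero iff every
#' contributing activation was non-positive). Always satisfies
#' `dead + alive = width`.
#'
#' @param activations An activation tibble from [extract_activations()] (or
#'   any data frame whose feature columns are named `f1..fW`).
#' @return A tibble `(dead, alive, width)`.
#' @export
count_dead_units <- function(activations) {
  m <- activation_matrix(activations)
  if (nrow(m) == 0) abort("empty activation table", class = "dualpathnet_spec_error")
  dead <- sum(colSums(m != 0) == 0)
  tibble(dead = dead, alive = ncol(m) - dead, width = ncol(m))
}

#' Embed activations in three dimensions with t-SNE
#'
#' t-distributed stochastic neighbor embedding of the pooled feature
#' vectors, for visualizing how the trained network arranges the classes in
#' activation space. This is the package's own implementation of the
#' standard algorithm (perplexity calibration by bisection, early
#' exaggeration, momentum gradient descent); it is deterministic given
#' `seed`.
#'
#' @param activations Activation tibble (see [extract_activations()]).
#' @param seed Integer seed for the random initialization.
#' @param perplexity Effective neighbor count; defaults to
#'   `min(30, floor(n / 4))` and must be below the sample count.
#' @param max_iter Gradient-descent iterations.
#' @return A tibble `(x, y, z, label, id)`, one row per sample.
#' @export
embed_3d <- function(activations, seed = 1L, perplexity = NULL,
                     max_iter = 500L) {
  m <- activation_matrix(activations)
  n <- nrow(m)
  if (n < 4) abort("need at least 4 samples to embed", class = "dualpathnet_spec_error")
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor(n / 4)))
  if (perplexity >= n) {
    abort("perplexity must be smaller than the sample count",
          class = "dualpathnet_spec_error")
  }
  coords <- withr::with_seed(seed, tsne_embed(m, dims = 3L,
                                              perplexity = perplexity,
                                              max_iter = max_iter))
  tibble(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    label = if ("label" %in% names(activations)) activations$label else NA_integer_,
    id = if ("id" %in% names(activations)) activations$id else sprintf("sample_%05d", seq_len(n))
  )
}

# ---- t-SNE -------------------------------------------------------------------

# Conditional Gaussian affinities calibrated to a target perplexity by
# bisection on the precision of each point's kernel.
tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) {
        H <- 0
        p <- p * 0
      } else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      if (abs(H - logU) < tol) break
      if (H > logU) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

tsne_embed <- function(X, dims = 3L, perplexity = 30, max_iter = 500L) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5; final_momentum <- 0.8
  eta <- 200
  exaggeration <- 4
  Pe <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == 51) Pe <- P
    if (iter == 251) momentum <- final_momentum
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y), "-")
  }
  Y
}

#' Write/read activation and embedding tables
#'
#' CSV with one row per sample: feature columns `f1..fW` (or `x,y,z`), plus
#' `label` and `id`.
#'
#' @param x Tibble to write.
#' @param path CSV path.
#' @export
write_activations <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_activations
#' @export
read_activations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dualpathnet_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE)
}
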