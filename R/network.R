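bn_eps <- 1e-5
bn_momentum <- 0.9 # running-statistics retention

#' Training hyperparameters
#'
#' The stochastic-gradient-descent protocol: initial learning rate 0.01,
#' momentum 0.9, weight decay 0.0005, learning-rate decay factor 0.1. The
#' decay epochs default to a conventional two-step schedule at ceiling(E/2)
#' and ceiling(3E/4). Batch-size presets used in the original experiments
#' were 56 (sensor images), 68 (reductive network) and 7 (deepened
#' networks); the default here is 7.
#'
#' @param learning_rate Initial SGD step size.
#' @param momentum Momentum fraction in [0, 1).
#' @param weight_decay L2 coefficient, applied to convolution and
#'   fully-connected weights only (not to batch-norm parameters or biases).
#' @param lr_decay_factor Multiplier applied at each decay epoch.
#' @param lr_decay_epochs Integer vector of epochs at whose start the
#'   learning rate is multiplied by `lr_decay_factor`; `NULL` for the
#'   default schedule.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size (>= 1).
#' @param seed Integer seed controlling shuffling (and hence the whole run).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.01, momentum = 0.9,
                            weight_decay = 0.0005, lr_decay_factor = 0.1,
                            lr_decay_epochs = NULL, epochs = 30,
                            batch_size = 7, seed = 1L) {
  if (learning_rate <= 0) abort("learning_rate must be > 0", class = "dualpathnet_spec_error")
  if (momentum < 0 || momentum >= 1) abort("momentum must be in [0, 1)", class = "dualpathnet_spec_error")
  if (batch_size < 1) abort("batch_size must be >= 1", class = "dualpathnet_spec_error")
  structure(list(
    learning_rate = learning_rate, momentum = momentum,
    weight_decay = weight_decay, lr_decay_factor = lr_decay_factor,
    lr_decay_epochs = lr_decay_epochs, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), seed = as.integer(seed)
  ), class = "training_config")
}

default_decay_epochs <- function(epochs) {
  unique(pmax(2L, c(ceiling(epochs / 2), ceiling(3 * epochs / 4))))
}

# ---- parameter initialization ----------------------------------------------

init_conv_unit <- function(kernel, cin, filters, stride, pad) {
  fan_in <- kernel * kernel * cin
  fan_out <- kernel * kernel * filters
  sd <- sqrt(2 / (fan_in + fan_out)) # Xavier/Glorot normal
  list(
    k = kernel, stride = stride, pad = pad, cin = cin, filters = filters,
    W = matrix(rnorm(fan_in * filters, 0, sd), fan_in, filters),
    bn = list(gamma = rep(1, filters), beta = rep(0, filters),
              rmean = rep(0, filters), rvar = rep(1, filters))
  )
}

#' Materialize an architecture into an untrained network
#'
#' Every convolution is followed by batch normalization and a ReLU; the tail
#' is global average pooling, flatten, a fully connected layer with
#' `n_classes` outputs, and softmax. Weights are drawn from the Xavier
#' (Glorot) normal scheme, which keeps gradient scales comparable across
#' layers; biases start at zero. Construction is deterministic given `seed`.
#'
#' @param spec An `arch_spec`; it must pass [audit_spec()].
#' @param n_classes Number of output classes (overrides the spec's
#'   fully-connected row).
#' @param width_multiplier Optional filter-count scale (see
#'   [scale_arch_spec()]) so the architecture shape can be trained at desk
#'   scale on a CPU.
#' @param seed Integer seed for the weight draw.
#' @return A `dual_cnn` model object.
#' @export
build_network <- function(spec, n_classes = 5L, width_multiplier = 1,
                          seed = 1L) {
  audit <- audit_spec(spec)
  if (!audit_passed(audit)) {
    abort(sprintf("spec '%s' fails its shape audit (%d mismatches); fix it before building",
                  spec$name, attr(audit, "n_mismatch")),
          class = "dualpathnet_spec_error")
  }
  spec <- scale_arch_spec(spec, width_multiplier)
  layers <- withr::with_seed(seed, {
    ch <- spec$input[3]
    feat <- NULL
    lapply(spec$modules, function(m) {
      out <- switch(m$kind,
        simple_conv = {
          b <- m$branches[[1]]
          list(kind = m$kind,
               units = list(init_conv_unit(b$kernel, ch, b$filters, b$stride, b$padding)))
        },
        normal_dual = {
          list(kind = m$kind, units = lapply(m$branches, function(b) {
            init_conv_unit(b$kernel, ch, b$filters, b$stride, b$padding)
          }))
        },
        reduction_dual = {
          b <- m$branches[[1]]
          list(kind = m$kind,
               units = list(init_conv_unit(3L, ch, b$filters, 2L, 1L)))
        },
        fully_connected = {
          sd <- sqrt(2 / (ch + n_classes))
          list(kind = m$kind,
               W = matrix(rnorm(ch * n_classes, 0, sd), ch, n_classes),
               b = rep(0, n_classes))
        },
        list(kind = m$kind)
      )
      ch <<- switch(m$kind,
        simple_conv = out$units[[1]]$filters,
        normal_dual = sum(vapply(out$units, `[[`, 0L, "filters")),
        reduction_dual = out$units[[1]]$filters + ch,
        fully_connected = n_classes,
        ch)
      out
    })
  })
  structure(list(
    spec = spec, n_classes = as.integer(n_classes),
    width_multiplier = width_multiplier, seed = as.integer(seed),
    layers = layers, config = NULL,
    history = tibble(epoch = integer(), train_loss = double(),
                     val_accuracy = double(), lr = double())
  ), class = "dual_cnn")
}

#' @export
print.dual_cnn <- function(x, ...) {
  cat(sprintf("<dual_cnn '%s'> input %dx%dx%d, %d modules, %d classes, %d parameters\n",
              x$spec$name, x$spec$input[1], x$spec$input[2], x$spec$input[3],
              length(x$layers), x$n_classes, n_parameters(x)))
  if (nrow(x$history) > 0) {
    best <- which.max(x$history$val_accuracy)
    cat(sprintf("  trained %d epochs; best val accuracy %.4f at epoch %d\n",
                nrow(x$history), x$history$val_accuracy[best],
                x$history$epoch[best]))
  }
  invisible(x)
}

n_parameters <- function(model) {
  total <- 0L
  for (L in model$layers) {
    if (!is.null(L$units)) {
      for (u in L$units) total <- total + length(u$W) + 2L * u$filters
    }
    if (L$kind == "fully_connected") total <- total + length(L$W) + length(L$b)
  }
  total
}

# ---- batch plumbing ---------------------------------------------------------

# Activation matrices are (N*H*W) x C with rows ordered sample, then image
# row, then image column (matching the C++ kernels).
as_act_matrix <- function(images) {
  d <- dim(images[[1]])
  n <- length(images); h <- d[1]; w <- d[2]; ch <- d[3]
  X <- matrix(0, n * h * w, ch)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!identical(dim(img), d)) {
      abort("all images in a batch must share one shape", class = "dualpathnet_spec_error")
    }
    for (c in seq_len(ch)) {
      X[((i - 1) * h * w + 1):(i * h * w), c] <- as.vector(t(img[, , c]))
    }
  }
  list(X = X, n = n, h = h, w = w)
}

check_input_shape <- function(model, images) {
  d <- dim(images[[1]])
  want <- model$spec$input
  if (d[1] != want[2] || d[2] != want[1] || d[3] != want[3]) {
    abort(sprintf("images are %dx%dx%d but the network expects %dx%dx%d",
                  d[2], d[1], d[3], want[1], want[2], want[3]),
          class = "dualpathnet_spec_error")
  }
}

bn_fwd <- function(z, bnp, training) {
  if (training) {
    mu <- colMeans(z)
    va <- pmax(colmeans_sq(z) - mu^2, 0)
    istd <- 1 / sqrt(va + bn_eps)
    xhat <- colscale_shift(z, istd, -mu * istd)
    y <- colscale_shift(xhat, bnp$gamma, bnp$beta)
    list(y = y, cache = list(xhat = xhat, istd = istd),
         running = list(rmean = bn_momentum * bnp$rmean + (1 - bn_momentum) * mu,
                        rvar = bn_momentum * bnp$rvar + (1 - bn_momentum) * va))
  } else {
    scale <- bnp$gamma / sqrt(bnp$rvar + bn_eps)
    list(y = colscale_shift(z, scale, bnp$beta - bnp$rmean * scale),
         cache = NULL, running = NULL)
  }
}

conv_unit_fwd <- function(X, n, h, w, u, training) {
  cols <- im2col_nhwc(X, n, h, w, u$k, u$stride, u$pad)
  ho <- (h - u$k + 2L * u$pad) %/% u$stride + 1L
  wo <- (w - u$k + 2L * u$pad) %/% u$stride + 1L
  bn <- bn_fwd(cols %*% u$W, u$bn, training)
  a <- relu_fwd(bn$y)
  list(a = a, ho = ho, wo = wo, running = bn$running,
       cache = if (training) list(cols = cols, bn = bn$cache, a = a))
}

conv_unit_bwd <- function(dA, cache, u, n, h, w, need_dx = TRUE) {
  dY <- relu_bwd(dA, cache$a)
  bn <- bn_bwd_fused(dY, cache$bn$xhat, u$bn$gamma, cache$bn$istd)
  list(W = crossprod(cache$cols, bn$dx),
       gamma = bn$dgamma, beta = bn$dbeta,
       dX = if (need_dx) {
         col2im_nhwc(tcrossprod(bn$dx, u$W), n, h, w, u$cin,
                     u$k, u$stride, u$pad)
       })
}

net_forward <- function(model, X, n, h, w, training = FALSE) {
  nl <- length(model$layers)
  caches <- vector("list", nl)
  shapes <- matrix(0L, nl, 3)
  pooled <- NULL
  logits <- NULL
  for (i in seq_len(nl)) {
    L <- model$layers[[i]]
    if (L$kind %in% c("simple_conv", "normal_dual", "reduction_dual")) {
      in_dim <- list(h = h, w = w, c = ncol(X))
      rs <- lapply(L$units, function(u) conv_unit_fwd(X, n, h, w, u, training))
      if (training) {
        for (j in seq_along(rs)) {
          if (!is.null(rs[[j]]$running)) {
            model$layers[[i]]$units[[j]]$bn[c("rmean", "rvar")] <- rs[[j]]$running
          }
        }
      }
      parts <- lapply(rs, `[[`, "a")
      pool_cache <- NULL
      if (L$kind == "reduction_dual") {
        mp <- maxpool_nhwc(X, n, h, w, 3L, 2L, 1L)
        parts <- c(parts, list(mp$out))
        pool_cache <- list(argmax = mp$argmax, nrow_x = nrow(X))
      }
      X <- do.call(cbind, parts)
      h <- rs[[1]]$ho; w <- rs[[1]]$wo
      caches[[i]] <- list(in_dim = in_dim,
                          units = lapply(rs, `[[`, "cache"),
                          pool = pool_cache)
    } else if (L$kind == "global_pool") {
      caches[[i]] <- list(hw = h * w)
      X <- rowsum(X, rep(seq_len(n), each = h * w), reorder = FALSE) / (h * w)
      pooled <- X
      h <- 1L; w <- 1L
    } else if (L$kind == "flatten") {
      # pooled rows are already flat vectors
    } else if (L$kind == "fully_connected") {
      caches[[i]] <- list(Xin = X)
      X <- sweep(X %*% L$W, 2, L$b, "+")
      logits <- X
    } else if (L$kind == "softmax") {
      X <- softmax_rows(X)
    }
    shapes[i, ] <- c(w, h, ncol(X))
  }
  list(probs = X, logits = logits, pooled = pooled, caches = caches,
       shapes = shapes, model = model)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

net_backward <- function(model, fwd, dLogits, n) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  d <- dLogits
  for (i in rev(seq_len(nl))) {
    L <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (L$kind == "softmax") {
      # fused with the cross-entropy gradient on the logits
    } else if (L$kind == "fully_connected") {
      grads[[i]] <- list(W = crossprod(cache$Xin, d), b = colSums(d))
      d <- tcrossprod(d, L$W)
    } else if (L$kind == "flatten") {
    } else if (L$kind == "global_pool") {
      d <- d[rep(seq_len(n), each = cache$hw), , drop = FALSE] / cache$hw
    } else if (L$kind %in% c("simple_conv", "normal_dual", "reduction_dual")) {
      in_dim <- cache$in_dim
      offsets <- cumsum(c(0L, vapply(L$units, `[[`, 0L, "filters")))
      dX <- NULL
      ug <- vector("list", length(L$units))
      for (j in seq_along(L$units)) {
        dA <- d[, (offsets[j] + 1):offsets[j + 1], drop = FALSE]
        g <- conv_unit_bwd(dA, cache$units[[j]], L$units[[j]],
                           n, in_dim$h, in_dim$w, need_dx = i > 1)
        ug[[j]] <- g[c("W", "gamma", "beta")]
        if (i > 1) dX <- if (is.null(dX)) g$dX else dX + g$dX
      }
      if (L$kind == "reduction_dual") {
        dPool <- d[, (offsets[length(offsets)] + 1):ncol(d), drop = FALSE]
        dX <- dX + maxpool_bwd_nhwc(dPool, cache$pool$argmax, cache$pool$nrow_x)
      }
      grads[[i]] <- list(units = ug)
      d <- dX
    }
  }
  grads
}

init_momentum_state <- function(model) {
  lapply(model$layers, function(L) {
    if (!is.null(L$units)) {
      list(units = lapply(L$units, function(u) {
        list(W = u$W * 0, gamma = u$bn$gamma * 0, beta = u$bn$beta * 0)
      }))
    } else if (L$kind == "fully_connected") {
      list(W = L$W * 0, b = L$b * 0)
    } else NULL
  })
}

sgd_step <- function(model, grads, state, lr, momentum, wd) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    L <- model$layers[[i]]
    if (!is.null(g$units)) {
      for (j in seq_along(g$units)) {
        gw <- g$units[[j]]$W + wd * L$units[[j]]$W
        state[[i]]$units[[j]]$W <- momentum * state[[i]]$units[[j]]$W + gw
        model$layers[[i]]$units[[j]]$W <- L$units[[j]]$W - lr * state[[i]]$units[[j]]$W
        for (p in c("gamma", "beta")) {
          state[[i]]$units[[j]][[p]] <- momentum * state[[i]]$units[[j]][[p]] + g$units[[j]][[p]]
          model$layers[[i]]$units[[j]]$bn[[p]] <-
            L$units[[j]]$bn[[p]] - lr * state[[i]]$units[[j]][[p]]
        }
      }
    } else if (L$kind == "fully_connected") {
      gw <- g$W + wd * L$W
      state[[i]]$W <- momentum * state[[i]]$W + gw
      model$layers[[i]]$W <- L$W - lr * state[[i]]$W
      state[[i]]$b <- momentum * state[[i]]$b + g$b
      model$layers[[i]]$b <- L$b - lr * state[[i]]$b
    }
  }
  list(model = model, state = state)
}

check_runtime_shapes <- function(model, shapes) {
  want <- infer_shapes(model$spec, check_channels = FALSE)
  got <- tibble(width = shapes[, 1], height = shapes[, 2], channels = shapes[, 3])
  same <- want$width == got$width & want$height == got$height &
    want$channels == got$channels
  # the classifier head may differ from the spec's declared class count
  same[want$kind %in% c("fully_connected", "softmax")] <- TRUE
  if (!all(same)) {
    abort(sprintf("runtime shapes diverge from the shape calculus at module %d",
                  which(!same)[1]), class = "dualpathnet_spec_error")
  }
  invisible(TRUE)
}

# ---- training ----------------------------------------------------------------

#' Train a dual-path network
#'
#' Minibatch stochastic gradient descent with momentum and weight decay on
#' the softmax cross-entropy, with step learning-rate decay. The first batch
#' of the run is shape-audited against [infer_shapes()]. Fully reproducible
#' given `config$seed`.
#'
#' @param model A `dual_cnn` from [build_network()].
#' @param train Image-set tibble `(id, image, label)`; labels in
#'   `0..n_classes-1`.
#' @param validation Optional image-set tibble; per-epoch validation accuracy
#'   is recorded in the history.
#' @param config A [training_config()].
#' @return The trained `dual_cnn` with a `history` tibble
#'   `(epoch, train_loss, val_accuracy, lr)`.
#' @export
train_network <- function(model, train, validation = NULL,
                          config = training_config()) {
  stopifnot(inherits(model, "dual_cnn"))
  if (is.null(train) || nrow(train) == 0) {
    abort("empty training set", class = "dualpathnet_spec_error")
  }
  labels <- as.integer(train$label)
  if (any(labels < 0 | labels >= model$n_classes)) {
    abort(sprintf("labels must lie in 0..%d", model$n_classes - 1),
          class = "dualpathnet_spec_error")
  }
  model$config <- config
  if (config$epochs == 0) return(model)
  check_input_shape(model, train$image)
  decay_epochs <- config$lr_decay_epochs %||% default_decay_epochs(config$epochs)
  n <- nrow(train)
  state <- init_momentum_state(model)
  history <- vector("list", config$epochs)
  withr::with_seed(config$seed, {
    lr <- config$learning_rate
    first_batch <- TRUE
    for (epoch in seq_len(config$epochs)) {
      if (epoch %in% decay_epochs) lr <- lr * config$lr_decay_factor
      order <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1, n)]
        act <- as_act_matrix(train$image[idx])
        fwd <- net_forward(model, act$X, act$n, act$h, act$w, training = TRUE)
        model <- fwd$model # batch-norm running statistics
        if (first_batch) {
          check_runtime_shapes(model, fwd$shapes)
          first_batch <- FALSE
        }
        y <- labels[idx] + 1L
        p <- fwd$probs[cbind(seq_along(idx), y)]
        loss <- -mean(log(pmax(p, 1e-12)))
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
                class = "dualpathnet_divergence_error")
        }
        losses <- c(losses, loss)
        onehot <- matrix(0, length(idx), model$n_classes)
        onehot[cbind(seq_along(idx), y)] <- 1
        dLogits <- (fwd$probs - onehot) / length(idx)
        grads <- net_backward(model, fwd, dLogits, act$n)
        upd <- sgd_step(model, grads, state, lr, config$momentum,
                        config$weight_decay)
        model <- upd$model
        state <- upd$state
      }
      val_acc <- NA_real_
      if (!is.null(validation) && nrow(validation) > 0) {
        preds <- predict(model, validation)
        val_acc <- mean(preds$pred == validation$label)
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 val_accuracy = val_acc, lr = lr)
    }
  })
  model$history <- dplyr::bind_rows(history)
  model
}

#' Predict classes and probabilities
#'
#' Softmax probabilities per class and the argmax class index (ties broken
#' toward the lowest class), in input order.
#'
#' @param object A `dual_cnn`.
#' @param images An image-set tibble (with an `image` list column) or a bare
#'   list of image arrays.
#' @param batch_size Evaluation chunk size.
#' @param ... Unused.
#' @return A tibble with `id` (when available), `pred` (class index, 0-based)
#'   and one `prob_<k>` column per class.
#' @export
predict.dual_cnn <- function(object, images, batch_size = 32L, ...) {
  imgs <- if (is.data.frame(images)) images$image else images
  ids <- if (is.data.frame(images) && "id" %in% names(images)) images$id else NULL
  check_input_shape(object, imgs)
  probs <- matrix(0, length(imgs), object$n_classes)
  for (start in seq(1, length(imgs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(imgs))
    act <- as_act_matrix(imgs[idx])
    fwd <- net_forward(object, act$X, act$n, act$h, act$w, training = FALSE)
    probs[idx, ] <- fwd$probs
  }
  out <- tibble(pred = max.col(probs, ties.method = "first") - 1L)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble(id = ids), out)
  colnames(probs) <- paste0("prob_", seq_len(object$n_classes) - 1L)
  dplyr::bind_cols(out, as_tibble(probs))
}

pooled_features <- function(model, images, batch_size = 32L) {
  imgs <- if (is.data.frame(images)) images$image else images
  check_input_shape(model, imgs)
  width <- flatten_length(model$spec)
  feats <- matrix(0, length(imgs), width)
  for (start in seq(1, length(imgs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(imgs))
    act <- as_act_matrix(imgs[idx])
    fwd <- net_forward(model, act$X, act$n, act$h, act$w, training = FALSE)
    feats[idx, ] <- fwd$pooled
  }
  feats
}

#' Broom-style accessors for trained networks
#'
#' `tidy()` returns the per-epoch history; `glance()` a one-row model
#' summary with the best validation epoch.
#'
#' @param x A `dual_cnn`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dual_cnn
#' @export
tidy.dual_cnn <- function(x, ...) x$history

#' @rdname tidy.dual_cnn
#' @method glance dual_cnn
#' @export
glance.dual_cnn <- function(x, ...) {
  h <- x$history
  best <- if (nrow(h) > 0 && any(!is.na(h$val_accuracy))) which.max(h$val_accuracy) else NA_integer_
  tibble(
    architecture = x$spec$name,
    n_parameters = n_parameters(x),
    epochs_run = nrow(h),
    best_epoch = if (is.na(best)) NA_integer_ else h$epoch[best],
    best_val_accuracy = if (is.na(best)) NA_real_ else h$val_accuracy[best],
    final_train_loss = if (nrow(h) > 0) h$train_loss[nrow(h)] else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Save or load a model checkpoint
#'
#' A checkpoint is a single file holding the weights, the architecture spec,
#' the training configuration and the history.
#'
#' @param model A `dual_cnn`.
#' @param path Checkpoint file path.
#' @return `load_model()` returns the `dual_cnn`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("checkpoint not found: ", path), class = "dualpathnet_io_error")
  }
  model <- readRDS(path)
  if (!inherits(model, "dual_cnn")) {
    abort("file is not a dual_cnn checkpoint", class = "dualpathnet_io_error")
  }
  model
}
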