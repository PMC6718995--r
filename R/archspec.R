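#' @useDynLib dualpathnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Padding conventions forced by the printed output sizes: 1x1 convs are
# unpadded, 3x3 convs and pools (stride 1 or 2) use p = 1, the 9x9 stride-3
# stem conv uses p = 2.
default_padding <- function(kernel) {
  switch(as.character(kernel), `1` = 0L, `3` = 1L, `9` = 2L, as.integer(kernel %/% 2))
}

#' Output width of a square convolution
#'
#' Computes the spatial output size of a convolution (or pooling window) on a
#' square input: `floor((win - k + 2p) / s) + 1`. Integer (floor) division is
#' the convention throughout the package; it is the only choice that chains
#' the bundled architecture tables exactly (224 -> 74 -> 37 -> 19 -> 10 for
#' the reductive network).
#'
#' @param win Input width in pixels (positive integer).
#' @param k Kernel width in pixels.
#' @param p Padding in pixels (non-negative).
#' @param s Stride in pixels (>= 1).
#' @param .where Optional label naming the module, used in error messages.
#' @return The output width in pixels (positive integer).
#' @examples
#' conv_output_size(224, 9, 2, 3) # 74
#' conv_output_size(74, 3, 1, 2)  # 37
#' @export
conv_output_size <- function(win, k, p = 0L, s = 1L, .where = NULL) {
  stopifnot(length(win) == 1, length(k) == 1, length(p) == 1, length(s) == 1)
  if (s < 1) abort("stride must be >= 1", class = "dualpathnet_geometry_error")
  if (p < 0) abort("padding must be >= 0", class = "dualpathnet_geometry_error")
  out <- (win - k + 2L * p) %/% s + 1L
  if (out < 1) {
    where <- if (is.null(.where)) "" else paste0(" in ", .where)
    abort(sprintf(
      "invalid geometry%s: input width %d, kernel %d, padding %d, stride %d gives non-positive output",
      where, as.integer(win), as.integer(k), as.integer(p), as.integer(s)
    ), class = "dualpathnet_geometry_error")
  }
  as.integer(out)
}

#' Convolution branch description
#'
#' @param kernel Kernel width = height in pixels (1, 3 or 9).
#' @param filters Number of output filters.
#' @param stride Stride in pixels.
#' @param padding Padding in pixels; defaults to the package convention
#'   (0 for 1x1, 1 for 3x3, 2 for 9x9).
#' @param in_channels Optional declared input channel depth (for auditing
#'   against a printed table row).
#' @return A `conv_kernel` list.
#' @export
conv_kernel <- function(kernel, filters, stride = 1L, padding = NULL,
                        in_channels = NULL) {
  if (!kernel %in% c(1L, 3L, 9L)) {
    abort("kernel width must be 1, 3 or 9", class = "dualpathnet_spec_error")
  }
  if (!stride %in% c(1L, 2L, 3L)) {
    abort("stride must be 1, 2 or 3", class = "dualpathnet_spec_error")
  }
  if (is.null(padding)) padding <- default_padding(kernel)
  structure(list(
    kernel = as.integer(kernel), filters = as.integer(filters),
    stride = as.integer(stride), padding = as.integer(padding),
    in_channels = if (is.null(in_channels)) NULL else as.integer(in_channels)
  ), class = "conv_kernel")
}

new_module <- function(kind, branches = list(), pool_kernel = NULL,
                       out_classes = NULL, declared_output = NULL) {
  structure(list(
    kind = kind, branches = branches, pool_kernel = pool_kernel,
    out_classes = out_classes, declared_output = canonical_shape(declared_output)
  ), class = "arch_module")
}

canonical_shape <- function(x) {
  if (is.null(x)) return(NULL)
  x <- as.integer(x)
  if (length(x) == 1) x <- c(1L, 1L, x) # flatten / FC rows print "(n x 1)"
  if (length(x) != 3) abort("a shape is width, height, channels", class = "dualpathnet_spec_error")
  x
}

#' Module constructors
#'
#' Builders for the module kinds of the dual-path architecture family: a
#' plain stem convolution; a normal dual-path module (parallel 1x1 and 3x3
#' stride-1 branches, channel-concatenated); a reduction dual-path module
#' (3x3 stride-2 convolution branch plus 3x3 stride-2 max-pooling branch that
#' passes all input channels through); global average pooling; flatten; the
#' fully connected classifier head; and softmax.
#'
#' @param filters,filters_1x1,filters_3x3 Filter counts for the branches.
#' @param kernel,stride,padding Stem convolution geometry.
#' @param in_channels Declared input channel depth (optional, for auditing).
#' @param pool_kernel Declared pooling window width (optional, for auditing).
#' @param classes Number of output classes of the fully connected layer.
#' @param output Optional declared output shape `c(w, h, channels)` (or a
#'   single length for flatten/fully-connected rows) as printed in an
#'   architecture table; audited by [audit_spec()].
#' @return An `arch_module` object.
#' @name arch-modules
NULL

#' @rdname arch-modules
#' @export
mod_simple_conv <- function(filters, kernel = 3L, stride = 1L, padding = NULL,
                            in_channels = NULL, output = NULL) {
  new_module("simple_conv",
    branches = list(conv_kernel(kernel, filters, stride, padding, in_channels)),
    declared_output = output
  )
}

#' @rdname arch-modules
#' @export
mod_normal_dual <- function(filters_1x1, filters_3x3, in_channels = NULL,
                            output = NULL) {
  new_module("normal_dual",
    branches = list(
      conv_kernel(1L, filters_1x1, 1L, in_channels = in_channels),
      conv_kernel(3L, filters_3x3, 1L, in_channels = in_channels)
    ),
    declared_output = output
  )
}

#' @rdname arch-modules
#' @export
mod_reduction_dual <- function(filters, in_channels = NULL, output = NULL) {
  new_module("reduction_dual",
    branches = list(conv_kernel(3L, filters, 2L, in_channels = in_channels)),
    pool_kernel = 3L,
    declared_output = output
  )
}

#' @rdname arch-modules
#' @export
mod_global_pool <- function(pool_kernel = NULL, output = NULL) {
  new_module("global_pool", pool_kernel = pool_kernel, declared_output = output)
}

#' @rdname arch-modules
#' @export
mod_flatten <- function(output = NULL) new_module("flatten", declared_output = output)

#' @rdname arch-modules
#' @export
mod_fully_connected <- function(classes, output = NULL) {
  new_module("fully_connected", out_classes = as.integer(classes),
             declared_output = output)
}

#' @rdname arch-modules
#' @export
mod_softmax <- function(output = NULL) new_module("softmax", declared_output = output)

#' Declare a dual-path CNN architecture
#'
#' An architecture is an input shape plus an ordered list of modules. The
#' structural invariants of the family are enforced: the first module is a
#' simple convolution, and the tail is exactly one global pooling, flatten,
#' fully connected and softmax module, in that order.
#'
#' @param name Identifier for the architecture.
#' @param input Input shape, `c(width, height, channels)`.
#' @param modules List of `arch_module` objects (see [mod_simple_conv()]).
#' @return An `arch_spec` object.
#' @export
arch_spec <- function(name, input, modules) {
  spec <- structure(list(
    name = name,
    input = canonical_shape(input),
    modules = modules
  ), class = "arch_spec")
  validate_arch_spec(spec)
  spec
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec '%s'> input %dx%dx%d, %d modules\n",
              x$name, x$input[1], x$input[2], x$input[3], length(x$modules)))
  invisible(x)
}

validate_arch_spec <- function(spec) {
  if (any(spec$input < 1)) abort("input shape entries must be >= 1", class = "dualpathnet_spec_error")
  kinds <- vapply(spec$modules, `[[`, "", "kind")
  if (length(kinds) < 5) abort("an architecture needs a stem and the four-module tail", class = "dualpathnet_spec_error")
  if (kinds[1] != "simple_conv") {
    abort("first module must be a simple convolution", class = "dualpathnet_spec_error")
  }
  tail_kinds <- c("global_pool", "flatten", "fully_connected", "softmax")
  n <- length(kinds)
  if (!identical(kinds[(n - 3):n], tail_kinds) ||
      any(vapply(tail_kinds, function(k) sum(kinds == k), 0L) != 1L)) {
    abort("tail must be exactly one global_pool, flatten, fully_connected, softmax, in that order",
          class = "dualpathnet_spec_error")
  }
  if (!all(kinds[2:(n - 4)] %in% c("normal_dual", "reduction_dual")) && n > 5) {
    abort("body modules must be normal_dual or reduction_dual", class = "dualpathnet_spec_error")
  }
  invisible(spec)
}

#' Output shape of one module
#'
#' Applies a single module's shape semantics to an incoming
#' width x height x channels triple: normal dual-path modules preserve the
#' spatial size and concatenate the two branches' filter counts; reduction
#' modules halve width and height via [conv_output_size()] with k = 3, p = 1,
#' s = 2 and append all incoming channels (the max-pool branch) to the
#' convolution branch's filters; global pooling collapses to 1 x 1.
#'
#' @param input Incoming shape `c(width, height, channels)`.
#' @param m An `arch_module`.
#' @param check_channels If `TRUE`, a declared branch input depth that does
#'   not match the incoming channels raises an audit error.
#' @param .where Label used in error messages.
#' @return The outgoing shape `c(width, height, channels)` (flatten and later
#'   stages are reported as `c(1, 1, length)`).
#' @export
module_output <- function(input, m, check_channels = TRUE, .where = NULL) {
  input <- canonical_shape(input)
  w <- input[1]; h <- input[2]; ch <- input[3]
  where <- if (is.null(.where)) m$kind else .where
  check_depth <- function(b) {
    if (check_channels && !is.null(b$in_channels) && b$in_channels != ch) {
      abort(sprintf("%s: declared kernel depth %d does not match incoming channels %d",
                    where, b$in_channels, ch), class = "dualpathnet_channel_error")
    }
  }
  switch(m$kind,
    simple_conv = {
      b <- m$branches[[1]]; check_depth(b)
      wo <- conv_output_size(w, b$kernel, b$padding, b$stride, .where = where)
      ho <- conv_output_size(h, b$kernel, b$padding, b$stride, .where = where)
      c(wo, ho, b$filters)
    },
    normal_dual = {
      for (b in m$branches) check_depth(b)
      c(w, h, sum(vapply(m$branches, `[[`, 0L, "filters")))
    },
    reduction_dual = {
      b <- m$branches[[1]]; check_depth(b)
      wo <- conv_output_size(w, 3L, 1L, 2L, .where = where)
      ho <- conv_output_size(h, 3L, 1L, 2L, .where = where)
      c(wo, ho, b$filters + ch) # pool branch passes every input channel through
    },
    global_pool = c(1L, 1L, ch),
    flatten = c(1L, 1L, ch),
    fully_connected = c(1L, 1L, m$out_classes),
    softmax = c(1L, 1L, ch),
    abort(paste0("unknown module kind: ", m$kind), class = "dualpathnet_spec_error")
  )
}

#' Infer every intermediate shape of an architecture
#'
#' Chains [module_output()] over the module list, starting from the declared
#' input shape. Deterministic and total on valid specs.
#'
#' @param spec An `arch_spec`.
#' @param check_channels Passed to [module_output()].
#' @return A tibble with one row per module: `module` (index), `kind`,
#'   `width`, `height`, `channels`.
#' @export
infer_shapes <- function(spec, check_channels = TRUE) {
  validate_arch_spec(spec)
  shape <- spec$input
  rows <- vector("list", length(spec$modules))
  for (i in seq_along(spec$modules)) {
    m <- spec$modules[[i]]
    shape <- module_output(shape, m, check_channels = check_channels,
                           .where = sprintf("module %d (%s)", i, m$kind))
    rows[[i]] <- tibble(module = i, kind = m$kind,
                        width = shape[1], height = shape[2], channels = shape[3])
  }
  dplyr::bind_rows(rows)
}

#' Length of the flattened feature vector
#'
#' @param spec An `arch_spec`.
#' @return Integer: the pooled feature dimension entering the classifier.
#' @export
flatten_length <- function(spec) {
  sh <- infer_shapes(spec, check_channels = FALSE)
  sh$channels[sh$kind == "flatten"][1]
}

#' Audit an architecture against its declared output sizes
#'
#' Re-derives every module's output shape from the shape calculus and
#' compares it with the `declared_output` recorded on each module (the
#' printed "Output Size" table cells). Channel-depth mismatches between a
#' branch's declared kernel depth and the incoming channels are recorded as
#' report entries, not raised.
#'
#' @param spec An `arch_spec`.
#' @return A tibble with per-module inferred and declared shapes, a `match`
#'   column (`NA` where no output was declared), and a `note` column for
#'   depth mismatches. The number of mismatches is in attribute
#'   `n_mismatch`; see [audit_passed()].
#' @export
audit_spec <- function(spec) {
  validate_arch_spec(spec)
  shape <- spec$input
  rows <- vector("list", length(spec$modules))
  for (i in seq_along(spec$modules)) {
    m <- spec$modules[[i]]
    note <- NA_character_
    for (b in m$branches) {
      if (!is.null(b$in_channels) && b$in_channels != shape[3]) {
        note <- sprintf("declared kernel depth %d vs incoming channels %d",
                        b$in_channels, shape[3])
      }
    }
    shape <- module_output(shape, m, check_channels = FALSE)
    decl <- m$declared_output
    match <- if (is.null(decl)) NA else identical(canonical_shape(decl), as.integer(shape))
    rows[[i]] <- tibble(
      module = i, kind = m$kind,
      width = shape[1], height = shape[2], channels = shape[3],
      declared_width = if (is.null(decl)) NA_integer_ else decl[1],
      declared_height = if (is.null(decl)) NA_integer_ else decl[2],
      declared_channels = if (is.null(decl)) NA_integer_ else decl[3],
      match = match, note = note
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_mismatch") <- sum(!out$match, na.rm = TRUE) + sum(!is.na(out$note))
  out
}

#' @rdname audit_spec
#' @param audit A tibble returned by [audit_spec()].
#' @export
audit_passed <- function(audit) attr(audit, "n_mismatch") == 0L

#' Scale every filter count of an architecture
#'
#' Multiplies all convolution filter counts by `width_multiplier` (rounding,
#' minimum 1) so the architecture shape can be trained faithfully at desk
#' scale. Declared outputs and declared kernel depths are dropped since they
#' no longer apply.
#'
#' @param spec An `arch_spec`.
#' @param width_multiplier Positive scale factor, e.g. 0.25.
#' @return A new `arch_spec` named `"<name>@<width_multiplier>"`.
#' @export
scale_arch_spec <- function(spec, width_multiplier) {
  stopifnot(width_multiplier > 0)
  if (width_multiplier == 1) return(spec)
  mods <- lapply(spec$modules, function(m) {
    m$branches <- lapply(m$branches, function(b) {
      b$filters <- max(1L, as.integer(round(b$filters * width_multiplier)))
      b$in_channels <- NULL
      b
    })
    m$declared_output <- NULL
    m
  })
  arch_spec(sprintf("%s@%g", spec$name, width_multiplier), spec$input, mods)
}

# ---- bundled architectures -------------------------------------------------

table2_body <- function() {
  list(
    mod_normal_dual(32, 32, in_channels = 96, output = c(74, 74, 64)),
    mod_normal_dual(32, 48, in_channels = 64, output = c(74, 74, 80)),
    mod_reduction_dual(80, in_channels = 80, output = c(37, 37, 160)),
    mod_normal_dual(112, 48, in_channels = 160, output = c(37, 37, 160)),
    mod_normal_dual(96, 64, in_channels = 160, output = c(37, 37, 160)),
    mod_normal_dual(80, 80, in_channels = 160, output = c(37, 37, 160)),
    mod_normal_dual(48, 96, in_channels = 160, output = c(37, 37, 144)),
    mod_reduction_dual(96, in_channels = 144, output = c(19, 19, 240)),
    mod_normal_dual(176, 160, in_channels = 240, output = c(19, 19, 336)),
    mod_normal_dual(176, 160, in_channels = 336, output = c(19, 19, 336)),
    mod_reduction_dual(96, in_channels = 336, output = c(10, 10, 432)),
    mod_normal_dual(176, 160, in_channels = 432, output = c(10, 10, 336)),
    mod_normal_dual(176, 160, in_channels = 336, output = c(10, 10, 336))
  )
}

# Same module sequence evaluated at other spatial resolutions; declared
# outputs follow from the halving arithmetic.
respaced <- function(mods, widths) {
  stopifnot(length(mods) == length(widths))
  purrr::map2(mods, widths, function(m, w) {
    if (!is.null(m$declared_output)) m$declared_output[1:2] <- c(w, w)
    m
  })
}

spec_reductive <- function() {
  arch_spec("reductive", c(224, 224, 3), c(
    list(mod_simple_conv(96, kernel = 9, stride = 3, padding = 2,
                         in_channels = 3, output = c(74, 74, 96))),
    table2_body(),
    list(
      mod_global_pool(pool_kernel = 10, output = c(1, 1, 336)),
      mod_flatten(output = 336),
      mod_fully_connected(5, output = 5),
      mod_softmax(output = 5)
    )
  ))
}

spec_original <- function() {
  arch_spec("original", c(64, 64, 3), c(
    list(mod_simple_conv(96, kernel = 3, stride = 1,
                         in_channels = 3, output = c(64, 64, 96))),
    respaced(table2_body(), c(64, 64, 32, 32, 32, 32, 32, 16, 16, 16, 8, 8, 8)),
    list(
      mod_global_pool(pool_kernel = 8, output = c(1, 1, 336)),
      mod_flatten(output = 336),
      mod_fully_connected(5, output = 5),
      mod_softmax(output = 5)
    )
  ))
}

deepened_front <- function() {
  c(
    list(mod_simple_conv(96, kernel = 3, stride = 1,
                         in_channels = 3, output = c(224, 224, 96))),
    respaced(table2_body(),
             c(224, 224, 112, 112, 112, 112, 112, 56, 56, 56, 28, 28, 28))
  )
}

spec_deepened <- function() {
  arch_spec("deepened", c(224, 224, 3), c(
    deepened_front(),
    list(
      mod_reduction_dual(112, in_channels = 336, output = c(14, 14, 448)),
      mod_normal_dual(224, 192, in_channels = 448, output = c(14, 14, 416)),
      mod_normal_dual(224, 192, in_channels = 416, output = c(14, 14, 416)),
      mod_reduction_dual(112, in_channels = 416, output = c(7, 7, 528)),
      mod_normal_dual(224, 192, in_channels = 528, output = c(7, 7, 416)),
      mod_normal_dual(224, 192, in_channels = 416, output = c(7, 7, 416)),
      mod_global_pool(pool_kernel = 7, output = c(1, 1, 416)),
      mod_flatten(output = 416),
      mod_fully_connected(5, output = 5),
      mod_softmax(output = 5)
    )
  ))
}

spec_revised_deepened <- function() {
  arch_spec("revised_deepened", c(224, 224, 3), c(
    deepened_front(),
    list(
      mod_reduction_dual(96, in_channels = 336, output = c(14, 14, 432)),
      mod_normal_dual(176, 160, in_channels = 432, output = c(14, 14, 336)),
      mod_normal_dual(176, 160, in_channels = 336, output = c(14, 14, 336)),
      mod_reduction_dual(96, in_channels = 336, output = c(7, 7, 432)),
      mod_normal_dual(176, 160, in_channels = 432, output = c(7, 7, 336)),
      mod_normal_dual(176, 160, in_channels = 336, output = c(7, 7, 336)),
      mod_global_pool(pool_kernel = 7, output = c(1, 1, 336)),
      mod_flatten(output = 336),
      mod_fully_connected(5, output = 5),
      mod_softmax(output = 5)
    )
  ))
}

#' The four bundled dual-path architectures
#'
#' `original` (64x64 input, 3x3 stride-1 stem), `reductive` (224x224 input,
#' 9x9 stride-3 stem), `deepened` (224x224, six extra modules with wider
#' kernels in the tail) and `revised_deepened` (224x224, the six extra
#' modules with the narrower kernel counts). Every spec carries the printed
#' output-size cells as `declared_output` and passes [audit_spec()].
#'
#' @return A named list of four `arch_spec` objects.
#' @export
builtin_specs <- function() {
  list(
    original = spec_original(),
    reductive = spec_reductive(),
    deepened = spec_deepened(),
    revised_deepened = spec_revised_deepened()
  )
}

# ---- spec files ------------------------------------------------------------

#' Read or write an architecture spec file
#'
#' Architecture files are flat YAML: a `name`, an `input` shape, and one
#' entry per module with its kind and kernel/filter/stride fields. Files for
#' the four bundled architectures ship under
#' `system.file("extdata", "archs", package = "dualpathnet")`.
#'
#' @param path File path.
#' @return `read_arch_spec()` returns an `arch_spec`;
#'   `write_arch_spec()` returns `path` invisibly.
#' @export
read_arch_spec <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("architecture file not found: ", path), class = "dualpathnet_io_error")
  }
  y <- yaml::read_yaml(path)
  mods <- lapply(y$modules, function(m) {
    out <- if (is.null(m$output)) NULL else unlist(m$output)
    switch(m$kind,
      simple_conv = mod_simple_conv(m$filters, kernel = m$kernel %||% 3L,
                                    stride = m$stride %||% 1L,
                                    padding = m$padding,
                                    in_channels = m$in_channels, output = out),
      normal_dual = mod_normal_dual(m$filters_1x1, m$filters_3x3,
                                    in_channels = m$in_channels, output = out),
      reduction_dual = mod_reduction_dual(m$filters, in_channels = m$in_channels,
                                          output = out),
      global_pool = mod_global_pool(pool_kernel = m$pool_kernel, output = out),
      flatten = mod_flatten(output = out),
      fully_connected = mod_fully_connected(m$classes, output = out),
      softmax = mod_softmax(output = out),
      abort(paste0("unknown module kind in file: ", m$kind),
            class = "dualpathnet_spec_error")
    )
  })
  arch_spec(y$name, unlist(y$input), mods)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_arch_spec
#' @param spec An `arch_spec` to serialize.
#' @export
write_arch_spec <- function(spec, path) {
  mods <- lapply(spec$modules, function(m) {
    entry <- list(kind = m$kind)
    if (m$kind == "simple_conv") {
      b <- m$branches[[1]]
      entry <- c(entry, list(kernel = b$kernel, filters = b$filters,
                             stride = b$stride, padding = b$padding))
      if (!is.null(b$in_channels)) entry$in_channels <- b$in_channels
    } else if (m$kind == "normal_dual") {
      entry$filters_1x1 <- m$branches[[1]]$filters
      entry$filters_3x3 <- m$branches[[2]]$filters
      if (!is.null(m$branches[[1]]$in_channels)) {
        entry$in_channels <- m$branches[[1]]$in_channels
      }
    } else if (m$kind == "reduction_dual") {
      entry$filters <- m$branches[[1]]$filters
      if (!is.null(m$branches[[1]]$in_channels)) {
        entry$in_channels <- m$branches[[1]]$in_channels
      }
    } else if (m$kind == "global_pool") {
      if (!is.null(m$pool_kernel)) entry$pool_kernel <- m$pool_kernel
    } else if (m$kind == "fully_connected") {
      entry$classes <- m$out_classes
    }
    if (!is.null(m$declared_output)) entry$output <- as.integer(m$declared_output)
    entry
  })
  yaml::write_yaml(list(name = spec$name,
                        input = as.integer(spec$input),
                        modules = mods), path)
  invisible(path)
}

#' Locate a bundled or user architecture
#'
#' Resolves `name_or_path` first against the four builtin names, then as a
#' file path to a YAML spec.
#'
#' @param name_or_path Builtin name (`"original"`, `"reductive"`,
#'   `"deepened"`, `"revised_deepened"`) or a path.
#' @return An `arch_spec`.
#' @export
resolve_arch <- function(name_or_path) {
  builtins <- builtin_specs()
  if (name_or_path %in% names(builtins)) return(builtins[[name_or_path]])
  read_arch_spec(name_or_path)
}
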