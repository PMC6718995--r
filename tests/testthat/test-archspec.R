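test_that("conv_output_size reproduces the printed stem and reduction widths", {
  expect_identical(conv_output_size(224, 9, 2, 3), 74L)
  expect_identical(conv_output_size(74, 3, 1, 2), 37L)
  # 1x1 stride-1 is geometric identity
  for (w in c(1L, 7L, 64L, 224L)) {
    expect_identical(conv_output_size(w, 1, 0, 1), w)
  }
  # three successive halvings from the 64-pixel canvas end at 8x8
  w <- 64L
  for (expected in c(32L, 16L, 8L)) {
    w <- conv_output_size(w, 3, 1, 2)
    expect_identical(w, expected)
  }
})

test_that("conv_output_size matches the sliding-window oracle on a parameter grid", {
  for (k in c(1L, 3L, 9L)) {
    for (p in c(0L, 1L, 2L)) {
      for (s in c(1L, 2L, 3L)) {
        for (win in seq(max(k, 3L), 40L, by = 7L)) {
          expect_identical(conv_output_size(win, k, p, s),
                           slide_count(win, k, p, s),
                           info = sprintf("win=%d k=%d p=%d s=%d", win, k, p, s))
        }
      }
    }
  }
})

test_that("invalid geometry raises an error naming the module", {
  expect_error(conv_output_size(2, 9, 0, 1, .where = "module 1 (simple_conv)"),
               "module 1", class = "dualpathnet_geometry_error")
  expect_error(conv_output_size(5, 3, 0, 0), class = "dualpathnet_geometry_error")
})

test_that("module_output implements dual-path concatenation semantics", {
  # normal dual: printed 19x19x240 -> 19x19x336 (176 + 160)
  out <- module_output(c(19, 19, 240), mod_normal_dual(176, 160, in_channels = 240))
  expect_identical(out, c(19L, 19L, 336L))
  # reduction dual: printed 14x14x416 -> 7x7x528 (112 conv + 416 pass-through)
  out <- module_output(c(14, 14, 416), mod_reduction_dual(112, in_channels = 416))
  expect_identical(out, c(7L, 7L, 528L))
  # global pooling collapses 10x10x336 to 1x1x336
  out <- module_output(c(10, 10, 336), mod_global_pool())
  expect_identical(out, c(1L, 1L, 336L))
})

test_that("channel depth mismatches are caught", {
  expect_error(
    module_output(c(19, 19, 200), mod_normal_dual(176, 160, in_channels = 240)),
    "declared kernel depth", class = "dualpathnet_channel_error"
  )
})

test_that("channel conservation holds for dual modules on random cases", {
  withr::with_seed(11, {
    for (i in 1:25) {
      ch <- sample(8:512, 1)
      f1 <- sample(8:256, 1); f3 <- sample(8:256, 1)
      w <- sample(7:64, 1)
      out <- module_output(c(w, w, ch), mod_normal_dual(f1, f3))
      expect_identical(out[3], as.integer(f1 + f3))
      fr <- sample(8:256, 1)
      out <- module_output(c(w, w, ch), mod_reduction_dual(fr))
      expect_identical(out[3], as.integer(fr + ch))
    }
  })
})

test_that("bundled architectures reproduce every printed output-size cell", {
  specs <- builtin_specs()
  expect_length(specs, 4)
  for (nm in names(specs)) {
    audit <- audit_spec(specs[[nm]])
    expect_identical(attr(audit, "n_mismatch"), 0L, info = nm)
    expect_true(all(audit$match, na.rm = TRUE), info = nm)
  }
  # every module of the two fully printed tables carries a declared cell
  expect_true(all(!is.na(audit_spec(specs$reductive)$match)))
  expect_true(all(!is.na(audit_spec(specs$deepened)$match)))
  expect_identical(flatten_length(specs$reductive), 336L)
  expect_identical(flatten_length(specs$deepened), 416L)
  expect_identical(flatten_length(specs$revised_deepened), 336L)
  # original: last dual modules see 8x8 maps
  sh <- infer_shapes(specs$original)
  last_dual <- max(which(sh$kind == "normal_dual"))
  expect_identical(sh$width[last_dual], 8L)
  expect_identical(sh$height[last_dual], 8L)
})

test_that("a perturbed filter count is flagged at the right module", {
  spec <- builtin_specs()$reductive
  spec$modules[[2]]$branches[[1]]$filters <- 33L # was 32
  audit <- audit_spec(spec)
  expect_gt(attr(audit, "n_mismatch"), 0)
  expect_false(audit$match[2])
})

test_that("infer_shapes is deterministic and total on a degenerate spec", {
  spec <- arch_spec("degenerate", c(9, 9, 1), list(
    mod_simple_conv(4, kernel = 3, stride = 1),
    mod_global_pool(),
    mod_flatten(),
    mod_fully_connected(2),
    mod_softmax()
  ))
  sh1 <- infer_shapes(spec)
  sh2 <- infer_shapes(spec)
  expect_identical(sh1, sh2)
  expect_identical(nrow(sh1), length(spec$modules))
  expect_true(all(sh1$width >= 1 & sh1$height >= 1 & sh1$channels >= 1))
})

test_that("structural invariants are enforced", {
  expect_error(arch_spec("bad", c(16, 16, 3), list(
    mod_normal_dual(4, 4), mod_global_pool(), mod_flatten(),
    mod_fully_connected(2), mod_softmax()
  )), "simple convolution", class = "dualpathnet_spec_error")
  expect_error(arch_spec("bad", c(16, 16, 3), list(
    mod_simple_conv(8), mod_flatten(), mod_global_pool(),
    mod_fully_connected(2), mod_softmax()
  )), class = "dualpathnet_spec_error")
})

test_that("spec files round-trip through the YAML format", {
  dir <- withr::local_tempdir()
  for (nm in c("original", "deepened")) {
    spec <- builtin_specs()[[nm]]
    path <- file.path(dir, paste0(nm, ".yaml"))
    write_arch_spec(spec, path)
    rt <- read_arch_spec(path)
    expect_identical(infer_shapes(rt), infer_shapes(spec))
    expect_true(audit_passed(audit_spec(rt)))
  }
  bundled <- system.file("extdata", "archs", "reductive.yaml", package = "dualpathnet")
  expect_true(nzchar(bundled))
  expect_true(audit_passed(audit_spec(read_arch_spec(bundled))))
  expect_error(read_arch_spec(file.path(dir, "nope.yaml")),
               "nope.yaml", class = "dualpathnet_io_error")
})

test_that("scale_arch_spec shrinks filters but preserves structure", {
  spec <- scale_arch_spec(builtin_specs()$original, 0.25)
  sh <- infer_shapes(spec, check_channels = FALSE)
  expect_identical(sh$width, infer_shapes(builtin_specs()$original)$width)
  expect_identical(flatten_length(spec), 84L) # 44 + 40 from the last dual
})
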