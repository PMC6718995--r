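make_specimens <- function(...) {
  tibble::tibble(...)
}

test_that("normalize_parameters max-scales each parameter independently", {
  one <- make_specimens(doping = 2, angle = 30, force = 4, pressure = 5e4,
                        current = 10, label = 0L)
  norm <- normalize_parameters(one)
  for (col in c("doping", "angle", "force", "pressure", "current")) {
    expect_equal(norm[[col]], 1.0)
  }
  two <- make_specimens(doping = c(1, 2), angle = c(10, 20), force = c(1, 4),
                        pressure = c(1e4, 5e4), current = c(2, 4),
                        label = c(0L, 1L))
  norm <- normalize_parameters(two)
  expect_equal(norm$current, c(0.5, 1.0))
  expect_true(all(as.matrix(norm[, c("doping", "angle", "force", "pressure", "current")]) <= 1))
  expect_identical(norm$label, two$label)
})

test_that("an all-zero parameter column warns and stays zero", {
  z <- make_specimens(doping = c(0, 0), angle = c(1, 2), force = c(1, 2),
                      pressure = c(1, 2), current = c(1, 2), label = c(0L, 1L))
  expect_warning(norm <- normalize_parameters(z), "doping")
  expect_equal(norm$doping, c(0, 0))
})

test_that("pressure range expansion has the arithmetic-progression cardinality", {
  s <- make_specimens(doping = 1, angle = 2, force = 3, pressure_low = 0,
                      pressure_high = 590, current = 5, label = 3L)
  out <- expand_pressure_range(s, increment = 295)
  expect_identical(nrow(out), 3L)
  expect_equal(out$pressure, c(0, 295, 590))
  expect_true(all(out$label == 3L))

  out <- expand_pressure_range(s, increment = 147.5)
  expect_identical(nrow(out), 5L)

  degenerate <- make_specimens(doping = 1, angle = 2, force = 3,
                               pressure_low = 100, pressure_high = 100,
                               current = 5, label = 0L)
  expect_identical(nrow(expand_pressure_range(degenerate)), 1L)

  expect_error(expand_pressure_range(s, increment = 0),
               class = "dualpathnet_spec_error")
})

test_that("expansion cardinality matches floor((high-low)/inc)+1 on random ranges", {
  withr::with_seed(7, {
    for (i in 1:40) {
      low <- runif(1, 0, 1e5)
      high <- low + runif(1, 0, 5e4)
      inc <- runif(1, 50, 5000)
      s <- make_specimens(doping = 1, angle = 1, force = 1,
                          pressure_low = low, pressure_high = high,
                          current = 1, label = 0L)
      expect_identical(nrow(expand_pressure_range(s, increment = inc)),
                       as.integer(floor((high - low) / inc) + 1))
    }
  })
})

test_that("the five zones partition the canvas with the background", {
  layout <- zone_layout()
  expect_identical(attr(layout, "canvas"), 64L)
  expect_true(all(layout$height == 20L & layout$width == 20L))
  total <- matrix(0L, 64, 64)
  for (z in 1:5) total <- total + dualpathnet:::zone_mask(layout, z)
  expect_true(all(total <= 1L)) # pairwise disjoint
  expect_identical(sum(total), 5L * 400L)
})

test_that("zone encoding round-trips parameter values within quantization", {
  layout <- zone_layout()
  s <- make_specimens(doping = 0.2, angle = 0.4, force = 0.6, pressure = 0.8,
                      current = 1.0, label = 1L)
  img <- encode_specimen(s, layout)
  values <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  for (z in 1:5) {
    mask <- dualpathnet:::zone_mask(layout, z)
    expect_lt(abs(mean(img[mask]) / 255 - values[z]), 1 / 255)
  }
  # current = 1.0 renders zone 5 as pure white
  expect_true(all(img[dualpathnet:::zone_mask(layout, 5)] == 255L))
  # background black
  bg <- !Reduce(`|`, lapply(1:5, function(z) dualpathnet:::zone_mask(layout, z)))
  expect_true(all(img[bg] == 0L))

  zero <- make_specimens(doping = 0, angle = 0, force = 0, pressure = 0,
                         current = 0, label = 0L)
  expect_true(all(encode_specimen(zero, layout) == 0L))

  bad <- make_specimens(doping = 1.2, angle = 0, force = 0, pressure = 0,
                        current = 0, label = 0L)
  expect_error(encode_specimen(bad, layout), class = "dualpathnet_spec_error")
})

test_that("encoding is local: changing one parameter changes only its zone", {
  layout <- zone_layout()
  a <- make_specimens(doping = 0.5, angle = 0.3, force = 0.7, pressure = 0.2,
                      current = 0.9, label = 0L)
  b <- a; b$angle <- 0.8
  ia <- encode_specimen(a, layout); ib <- encode_specimen(b, layout)
  diff <- ia != ib
  expect_true(all(diff[dualpathnet:::zone_mask(layout, 2)]))
  expect_true(all(!diff[!dualpathnet:::zone_mask(layout, 2)]))
})

test_that("encoding is injective on the quantized parameter grid", {
  layout <- zone_layout()
  withr::with_seed(3, {
    grid <- round(matrix(runif(60 * 5), 60, 5) * 255) / 255
    grid <- grid[!duplicated(grid), , drop = FALSE]
    sigs <- apply(grid, 1, function(v) {
      s <- tibble::tibble(doping = v[1], angle = v[2], force = v[3],
                          pressure = v[4], current = v[5], label = 0L)
      paste(encode_specimen(s, layout), collapse = ",")
    })
    expect_identical(anyDuplicated(sigs), 0L)
  })
})

test_that("encode_dataset writes one PNG per specimen, byte-identically on re-run", {
  specimens <- normalize_parameters(gen_sensor_specimens(n_specimens = 3, seed = 4))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  lab1 <- encode_dataset(specimens, zone_layout(), dir1)
  lab2 <- encode_dataset(specimens, zone_layout(), dir2)
  expect_identical(nrow(lab1), 3L)
  expect_setequal(list.files(dir1, pattern = "png$"), lab1$filename)
  expect_true(file.exists(file.path(dir1, "labels.csv")))
  for (f in lab1$filename) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e5),
                     readBin(file.path(dir2, f), "raw", 1e5))
  }
})

test_that("range-bearing specimen tables expand into many images", {
  specimens <- gen_sensor_specimens(n_specimens = 10, pressure_half_range = 2950,
                                    seed = 5)
  expanded <- expand_pressure_range(specimens, increment = 295)
  expect_gt(nrow(expanded), 10 * 15) # each row expands to ~21 steps
  expect_true("pressure" %in% names(expanded))
  expect_false("pressure_low" %in% names(expanded))
})
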