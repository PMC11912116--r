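test_that("total weight sums peak weights and scaling is linear", {
  empty <- peak_spectrum(matrix(numeric(0), 0, 2), numeric(0))
  expect_identical(total_weight(empty), 0)

  sp <- peak_spectrum(rbind(c(1, 20), c(2, 30)), c(2, 3))
  expect_identical(total_weight(sp), 5)

  expect_identical(scale_spectrum(sp, 1), sp)
  expect_equal(scale_spectrum(sp, 0)$weights, c(0, 0))
  expect_equal(scale_spectrum(sp, 0.5)$weights, c(1, 1.5))
  for (a in c(0.25, 2, 7.5)) {
    expect_equal(total_weight(scale_spectrum(sp, a)), a * total_weight(sp))
  }
  expect_error(scale_spectrum(sp, -1), "nonnegative")
})

test_that("peak spectra validate their invariants", {
  expect_error(peak_spectrum(rbind(c(1, 2)), c(-1)), ">= 0")
  expect_error(peak_spectrum(rbind(c(1, 2)), c(1, 2)), "disagree")
  expect_error(peak_spectrum(rbind(c(1, 2, 3, 4)), 1), "dim")
  # zero-weight peaks are permitted
  sp <- peak_spectrum(rbind(c(1, 2), c(3, 4)), c(0, 1))
  expect_equal(total_weight(sp), 1)
})

test_that("peak-list files round-trip exactly", {
  d <- withr::local_tempdir()
  p <- file.path(d, "x.csv")

  sp <- peak_spectrum(rbind(c(1.23, 20.5), c(4.56, 77.1)), c(2, 3))
  write_peaklist(sp, p)
  back <- read_peaklist(p)
  expect_equal(back$positions, sp$positions)
  expect_equal(back$weights, sp$weights)

  # empty data section
  writeLines("shift_1,shift_2,weight", p)
  expect_equal(length(read_peaklist(p)$weights), 0L)

  # 100-peak random spectrum, arbitrary doubles
  set.seed(1)
  rnd <- peak_spectrum(cbind(runif(100, 0, 10), runif(100, 0, 160)),
                       rexp(100))
  write_peaklist(rnd, p)
  back <- read_peaklist(p)
  expect_identical(back$positions, rnd$positions)
  expect_identical(back$weights, rnd$weights)
})

test_that("malformed peak-list files are rejected with a row number", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.csv")
  writeLines(c("shift_1,shift_2,weight", "1,20,2", "2,abc,1"), p)
  expect_error(read_peaklist(p), "row 2")
  writeLines(c("shift_1,shift_2,weight", "1,20,-2"), p)
  expect_error(read_peaklist(p), "row 1.*negative")
  writeLines(c("shift_1,weight", "1,2"), p)
  expect_error(read_peaklist(p, dim = 2), "expected dim 2")
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_peaklist(p), "must have columns")
})

test_that("grid files round-trip exactly, 1D and 2D", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.csv")

  g <- grid_spectrum(list(c(1, 2, 3), c(10, 20)),
                     matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  write_grid(g, p)
  back <- read_grid(p)
  expect_identical(back$axes, g$axes)
  expect_identical(back$values, g$values)
  expect_equal(length(grid_to_peaks(back, floor = -Inf)$weights), 6L)

  # single-row grid is degenerate but valid
  g1 <- grid_spectrum(list(5.5, c(1, 2, 3)), matrix(c(9, 8, 7), 1, 3))
  write_grid(g1, p)
  expect_identical(read_grid(p)$values, g1$values)

  # 1D dialect
  gd <- grid_spectrum(c(1.5, 2.5, 3.5), c(-1, 0, 4))
  write_grid(gd, p)
  expect_identical(read_grid(p)$values, gd$values)

  # random 64x64 grid with negatives
  set.seed(2)
  gr <- grid_spectrum(list(sort(runif(64, 0, 10)), sort(runif(64, 0, 160))),
                      matrix(rnorm(64 * 64), 64, 64))
  write_grid(gr, p)
  back <- read_grid(p)
  expect_identical(back$axes, gr$axes)
  expect_identical(back$values, gr$values)
})

test_that("malformed grid files are rejected", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.csv")
  writeLines(c(",1,2", "10,1,2", "20,3"), p)
  expect_error(read_grid(p), "ragged")
  expect_error(grid_spectrum(list(c(1, 2, 1)), c(1, 2, 3)), "monotone")
})

test_that("binning conserves intensity and pools cells", {
  ones <- grid_spectrum(list(1:4, 1:4), matrix(1, 4, 4))
  b <- bin_grid(ones, c(2, 2))
  expect_equal(b$values, matrix(4, 2, 2))
  expect_equal(b$axes[[1]], c(1.5, 3.5))

  # identity binning
  g <- grid_spectrum(list(1:3, 1:5), matrix(rnorm(15), 3, 5))
  same <- bin_grid(g, c(3, 5))
  expect_equal(same$values, g$values)
  expect_equal(same$axes, g$axes)

  # remainder cells merge into the last bin; totals conserved
  set.seed(3)
  g2 <- grid_spectrum(list(sort(runif(10)), sort(runif(6))),
                      matrix(rnorm(60), 10, 6))
  b2 <- bin_grid(g2, c(3, 2))
  expect_equal(dim(b2$values), c(3L, 2L))
  expect_lt(abs(sum(b2$values) - sum(g2$values)),
            1e-12 * max(1, abs(sum(g2$values))))
  # last bin along axis 1 holds rows 7:10
  expect_equal(b2$axes[[1]][3], mean(g2$axes[[1]][7:10]))

  # descending axes keep their direction
  g3 <- grid_spectrum(list(c(9, 6, 3, 0)), c(1, 2, 3, 4))
  b3 <- bin_grid(g3, 2)
  expect_true(all(diff(b3$axes[[1]]) < 0))
  expect_equal(b3$values[, 1], c(3, 7))

  expect_error(bin_grid(g2, c(11, 2)), "axis 1")
  expect_error(bin_grid(g2, c(0, 2)), "axis 1")
})

test_that("grid-to-peaks conversion filters at the floor", {
  z <- grid_spectrum(list(1:2, 1:2), matrix(0, 2, 2))
  expect_equal(length(grid_to_peaks(z)$weights), 0L)

  g <- grid_spectrum(list(1:4), c(-1, 0, 2, 5))
  expect_equal(sort(grid_to_peaks(g, floor = 0)$weights), c(2, 5))
  expect_equal(grid_to_peaks(g, floor = 3)$weights, 5)
  # never emits negative weights at the default floor
  expect_true(all(grid_to_peaks(g)$weights > 0))

  # conversion below every value preserves the full total
  set.seed(4)
  gr <- grid_spectrum(list(sort(runif(10)), sort(runif(8))),
                      matrix(rexp(80), 10, 8))
  b <- bin_grid(gr, c(4, 3))
  expect_lt(abs(total_weight(grid_to_peaks(b, floor = -Inf)) -
                  sum(gr$values)),
            1e-12 * sum(gr$values))
  # peak coordinates come from the grid axes
  pk <- grid_to_peaks(b, floor = -Inf)
  expect_true(all(pk$positions[, 1] %in% b$axes[[1]]))
})

test_that("compound libraries enforce their invariants", {
  s1 <- peak_spectrum(rbind(c(1, 20)), 1, id = "a")
  s2 <- peak_spectrum(rbind(c(2, 30)), 2, id = "b")
  lib <- compound_library(list(s1, s2), c(30, 10))
  expect_equal(length(lib), 2L)
  expect_equal(lib["b"]$ref_concentrations, 10)

  expect_error(compound_library(list(s1, s1)), "unique")
  expect_error(compound_library(list(s1), -1), "positive")
  empty <- peak_spectrum(matrix(numeric(0), 0, 2), numeric(0), id = "e")
  expect_error(compound_library(list(empty)), "nonempty")
  s3 <- peak_spectrum(rbind(1.5), 1, id = "c", dim = 1)
  expect_error(compound_library(list(s1, s3)), "dimensionality")
})

test_that("libraries round-trip through manifest and files", {
  d <- withr::local_tempdir()
  lib <- make_library(4, c(2, 5), seed = 9)
  manifest <- write_library(lib, file.path(d, "lib"))
  back <- read_library(manifest)
  expect_identical(back$ids, lib$ids)
  expect_identical(back$ref_concentrations, lib$ref_concentrations)
  for (k in seq_along(lib$ids)) {
    expect_identical(back$spectra[[k]]$positions, lib$spectra[[k]]$positions)
    expect_identical(back$spectra[[k]]$weights, lib$spectra[[k]]$weights)
  }
})
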