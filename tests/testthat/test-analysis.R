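fake_result <- function(flows, production = 1) {
  structure(list(source_flows = flows, production = production,
                 alpha = flows * NA_real_),
            class = "flow_result")
}

test_that("detection compares flow fractions to the threshold", {
  res <- fake_result(c(a = 0.1, b = 0.001))
  det <- detect(res, 1, 0.003)
  expect_equal(det$detected, c(TRUE, FALSE))

  # threshold zero detects every compound with positive flow
  det0 <- detect(res, 1, 0)
  expect_true(all(det0$detected))

  # thresholds above one detect nothing when fractions are <= 1
  det2 <- detect(res, 1, 1.5)
  expect_false(any(det2$detected))

  # the boundary is closed
  det3 <- detect(fake_result(c(a = 0.003)), 1, 0.003)
  expect_true(det3$detected)

  expect_error(detect(res, 0, 0.1), "positive")
  expect_error(detect(res, 1, -0.1), "nonnegative")
})

test_that("concentrations follow alpha times the reference", {
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1, 20)), 4, id = "c1"),
    peak_spectrum(rbind(c(5, 90)), 2, id = "c2")), c(30, 10))
  res <- structure(list(
    source_flows = c(c1 = 2, c2 = 0), production = 2),
    class = "flow_result")
  q <- quantify(res, lib)
  expect_equal(q$alpha, c(0.5, 0))
  expect_equal(q$predicted_mM, c(15, 0))
})

test_that("relative errors, their mean and the error band", {
  qe <- quant_errors(c(a = 2), c(a = 4))
  expect_equal(unname(qe$errors), -0.5)
  expect_equal(qe$in_band, 1)  # -0.5 sits inside the closed band

  qe2 <- quant_errors(c(a = 1.2, b = 0.7), c(a = 1, b = 1))
  expect_equal(qe2$mean_abs_error, 0.25)

  qe3 <- quant_errors(c(a = 3, b = 5), c(a = 3, b = 5))
  expect_equal(qe3$mean_abs_error, 0)
  expect_equal(qe3$in_band, 1)

  # overestimation beyond double the truth leaves the band
  qe4 <- quant_errors(c(a = 2.5, b = 1), c(a = 1, b = 1))
  expect_equal(qe4$in_band, 0.5)

  # nonpositive truths are excluded and flagged
  qe5 <- quant_errors(c(a = 1, b = 1), c(a = 1, b = 0))
  expect_equal(qe5$excluded, "b")
  expect_equal(names(qe5$errors), "a")
})

test_that("precision, recall and F1 follow their definitions", {
  lib_ids <- sprintf("m%02d", 1:10)
  m <- classification_metrics(c("m01", "m02", "m03"),
                              c("m01", "m02", "m04"), lib_ids)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)

  perfect <- classification_metrics(c("m01", "m02"), c("m01", "m02"),
                                    lib_ids)
  expect_equal(perfect$f1, 1)

  disjoint <- classification_metrics(c("m03"), c("m01"), lib_ids)
  expect_equal(disjoint$f1, 0)

  nothing <- classification_metrics(character(0), c("m01"), lib_ids)
  expect_equal(nothing$precision, 0)
  expect_equal(nothing$f1, 0)

  expect_error(classification_metrics("m01", "zz", lib_ids), "library")
})

test_that("parameter scans reuse one solve per radius consistently", {
  set.seed(14)
  lib <- make_library(5, c(2, 4), seed = 51)
  mix <- make_mixture_peaks(lib, mixture_spec(
    setNames(runif(3, 2, 6), lib$ids[1:3]),
    shift_noise_sd = 0.01, weight_noise_cv = 0.1, seed = 52))
  truth <- lib$ids[1:3]

  tab <- parameter_scan(lib, mix$target, truth, radii = 0.08,
                        thresholds = 0.005)
  res <- solve_mcf(build_flow_network(lib, mix$target, 0.08))
  det <- detect(res, total_weight(mix$target), 0.005)
  met <- classification_metrics(det, truth, lib)
  expect_equal(tab$f1, met$f1)
  expect_equal(tab$precision, met$precision)

  # recall is non-increasing and the detected set shrinks as the
  # threshold grows, for each radius
  tab2 <- parameter_scan(lib, mix$target, truth,
                         radii = c(0.05, 0.1),
                         thresholds = c(0, 0.003, 0.01, 0.05, 0.2))
  for (r in unique(tab2$r)) {
    sub <- tab2[tab2$r == r, ]
    expect_true(all(diff(sub$recall) <= 1e-12))
    expect_true(all(diff(sub$tp + sub$fp) <= 1e-12))
  }

  # deterministic: the same scan twice is bit-identical
  tab3 <- parameter_scan(lib, mix$target, truth,
                         radii = c(0.05, 0.1),
                         thresholds = c(0, 0.003, 0.01, 0.05, 0.2))
  expect_identical(tab2, tab3)
})
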