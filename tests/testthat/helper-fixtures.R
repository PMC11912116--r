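# Shared fixtures and the independent LP oracle bridge.

hsqc_metric <- function() shift_metric(c(1, 0.1))

# two compounds (2 and 3 peaks) and a 4-peak target, everything mutually
# within radius 10 on the scaled metric -- used for construction counting
dense_toy <- function() {
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1.0, 20), c(1.2, 22)), c(1, 1), id = "c1"),
    peak_spectrum(rbind(c(1.1, 21), c(1.3, 23), c(1.4, 24)), c(2, 1, 1),
                  id = "c2")))
  target <- peak_spectrum(rbind(c(1.05, 20.5), c(1.15, 21.5),
                                c(1.25, 22.5), c(1.35, 23.5)),
                          c(1, 1, 1, 1), id = "t")
  list(library = lib, target = target)
}

# one compound, two equal peaks, each matched by one distinct target peak
# at scaled distances 0.01 and 0.02
matched_pair <- function() {
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1, 20), c(3, 50)), c(1, 1), id = "c1")))
  target <- peak_spectrum(rbind(c(1.01, 20), c(3.02, 50)), c(1, 1),
                          id = "t")
  list(library = lib, target = target)
}

# two single-peak compounds competing for one target peak (w = 1) at
# scaled distances 0.01 and 0.02
competition_fixture <- function() {
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1.01, 20)), 1, id = "near"),
    peak_spectrum(rbind(c(1.02, 20)), 1, id = "far")))
  target <- peak_spectrum(rbind(c(1.00, 20)), 1, id = "t")
  list(library = lib, target = target)
}

# random small instance: targets are biased toward compound peaks so that
# assignment arcs exist at moderate radii
random_instance <- function(seed, max_compounds = 5, max_peaks = 4,
                            max_targets = 20) {
  set.seed(seed)
  K <- sample(seq_len(max_compounds), 1)
  lib <- make_library(K, c(1, max_peaks), seed = seed + 1)
  nt <- sample(3:max_targets, 1)
  tpos <- cbind(runif(nt, 0, 10), runif(nt, 0, 160))
  pos <- do.call(rbind, lapply(lib$spectra, function(s) s$positions))
  for (j in seq_len(min(nt, nrow(pos)))) {
    tpos[j, ] <- pos[j, ] + c(rnorm(1, 0, 0.05), rnorm(1, 0, 0.5))
  }
  target <- peak_spectrum(tpos, runif(nt, 0.5, 2), id = "t")
  list(library = lib, target = target,
       r = runif(1, 0.05, 0.3))
}

# serialize instances and solve the full network LP with the independent
# scipy/HiGHS oracle; returns the vector of optimal objective values
oracle_objectives <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, infile, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(testthat::test_path("oracle_full_lp.py"),
                                infile, outfile))
  if (!identical(status, 0L)) stop("oracle run failed")
  out <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  stopifnot(all(out$status == 0))
  out$objective
}

oracle_instance <- function(library, target, r, c_absorption = 1e6,
                            metric = hsqc_metric()) {
  list(axis_scales = metric$axis_scales, r = r,
       c_absorption = c_absorption,
       target_positions = target$positions,
       target_weights = target$weights,
       compounds = lapply(library$spectra, function(s) {
         list(positions = s$positions, weights = s$weights)
       }))
}

expect_feasible <- function(result, vy, tol = 1e-8) {
  expect_lt(result$residuals$conservation, tol * vy)
  expect_lt(result$residuals$capacity, tol * vy)
  expect_lt(result$residuals$proportionality, tol * vy)
}

# the quantification benchmark: 10 compounds (3-8 peaks), true
# concentrations 2-6 mM against 30 mM library spectra, shift noise
# 0.01 ppm on the 1H-scaled metric (per-axis 0.01 / 0.1 ppm), 10% weight
# noise, rendered on a 256x256 grid (with margins for shifted peaks) with
# Gaussian peaks (0.03 / 0.3 ppm) and baseline noise sd 0.002, floored at
# 3 sigma; identical to the conditions used by scripts/acceptance.R
quant_benchmark <- function(seed = 100, grid_shape = c(256L, 256L)) {
  lib <- make_library(10, c(3, 8), seed = seed)
  set.seed(seed + 1)
  conc <- setNames(runif(10, 2, 6), lib$ids)
  mix <- make_mixture_peaks(lib, mixture_spec(
    conc, shift_noise_sd = c(0.01, 0.1), weight_noise_cv = 0.1,
    seed = seed + 2))
  grid <- render_grid(mix$target,
                      grid_axes(ranges = list(c(-0.5, 10.5), c(-8, 168)),
                                shape = grid_shape),
                      peak_shape(c(0.03, 0.3)),
                      baseline_noise_sd = 0.002, seed = seed + 3)
  target <- grid_to_peaks(grid, floor = 0.006)
  list(library = lib, target = target, grid = grid,
       truth = setNames(mix$truth$concentration_mM, mix$truth$compound_id))
}

mean_abs_err <- function(result, library, truth) {
  quant_errors(quantify(result, library), truth)$mean_abs_error
}
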