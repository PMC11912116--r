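test_that("hand-checkable flows are solved exactly", {
  fx <- matched_pair()
  net <- build_flow_network(fx$library, fx$target, r = 0.05)
  res <- solve_mcf(net)
  # both target peaks filled through the proportional split
  expect_equal(res$source_flows[["c1"]], 2, tolerance = 1e-12)
  expect_equal(res$total_cost, 0.03, tolerance = 1e-9)
  expect_equal(res$absorbed, 0, tolerance = 1e-12)
  expect_feasible(res, net$production)

  # no assignment arcs: everything is absorbed
  far <- build_flow_network(fx$library, fx$target, r = 1e-4)
  res0 <- solve_mcf(far)
  expect_equal(unname(res0$source_flows), c(0))
  expect_equal(res0$absorbed, 2)
  expect_equal(res0$total_cost, 2e6)

  # competition: all capacity goes to the nearer compound
  cf <- competition_fixture()
  resA <- solve_mcf(build_flow_network(cf$library, cf$target, r = 0.05))
  expect_equal(unname(resA$source_flows), c(1, 0), tolerance = 1e-12)
  expect_equal(resA$total_cost, 0.01, tolerance = 1e-9)
})

test_that("a compound with any unmatched peak carries zero flow", {
  # second peak of c1 has no target within r, so peak proportionality
  # forces the whole compound out (no tolerance for missing peaks)
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1, 20), c(5, 120)), c(1, 1), id = "c1")))
  target <- peak_spectrum(rbind(c(1, 20)), 1, id = "t")
  res <- solve_mcf(build_flow_network(lib, target, r = 0.05))
  expect_equal(res$source_flows[["c1"]], 0)
  expect_equal(res$absorbed, 1)
})

test_that("independent optimization ignores competition", {
  cf <- competition_fixture()
  resB <- solve_independent(cf$library, cf$target, r = 0.05)
  # both compounds receive the full target weight
  expect_equal(unname(resB$source_flows), c(1, 1), tolerance = 1e-12)

  # a single-compound library: identical to the simultaneous solve
  fx <- matched_pair()
  rA <- solve_mcf(build_flow_network(fx$library, fx$target, r = 0.05))
  rB <- solve_independent(fx$library, fx$target, r = 0.05)
  expect_equal(rB$source_flows, rA$source_flows, tolerance = 1e-12)
  expect_equal(rB$total_cost, rA$total_cost, tolerance = 1e-12)

  # disjoint target neighborhoods: independent equals simultaneous
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1, 20)), 1, id = "a"),
    peak_spectrum(rbind(c(5, 120)), 1, id = "b")))
  target <- peak_spectrum(rbind(c(1.01, 20), c(5.01, 120)), c(2, 3))
  rA <- solve_mcf(build_flow_network(lib, target, r = 0.05))
  rB <- solve_independent(lib, target, r = 0.05)
  expect_equal(rB$source_flows, rA$source_flows, tolerance = 1e-12)
})

test_that("incremental assignment reserves early flow", {
  # single-step ladder is the single-pass solve
  fx <- matched_pair()
  rA <- solve_mcf(build_flow_network(fx$library, fx$target, r = 0.05))
  rC <- solve_incremental(fx$library, fx$target,
                          incremental_schedule(0.05))
  expect_equal(rC$source_flows, rA$source_flows, tolerance = 1e-12)

  # near compound locks the capacity in step 1; far gets nothing later
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1.01, 20)), 1, id = "near"),
    peak_spectrum(rbind(c(1.03, 20)), 1, id = "far")))
  target <- peak_spectrum(rbind(c(1.00, 20)), 1, id = "t")
  rC <- solve_incremental(lib, target, incremental_schedule(c(0.02, 0.05)))
  expect_equal(unname(rC$source_flows), c(1, 0), tolerance = 1e-12)

  # cumulative source flows never decrease along the ladder
  set.seed(13)
  fx <- random_instance(4242)
  sched <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  prev <- rep(0, length(fx$library$ids))
  for (t in seq_along(sched)) {
    res <- solve_incremental(fx$library, fx$target,
                             incremental_schedule(sched[seq_len(t)]))
    expect_true(all(res$source_flows >= prev - 1e-9))
    prev <- res$source_flows
  }

  expect_error(incremental_schedule(c(0.1, 0.1)), "strictly increasing")
  expect_error(incremental_schedule(c(-0.1, 0.2)), "positive")
})

test_that("concentration factors scale assigned flow by library weight", {
  lib <- compound_library(list(
    peak_spectrum(rbind(c(1, 20), c(2, 30)), c(1, 3), id = "c1")))
  target <- peak_spectrum(rbind(c(1, 20), c(2, 30)), c(0.5, 1.5))
  res <- solve_mcf(build_flow_network(lib, target, r = 0.01))
  # f = 2, V_X = 4
  expect_equal(res$alpha[["c1"]], 0.5, tolerance = 1e-9)
  res2 <- concentration_factors(res, lib)
  expect_equal(res2$alpha, res$alpha)

  far <- solve_mcf(build_flow_network(lib,
                                      peak_spectrum(rbind(c(9, 150)), 1),
                                      r = 0.01))
  expect_equal(far$alpha[["c1"]], 0)
})

test_that("exact superpositions are recovered exactly by all setups", {
  r <- 0.1
  lib <- make_library(6, c(2, 5), min_separation = 2.5 * r, seed = 31)
  alpha_true <- setNames(seq(0.05, 0.35, length.out = 6), lib$ids)
  mix <- make_mixture_peaks(lib, mixture_spec(
    alpha_true * lib$ref_concentrations, seed = 32))
  for (setup in c("A", "B", "C")) {
    res <- switch(setup,
      A = solve_mcf(build_flow_network(lib, mix$target, r)),
      B = solve_independent(lib, mix$target, r),
      C = solve_incremental(lib, mix$target,
                            incremental_schedule(r_max = r, step = 0.025)))
    expect_lt(max(abs(res$alpha - alpha_true) / alpha_true), 1e-6)
    expect_feasible(res, total_weight(mix$target))
  }
})

test_that("solver agrees with the independent full-system LP oracle", {
  insts <- list(); mine <- numeric(0)
  for (s in 1:12) {
    fx <- random_instance(9000 + s)
    net <- build_flow_network(fx$library, fx$target, fx$r,
                              metric = hsqc_metric())
    res <- solve_mcf(net)
    expect_feasible(res, net$production)
    mine <- c(mine, res$total_cost)
    insts[[s]] <- oracle_instance(fx$library, fx$target, fx$r)
  }
  oracle <- oracle_objectives(insts)
  expect_lt(max(abs(mine - oracle) / pmax(1, abs(oracle))), 1e-9)
})
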