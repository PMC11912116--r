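# Reduced LP formulation.
#
# Because the hub->peak split is fixed at p_i = v_i / V_Xk, hub and peak arc
# flows are determined by one volume F_k per compound. The LP variables are
# therefore: one flow per peak->target arc, one F_k per compound, and the
# absorbed volume; constraints are per-peak proportionality
# (sum_j f_ij = p_i F_k), per-target capacity (sum_i f_ij <= w_j), and
# source conservation (sum_k F_k + f_abs = production).
#
# Presolve: a compound with any peak that has no target node within the
# radius is fixed at F_k = 0 (peak proportionality admits no other value;
# there is no tolerance for missing peaks), and its rows/columns are
# dropped. Target nodes with no inbound arc cannot receive flow and are
# dropped as well. The reduced LP always admits the feasible starting basis
# {absorption, capacity slacks, one degenerate arc per peak row}, which the
# C++ simplex core uses directly.

lp_from_network <- function(network) {
  peaks <- network$peaks
  arcs <- network$arcs
  K <- length(network$compound_ids)

  has_arc <- tabulate(arcs$peak, nbins = nrow(peaks)) > 0L
  bad_compound <- unique(peaks$compound[!has_arc])
  active_k <- setdiff(seq_len(K), bad_compound)
  act_peak <- which(has_arc & peaks$compound %in% active_k)
  arc_keep <- which(arcs$peak %in% act_peak)
  arcs <- arcs[arc_keep, , drop = FALSE]
  act_tgt <- sort(unique(arcs$target))

  n_arc <- nrow(arcs); n_k <- length(active_k); n_t <- length(act_tgt)
  m <- length(act_peak) + n_t + 1L
  n <- n_arc + n_k + 1L + n_t

  peak_row <- match(arcs$peak, act_peak)
  tgt_row <- length(act_peak) + match(arcs$target, act_tgt)
  col_F <- n_arc + seq_len(n_k)
  col_abs <- n_arc + n_k + 1L
  col_slack <- col_abs + seq_len(n_t)

  A <- matrix(0, m, n)
  if (n_arc) {
    A[cbind(peak_row, seq_len(n_arc))] <- 1
    A[cbind(tgt_row, seq_len(n_arc))] <- 1
  }
  if (n_k) {
    krow <- match(peaks$compound[act_peak], active_k)
    A[cbind(seq_along(act_peak), col_F[krow])] <- -peaks$fraction[act_peak]
  }
  if (n_t) A[cbind(length(act_peak) + seq_len(n_t), col_slack)] <- 1
  A[m, c(col_F, col_abs)] <- 1

  b <- c(rep(0, length(act_peak)),
         network$target_capacity[act_tgt],
         network$production)
  cost <- c(arcs$cost, rep(0, n_k), network$c_absorption, rep(0, n_t))

  basis0 <- c(match(seq_along(act_peak), peak_row),  # first arc per peak row
              col_slack, col_abs)

  list(A = A, b = b, cost = cost, basis0 = basis0,
       arcs = arcs, active_k = active_k, act_peak = act_peak,
       act_tgt = act_tgt, col_F = col_F, col_abs = col_abs)
}

flow_residuals <- function(network, source_flows, arc_flows, absorbed) {
  inflow <- rep(0, length(network$target_capacity))
  if (nrow(arc_flows)) {
    agg <- rowsum(arc_flows$flow, arc_flows$target)
    inflow[as.integer(rownames(agg))] <- agg[, 1L]
  }
  peak_out <- rep(0, nrow(network$peaks))
  if (nrow(arc_flows)) {
    agg <- rowsum(arc_flows$flow, arc_flows$peak)
    peak_out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  fk <- source_flows[network$peaks$compound]
  list(
    conservation = abs(sum(source_flows) + absorbed - network$production),
    capacity = max(0, max(c(0, inflow - network$target_capacity))),
    proportionality = max(c(0, abs(peak_out - network$peaks$fraction * fk))))
}

new_flow_result <- function(network, source_flows, arc_flows, absorbed,
                            total_cost, setup, status, iterations,
                            residuals = NULL, extra_params = list()) {
  alpha <- source_flows / network$compound_weights
  params <- c(list(setup = setup, r = network$radius,
                   c_absorption = network$c_absorption,
                   axis_scales = network$metric$axis_scales),
              extra_params)
  structure(list(
    source_flows = setNames(source_flows, network$compound_ids),
    arc_flows = arc_flows,
    absorbed = absorbed,
    total_cost = total_cost,
    alpha = setNames(alpha, network$compound_ids),
    production = network$production,
    params = params,
    status = list(code = status, iterations = iterations),
    residuals = residuals), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  assigned <- sum(x$source_flows)
  cat(sprintf(paste0(
    "<flow_result (setup %s): %d compounds, assigned %.6g of %.6g ",
    "(%.1f%%), absorbed %.6g\n  total cost %.6g, %d compounds with ",
    "positive flow>\n"),
    x$params$setup, length(x$source_flows), assigned, x$production,
    100 * assigned / x$production, x$absorbed, x$total_cost,
    sum(x$source_flows > 0)))
  invisible(x)
}

solver_statuses <- c("2" = "unbounded (should not occur on a valid network)",
                     "3" = "iteration limit reached",
                     "4" = "numerically singular basis")

#' Solve the minimum-cost flow on an assignment network
#'
#' Finds the feasible flow of minimal cost on a network built by
#' [build_flow_network()]: all source production must leave the source
#' (toward compounds or the absorption sink), target inflow may not exceed
#' the sink capacities, and every compound distributes its flow across its
#' peaks in fixed proportions. This is the single-pass simultaneous
#' optimization (setup A when the target came from grid data, setup D for a
#' picked peak list); all library compounds compete for target intensity in
#' one linear program.
#'
#' @param network a [flow_network][build_flow_network()].
#' @param setup label stored in the result parameters (default `"A"`).
#' @return A `flow_result` with per-compound source flows `f_s->k`, positive
#'   arc flows, absorbed volume, objective value, concentration factors
#'   `alpha = f_s->k / V_Xk`, and feasibility residuals.
#' @export
solve_mcf <- function(network, setup = "A") {
  stopifnot(inherits(network, "flow_network"))
  lp <- lp_from_network(network)
  sol <- .simplex_solve(lp$A, lp$b, lp$cost, lp$basis0 - 1L)
  if (sol$status != 0) {
    stop("LP solver failed: ", solver_statuses[as.character(sol$status)],
         " (status ", sol$status, " after ", sol$iterations, " iterations)",
         call. = FALSE)
  }
  x <- sol$x
  source_flows <- rep(0, length(network$compound_ids))
  source_flows[lp$active_k] <- x[lp$col_F]
  arc_flows <- data.frame(
    compound_id = network$compound_ids[network$peaks$compound[lp$arcs$peak]],
    compound = network$peaks$compound[lp$arcs$peak],
    peak = lp$arcs$peak,
    target = lp$arcs$target,
    flow = if (nrow(lp$arcs)) x[seq_len(nrow(lp$arcs))] else numeric(0),
    cost = lp$arcs$cost)
  arc_flows <- arc_flows[arc_flows$flow > 1e-12 * max(1, network$production),
                         , drop = FALSE]
  rownames(arc_flows) <- NULL
  absorbed <- x[lp$col_abs]
  res <- flow_residuals(network, source_flows, arc_flows, absorbed)
  new_flow_result(network, source_flows, arc_flows, absorbed,
                  sol$objective, setup, sol$status, sol$iterations,
                  residuals = res)
}

#' Independent per-compound optimization (setup B)
#'
#' Solves one single-compound flow problem per library entry, each against
#' the full target capacities. Compounds do not compete: two compounds whose
#' peaks overlap the same target intensity can both receive full flow, which
#' is the over-detection mode that simultaneous optimization avoids. Source
#' conservation holds within each per-compound run but not across the
#' concatenated result; the reported `absorbed` is the sum over runs and is
#' bookkeeping only.
#'
#' @param library a [compound_library()].
#' @param target a [peak_spectrum()].
#' @param r assignment radius.
#' @param c_absorption absorption cost (must exceed `r`).
#' @param metric a [shift_metric()].
#' @return A `flow_result`; `total_cost` is the sum of the per-compound
#'   objectives.
#' @export
solve_independent <- function(library, target, r, c_absorption = 1e6,
                              metric = default_metric(target$dim)) {
  stopifnot(inherits(library, "compound_library"))
  full <- build_flow_network(library, target, r, c_absorption, metric)
  source_flows <- rep(0, length(library$ids))
  arc_list <- vector("list", length(library$ids))
  absorbed <- 0; total_cost <- 0; iters <- 0L
  worst <- list(conservation = 0, capacity = 0, proportionality = 0)
  for (k in seq_along(library$ids)) {
    net_k <- build_flow_network(library[k], target, r, c_absorption, metric)
    res_k <- solve_mcf(net_k, setup = "B")
    source_flows[k] <- res_k$source_flows[[1]]
    if (nrow(res_k$arc_flows)) {
      af <- res_k$arc_flows
      af$compound_id <- library$ids[k]
      af$compound <- k
      # re-index peaks into the full-library roster
      af$peak <- which(full$peaks$compound == k)[af$peak]
      arc_list[[k]] <- af
    }
    absorbed <- absorbed + res_k$absorbed
    total_cost <- total_cost + res_k$total_cost
    iters <- iters + res_k$status$iterations
    worst <- Map(max, worst, res_k$residuals)
  }
  arc_flows <- do.call(rbind, c(arc_list[!vapply(arc_list, is.null, TRUE)],
                                list(make.row.names = FALSE)))
  if (is.null(arc_flows)) arc_flows <- empty_arc_flows()
  new_flow_result(full, source_flows, arc_flows, absorbed, total_cost,
                  "B", 0L, iters, residuals = worst)
}

empty_arc_flows <- function() {
  data.frame(compound_id = character(0), compound = integer(0),
             peak = integer(0), target = integer(0), flow = numeric(0),
             cost = numeric(0))
}

#' Incremental radius schedule
#'
#' A strictly increasing ladder of assignment radii for incremental flow
#' assignment ([solve_incremental()]). The default ladder climbs from
#' `step` to `r_max` in increments of `step` (0.01 on the 1H-scaled metric).
#'
#' @param radii strictly increasing positive radii, ending at the maximal
#'   assignment radius. Overrides `r_max`/`step` when given.
#' @param r_max maximal assignment radius.
#' @param step ladder increment.
#' @return An object of class `incremental_schedule`.
#' @export
incremental_schedule <- function(radii = NULL, r_max = NULL, step = 0.01) {
  if (is.null(radii)) {
    if (is.null(r_max)) stop("supply `radii` or `r_max`", call. = FALSE)
    radii <- unique(c(seq(step, r_max, by = step), r_max))
  }
  radii <- as.numeric(radii)
  if (!length(radii) || any(!is.finite(radii)) || any(radii <= 0) ||
      any(diff(radii) <= 0)) {
    stop("radii must be strictly increasing and positive", call. = FALSE)
  }
  structure(list(radii = radii), class = "incremental_schedule")
}

#' Incremental flow assignment (setup C)
#'
#' Repeatedly solves minimum-cost flows for increasing assignment radii,
#' reserving all flow once assigned: after each step, assigned target
#' capacity is removed and the reserved flow is never displaced in later
#' steps. Close matches are therefore locked in before larger radii admit
#' distant (potentially spurious) assignments, which stabilizes the fit at
#' large `r`. Each step's production equals the residual total capacity, so
#' the absorption cost does not distort the step optima. Peak
#' proportionality holds within each step; cumulatively, only the relaxed
#' flow-conservation form holds.
#'
#' @param library a [compound_library()].
#' @param target a [peak_spectrum()].
#' @param schedule an [incremental_schedule()] (a single radius reduces to
#'   the single-pass solve at that radius).
#' @param c_absorption absorption cost (must exceed the largest radius).
#' @param metric a [shift_metric()].
#' @return A `flow_result` with cumulative source and arc flows;
#'   `absorbed` is the overall unassigned volume `V_Y - sum(f_s->k)` and
#'   `total_cost` is the cumulative assignment cost plus the absorption
#'   cost of that unassigned volume. `params$r` records the maximal radius.
#' @export
solve_incremental <- function(library, target, schedule,
                              c_absorption = 1e6,
                              metric = default_metric(target$dim)) {
  stopifnot(inherits(library, "compound_library"))
  if (is.numeric(schedule)) schedule <- incremental_schedule(schedule)
  stopifnot(inherits(schedule, "incremental_schedule"))
  radii <- schedule$radii
  full <- build_flow_network(library, target, max(radii), c_absorption,
                             metric)
  w_res <- target$weights
  cum_flows <- rep(0, length(library$ids))
  arc_list <- list()
  assign_cost <- 0; iters <- 0L
  worst <- list(conservation = 0, capacity = 0, proportionality = 0)
  tol <- 1e-12 * max(1, total_weight(target))
  target_t <- target
  for (r_t in radii) {
    if (sum(w_res) <= tol) break
    target_t$weights <- w_res
    net_t <- build_flow_network(library, target_t, r_t, c_absorption,
                                metric)
    res_t <- solve_mcf(net_t, setup = "C")
    cum_flows <- cum_flows + res_t$source_flows
    if (nrow(res_t$arc_flows)) {
      arc_list[[length(arc_list) + 1L]] <- res_t$arc_flows
      inflow <- rowsum(res_t$arc_flows$flow, res_t$arc_flows$target)
      j <- as.integer(rownames(inflow))
      w_res[j] <- pmax(0, w_res[j] - inflow[, 1L])
      assign_cost <- assign_cost +
        sum(res_t$arc_flows$flow * res_t$arc_flows$cost)
    }
    iters <- iters + res_t$status$iterations
    worst <- Map(max, worst, res_t$residuals)
  }
  arc_flows <- if (length(arc_list)) {
    af <- do.call(rbind, c(arc_list, list(make.row.names = FALSE)))
    agg <- rowsum(af$flow, paste(af$peak, af$target))
    key <- !duplicated(paste(af$peak, af$target))
    out <- af[key, , drop = FALSE]
    out$flow <- agg[match(paste(out$peak, out$target), rownames(agg)), 1L]
    rownames(out) <- NULL
    out
  } else {
    empty_arc_flows()
  }
  absorbed <- total_weight(target) - sum(cum_flows)
  total_cost <- assign_cost + absorbed * c_absorption
  new_flow_result(full, cum_flows, arc_flows, absorbed, total_cost,
                  "C", 0L, iters, residuals = worst,
                  extra_params = list(schedule = radii))
}

#' Concentration factors from assigned flows
#'
#' The factor `alpha_k = f_s->k / V_Xk` is the scale at which compound `k`'s
#' library spectrum accounts for the flow assigned to it; scaling the
#' library spectrum by `alpha_k` reproduces exactly the assigned intensity.
#' Predicted mixture concentrations follow as `c_k = alpha_k * c_k_ref`
#' (see [quantify()]).
#'
#' @param result a `flow_result`.
#' @param library the [compound_library()] the result was computed from.
#' @return The `flow_result` with its `alpha` field (re)computed.
#' @export
concentration_factors <- function(result, library) {
  stopifnot(inherits(result, "flow_result"),
            inherits(library, "compound_library"))
  idx <- match(names(result$source_flows), library$ids)
  if (anyNA(idx)) stop("result and library compound ids differ",
                       call. = FALSE)
  vx <- vapply(library$spectra, total_weight, 1)[idx]
  result$alpha <- result$source_flows / vx
  result
}
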