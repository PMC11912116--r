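#' Containment calls from assigned flows
#'
#' A compound is classified as contained in the mixture when the fraction of
#' target intensity explained by it, `f_s->k / V_Y`, reaches the detection
#' threshold `theta` (closed boundary). Useful thresholds for
#' well-concentrated mixtures lie around 0.003-0.01; dilute components need
#' smaller values.
#'
#' @param result a `flow_result`.
#' @param target_total total target weight `V_Y`; defaults to the production
#'   recorded in the result.
#' @param threshold dimensionless detection threshold `theta >= 0`.
#' @return A data frame (class `detection_report`) with columns
#'   `compound_id`, `flow_fraction`, `detected`, plus the threshold as an
#'   attribute.
#' @export
detect <- function(result, target_total = result$production, threshold) {
  stopifnot(inherits(result, "flow_result"))
  if (!is.numeric(target_total) || length(target_total) != 1L ||
      target_total <= 0) {
    stop("`target_total` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a single nonnegative number", call. = FALSE)
  }
  frac <- result$source_flows / target_total
  out <- data.frame(compound_id = names(result$source_flows),
                    flow_fraction = unname(frac),
                    detected = unname(frac >= threshold))
  attr(out, "threshold") <- threshold
  class(out) <- c("detection_report", "data.frame")
  out
}

#' Concentration estimates from a flow result
#'
#' Predicted mixture concentrations are `c_k = alpha_k * c_k_ref`, where
#' `alpha_k = f_s->k / V_Xk` is the concentration factor and `c_k_ref` the
#' concentration at which the library spectrum of compound `k` was acquired.
#'
#' @param result a `flow_result` (its `alpha` is recomputed from `library`).
#' @param library the [compound_library()] used for the fit.
#' @return A data frame with columns `compound_id`, `source_flow`, `alpha`,
#'   `predicted_mM`.
#' @export
quantify <- function(result, library) {
  result <- concentration_factors(result, library)
  idx <- match(names(result$source_flows), library$ids)
  data.frame(compound_id = names(result$source_flows),
             source_flow = unname(result$source_flows),
             alpha = unname(result$alpha),
             predicted_mM = unname(result$alpha *
                                     library$ref_concentrations[idx]))
}

#' Relative quantification errors
#'
#' For every compound with known true concentration `c_k_true > 0`, the
#' relative prediction error is `e_k = (c_k - c_k_true) / c_k_true`. The
#' summary reports the mean error magnitude `mean(|e_k|)` and the fraction
#' of errors inside the band `[-0.5, 1.0]` (i.e. between half and double
#' the true concentration, boundaries included).
#'
#' @param predicted named numeric vector of predicted concentrations (or a
#'   data frame from [quantify()], using its `predicted_mM` column).
#' @param truth named numeric vector of true concentrations; compounds with
#'   nonpositive truth are excluded and reported in `excluded`.
#' @return A list with `errors` (named vector over evaluated compounds),
#'   `mean_abs_error`, `in_band`, and `excluded`.
#' @export
quant_errors <- function(predicted, truth) {
  if (is.data.frame(predicted)) {
    predicted <- setNames(predicted$predicted_mM, predicted$compound_id)
  }
  if (is.null(names(predicted)) || is.null(names(truth))) {
    stop("`predicted` and `truth` must be named by compound id",
         call. = FALSE)
  }
  ok <- names(truth)[truth > 0]
  excluded <- setdiff(names(truth), ok)
  missing <- setdiff(ok, names(predicted))
  if (length(missing)) {
    stop("no prediction for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e <- (predicted[ok] - truth[ok]) / truth[ok]
  list(errors = e,
       mean_abs_error = mean(abs(e)),
       in_band = mean(e >= -0.5 & e <= 1.0),
       excluded = excluded)
}

#' Precision, recall and F1 of a detection
#'
#' Compounds of the library outside the truth set count as negatives; the
#' truth set must be part of the library. `F1 = 2PR/(P+R)`, defined as 0
#' when precision and recall are both 0 (and precision reported as 0 when
#' nothing is detected).
#'
#' @param detected character vector of detected compound ids (or a
#'   `detection_report`).
#' @param truth character vector of truly contained compound ids.
#' @param library character vector of all library ids (or a
#'   [compound_library()]).
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(detected, truth, library) {
  if (inherits(detected, "detection_report")) {
    detected <- detected$compound_id[detected$detected]
  }
  if (inherits(library, "compound_library")) library <- library$ids
  detected <- unique(as.character(detected))
  truth <- unique(as.character(truth))
  if (!all(truth %in% library)) {
    stop("truth ids must be contained in the library", call. = FALSE)
  }
  if (!all(detected %in% library)) {
    stop("detected ids must be contained in the library", call. = FALSE)
  }
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  fn <- length(setdiff(truth, detected))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' Scan assignment radii and detection thresholds
#'
#' Computes the detection performance over a grid of assignment radii and
#' thresholds. One flow problem is solved per radius; the thresholds are
#' pure post-processing of the same flows, so the scan costs no more than
#' one solve per radius.
#'
#' @param library a [compound_library()].
#' @param target a [peak_spectrum()].
#' @param truth character vector of truly contained compound ids.
#' @param radii numeric vector of assignment radii.
#' @param thresholds numeric vector of detection thresholds.
#' @param setup `"A"` (single-pass simultaneous), `"B"` (independent) or
#'   `"C"` (incremental; each radius is used as the ladder top with the
#'   default step).
#' @param c_absorption absorption cost.
#' @param metric a [shift_metric()].
#' @param step ladder increment for setup C.
#' @return A data frame (one row per radius/threshold pair) with columns
#'   `r`, `theta`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, with the
#'   arg-max row index in attribute `best`.
#' @export
parameter_scan <- function(library, target, truth, radii, thresholds,
                           setup = "A", c_absorption = 1e6,
                           metric = default_metric(target$dim),
                           step = 0.01) {
  setup <- match.arg(setup, c("A", "B", "C"))
  rows <- vector("list", length(radii) * length(thresholds))
  n <- 0L
  for (r in radii) {
    res <- switch(setup,
      A = solve_mcf(build_flow_network(library, target, r, c_absorption,
                                       metric)),
      B = solve_independent(library, target, r, c_absorption, metric),
      C = solve_incremental(library, target,
                            incremental_schedule(r_max = r, step = step),
                            c_absorption, metric))
    for (th in thresholds) {
      det <- detect(res, total_weight(target), th)
      met <- classification_metrics(det, truth, library)
      n <- n + 1L
      rows[[n]] <- data.frame(r = r, theta = th, tp = met$tp, fp = met$fp,
                              fn = met$fn, precision = met$precision,
                              recall = met$recall, f1 = met$f1)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "best") <- which.max(out$f1)
  out
}
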