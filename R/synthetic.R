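# Seeded generators emulating the structure of experimental HSQC data:
# libraries of individual compound peak lists acquired at a known reference
# concentration, mixture peak lists formed as noisy scaled superpositions,
# and gridded spectra rendered from peak lists with Gaussian peak shapes
# and additive baseline noise.

#' Generate a synthetic compound library
#'
#' Peak positions are uniform over the given per-axis ppm ranges (defaults:
#' 1H 0-10 ppm, 13C 0-160 ppm); peak weights are drawn from a gamma
#' distribution (shape 2) and normalized so that each compound's total
#' weight equals its reference concentration — i.e. unit spectrometer
#' sensitivity, `V_Xk = c_k_ref`. Optionally, a minimum pairwise scaled
#' distance between all peaks (across compounds) is enforced by rejection
#' sampling, which is how well-separated benchmark libraries are built.
#'
#' @param n_compounds number of compounds.
#' @param peaks_per_compound integer range `c(min, max)` of peaks per
#'   compound (single number for a fixed count). Default 1-20, the typical
#'   spread of HSQC metabolite peak lists.
#' @param dim number of axes (default 2).
#' @param shift_ranges list of `c(min, max)` ppm ranges per axis.
#' @param ref_concentration acquisition concentration(s), mM (default 30).
#' @param min_separation minimal pairwise distance between any two peaks in
#'   the library under `metric` (0 disables the constraint).
#' @param metric a [shift_metric()] used for the separation constraint.
#' @param seed integer seed; fixes the library completely.
#' @return A [compound_library()] with ids `"cmpd_001"`, ...
#' @export
make_library <- function(n_compounds, peaks_per_compound = c(1L, 20L),
                         dim = 2L,
                         shift_ranges = list(c(0, 10), c(0, 160)),
                         ref_concentration = 30,
                         min_separation = 0,
                         metric = default_metric(dim),
                         seed = 1L) {
  if (n_compounds < 1L) stop("n_compounds must be >= 1", call. = FALSE)
  if (length(peaks_per_compound) == 1L) {
    peaks_per_compound <- rep(peaks_per_compound, 2L)
  }
  if (length(shift_ranges) != dim ||
      any(vapply(shift_ranges, function(x) diff(x) <= 0, TRUE))) {
    stop("`shift_ranges` must give one increasing c(min, max) per axis",
         call. = FALSE)
  }
  with_seed(seed, {
    npk <- sample(peaks_per_compound[1]:peaks_per_compound[2],
                  n_compounds, replace = TRUE)
    placed <- matrix(numeric(0), 0, dim)
    draw_pos <- function(n) {
      out <- matrix(0, n, dim)
      for (a in seq_len(dim)) {
        out[, a] <- runif(n, shift_ranges[[a]][1], shift_ranges[[a]][2])
      }
      out
    }
    spectra <- vector("list", n_compounds)
    ids <- sprintf("cmpd_%03d", seq_len(n_compounds))
    ref <- rep_len(ref_concentration, n_compounds)
    for (k in seq_len(n_compounds)) {
      pos <- matrix(0, npk[k], dim)
      for (i in seq_len(npk[k])) {
        for (attempt in seq_len(10000L)) {
          p <- draw_pos(1L)
          if (min_separation <= 0 || nrow(placed) == 0L ||
              min(dist2_to_all(p[1, ], placed, metric$axis_scales)) >
                min_separation^2) break
          if (attempt == 10000L) {
            stop("could not place peaks at the requested separation",
                 call. = FALSE)
          }
        }
        pos[i, ] <- p
        placed <- rbind(placed, p)
      }
      w <- rgamma(npk[k], shape = 2, rate = 1)
      w <- w / sum(w) * ref[k]
      spectra[[k]] <- peak_spectrum(pos, w, id = ids[k])
    }
    compound_library(spectra, ref, ids = ids)
  })
}

#' Mixture specification
#'
#' The conditions under which a synthetic mixture target is generated: the
#' truly contained compounds with their concentrations, peak position noise
#' (zero-mean Gaussian, per axis, in ppm), multiplicative weight noise
#' (lognormal with the given coefficient of variation and unit mean), and
#' the seed that fixes all randomness.
#'
#' @param contained named numeric vector: true concentration `c_k_true`
#'   (mM, > 0) per contained compound id.
#' @param shift_noise_sd per-axis standard deviation of peak position noise
#'   (ppm; recycled across axes).
#' @param weight_noise_cv coefficient of variation of the multiplicative
#'   weight noise.
#' @param baseline_noise_sd standard deviation of additive grid baseline
#'   noise (intensity units; used by [render_grid()] wrappers).
#' @param seed integer seed.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(contained, shift_noise_sd = 0,
                         weight_noise_cv = 0, baseline_noise_sd = 0,
                         seed = 1L) {
  if (is.null(names(contained)) || any(!nzchar(names(contained)))) {
    stop("`contained` must be named by compound id", call. = FALSE)
  }
  if (any(contained <= 0)) {
    stop("true concentrations must be > 0", call. = FALSE)
  }
  structure(list(contained = contained,
                 shift_noise_sd = shift_noise_sd,
                 weight_noise_cv = weight_noise_cv,
                 baseline_noise_sd = baseline_noise_sd,
                 seed = as.integer(seed)), class = "mixture_spec")
}

#' Generate a mixture target peak list
#'
#' The target is the union over contained compounds of their library peaks,
#' scaled by `alpha_k_true = c_k_true / c_k_ref`, with positions perturbed
#' by zero-mean Gaussian shift noise and weights by lognormal multiplicative
#' noise of unit mean. With zero noise the target is an exact superposition,
#' for which the flow methods recover the generating factors exactly.
#'
#' @param library a [compound_library()].
#' @param spec a [mixture_spec()]; all contained ids must be in the library.
#' @return A list with `target` (a [peak_spectrum()]) and `truth` (data
#'   frame with `compound_id`, `concentration_mM`, `alpha`).
#' @export
make_mixture_peaks <- function(library, spec) {
  stopifnot(inherits(library, "compound_library"),
            inherits(spec, "mixture_spec"))
  ids <- names(spec$contained)
  idx <- match(ids, library$ids)
  if (anyNA(idx)) {
    stop("unknown compound id(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  dim <- library$spectra[[1]]$dim
  sds <- rep_len(spec$shift_noise_sd, dim)
  cv <- spec$weight_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(spec$seed, {
    pos_list <- list(); w_list <- list()
    alpha <- numeric(length(ids))
    for (q in seq_along(ids)) {
      k <- idx[q]
      sp <- library$spectra[[k]]
      alpha[q] <- spec$contained[q] / library$ref_concentrations[k]
      pos <- sp$positions
      for (a in seq_len(dim)) {
        if (sds[a] > 0) pos[, a] <- pos[, a] + rnorm(nrow(pos), 0, sds[a])
      }
      w <- sp$weights * alpha[q]
      if (cv > 0) {
        w <- w * rlnorm(length(w), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      pos_list[[q]] <- pos
      w_list[[q]] <- w
    }
    target <- peak_spectrum(do.call(rbind, pos_list),
                            unlist(w_list, use.names = FALSE),
                            id = "mixture")
    list(target = target,
         truth = data.frame(compound_id = ids,
                            concentration_mM = unname(spec$contained),
                            alpha = alpha))
  })
}

#' Gaussian peak shape
#'
#' Per-axis standard deviations (ppm) of the Gaussian used to deposit peaks
#' on a grid. Defaults, `c(0.03, 0.3)`, correspond to 1H line widths at the
#' narrow end of the 0.03-0.09 ppm range seen in experimental HSQC spectra,
#' with a tenfold wider 13C width consistent with the axis scaling.
#'
#' @param widths positive numeric vector, one standard deviation per axis.
#' @return An object of class `peak_shape`.
#' @export
peak_shape <- function(widths = c(0.03, 0.3)) {
  widths <- as.numeric(widths)
  if (!length(widths) || any(!is.finite(widths)) || any(widths <= 0)) {
    stop("peak widths must be positive", call. = FALSE)
  }
  structure(list(widths = widths), class = "peak_shape")
}

#' Render a peak list onto an intensity grid
#'
#' Each peak is deposited as a discretized Gaussian: the per-axis kernel is
#' evaluated at the cell coordinates, truncated at 4 standard deviations and
#' renormalized, so the discrete sum over cells equals the peak weight
#' exactly. Additive zero-mean Gaussian baseline noise is applied to every
#' cell afterwards.
#'
#' @param spectrum a [peak_spectrum()] (1D or 2D) whose peaks all lie within
#'   the axis ranges.
#' @param axes list of ppm coordinate vectors (one per axis), e.g. from
#'   [grid_axes()].
#' @param shape a [peak_shape()].
#' @param baseline_noise_sd standard deviation of the baseline noise.
#' @param seed integer seed (used for the baseline noise).
#' @return A [grid_spectrum()].
#' @export
render_grid <- function(spectrum, axes, shape = peak_shape(),
                        baseline_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spectrum, "peak_spectrum"),
            inherits(shape, "peak_shape"))
  if (is.numeric(axes)) axes <- list(axes)
  ndim <- length(axes)
  if (ndim != spectrum$dim || ndim > 2L) {
    stop("`axes` must match the spectrum dimensionality (1 or 2)",
         call. = FALSE)
  }
  widths <- rep_len(shape$widths, ndim)
  for (a in seq_len(ndim)) {
    rng <- range(axes[[a]])
    if (nrow(spectrum$positions) &&
        (any(spectrum$positions[, a] < rng[1]) ||
         any(spectrum$positions[, a] > rng[2]))) {
      stop("peaks lie outside the grid axes (axis ", a, ")", call. = FALSE)
    }
  }
  n1 <- length(axes[[1]])
  n2 <- if (ndim == 2L) length(axes[[2]]) else 1L
  values <- matrix(0, n1, n2)
  kern <- function(ax, center, sd) {
    sel <- which(abs(ax - center) <= 4 * sd)
    if (!length(sel)) sel <- which.min(abs(ax - center))
    k <- exp(-0.5 * ((ax[sel] - center) / sd)^2)
    list(idx = sel, w = k / sum(k))
  }
  for (i in seq_len(nrow(spectrum$positions))) {
    k1 <- kern(axes[[1]], spectrum$positions[i, 1], widths[1])
    if (ndim == 1L) {
      values[k1$idx, 1L] <- values[k1$idx, 1L] + spectrum$weights[i] * k1$w
    } else {
      k2 <- kern(axes[[2]], spectrum$positions[i, 2], widths[2])
      values[k1$idx, k2$idx] <- values[k1$idx, k2$idx] +
        spectrum$weights[i] * outer(k1$w, k2$w)
    }
  }
  if (baseline_noise_sd > 0) {
    values <- values + with_seed(seed, {
      matrix(rnorm(n1 * n2, 0, baseline_noise_sd), n1, n2)
    })
  }
  grid_spectrum(axes, if (ndim == 1L) values[, 1L] else values)
}

#' Regular grid axes over ppm ranges
#'
#' @param ranges list of `c(min, max)` ppm ranges per axis.
#' @param shape integer vector of cells per axis.
#' @return A list of coordinate vectors usable as `axes` in [render_grid()].
#' @export
grid_axes <- function(ranges = list(c(0, 10), c(0, 160)),
                      shape = c(256L, 256L)) {
  Map(function(rg, n) seq(rg[1], rg[2], length.out = n), ranges,
      as.integer(shape))
}
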