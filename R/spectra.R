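#' Peak-list spectrum
#'
#' A spectrum represented as a finite weighted point set in chemical-shift
#' space: `n` peaks with ppm coordinates on `dim` axes (1-3) and nonnegative
#' intensity weights. The same representation serves library compounds,
#' peak-list targets, and gridded targets after [grid_to_peaks()].
#'
#' @param positions numeric matrix (`n x dim`) of ppm coordinates, or a
#'   numeric vector for a one-dimensional spectrum.
#' @param weights numeric vector of `n` nonnegative peak intensities.
#' @param id character label.
#' @param dim number of chemical-shift axes; inferred from `positions` when
#'   omitted.
#' @return An object of class `peak_spectrum` with fields `id`, `dim`,
#'   `positions` (matrix) and `weights`.
#' @examples
#' sp <- peak_spectrum(cbind(c(1.2, 3.4), c(20, 55)), c(2, 3), id = "ala")
#' total_weight(sp)
#' @export
peak_spectrum <- function(positions, weights = numeric(0), id = "spectrum",
                          dim = NULL) {
  if (is.null(positions)) positions <- matrix(numeric(0), 0, dim %||% 1L)
  if (!is.matrix(positions)) {
    positions <- matrix(as.numeric(positions), ncol = dim %||% 1L)
  }
  storage.mode(positions) <- "double"
  weights <- as.numeric(weights)
  d <- ncol(positions)
  if (!is.null(dim) && nrow(positions) > 0 && d != dim) {
    stop("positions have ", d, " columns but dim = ", dim, call. = FALSE)
  }
  if (!is.null(dim)) d <- as.integer(dim)
  if (d < 1L || d > 3L) stop("dim must be 1, 2 or 3", call. = FALSE)
  if (nrow(positions) != length(weights)) {
    stop("positions and weights disagree in length", call. = FALSE)
  }
  if (anyNA(positions) || anyNA(weights)) {
    stop("positions and weights must be finite", call. = FALSE)
  }
  if (any(weights < 0)) stop("peak weights must be >= 0", call. = FALSE)
  structure(
    list(id = as.character(id), dim = as.integer(d),
         positions = unname(positions), weights = weights),
    class = "peak_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peak_spectrum <- function(x, ...) {
  cat(sprintf("<peak_spectrum '%s': %d peaks, %dD, total weight %.6g>\n",
              x$id, length(x$weights), x$dim, total_weight(x)))
  invisible(x)
}

#' Total weight of a spectrum
#'
#' Sum of all peak weights (for a grid, of all intensity values). The total
#' weight of the target spectrum sets the source production of the flow
#' network, and per-compound totals enter the concentration factors.
#'
#' @param spectrum a [peak_spectrum()] or [grid_spectrum()].
#' @return A single nonnegative number (0 for an empty spectrum).
#' @export
total_weight <- function(spectrum) UseMethod("total_weight")

#' @export
total_weight.peak_spectrum <- function(spectrum) sum(spectrum$weights)

#' @export
total_weight.grid_spectrum <- function(spectrum) sum(spectrum$values)

#' Scale a spectrum by a concentration factor
#'
#' Multiplies every peak weight by `factor`, leaving positions untouched —
#' the elementary operation behind reconstructing a mixture as a union of
#' library spectra scaled by concentration factors.
#'
#' @param spectrum a [peak_spectrum()].
#' @param factor single nonnegative number.
#' @return The scaled `peak_spectrum`.
#' @export
scale_spectrum <- function(spectrum, factor) {
  stopifnot(inherits(spectrum, "peak_spectrum"))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 0) {
    stop("`factor` must be a single nonnegative number", call. = FALSE)
  }
  spectrum$weights <- spectrum$weights * factor
  spectrum
}

#' Grid spectrum
#'
#' Raw spectral intensities on a rectilinear ppm grid (1 or 2 axes). Values
#' may be negative on input (baseline artifacts); conversion to a peak
#' spectrum clips them at the floor. Axes must be strictly monotone; their
#' direction is preserved through binning.
#'
#' @param axes list of numeric vectors of ppm coordinates, one per axis
#'   (or a single numeric vector for 1D).
#' @param values numeric array of intensities; `length(axes[[1]])` entries
#'   for 1D, a `length(axes[[1]]) x length(axes[[2]])` matrix for 2D.
#' @return An object of class `grid_spectrum` with fields `axes` (list) and
#'   `values` (matrix, `n1 x n2`; 1D grids are stored as `n1 x 1`).
#' @export
grid_spectrum <- function(axes, values) {
  if (is.numeric(axes)) axes <- list(axes)
  if (!is.list(axes) || !length(axes) %in% 1:2) {
    stop("`axes` must be a list of 1 or 2 numeric vectors", call. = FALSE)
  }
  axes <- lapply(axes, as.numeric)
  for (a in seq_along(axes)) {
    ax <- axes[[a]]
    if (length(ax) < 1L || anyNA(ax)) {
      stop("axis ", a, " must be nonempty and finite", call. = FALSE)
    }
    if (length(ax) > 1L) {
      d <- diff(ax)
      if (!(all(d > 0) || all(d < 0))) {
        stop("axis ", a, " is not strictly monotone", call. = FALSE)
      }
    }
  }
  values <- if (length(axes) == 1L) {
    matrix(as.numeric(values), ncol = 1L)
  } else {
    as.matrix(values)
  }
  storage.mode(values) <- "double"
  if (nrow(values) != length(axes[[1]]) ||
      (length(axes) == 2L && ncol(values) != length(axes[[2]]))) {
    stop("`values` shape does not match axis lengths", call. = FALSE)
  }
  if (anyNA(values)) stop("grid values must be finite", call. = FALSE)
  structure(list(axes = axes, values = unname(values)),
            class = "grid_spectrum")
}

#' @export
print.grid_spectrum <- function(x, ...) {
  cat(sprintf("<grid_spectrum: %s points, total intensity %.6g>\n",
              paste(vapply(x$axes, length, 1L), collapse = " x "),
              sum(x$values)))
  invisible(x)
}

#' Bin a grid spectrum to a coarser resolution
#'
#' Sum-pools blocks of adjacent grid cells so that total intensity is
#' conserved exactly; the output coordinate of each bin is the arithmetic
#' mean of its constituent input coordinates. When an axis length is not
#' divisible by the requested length, the trailing remainder cells are
#' merged into the last bin.
#'
#' @param grid a [grid_spectrum()].
#' @param target_shape integer vector, requested number of cells per axis
#'   (each between 1 and the current axis length).
#' @return The binned `grid_spectrum`.
#' @export
bin_grid <- function(grid, target_shape) {
  stopifnot(inherits(grid, "grid_spectrum"))
  ndim <- length(grid$axes)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != ndim) {
    stop("`target_shape` must give one length per axis", call. = FALSE)
  }
  groups <- vector("list", ndim)
  for (a in seq_len(ndim)) {
    n <- length(grid$axes[[a]]); k <- target_shape[a]
    if (is.na(k) || k < 1L || k > n) {
      stop("target length for axis ", a, " must be in [1, ", n, "]",
           call. = FALSE)
    }
    size <- n %/% k
    g <- rep(seq_len(k), times = c(rep(size, k - 1L), n - size * (k - 1L)))
    groups[[a]] <- g
  }
  ax_out <- lapply(seq_len(ndim), function(a) {
    as.numeric(rowsum(grid$axes[[a]], groups[[a]], reorder = TRUE)) /
      tabulate(groups[[a]], nbins = target_shape[a])
  })
  v <- rowsum(grid$values, groups[[1]], reorder = TRUE)
  if (ndim == 2L) {
    v <- t(rowsum(t(v), groups[[2]], reorder = TRUE))
  }
  grid_spectrum(ax_out, unname(v))
}

#' Convert a grid spectrum to a peak spectrum
#'
#' Every grid cell with intensity strictly above `floor` becomes one peak at
#' the cell's ppm coordinates with the cell value as weight; all other cells
#' (including negative baseline values when `floor >= 0`) are dropped. Grid
#' cells and picked peaks are treated identically downstream: both are just
#' weighted nodes of the flow network.
#'
#' @param grid a [grid_spectrum()].
#' @param floor intensity threshold; default 0 removes negative baseline
#'   artifacts and empty cells. Raise it to a noise level (e.g. 3 times the
#'   baseline standard deviation) to exclude noise cells.
#' @param id label for the resulting spectrum.
#' @return A [peak_spectrum()] with `dim` equal to the number of grid axes.
#' @export
grid_to_peaks <- function(grid, floor = 0, id = "grid") {
  stopifnot(inherits(grid, "grid_spectrum"))
  keep <- which(grid$values > floor)
  ndim <- length(grid$axes)
  if (length(keep) == 0L) {
    return(peak_spectrum(matrix(numeric(0), 0, ndim), numeric(0), id = id))
  }
  n1 <- length(grid$axes[[1]])
  i1 <- ((keep - 1L) %% n1) + 1L
  pos <- if (ndim == 1L) {
    cbind(grid$axes[[1]][i1])
  } else {
    i2 <- ((keep - 1L) %/% n1) + 1L
    cbind(grid$axes[[1]][i1], grid$axes[[2]][i2])
  }
  peak_spectrum(pos, grid$values[keep], id = id)
}

#' Compound library
#'
#' An ordered collection of individual compound peak spectra with the
#' concentrations at which the library spectra were acquired. Every spectrum
#' must be nonempty with positive total weight, all spectra must share one
#' dimensionality, and compound ids must be unique.
#'
#' @param spectra list of [peak_spectrum()] objects.
#' @param ref_concentrations numeric vector of positive acquisition
#'   concentrations (mM), one per compound (recycled if length 1).
#' @param ids character vector of compound ids; defaults to the spectra ids.
#' @return An object of class `compound_library` with fields `ids`,
#'   `spectra` and `ref_concentrations`.
#' @export
compound_library <- function(spectra, ref_concentrations = 30, ids = NULL) {
  if (inherits(spectra, "peak_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("library must contain >= 1 compound", call. = FALSE)
  if (!all(vapply(spectra, inherits, TRUE, "peak_spectrum"))) {
    stop("`spectra` must be a list of peak_spectrum objects", call. = FALSE)
  }
  ids <- ids %||% vapply(spectra, `[[`, "", "id")
  ids <- as.character(ids)
  if (length(ids) != length(spectra)) {
    stop("`ids` must match the number of spectra", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("compound ids must be unique", call. = FALSE)
  ref <- rep_len(as.numeric(ref_concentrations), length(spectra))
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("reference concentrations must be positive", call. = FALSE)
  }
  dims <- vapply(spectra, `[[`, 1L, "dim")
  if (length(unique(dims)) != 1L) {
    stop("all library spectra must share one dimensionality", call. = FALSE)
  }
  tw <- vapply(spectra, total_weight, 1)
  if (any(vapply(spectra, function(s) length(s$weights), 1L) == 0L) ||
      any(tw <= 0)) {
    stop("every library spectrum must be nonempty with total weight > 0",
         call. = FALSE)
  }
  structure(list(ids = ids, spectra = spectra, ref_concentrations = ref),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  np <- vapply(x$spectra, function(s) length(s$weights), 1L)
  cat(sprintf("<compound_library: %d compounds, %dD, %d peaks total>\n",
              length(x$ids), x$spectra[[1]]$dim, sum(np)))
  invisible(x)
}

#' @export
length.compound_library <- function(x) length(x$ids)

#' Extract a sub-library
#'
#' @param x a [compound_library()].
#' @param i index vector (integer, logical, or compound ids).
#' @param ... ignored.
#' @export
`[.compound_library` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown compound id", call. = FALSE)
  compound_library(x$spectra[i], x$ref_concentrations[i], ids = x$ids[i])
}
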