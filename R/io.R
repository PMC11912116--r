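# File dialects
#
# Peak list: CSV with header; columns shift_1 .. shift_<dim> (ppm; axis order
# 1H then 13C for 2D HSQC), weight, and optionally compound_id for
# concatenated library files. UTF-8, '.' decimal separator.
#
# Grid, 2D: first row = axis-2 ppm coordinates with a blank leading cell;
# each following row = axis-1 coordinate followed by the intensities.
# Grid, 1D: two columns (ppm, intensity) with header.
#
# Library manifest: CSV with columns compound_id, path (relative to the
# manifest), ref_concentration_mM.

# shortest decimal representation that reads back to the identical double
fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

stop_row <- function(row, msg) {
  stop("row ", row, ": ", msg, call. = FALSE)
}

#' Read and write peak-list files
#'
#' Reads a peak list from the package's CSV dialect (columns
#' `shift_1` ... `shift_<dim>` and `weight`). Writing uses the shortest
#' decimal representation that parses back to the identical double, so a
#' write/read round trip is exact.
#'
#' @param path file path.
#' @param dim expected number of axes; inferred from the header when `NULL`.
#' @param id spectrum label; defaults to the file name.
#' @return `read_peaklist()` returns a [peak_spectrum()];
#'   `write_peaklist()` returns `path` invisibly.
#' @export
read_peaklist <- function(path, dim = NULL, id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  shift_cols <- grep("^shift_[0-9]+$", names(df), value = TRUE)
  d <- length(shift_cols)
  if (d == 0L || !"weight" %in% names(df)) {
    stop("peak-list file must have columns shift_1..shift_dim and weight: ",
         path, call. = FALSE)
  }
  shift_cols <- paste0("shift_", seq_len(d))
  if (!all(shift_cols %in% names(df))) {
    stop("shift columns must be numbered consecutively from shift_1: ",
         path, call. = FALSE)
  }
  if (!is.null(dim) && d != dim) {
    stop("expected dim ", dim, " but file has ", d, " shift columns: ",
         path, call. = FALSE)
  }
  n <- nrow(df)
  if (n == 0L) {
    return(peak_spectrum(matrix(numeric(0), 0, d), numeric(0),
                         id = id %||% basename(path), dim = d))
  }
  pos <- matrix(0, n, d)
  for (a in seq_len(d)) {
    v <- suppressWarnings(as.numeric(df[[shift_cols[a]]]))
    bad <- which(is.na(v))
    if (length(bad)) stop_row(bad[1], paste0("non-numeric ", shift_cols[a]))
    pos[, a] <- v
  }
  w <- suppressWarnings(as.numeric(df[["weight"]]))
  bad <- which(is.na(w))
  if (length(bad)) stop_row(bad[1], "non-numeric weight")
  bad <- which(w < 0)
  if (length(bad)) stop_row(bad[1], "negative weight")
  peak_spectrum(pos, w, id = id %||% basename(path), dim = d)
}

#' @rdname read_peaklist
#' @param spectrum a [peak_spectrum()] to write.
#' @export
write_peaklist <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "peak_spectrum"))
  d <- spectrum$dim
  cols <- c(paste0("shift_", seq_len(d)), "weight")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  n <- length(spectrum$weights)
  if (n > 0L) {
    body <- do.call(paste, c(
      lapply(seq_len(d), function(a) fmt_num(spectrum$positions[, a])),
      list(fmt_num(spectrum$weights), sep = ",")))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read and write grid files
#'
#' 2D grids use a matrix layout: the first row holds the axis-2 ppm
#' coordinates (with a blank leading cell) and each following row holds an
#' axis-1 coordinate followed by that row's intensities. 1D grids are
#' two-column (ppm, intensity) files. Round trips are exact.
#'
#' @param path file path.
#' @return `read_grid()` returns a [grid_spectrum()]; `write_grid()` returns
#'   `path` invisibly.
#' @export
read_grid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty grid file: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  if (nzchar(trimws(header[1]))) {
    # 1D dialect: header (ppm, intensity)
    if (length(header) != 2L) {
      stop("1D grid file must have exactly two columns: ", path,
           call. = FALSE)
    }
    body <- cells[-1]
    if (any(lengths(body) != 2L)) {
      stop_row(which(lengths(body) != 2L)[1] + 1L, "ragged row")
    }
    ax <- as.numeric(vapply(body, `[[`, "", 1L))
    v <- as.numeric(vapply(body, `[[`, "", 2L))
    if (anyNA(ax) || anyNA(v)) stop("non-numeric grid entry: ", path,
                                    call. = FALSE)
    return(grid_spectrum(list(ax), v))
  }
  ax2 <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(ax2)) stop("non-numeric axis-2 coordinate: ", path, call. = FALSE)
  body <- cells[-1]
  ragged <- which(lengths(body) != length(header))
  if (length(ragged)) stop_row(ragged[1] + 1L, "ragged row")
  m <- matrix(suppressWarnings(as.numeric(unlist(body))),
              nrow = length(body), byrow = TRUE)
  if (anyNA(m)) stop("non-numeric grid entry: ", path, call. = FALSE)
  grid_spectrum(list(m[, 1L], ax2), m[, -1L, drop = FALSE])
}

#' @rdname read_grid
#' @param grid a [grid_spectrum()] to write.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "grid_spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(grid$axes) == 1L) {
    writeLines("ppm,intensity", con)
    writeLines(paste(fmt_num(grid$axes[[1]]), fmt_num(grid$values[, 1L]),
                     sep = ","), con)
  } else {
    writeLines(paste(c("", fmt_num(grid$axes[[2]])), collapse = ","), con)
    rows <- vapply(seq_along(grid$axes[[1]]), function(i) {
      paste(c(fmt_num(grid$axes[[1]][i]), fmt_num(grid$values[i, ])),
            collapse = ",")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read and write a compound library
#'
#' A library is stored as a manifest CSV (columns `compound_id`, `path`,
#' `ref_concentration_mM`) next to one peak-list file per compound; paths in
#' the manifest are resolved relative to the manifest's directory.
#'
#' @param manifest path to the manifest CSV.
#' @return `read_library()` returns a [compound_library()];
#'   `write_library()` returns the manifest path invisibly.
#' @export
read_library <- function(manifest) {
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("compound_id", "path", "ref_concentration_mM")
  if (!all(need %in% names(df))) {
    stop("library manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(manifest))
  spectra <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_peaklist(p, id = df$compound_id[i])
  })
  compound_library(spectra, df$ref_concentration_mM, ids = df$compound_id)
}

#' @rdname read_library
#' @param library a [compound_library()].
#' @param dir output directory (created if needed); the manifest is written
#'   as `library.csv` with one `<compound_id>.csv` peak list per compound.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "compound_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(gsub("[^A-Za-z0-9._-]", "_", library$ids), ".csv")
  for (i in seq_along(library$ids)) {
    write_peaklist(library$spectra[[i]], file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "library.csv")
  df <- data.frame(compound_id = library$ids, path = files,
                   ref_concentration_mM = fmt_num(library$ref_concentrations))
  write.csv(df, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
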