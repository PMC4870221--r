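# Minimal single-variable raster container on a projected km grid, plus
# ESRI ASCII grid I/O (the plain-text interchange format the package reads
# and writes; no-data honoured on both paths).

#' Single-variable climate raster
#'
#' @param values Numeric matrix; row 1 is the northernmost row (ESRI ASCII
#'   row order). `NA` marks no-data.
#' @param cell_size_km Cell edge length, km.
#' @param xll,yll Coordinates of the lower-left grid corner, km.
#' @param variable Optional tag, e.g. `"temperature"` or `"precipitation"`.
#' @param epoch Optional tag, e.g. `"present"` or `"lgm"`.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(values, cell_size_km, xll = 0, yll = 0,
                         variable = NULL, epoch = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  if (identical(variable, "precipitation") && any(values < 0, na.rm = TRUE))
    stop("precipitation cannot be negative")
  structure(list(values = values, cell_size_km = cell_size_km,
                 xll = xll, yll = yll, variable = variable, epoch = epoch),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("climate_grid", if (!is.null(x$variable)) paste0("[", x$variable, "]"),
      if (!is.null(x$epoch)) paste0("(", x$epoch, ")"), ":",
      nrow(x$values), "x", ncol(x$values), "cells of",
      x$cell_size_km, "km; range",
      paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " .. "), "\n")
  invisible(x)
}

same_georef <- function(a, b) {
  all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$cell_size_km, b$cell_size_km)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
}

#' Cell-centre coordinates of a climate grid
#'
#' @param g A [climate_grid()].
#' @return `data.frame` with `x`, `y` (km) in row-major order (row 1 first).
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size_km
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  data.frame(x = g$xll + (cols - 0.5) * cs,
             y = g$yll + (nr - rows + 0.5) * cs)
}

#' Grid values as a row-major vector
#'
#' Cell order matches [grid_coords()] and [grid_cell_coords()] (row-major,
#' northern row first), the order used for per-cell predictor tables.
#'
#' @param g A [climate_grid()].
#' @return Numeric vector of length `nrow * ncol`.
#' @export
grid_values <- function(g) as.vector(t(g$values))

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param variable,epoch Optional tags attached to the result.
#' @return A [climate_grid()]; no-data cells become `NA`.
#' @export
read_esri_ascii <- function(path, variable = NULL, epoch = NULL) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != hdr$nrows * hdr$ncols)
    stop("grid body size does not match header in ", path)
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  climate_grid(vals, cell_size_km = hdr$cellsize,
               xll = hdr$xllcorner, yll = hdr$yllcorner,
               variable = variable, epoch = epoch)
}

#' Write an ESRI ASCII grid
#'
#' @param g A [climate_grid()].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", format(g$xll, scientific = FALSE)),
           paste("yllcorner", format(g$yll, scientific = FALSE)),
           paste("cellsize", format(g$cell_size_km, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(v, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
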