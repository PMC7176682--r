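#' Lightweight in-memory raster
#'
#' A `grid_raster` wraps a numeric matrix together with its grid geometry
#' (cell size and lower-left corner of the extent). Row 1 of the matrix is the
#' northernmost row, matching the row order of ESRI ASCII grids. `NA` cells are
#' NoData.
#'
#' @param values numeric matrix of cell values (row 1 = top).
#' @param cellsize edge length of a (square) cell, in map units.
#' @param xll,yll coordinates of the lower-left corner of the extent.
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(1:6, 2, 3), cellsize = 100)
#' dim(r)
#' @export
grid_raster <- function(values, cellsize = 1, xll = 0, yll = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Extract the value matrix of a raster
#' @param x a `grid_raster`.
#' @return The numeric matrix of cell values.
#' @export
raster_values <- function(x) {
  stopifnot(inherits(x, "grid_raster"))
  x$values
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_raster> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              d[1], d[2], x$cellsize, x$xll, x$yll))
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d valid, %d NoData)\n",
                min(v), mean(v), max(v), length(v), sum(is.na(x$values))))
  else cat("  all cells NoData\n")
  invisible(x)
}

#' Test that two rasters share the same grid
#'
#' @param a,b `grid_raster` objects.
#' @param tol numeric tolerance on geometry fields.
#' @return `TRUE` or `FALSE`.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

stop_if_geometry_mismatch <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch between %s", what), call. = FALSE)
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param x a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @param digits significant digits used when formatting values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(x, "grid_raster"))
  d <- dim(x$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", d[2]),
    sprintf("NROWS %d", d[1]),
    sprintf("XLLCORNER %.10g", x$xll),
    sprintf("YLLCORNER %.10g", x$yll),
    sprintf("CELLSIZE %.10g", x$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  v <- x$values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1L, function(row)
    paste(format(row, trim = TRUE, digits = digits, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return A `grid_raster`; NoData cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value", "xllcenter", "yllcenter")) {
      hdr[[key]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("not an ESRI ASCII grid: missing NCOLS/NROWS header")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- if (is.null(hdr$cellsize)) 1 else hdr$cellsize
  # cell-centre registered headers are shifted back to corner registration
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid_raster(m, cellsize = cs, xll = xll, yll = yll)
}

#' Aggregate a raster to a coarser resolution by block mean
#'
#' Each coarse cell is the arithmetic mean of its `fact` x `fact` block of fine
#' cells. Partial blocks at the bottom/right edges average over the cells that
#' are available. NoData cells are ignored in the mean; a coarse cell is NoData
#' only when every contributing fine cell is NoData. The grid is anchored at
#' the top-left corner, so when `fact` does not divide the dimensions the
#' coarse extent extends slightly south/east of the fine one.
#'
#' @param x a `grid_raster`.
#' @param fact positive integer aggregation factor.
#' @return A `grid_raster` at `fact`-times coarser resolution; attributes of
#'   `x` (e.g. provenance) are carried over and the `resolution` attribute is
#'   set to `"aggregated"` when `fact > 1`.
#' @export
aggregate_raster <- function(x, fact) {
  stopifnot(inherits(x, "grid_raster"))
  fact <- as.integer(fact)
  if (is.na(fact) || fact < 1L) stop("`fact` must be a positive integer")
  if (fact == 1L) return(x)
  v <- x$values
  nr <- nrow(v); nc <- ncol(v)
  gr <- ceiling(seq_len(nr) / fact)
  gc <- ceiling(seq_len(nc) / fact)
  ok <- !is.na(v)
  vz <- v; vz[!ok] <- 0
  sums <- rowsum(vz, gr)                 # collapse rows
  cnts <- rowsum(ok + 0, gr)
  sums <- t(rowsum(t(sums), gc))         # collapse cols
  cnts <- t(rowsum(t(cnts), gc))
  m <- sums / cnts
  m[cnts == 0] <- NA_real_
  nrc <- nrow(m)
  ytop <- x$yll + nr * x$cellsize
  out <- grid_raster(m, cellsize = x$cellsize * fact,
                     xll = x$xll, yll = ytop - nrc * x$cellsize * fact)
  for (a in setdiff(names(attributes(x)), c("names", "class")))
    attr(out, a) <- attr(x, a)
  attr(out, "resolution") <- "aggregated"
  attr(out, "agg_factor") <- fact
  out
}

#' Aggregate a binary mask by majority rule
#'
#' Coarse cell is 1 when at least half of its valid fine cells are 1. Used to
#' carry the study-area mask to the analysis resolution.
#'
#' @param x a `grid_raster` with values in `{0, 1}` (and `NA`).
#' @param fact positive integer aggregation factor.
#' @return A binary `grid_raster`.
#' @export
aggregate_mask <- function(x, fact) {
  m <- aggregate_raster(x, fact)
  m$values <- (m$values >= 0.5) + 0
  m
}
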