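#' Fuzzy algebraic sum of per-footprint modification values
#'
#' Combines the modification values of the footprints overlapping a cell into
#' one degree of human modification: `H = 1 - prod(1 - h_j)`. The result is at
#' least as large as the largest contributing value, increases with every
#' additional footprint, and never exceeds 1. An empty input (no footprint)
#' gives 0.
#'
#' @param h numeric vector of per-footprint values, each in `[0, 1]`.
#' @return A single value in `[0, 1]`.
#' @examples
#' fuzzy_sum(c(0.5, 0.5))  # 0.75
#' fuzzy_sum(numeric(0))   # 0
#' @export
fuzzy_sum <- function(h) {
  h <- as.numeric(h)
  if (anyNA(h) || any(h < 0 | h > 1))
    stop("all `h` values must lie in [0, 1]")
  1 - prod(1 - h)
}

#' Per-category modification value under an index choice
#'
#' Looks up the catalog value for a category in a region and returns `h_F`,
#' `h_U`, or their arithmetic mean for the averaged index `H_FU`.
#'
#' @param catalog a `footprint_catalog`.
#' @param category category identifier.
#' @param region `"forest"` or `"agriculture"`.
#' @param index one of `"H_F"`, `"H_U"`, `"H_FU"`.
#' @return A value in `[0, 1]`.
#' @export
effective_h <- function(catalog, category, region,
                        index = c("H_FU", "H_F", "H_U")) {
  index <- match.arg(index)
  i <- which(catalog$category == category & catalog$region == region)
  if (length(i) != 1L)
    stop(sprintf("no catalog entry for category '%s' in region '%s'",
                 category, region))
  switch(index,
         H_F = catalog$h_F[i],
         H_U = catalog$h_U[i],
         H_FU = (catalog$h_F[i] + catalog$h_U[i]) / 2)
}

#' Degree-of-human-modification surface
#'
#' Builds the raster of `H` values from a landscape bundle and a footprint
#' catalog. Per cell, the modification values of all footprint categories
#' occupying the cell are collected -- using the cell's region to select
#' region-specific values -- and combined by the fuzzy algebraic sum. Cells
#' with no footprint get `H = 0`.
#'
#' For the averaged index `H_FU`, averaging is applied per category before the
#' fuzzy sum by default (`fu_average = "category"`); the alternative
#' (`"surface"`) averages the finished `H_F` and `H_U` surfaces cell-wise. The
#' two agree exactly wherever at most one footprint is present.
#'
#' @param bundle a `landscape_bundle`.
#' @param catalog a `footprint_catalog` covering all bundle categories.
#' @param index `"H_F"`, `"H_U"`, or `"H_FU"`.
#' @param fu_average `"category"` or `"surface"`; only used for `H_FU`.
#' @return A `grid_raster` of `H` in `[0, 1]` with attribute `index`.
#' @export
modification_surface <- function(bundle, catalog,
                                 index = c("H_FU", "H_F", "H_U"),
                                 fu_average = c("category", "surface")) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  index <- match.arg(index)
  fu_average <- match.arg(fu_average)

  if (index == "H_FU" && fu_average == "surface") {
    hf <- modification_surface(bundle, catalog, "H_F")
    hu <- modification_surface(bundle, catalog, "H_U")
    out <- hf
    out$values <- (hf$values + hu$values) / 2
    attr(out, "index") <- "H_FU"
    return(out)
  }

  cats <- names(bundle$footprints)
  missing <- setdiff(cats, catalog$category)
  if (length(missing))
    stop("catalog is missing categories: ", paste(missing, collapse = ", "))

  reg <- bundle$region$values
  forest <- reg == region_codes()[["forest"]]
  P <- matrix(1, nrow(reg), ncol(reg))
  for (cat in cats) {
    occ <- bundle$footprints[[cat]]
    stop_if_geometry_mismatch(bundle$region, occ, "footprint layers")
    if (any(!occ$values %in% c(0, 1)))
      stop(sprintf("footprint layer '%s' is not strictly binary", cat))
    hf <- ifelse(forest,
                 effective_h(catalog, cat, "forest", index),
                 effective_h(catalog, cat, "agriculture", index))
    P <- P * (1 - hf * occ$values)
  }
  out <- grid_raster(1 - P, cellsize = bundle$region$cellsize,
                     xll = bundle$region$xll, yll = bundle$region$yll)
  attr(out, "index") <- index
  out
}
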