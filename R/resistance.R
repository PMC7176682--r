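#' Scaling functions from human modification to resistance
#'
#' Two monotone scalings translate the degree of human modification `H` in
#' `[0, 1]` into a resistance contribution: the high-contrast tenth power
#' `(H + 1)^10` (values 1 to 1024) and the low-contrast linear `1 + H * 1000`
#' (values 1 to 1001). Both return 1 for unmodified cells.
#'
#' @param H numeric vector in `[0, 1]`.
#' @param contrast `"high"` or `"low"`.
#' @return Resistance contribution(s) `>= 1`.
#' @examples
#' scale_modification(c(0, 0.5, 1), "high")  # 1, 57.665..., 1024
#' scale_modification(c(0, 0.5, 1), "low")   # 1, 501, 1001
#' @export
scale_modification <- function(H, contrast = c("high", "low")) {
  contrast <- match.arg(contrast)
  if (anyNA(H) || any(H < 0 | H > 1)) stop("`H` must lie in [0, 1]")
  if (contrast == "high") (H + 1)^10 else 1 + H * 1000
}

#' Water-resistance levels
#'
#' Named constants for the resistance added to water cells: `low = 0` and
#' `high = 1000` are the uncertainty-analysis levels; `main = 57.7` is the
#' intermediate value used for the main map, corresponding to a modification
#' degree of 0.5 under the high-contrast scaling (`1.5^10` rounded to one
#' decimal).
#'
#' @return Named numeric vector `c(low = 0, main = 57.7, high = 1000)`.
#' @export
water_resistance_levels <- function() c(low = 0, main = 57.7, high = 1000)

#' Cell resistance from modification, slope, and water
#'
#' `R = f(H) + s/4 + w_res * w`, where `f` is the chosen scaling function,
#' `s` is percent slope, and `w` flags water cells. With high contrast a fully
#' modified cell contributes 1024, a 100% slope contributes 25, and a fully
#' modified water cell with `w_res = 1000` reaches the technical maximum 2024.
#' The water term is additive on top of `f(H)`: water cells are not excluded
#' from the modification surface.
#'
#' @param H degree of human modification in `[0, 1]`.
#' @param s percent slope in `[0, 100]`.
#' @param w water flag in `{0, 1}`.
#' @param contrast scaling contrast, `"high"` or `"low"`.
#' @param w_res water resistance `>= 0` (see [water_resistance_levels()]).
#' @return Resistance value(s) `>= 1`. Arguments are recycled cell-wise.
#' @examples
#' resistance(0.5, 0, 0, "high")               # 57.665...
#' resistance(1, 0, 1, "high", w_res = 1000)   # 2024
#' @export
resistance <- function(H, s = 0, w = 0, contrast = c("high", "low"),
                       w_res = water_resistance_levels()[["main"]]) {
  contrast <- match.arg(contrast)
  if (anyNA(s) || any(s < 0 | s > 100)) stop("`s` must lie in [0, 100]")
  if (anyNA(w) || any(!w %in% c(0, 1))) stop("`w` must be 0 or 1")
  if (length(w_res) != 1L || is.na(w_res) || w_res < 0)
    stop("`w_res` must be a single non-negative number")
  scale_modification(H, contrast) + s / 4 + w_res * w
}

#' Resistance raster from a modification surface
#'
#' Applies [resistance()] cell-wise using the bundle's slope and water rasters,
#' producing a fine-resolution resistance raster with provenance (index,
#' contrast, water resistance) recorded as an attribute.
#'
#' @param msurf a modification surface from [modification_surface()].
#' @param bundle the `landscape_bundle` providing slope and water layers.
#' @param contrast scaling contrast, `"high"` or `"low"`.
#' @param w_res water resistance (default: the main-map level 57.7).
#' @return A `grid_raster` of `R >= 1` with attributes `provenance` and
#'   `resolution = "fine"`. Aggregate with [aggregate_raster()].
#' @export
resistance_map <- function(msurf, bundle, contrast = c("high", "low"),
                           w_res = water_resistance_levels()[["main"]]) {
  contrast <- match.arg(contrast)
  stop_if_geometry_mismatch(msurf, bundle$slope, "modification and slope")
  stop_if_geometry_mismatch(msurf, bundle$water, "modification and water")
  v <- resistance(msurf$values, bundle$slope$values, bundle$water$values,
                  contrast, w_res)
  out <- grid_raster(v, cellsize = msurf$cellsize,
                     xll = msurf$xll, yll = msurf$yll)
  attr(out, "provenance") <- list(index = attr(msurf, "index"),
                                  contrast = contrast, w_res = w_res,
                                  slope_divisor = 4)
  attr(out, "resolution") <- "fine"
  out
}
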