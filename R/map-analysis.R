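#' Standardize a current-density map to z-scores
#'
#' Transforms the valid (typically buffer-clipped) cells to
#' `z = (x - mean) / sd`, using the population standard deviation (divide by
#' n); at raster cell counts the difference from the sample convention is
#' negligible. NoData cells are preserved.
#'
#' @param map a `grid_raster` with at least 2 valid cells and positive
#'   variance.
#' @return A `grid_raster` of z-scores (mean 0, sd 1 over valid cells), with
#'   attribute `standardized = TRUE`.
#' @export
standardize <- function(map) {
  stopifnot(inherits(map, "grid_raster"))
  ok <- !is.na(map$values)
  x <- map$values[ok]
  if (length(x) < 2L) stop("need at least 2 valid cells to standardize")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev <= 0) stop("cannot standardize a map with zero variance")
  map$values[ok] <- (x - mu) / sdev
  attr(map, "standardized") <- TRUE
  map
}

#' Classify cells as important by a z-score cutoff
#'
#' A cell contributes importantly to larger-scale connectivity when its
#' standardized current density is at least the cutoff (`z >= cutoff`; cells
#' exactly at the cutoff are classified important). Customary cutoffs are 0,
#' 1, and 2 standard deviations above the mean.
#'
#' @param z a standardized map from [standardize()].
#' @param cutoff numeric cutoff (typically 0, 1, or 2).
#' @return A binary `grid_raster` (1 = important), NoData preserved.
#' @export
classify <- function(z, cutoff) {
  stopifnot(inherits(z, "grid_raster"), is.numeric(cutoff),
            length(cutoff) == 1L)
  z$values <- (z$values >= cutoff) + 0
  attr(z, "cutoff") <- cutoff
  z
}

map_stack <- function(maps) {
  if (is.null(names(maps))) names(maps) <- paste0("map", seq_along(maps))
  ref_ok <- !is.na(maps[[1]]$values)
  for (m in maps[-1]) {
    stop_if_geometry_mismatch(maps[[1]], m, "maps")
    if (!identical(ref_ok, !is.na(m$values)))
      stop("maps must share an identical valid-cell mask")
  }
  vapply(maps, function(m) m$values[ref_ok], numeric(sum(ref_ok)))
}

#' Pairwise Pearson correlation between maps
#'
#' Cell-by-cell Pearson correlation over the shared valid cells of each pair
#' of maps.
#'
#' @param maps a (named) list of `grid_raster`s on one grid with identical
#'   valid-cell masks.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(maps) {
  X <- map_stack(maps)
  stats::cor(X)
}

#' Pairwise classification agreement between maps
#'
#' For each pair of binary classification rasters, the proportion of valid
#' cells classified the same way (important in both, or unimportant in both).
#'
#' @param maps a (named) list of binary `grid_raster`s from [classify()].
#' @return A symmetric agreement matrix in `[0, 1]` with unit diagonal.
#' @export
agreement_matrix <- function(maps) {
  X <- map_stack(maps)
  if (any(!X %in% c(0, 1))) stop("agreement requires binary classifications")
  k <- ncol(X)
  A <- matrix(1, k, k, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      A[i, j] <- A[j, i] <- mean(X[, i] == X[, j])
    }
  }
  A
}

#' Convert a similarity or correlation matrix to dissimilarities
#'
#' `"one_minus"` gives `D = 1 - m`; `"sqrt_one_minus"` gives
#' `D = sqrt(1 - m)`, the metric square-root transform that makes a
#' correlation-derived dissimilarity embeddable in Euclidean space (no
#' negative principal-coordinate eigenvalues to discard downstream).
#'
#' @param m symmetric matrix with unit diagonal and entries `<= 1`.
#' @param method `"one_minus"` or `"sqrt_one_minus"`.
#' @return A dissimilarity matrix with zero diagonal.
#' @export
to_dissimilarity <- function(m, method = c("one_minus", "sqrt_one_minus")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("matrix must have unit diagonal")
  if (any(m > 1 + 1e-12)) stop("similarity entries must not exceed 1")
  D <- 1 - m
  if (method == "sqrt_one_minus") D <- sqrt(pmax(D, 0))
  diag(D) <- 0
  D
}

#' The 2x2x2 factorial design of the uncertainty ensemble
#'
#' Eight maps crossing the human-modification index (`H_F` physical footprint
#' vs `H_U` intensity of use), water resistance (high = 1000 vs low = 0), and
#' scaling-function contrast (high vs low). The main averaged map (`H_FU`,
#' intermediate water resistance) is not part of the factorial. Row order
#' groups by scaling, then water resistance, then index, matching the layout
#' of the shipped published correlation matrix.
#'
#' @return A data frame with columns `map`, `scaling`, `water`, `h_index` and
#'   dummy columns `scaling_high`, `water_high`, `h_F` (0/1).
#' @export
factorial_design <- function() {
  d <- expand.grid(h_index = c("H_F", "H_U"), water = c("high", "low"),
                   scaling = c("high", "low"), stringsAsFactors = FALSE)
  d <- d[, c("scaling", "water", "h_index")]
  d$map <- sprintf("scale%s_water%s_%s", d$scaling, d$water,
                   sub("_", "", d$h_index))
  d$scaling_high <- as.integer(d$scaling == "high")
  d$water_high <- as.integer(d$water == "high")
  d$h_F <- as.integer(d$h_index == "H_F")
  d[, c("map", "scaling", "water", "h_index",
        "scaling_high", "water_high", "h_F")]
}

#' Variance partitioning of a dissimilarity matrix by db-RDA
#'
#' Distance-based redundancy analysis: the dissimilarity matrix is converted
#' to principal coordinates via Gower centring of `-D^2/2`; axes with positive
#' eigenvalues are retained (no Lingoes/Cailliez correction, mirroring default
#' db-RDA behaviour); the retained coordinates are regressed on every
#' non-empty subset of the dummy-coded factors; and each factor's unique
#' (marginal) fraction is the drop in explained variance when that factor is
#' removed from the full model. With `adjust = TRUE` the Ezekiel adjustment
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)` is applied to every subset
#' before differencing. The unexplained percentage is 100 minus the sum of the
#' unique fractions. Negative fractions are reported as-is.
#'
#' @param D an n x n dissimilarity matrix (or `dist`).
#' @param design a data frame of explanatory factors, one row per object in
#'   `D`; each column is dummy-coded (a two-level factor contributes one 0/1
#'   column).
#' @param adjust apply the Ezekiel adjustment (default `TRUE`).
#' @param tol relative eigenvalue tolerance for retaining PCoA axes.
#' @return An object of class `varpart_dbrda`: list with `fractions` (data
#'   frame of per-factor unique percentages), `unexplained_pct`,
#'   `full_r2` (of the full model, adjusted according to `adjust`),
#'   `subsets` (R2 and adjusted R2 for every factor subset), `adjusted`, and
#'   `degenerate`.
#' @export
varpart_dbrda <- function(D, design, adjust = TRUE, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n) stop("`D` must be square")
  if (any(abs(D - t(D)) > 1e-8)) stop("`D` must be symmetric")
  if (any(diag(D) != 0)) stop("`D` must have a zero diagonal")
  design <- as.data.frame(design)
  if (nrow(design) != n) stop("`design` must have one row per object in `D`")
  dummies <- lapply(design, function(col) {
    if (is.numeric(col) && all(col %in% c(0, 1))) return(matrix(col, ncol = 1))
    f <- factor(col)
    if (nlevels(f) < 2L) stop("each design factor needs at least 2 levels")
    stats::model.matrix(~f)[, -1, drop = FALSE]
  })
  fac_names <- names(design)
  k <- length(dummies)

  # principal coordinates of the Gower-centred -D^2/2 matrix
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% (-0.5 * D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  scale0 <- max(abs(e$values), 0)
  keep <- e$values > tol * max(scale0, .Machine$double.eps)
  degenerate <- !any(keep)
  if (degenerate) {
    warning("dissimilarity matrix has no positive inertia; ",
            "all objects are identical")
    fr <- data.frame(factor = fac_names, unique_pct = rep(0, k))
    return(structure(list(fractions = fr, unexplained_pct = 100,
                          full_r2 = 0, subsets = NULL, adjusted = adjust,
                          degenerate = TRUE), class = "varpart_dbrda"))
  }
  Y <- sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), `*`)
  total_inertia <- sum(e$values[keep])

  r2_subset <- function(which_factors) {
    if (!length(which_factors)) return(c(r2 = 0, p = 0))
    X <- do.call(cbind, dummies[which_factors])
    qrX <- qr(cbind(1, X))
    fit <- qr.fitted(qrX, Y)
    fit <- sweep(fit, 2, colMeans(fit))
    c(r2 = sum(fit^2) / total_inertia, p = qrX$rank - 1L)
  }
  ezekiel <- function(r2, p) 1 - (1 - r2) * (n - 1) / (n - 1 - p)

  subsets <- lapply(seq_len(2^k - 1L), function(code) {
    which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
  })
  sub_tab <- do.call(rbind, lapply(subsets, function(s) {
    v <- r2_subset(s)
    data.frame(subset = paste(fac_names[s], collapse = "+"),
               p = v[["p"]], r2 = v[["r2"]],
               adj_r2 = ezekiel(v[["r2"]], v[["p"]]))
  }))
  rownames(sub_tab) <- NULL

  score <- function(s) {
    row <- sub_tab[match(paste(fac_names[sort(s)], collapse = "+"),
                         sub_tab$subset), ]
    if (adjust) row$adj_r2 else row$r2
  }
  full <- score(seq_len(k))
  uniq <- vapply(seq_len(k),
                 function(i) full - score(setdiff(seq_len(k), i)),
                 numeric(1))
  fr <- data.frame(factor = fac_names, unique_pct = 100 * uniq)
  structure(list(fractions = fr,
                 unexplained_pct = 100 - sum(fr$unique_pct),
                 full_r2 = full, subsets = sub_tab, adjusted = adjust,
                 degenerate = FALSE),
            class = "varpart_dbrda")
}

#' @export
print.varpart_dbrda <- function(x, ...) {
  cat(sprintf("db-RDA variance partitioning (%s unique fractions)\n",
              if (x$adjusted) "Ezekiel-adjusted" else "unadjusted"))
  for (i in seq_len(nrow(x$fractions)))
    cat(sprintf("  %-14s %6.1f %%\n", x$fractions$factor[i],
                x$fractions$unique_pct[i]))
  cat(sprintf("  %-14s %6.1f %%\n", "unexplained", x$unexplained_pct))
  invisible(x)
}

#' Published map-correlation matrix from the Alberta uncertainty analysis
#'
#' The printed 8x8 cell-by-cell Pearson correlation matrix between the eight
#' factorial current-density maps of a published province-wide (Alberta,
#' Canada) connectivity uncertainty analysis, shipped as a package fixture.
#' Rows/columns follow [factorial_design()] order.
#'
#' @return An 8x8 correlation matrix with the design attached as attribute
#'   `design`.
#' @export
alberta_map_correlations <- function() {
  path <- system.file("extdata", "alberta_map_correlations.csv",
                      package = "ampscape", mustWork = TRUE)
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  stopifnot(nrow(m) == 8L, ncol(m) == 8L, isSymmetric(unname(m)))
  attr(m, "design") <- factorial_design()
  m
}

#' Reanalyze a published map-correlation matrix
#'
#' Converts the correlation matrix to dissimilarities and partitions the
#' between-map variance among the three design factors (water resistance,
#' scaling contrast, H index) with [varpart_dbrda()]. Defaults use the metric
#' `sqrt(1 - r)` transform and unadjusted fractions, the convention that best
#' reconstructs the published partitioning from the printed matrix (see the
#' methods vignette for the full reasoning).
#'
#' @param r correlation matrix (default: the shipped Alberta fixture).
#' @param method dissimilarity transform, see [to_dissimilarity()].
#' @param adjust apply the Ezekiel adjustment (default `FALSE`).
#' @return A `varpart_dbrda` object with factors `water`, `scaling`,
#'   `h_index`.
#' @export
reanalyze_map_correlations <- function(r = alberta_map_correlations(),
                                       method = "sqrt_one_minus",
                                       adjust = FALSE) {
  design <- attr(r, "design")
  if (is.null(design)) design <- factorial_design()
  D <- to_dissimilarity(unclass(r), method = method)
  varpart_dbrda(D, data.frame(water = design$water_high,
                              scaling = design$scaling_high,
                              h_index = design$h_F),
                adjust = adjust)
}
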