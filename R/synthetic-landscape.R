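#' Configuration for a synthetic landscape
#'
#' Describes the study-area grid, its buffer, and the statistical properties of
#' the generated layers. The buffer emulates the ring that surrounds a study
#' area during current computation so that boundary-node placement does not
#' bias current density inside the study area; a linear buffer width of at
#' least 20% of the study-area width is required.
#'
#' @param nrow,ncol study-area dimensions in fine-resolution cells.
#' @param cellsize cell edge length in map units.
#' @param buffer_fraction buffer ring width as a fraction of the study-area
#'   width; must be at least 0.2.
#' @param n_categories number of binary human-footprint categories (>= 0). The
#'   first category is rendered as one-cell-wide polylines (a roads analogue,
#'   exercising linear-feature rasterization); the rest as autocorrelated
#'   patches.
#' @param coverage expected per-category cover fraction in `[0, 1]`; recycled
#'   to `n_categories`.
#' @param water_fraction expected water cover fraction in `[0, 1]`.
#' @param slope_smoothness correlation range (in cells) of the percent-slope
#'   field.
#' @param slope_max maximum percent slope (0-100) of the generated field.
#' @param overlap in `[0, 1]`; share of a common latent field mixed into every
#'   patch category, controlling footprint co-occurrence (0 = independent).
#' @param seed integer RNG seed; a fixed seed makes [generate_landscape()]
#'   bit-reproducible.
#' @return An object of class `landscape_config`.
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(nrow = 100, ncol = 100, cellsize = 100,
                             buffer_fraction = 0.25, n_categories = 6,
                             coverage = 0.05, water_fraction = 0.05,
                             slope_smoothness = 8, slope_max = 45,
                             overlap = 0, seed = 1) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (is.na(nrow) || is.na(ncol) || nrow < 4L || ncol < 4L)
    stop("study-area dimensions must be integers >= 4")
  if (buffer_fraction < 0.2)
    stop("`buffer_fraction` must be at least 0.2 for unbiased node placement")
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 0L)
    stop("`n_categories` must be a non-negative integer")
  coverage <- rep_len(as.numeric(coverage), max(n_categories, 1L))
  if (any(coverage < 0 | coverage > 1)) stop("`coverage` must lie in [0, 1]")
  if (water_fraction < 0 || water_fraction > 1)
    stop("`water_fraction` must lie in [0, 1]")
  if (slope_max < 0 || slope_max > 100) stop("`slope_max` must lie in [0, 100]")
  if (overlap < 0 || overlap > 1) stop("`overlap` must lie in [0, 1]")
  structure(list(nrow = nrow, ncol = ncol, cellsize = cellsize,
                 buffer_fraction = buffer_fraction,
                 n_categories = n_categories, coverage = coverage,
                 water_fraction = water_fraction,
                 slope_smoothness = slope_smoothness, slope_max = slope_max,
                 overlap = overlap, seed = as.integer(seed)),
            class = "landscape_config")
}

footprint_names <- function(n) {
  if (n == 0L) character(0) else sprintf("cat%02d", seq_len(n))
}

#' Region codes used in region masks
#'
#' Region masks take value 1 in the forest-dominated region and 2 in the
#' agriculture-dominated region.
#' @return Named integer vector `c(forest = 1, agriculture = 2)`.
#' @export
region_codes <- function() c(forest = 1L, agriculture = 2L)

#' Generate a synthetic landscape bundle
#'
#' Produces, on a buffered grid, the layer stack that the connectivity pipeline
#' consumes: binary footprint occupancy rasters (autocorrelated patches plus a
#' one-cell-wide polyline category), a two-region mask with a wavy
#' forest/agriculture boundary, a smooth percent-slope field, a water mask of
#' contiguous patches, and the study-area mask (1 inside the study area, 0 in
#' the buffer-only ring). All layers share one grid geometry.
#'
#' @param config a [landscape_config()].
#' @return An object of class `landscape_bundle`: a list with elements
#'   `footprints` (named list of binary `grid_raster`s), `region`, `slope`,
#'   `water`, `study_mask` (all `grid_raster`s) and `config`.
#' @examples
#' b <- generate_landscape(landscape_config(nrow = 30, ncol = 30, seed = 42))
#' names(b$footprints)
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  b <- ceiling(config$buffer_fraction * config$ncol)
  nr <- config$nrow + 2L * b
  nc <- config$ncol + 2L * b
  cs <- config$cellsize
  geom <- function(m) grid_raster(m, cellsize = cs, xll = 0, yll = 0)

  with_seed(config$seed, {
    study <- matrix(0, nr, nc)
    study[(b + 1L):(b + config$nrow), (b + 1L):(b + config$ncol)] <- 1

    # wavy horizontal boundary: forest (1) above, agriculture (2) below
    wig <- stats::filter(stats::rnorm(nc), rep(1 / 9, 9), sides = 2, circular = TRUE)
    wig <- as.numeric(wig) / max(abs(wig), 1e-12) * (nr / 6)
    cut <- pmin(pmax(round(nr / 2 + wig), 1L), nr)
    region <- matrix(region_codes()[["agriculture"]], nr, nc)
    for (j in seq_len(nc)) region[seq_len(cut[j]), j] <- region_codes()[["forest"]]

    shared <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), 4L)
    shared <- (shared - mean(shared)) / stats::sd(shared)

    fps <- vector("list", config$n_categories)
    names(fps) <- footprint_names(config$n_categories)
    for (k in seq_len(config$n_categories)) {
      cov <- config$coverage[k]
      if (k == 1L) {
        # linear features: straight one-cell-wide segments between random
        # border points until the target coverage is reached
        m <- matrix(0, nr, nc)
        guard <- 0L
        while (mean(m) < cov && guard < 500L) {
          ends <- replicate(2, {
            side <- sample.int(4L, 1L)
            switch(side,
                   c(1L, sample.int(nc, 1L)),
                   c(nr, sample.int(nc, 1L)),
                   c(sample.int(nr, 1L), 1L),
                   c(sample.int(nr, 1L), nc))
          })
          m[trace_line(ends[1, 1], ends[2, 1], ends[1, 2], ends[2, 2])] <- 1
          guard <- guard + 1L
        }
        fps[[k]] <- geom(m)
      } else {
        own <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), 4L)
        own <- (own - mean(own)) / stats::sd(own)
        f <- sqrt(1 - config$overlap) * own + sqrt(config$overlap) * shared
        thr <- stats::quantile(f, 1 - cov, names = FALSE)
        fps[[k]] <- geom((f > thr) + 0)
      }
    }

    wf <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), 5L)
    wthr <- stats::quantile(wf, 1 - config$water_fraction, names = FALSE)
    water <- geom((wf > wthr) + 0)

    sl <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                        as.integer(config$slope_smoothness))
    rng <- range(sl)
    sl <- (sl - rng[1]) / max(rng[2] - rng[1], 1e-12) * config$slope_max
    slope <- geom(sl)

    structure(list(footprints = fps, region = geom(region), slope = slope,
                   water = water, study_mask = geom(study), config = config),
              class = "landscape_bundle")
  })
}

#' @export
print.landscape_bundle <- function(x, ...) {
  d <- dim(x$region)
  cat(sprintf(paste0("<landscape_bundle> %d x %d buffered grid ",
                     "(study area %d x %d), %d footprint categories\n"),
              d[1], d[2], x$config$nrow, x$config$ncol, length(x$footprints)))
  invisible(x)
}

#' Generate a synthetic footprint catalog
#'
#' Draws, for every footprint category and both regions, a physical-footprint
#' modification value `h_F` and an intensity-of-use value `h_U`, each uniform
#' on `[0, 1]`. Values are drawn independently for the forest- and
#' agriculture-dominated regions, mirroring expert scores that may differ
#' between regions.
#'
#' @param n_categories number of footprint categories (>= 0).
#' @param seed integer RNG seed.
#' @return A `footprint_catalog`: a data frame with columns `category`,
#'   `region` (`"forest"`/`"agriculture"`), `h_F`, `h_U`.
#' @export
generate_catalog <- function(n_categories, seed = 1) {
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 0L)
    stop("`n_categories` must be a non-negative integer")
  cats <- footprint_names(n_categories)
  with_seed(seed, {
    out <- data.frame(
      category = rep(cats, each = 2L),
      region = rep(c("forest", "agriculture"), times = n_categories),
      h_F = stats::runif(2L * n_categories),
      h_U = stats::runif(2L * n_categories),
      stringsAsFactors = FALSE
    )
    class(out) <- c("footprint_catalog", "data.frame")
    out
  })
}

#' Read or write a footprint catalog as CSV
#'
#' The CSV has columns `category,region,h_F,h_U` with one row per category and
#' region.
#'
#' @param catalog a `footprint_catalog` data frame.
#' @param path file path.
#' @return `read_catalog` returns a `footprint_catalog`; `write_catalog`
#'   returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "region", "h_F", "h_U")
  if (!all(need %in% names(out)))
    stop("catalog CSV must have columns category, region, h_F, h_U")
  if (any(out$h_F < 0 | out$h_F > 1 | out$h_U < 0 | out$h_U > 1, na.rm = TRUE))
    stop("catalog h values must lie in [0, 1]")
  class(out) <- c("footprint_catalog", "data.frame")
  out
}

#' Write all layers of a bundle to a directory
#'
#' Writes each footprint layer, the region mask, slope, water and study-area
#' masks as ESRI ASCII grids.
#'
#' @param bundle a `landscape_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$footprints))
    write_asc(bundle$footprints[[nm]], file.path(dir, paste0(nm, ".asc")))
  for (nm in c("region", "slope", "water", "study_mask"))
    write_asc(bundle[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}
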