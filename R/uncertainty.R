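#' Build one current-density map for a factor combination
#'
#' Convenience wrapper chaining modification surface, resistance, aggregation,
#' graph construction, boundary nodes, accumulation, and buffer clipping for a
#' single index / scaling / water-resistance combination.
#'
#' @param bundle a `landscape_bundle`.
#' @param catalog a `footprint_catalog`.
#' @param index `"H_F"`, `"H_U"`, or `"H_FU"`.
#' @param contrast `"high"` or `"low"`.
#' @param w_res water resistance.
#' @param agg_factor aggregation factor from fine to analysis resolution.
#' @param n_nodes number of boundary nodes.
#' @param threshold convergence correlation.
#' @param seed seed for node placement and pair sampling.
#' @param neighbourhood 4 or 8.
#' @param min_pairs solves before convergence checking.
#' @param nodes optional pre-computed `node_set` (shared across an ensemble).
#' @param clip clip the buffer zone afterwards (default `TRUE`).
#' @return A clipped `current_density_map`.
#' @export
current_density_map <- function(bundle, catalog, index = "H_FU",
                                contrast = "high",
                                w_res = water_resistance_levels()[["main"]],
                                agg_factor = 3, n_nodes = 20,
                                threshold = 0.999, seed = 1,
                                neighbourhood = 8, min_pairs = 10,
                                nodes = NULL, clip = TRUE) {
  msurf <- modification_surface(bundle, catalog, index)
  rmap <- resistance_map(msurf, bundle, contrast, w_res)
  rmap <- aggregate_raster(rmap, agg_factor)
  graph <- build_graph(rmap, neighbourhood)
  if (is.null(nodes)) nodes <- place_boundary_nodes(graph, n_nodes, seed = seed)
  cd <- accumulate(graph, nodes, threshold = threshold, seed = seed,
                   min_pairs = min_pairs)
  if (clip) {
    cmask <- aggregate_mask(bundle$study_mask, agg_factor)
    cd <- clip_to_study_area(cd, cmask)
  }
  attr(cd, "provenance") <- list(index = index, contrast = contrast,
                                 w_res = w_res, agg_factor = agg_factor)
  cd
}

#' Factorial uncertainty analysis of a connectivity map ensemble
#'
#' Builds the eight factorial current-density maps (and, optionally, the main
#' averaged `H_FU` map with intermediate water resistance), standardizes each
#' clipped map to z-scores, classifies cells at the given cutoffs, and
#' compares maps: the Pearson correlation matrix, one agreement matrix per
#' cutoff, their dissimilarity transforms, and a db-RDA variance partitioning
#' of each dissimilarity among the three design factors.
#'
#' The same boundary nodes and the same seeded pair sequence are used for all
#' maps so that ensemble differences reflect the design factors, not
#' pair-sampling noise.
#'
#' @param bundle a `landscape_bundle`.
#' @param catalog a `footprint_catalog`.
#' @param design the factorial design (default [factorial_design()]).
#' @param agg_factor aggregation factor from fine to analysis resolution.
#' @param n_nodes number of boundary nodes.
#' @param threshold convergence correlation in (0, 1).
#' @param seed master seed (node placement and pair sequence).
#' @param neighbourhood 4 or 8.
#' @param min_pairs solves before convergence checking starts.
#' @param cutoffs z-score cutoffs for classification.
#' @param include_main also compute the main `H_FU` map.
#' @param dissimilarity transform for [to_dissimilarity()].
#' @param adjust Ezekiel-adjust the variance fractions.
#' @return An object of class `connectivity_comparison`: list with `maps`
#'   (clipped standardized factorial maps), `main_map` (or `NULL`),
#'   `correlation`, `agreement` (list by cutoff), `dissimilarity` (list),
#'   `varpart` (list of `varpart_dbrda`), `design`, and `params`.
#' @export
run_uncertainty_analysis <- function(bundle, catalog,
                                     design = factorial_design(),
                                     agg_factor = 3, n_nodes = 20,
                                     threshold = 0.999, seed = 1,
                                     neighbourhood = 8, min_pairs = 10,
                                     cutoffs = c(0, 1, 2),
                                     include_main = TRUE,
                                     dissimilarity = "sqrt_one_minus",
                                     adjust = FALSE) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  wlev <- water_resistance_levels()

  # the two index surfaces are shared by four maps each; compute once
  msurfs <- list(H_F = modification_surface(bundle, catalog, "H_F"),
                 H_U = modification_surface(bundle, catalog, "H_U"))
  cmask <- aggregate_mask(bundle$study_mask, agg_factor)

  nodes <- NULL
  build_one <- function(msurf, contrast, w_res) {
    rmap <- aggregate_raster(resistance_map(msurf, bundle, contrast, w_res),
                             agg_factor)
    graph <- build_graph(rmap, neighbourhood)
    if (is.null(nodes))
      nodes <<- place_boundary_nodes(graph, n_nodes, seed = seed)
    cd <- accumulate(graph, nodes, threshold = threshold, seed = seed,
                     min_pairs = min_pairs)
    clip_to_study_area(cd, cmask)
  }

  maps <- vector("list", nrow(design))
  names(maps) <- design$map
  for (i in seq_len(nrow(design))) {
    maps[[i]] <- build_one(msurfs[[design$h_index[i]]], design$scaling[i],
                           wlev[[design$water[i]]])
  }
  main_map <- NULL
  if (include_main) {
    main_map <- build_one(modification_surface(bundle, catalog, "H_FU"),
                          "high", wlev[["main"]])
  }

  zmaps <- lapply(maps, standardize)
  cormat <- correlation_matrix(zmaps)
  agreements <- lapply(stats::setNames(cutoffs, paste0("z_ge_", cutoffs)),
                       function(ct) {
                         agreement_matrix(lapply(zmaps, classify, cutoff = ct))
                       })
  sims <- c(list(correlation = cormat), agreements)
  diss <- lapply(sims, to_dissimilarity, method = dissimilarity)
  dsg <- data.frame(water = design$water_high, scaling = design$scaling_high,
                    h_index = design$h_F)
  vps <- lapply(diss, varpart_dbrda, design = dsg, adjust = adjust)

  structure(list(maps = zmaps,
                 main_map = if (!is.null(main_map)) standardize(main_map),
                 correlation = cormat, agreement = agreements,
                 dissimilarity = diss, varpart = vps, design = design,
                 params = list(agg_factor = agg_factor, n_nodes = n_nodes,
                               threshold = threshold, seed = seed,
                               neighbourhood = neighbourhood,
                               min_pairs = min_pairs, cutoffs = cutoffs,
                               dissimilarity = dissimilarity,
                               adjust = adjust),
                 pairs_solved = vapply(maps, attr, integer(1), "pairs_solved")),
            class = "connectivity_comparison")
}

#' @export
print.connectivity_comparison <- function(x, ...) {
  cat(sprintf("<connectivity_comparison> %d factorial maps%s\n",
              length(x$maps),
              if (!is.null(x$main_map)) " + main map" else ""))
  cat(sprintf("  pairs solved per map: %s\n",
              paste(x$pairs_solved, collapse = ", ")))
  cat("  correlation-based variance partitioning:\n")
  print(x$varpart$correlation)
  invisible(x)
}
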