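#' Conductance graph of a resistance raster
#'
#' Turns a resistance raster into a weighted graph: nodes are the non-NoData
#' cells, edges join neighbouring cells (4- or 8-neighbourhood), and the edge
#' conductance between cells i and j is the inverse of the mean of their
#' resistances, `1 / ((R_i + R_j) / 2)` -- each cell contributes half its
#' resistance in series. Diagonal edges are further divided by `sqrt(2)` to
#' account for the larger centre-to-centre distance. The alternative
#' convention, mean of the two cell conductances, is available via
#' `conductance_rule = "mean_conductance"`.
#'
#' @param r a `grid_raster` of resistances, all positive and finite.
#' @param neighbourhood 8 (default) or 4.
#' @param conductance_rule `"mean_resistance"` (default) or
#'   `"mean_conductance"`.
#' @return An object of class `conductance_graph`: node count `n`, edge
#'   vectors `from`, `to`, `cond`, the sparse graph Laplacian `L`, the
#'   cell-to-node index matrix `idx`, and the source geometry. Errors if the
#'   graph is disconnected.
#' @export
build_graph <- function(r, neighbourhood = 8,
                        conductance_rule = c("mean_resistance",
                                             "mean_conductance")) {
  stopifnot(inherits(r, "grid_raster"))
  conductance_rule <- match.arg(conductance_rule)
  if (!neighbourhood %in% c(4, 8)) stop("`neighbourhood` must be 4 or 8")
  v <- r$values
  valid <- !is.na(v)
  nv <- sum(valid)
  if (nv < 2L) stop("raster must have at least 2 valid cells")
  if (any(v[valid] <= 0) || any(!is.finite(v[valid])))
    stop("all resistances must be positive and finite")
  nr <- nrow(v); nc <- ncol(v)
  idx <- matrix(NA_integer_, nr, nc)
  idx[valid] <- seq_len(nv)
  Rn <- v[valid]  # node resistances, column-major node order

  pair_block <- function(a, b, w) {
    keep <- !is.na(a) & !is.na(b)
    list(from = a[keep], to = b[keep], w = w)
  }
  blocks <- list(
    pair_block(idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE], 1),
    pair_block(idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE], 1)
  )
  if (neighbourhood == 8) {
    blocks <- c(blocks, list(
      pair_block(idx[-nr, -nc, drop = FALSE], idx[-1, -1, drop = FALSE],
                 1 / sqrt(2)),
      pair_block(idx[-nr, -1, drop = FALSE], idx[-1, -nc, drop = FALSE],
                 1 / sqrt(2))
    ))
  }
  from <- unlist(lapply(blocks, `[[`, "from"), use.names = FALSE)
  to <- unlist(lapply(blocks, `[[`, "to"), use.names = FALSE)
  wt <- unlist(lapply(blocks, function(b) rep(b$w, length(b$from))),
               use.names = FALSE)
  cond <- if (conductance_rule == "mean_resistance") {
    2 / (Rn[from] + Rn[to])
  } else {
    (1 / Rn[from] + 1 / Rn[to]) / 2
  }
  cond <- cond * wt

  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < nv || igraph::components(g)$no > 1L)
    stop("resistance raster is disconnected; cannot build a circuit")

  L <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = -c(cond, cond), dims = c(nv, nv))
  Matrix::diag(L) <- -Matrix::rowSums(L)

  structure(list(n = nv, from = from, to = to, cond = cond, L = L,
                 idx = idx, dim = c(nr, nc),
                 cellsize = r$cellsize, xll = r$xll, yll = r$yll,
                 neighbourhood = neighbourhood,
                 conductance_rule = conductance_rule),
            class = "conductance_graph")
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("<conductance_graph> %d nodes, %d edges (%d-neighbourhood, %s)\n",
              x$n, length(x$from), x$neighbourhood, x$conductance_rule))
  invisible(x)
}

# Solve L v = b with unit current injected at `source` and extracted at
# `sink`, with node `ground` held at zero volts. The per-edge currents are
# invariant to the choice of ground. A pre-computed Cholesky factor of
# L[-ground, -ground] can be supplied for repeated solves.
solve_injection <- function(graph, source, sink, ground = sink, chol = NULL) {
  n <- graph$n
  if (source == sink) stop("`source` and `sink` must differ")
  if (any(c(source, sink, ground) < 1L) || any(c(source, sink, ground) > n))
    stop("node index out of range")
  if (is.null(chol))
    chol <- Matrix::Cholesky(Matrix::forceSymmetric(
      graph$L[-ground, -ground, drop = FALSE]), LDL = FALSE, perm = TRUE)
  b <- numeric(n)
  b[source] <- 1
  b[sink] <- -1
  vred <- as.numeric(Matrix::solve(chol, b[-ground], system = "A"))
  v <- numeric(n)
  v[-ground] <- vred
  v
}

# Per-cell current density from a voltage vector: half the sum of absolute
# currents on incident edges; the terminals carry the injected magnitude, so a
# pass-through cell of a uniform chain registers exactly 1.
density_from_voltages <- function(graph, v, source, sink) {
  ecur <- graph$cond * abs(v[graph$from] - v[graph$to])
  acc <- rowsum(rep(ecur, 2L), c(graph$from, graph$to))
  d <- numeric(graph$n)
  d[as.integer(rownames(acc))] <- acc[, 1L] / 2
  d[source] <- 1
  d[sink] <- 1
  d
}

node_vector_to_raster <- function(graph, x) {
  m <- matrix(NA_real_, graph$dim[1], graph$dim[2])
  m[!is.na(graph$idx)] <- x[graph$idx[!is.na(graph$idx)]]
  grid_raster(m, cellsize = graph$cellsize, xll = graph$xll, yll = graph$yll)
}

#' Current density for one source-sink pair
#'
#' Injects one unit of current at `source`, extracts it at `sink` (grounded),
#' solves the Laplacian system, and returns the per-cell current density
#' raster. The voltage vector and the effective resistance between the
#' terminals (voltage drop under unit current) are attached as attributes.
#'
#' @param graph a `conductance_graph`.
#' @param source,sink node indices (see `graph$idx` for the cell-to-node map).
#' @return A `grid_raster` of non-negative current density with attributes
#'   `voltages`, `effective_resistance`, `source`, `sink`.
#' @export
solve_pair <- function(graph, source, sink) {
  stopifnot(inherits(graph, "conductance_graph"))
  v <- solve_injection(graph, source, sink, ground = sink)
  d <- density_from_voltages(graph, v, source, sink)
  out <- node_vector_to_raster(graph, d)
  attr(out, "voltages") <- v
  attr(out, "effective_resistance") <- v[source] - v[sink]
  attr(out, "source") <- source
  attr(out, "sink") <- sink
  out
}

#' Effective resistance between two nodes
#'
#' @inheritParams solve_pair
#' @return Voltage drop between `source` and `sink` under unit injected
#'   current.
#' @export
effective_resistance <- function(graph, source, sink) {
  v <- solve_injection(graph, source, sink, ground = sink)
  v[source] - v[sink]
}

#' Place boundary nodes along the outer margin of the grid
#'
#' Selects `n` cells at approximately equal arc-length intervals along the
#' outermost ring of the (buffered) raster extent, starting from a seeded
#' random offset, snapping to the nearest valid ring cell where needed.
#'
#' @param graph a `conductance_graph`.
#' @param n number of nodes (>= 2); the study that motivated this layout used
#'   50 nodes around a province-scale buffer.
#' @param seed optional integer seed for the starting offset.
#' @return An object of class `node_set`: a data frame with columns `order`,
#'   `node` (graph node index), `row`, `col`.
#' @export
place_boundary_nodes <- function(graph, n = 50, seed = NULL) {
  stopifnot(inherits(graph, "conductance_graph"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be at least 2")
  nr <- graph$dim[1]; nc <- graph$dim[2]
  ring <- rbind(
    cbind(1L, seq_len(nc)),
    cbind(seq(2L, nr), nc),
    cbind(nr, seq(nc - 1L, 1L)),
    cbind(seq(nr - 1L, 2L), 1L)
  )
  P <- nrow(ring)
  ring_nodes <- graph$idx[ring]
  if (sum(!is.na(ring_nodes)) < n)
    stop("perimeter has fewer valid cells than requested nodes")
  offset <- with_seed(seed, sample.int(P, 1L) - 1L)
  targets <- (offset + round((seq_len(n) - 1L) * P / n)) %% P + 1L
  chosen <- integer(0)
  pos <- integer(0)
  for (t in targets) {
    # nearest valid, unused ring position
    for (step in 0:(P - 1L)) {
      for (cand in unique(c((t + step - 1L) %% P + 1L,
                            (t - step - 1L) %% P + 1L))) {
        if (!is.na(ring_nodes[cand]) && !(cand %in% pos)) {
          pos <- c(pos, cand)
          chosen <- c(chosen, ring_nodes[cand])
          step <- NA
          break
        }
      }
      if (is.na(step)) break
    }
  }
  structure(data.frame(order = seq_len(n), node = chosen,
                       row = ring[pos, 1], col = ring[pos, 2]),
            class = c("node_set", "data.frame"))
}

#' Accumulate current density over random boundary-node pairs
#'
#' Repeatedly samples distinct unordered node pairs uniformly at random
#' without replacement (seeded), solves each pair, and sums the per-cell
#' current densities. After each solve beyond `min_pairs`, the Pearson
#' correlation between the cumulative map before and after the latest batch is
#' computed; accumulation stops once it reaches `threshold` (default 0.999,
#' "three nines") or when all pairs are exhausted. A single Cholesky
#' factorization with a fixed grounded reference node is reused across pairs;
#' per-cell currents are invariant to the choice of ground.
#'
#' @param graph a `conductance_graph`.
#' @param nodes a `node_set` from [place_boundary_nodes()].
#' @param threshold convergence correlation in (0, 1).
#' @param seed integer seed for the pair sequence.
#' @param min_pairs solves before convergence checking starts.
#' @param max_pairs optional cap on the number of pairs.
#' @param batch number of solves between convergence checks.
#' @return An object of classes `current_density_map` and `grid_raster`: the
#'   cumulative current-density raster with attributes `pairs_solved`, `trace`
#'   (data frame of per-check correlations), `threshold`, `converged`,
#'   `clipped` and `node_set`.
#' @export
accumulate <- function(graph, nodes, threshold = 0.999, seed = NULL,
                       min_pairs = 10, max_pairs = NULL, batch = 1) {
  stopifnot(inherits(graph, "conductance_graph"), inherits(nodes, "node_set"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  min_pairs <- max(2L, as.integer(min_pairs))
  ids <- nodes$node
  prs <- utils::combn(ids, 2L)
  npair <- ncol(prs)
  if (!is.null(max_pairs)) npair_use <- min(npair, as.integer(max_pairs))
  else npair_use <- npair
  ord <- with_seed(seed, sample.int(npair))[seq_len(npair_use)]

  ground <- ids[1]
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(
    graph$L[-ground, -ground, drop = FALSE]), LDL = FALSE, perm = TRUE)

  cum <- numeric(graph$n)
  trace_k <- integer(0)
  trace_rho <- numeric(0)
  converged <- FALSE
  k <- 0L
  for (p in ord) {
    prev <- cum
    s <- prs[1, p]; t <- prs[2, p]
    v <- solve_injection(graph, s, t, ground = ground, chol = chol)
    cum <- cum + density_from_voltages(graph, v, s, t)
    k <- k + 1L
    if (k >= min_pairs && k %% batch == 0L) {
      rho <- suppressWarnings(stats::cor(prev, cum))
      trace_k <- c(trace_k, k)
      trace_rho <- c(trace_rho, rho)
      if (!is.na(rho) && rho >= threshold) {
        converged <- TRUE
        break
      }
    }
  }
  out <- node_vector_to_raster(graph, cum)
  class(out) <- c("current_density_map", class(out))
  attr(out, "pairs_solved") <- k
  attr(out, "trace") <- data.frame(pair = trace_k, correlation = trace_rho)
  attr(out, "threshold") <- threshold
  attr(out, "converged") <- converged
  attr(out, "clipped") <- FALSE
  attr(out, "node_set") <- nodes
  out
}

#' @export
print.current_density_map <- function(x, ...) {
  cat(sprintf("<current_density_map> %d pairs solved, converged: %s, clipped: %s\n",
              attr(x, "pairs_solved"), isTRUE(attr(x, "converged")),
              isTRUE(attr(x, "clipped"))))
  NextMethod()
}

#' Remove the buffer zone from a current-density map
#'
#' Sets cells outside the study area to NoData, keeping values at retained
#' cells unchanged. The buffer only exists to remove node-placement bias and
#' is discarded before any map comparison.
#'
#' @param map a `current_density_map` (or any `grid_raster`).
#' @param study_mask a binary `grid_raster`, 1 inside the study area, on the
#'   same grid as `map`.
#' @return The clipped map with attribute `clipped = TRUE`.
#' @export
clip_to_study_area <- function(map, study_mask) {
  stop_if_geometry_mismatch(map, study_mask, "map and study mask")
  map$values[study_mask$values != 1 | is.na(study_mask$values)] <- NA_real_
  attr(map, "clipped") <- TRUE
  map
}
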