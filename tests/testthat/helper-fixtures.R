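# shared fixtures and independent oracles, built in code at test time

tiny_bundle <- function(nrow = 30, ncol = 30, n_categories = 3, seed = 42,
                        ...) {
  generate_landscape(landscape_config(nrow = nrow, ncol = ncol,
                                      n_categories = n_categories,
                                      seed = seed, ...))
}

tiny_catalog <- function(n = 3, seed = 7) generate_catalog(n, seed = seed)

# Independent circuit oracle: dense Laplacian assembled with plain loops,
# voltages from the Moore-Penrose pseudo-inverse, per-cell density as half the
# sum of absolute incident edge currents (terminals = injected magnitude).
# Cells are indexed column-major, matching graph node order on all-valid
# rasters. Deliberately shares no code with build_graph()/solve_pair().
oracle_density <- function(R, neighbourhood, source, sink) {
  nr <- nrow(R); nc <- ncol(R); n <- nr * nc
  id <- function(i, j) (j - 1L) * nr + i
  offs <- list(c(0, 1, 1), c(1, 0, 1))
  if (neighbourhood == 8)
    offs <- c(offs, list(c(1, 1, 1 / sqrt(2)), c(-1, 1, 1 / sqrt(2))))
  edges <- NULL
  L <- matrix(0, n, n)
  for (i in seq_len(nr)) for (j in seq_len(nc)) for (d in offs) {
    i2 <- i + d[1]; j2 <- j + d[2]
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
      cnd <- d[3] / ((R[i, j] + R[i2, j2]) / 2)
      a <- id(i, j); b <- id(i2, j2)
      L[a, b] <- L[a, b] - cnd; L[b, a] <- L[b, a] - cnd
      L[a, a] <- L[a, a] + cnd; L[b, b] <- L[b, b] + cnd
      edges <- rbind(edges, c(a, b, cnd))
    }
  }
  rhs <- numeric(n); rhs[source] <- 1; rhs[sink] <- -1
  v <- as.numeric(MASS::ginv(L) %*% rhs)
  dens <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    cur <- edges[k, 3] * abs(v[edges[k, 1]] - v[edges[k, 2]])
    dens[edges[k, 1]] <- dens[edges[k, 1]] + cur
    dens[edges[k, 2]] <- dens[edges[k, 2]] + cur
  }
  dens <- dens / 2
  dens[source] <- 1; dens[sink] <- 1
  list(density = matrix(dens, nr, nc), voltages = v)
}

# position of a cell along the clockwise perimeter ring used for node
# placement (top row, right column, bottom row reversed, left column reversed)
ring_position <- function(nr, nc, row, col) {
  if (row == 1L) return(col)
  if (col == nc) return(nc + row - 1L)
  if (row == nr) return(nc + nr - 1L + (nc - col))
  2L * nc + nr - 2L + (nr - row)
}

ring_length <- function(nr, nc) 2L * (nr + nc) - 4L
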