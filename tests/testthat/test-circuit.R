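test_that("edge conductances follow the half-cell series convention", {
  r <- grid_raster(matrix(c(1, 3), 1, 2))
  g <- build_graph(r, 4)
  expect_equal(g$cond, 0.5)  # 1 / mean(1, 3)

  g4 <- build_graph(grid_raster(matrix(1, 3, 3)), 4)
  expect_true(all(g4$cond == 1))
  expect_equal(length(g4$cond), 12)  # 2 * 3 * 2 rook edges on a 3x3

  g8 <- build_graph(grid_raster(matrix(1, 2, 2)), 8)
  diag_conds <- sort(g8$cond)[1:2]
  expect_equal(diag_conds, rep(1 / sqrt(2), 2))

  gm <- build_graph(grid_raster(matrix(c(1, 3), 1, 2)), 4,
                    conductance_rule = "mean_conductance")
  expect_equal(gm$cond, (1 + 1 / 3) / 2)
})

test_that("degenerate rasters are rejected", {
  m <- matrix(1, 3, 3)
  m[, 2] <- NA  # splits the raster into two components
  expect_error(build_graph(grid_raster(m), 4), "disconnected")
  expect_error(build_graph(grid_raster(matrix(c(1, -2), 1, 2)), 4),
               "positive")
  expect_error(build_graph(grid_raster(matrix(1, 1, 1)), 4), "2 valid cells")
})

test_that("uniform chains carry unit current with the series closed form", {
  g <- build_graph(grid_raster(matrix(1, 1, 5)), 4)
  sp <- solve_pair(g, 1, 5)
  expect_equal(as.vector(raster_values(sp)), rep(1, 5), tolerance = 1e-12)
  expect_equal(attr(sp, "effective_resistance"), 4, tolerance = 1e-12)

  # half-cell convention: R = {1, 2, 1} has inter-cell resistances 1.5 + 1.5
  g3 <- build_graph(grid_raster(matrix(c(1, 2, 1), 1, 3)), 4)
  expect_equal(effective_resistance(g3, 1, 3), 3, tolerance = 1e-12)
})

test_that("sparse solves match the dense pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  for (seed in 1:10) {
    set.seed(seed)
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    nb <- sample(c(4, 8), 1)
    R <- matrix(runif(nr * nc, 0.5, 10), nr, nc)
    g <- build_graph(grid_raster(R), nb)
    src <- sample(g$n, 1); snk <- sample(setdiff(seq_len(g$n), src), 1)
    sp <- solve_pair(g, src, snk)
    orc <- oracle_density(R, nb, src, snk)
    expect_equal(raster_values(sp), orc$density, tolerance = 1e-8)

    # Kirchhoff conservation at every non-terminal node
    v <- attr(sp, "voltages")
    resid <- as.numeric(g$L %*% v)
    resid[c(src, snk)] <- 0
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("currents are reciprocal and invariant to resistance rescaling", {
  set.seed(77)
  R <- matrix(runif(49, 0.5, 10), 7, 7)
  g <- build_graph(grid_raster(R), 8)
  a <- solve_pair(g, 3, 41)
  b <- solve_pair(g, 41, 3)
  expect_equal(raster_values(a), raster_values(b), tolerance = 1e-10)

  gs <- build_graph(grid_raster(R * 13), 8)
  a2 <- solve_pair(gs, 3, 41)
  expect_equal(raster_values(a2), raster_values(a), tolerance = 1e-10)
  expect_equal(attr(a2, "effective_resistance"),
               13 * attr(a, "effective_resistance"), tolerance = 1e-8)
})

test_that("raising a cell's resistance never increases its current", {
  # two parallel 1-cell corridors between the terminals
  R <- matrix(1, 3, 5)
  R[2, 2:4] <- 1000  # block the central path, leaving top and bottom rows
  g <- build_graph(grid_raster(R), 4)
  top_cell <- function(rr) {
    gg <- build_graph(grid_raster(rr), 4)
    sp <- solve_pair(gg, gg$idx[2, 1], gg$idx[2, 5])
    raster_values(sp)[1, 3]
  }
  before <- top_cell(R)
  R2 <- R
  R2[1, 3] <- R2[1, 3] * 10
  expect_lt(top_cell(R2), before)
})

test_that("boundary nodes are evenly spaced, distinct, and seeded", {
  g <- build_graph(grid_raster(matrix(1, 20, 20)), 8)
  ns <- place_boundary_nodes(g, 4, seed = 5)
  expect_equal(nrow(ns), 4)
  expect_equal(anyDuplicated(ns$node), 0)
  P <- ring_length(20, 20)
  pos <- sort(mapply(ring_position, 20, 20, ns$row, ns$col))
  gaps <- diff(c(pos, pos[1] + P))
  expect_true(all(abs(gaps - P / 4) <= 2))

  ns2 <- place_boundary_nodes(g, 2, seed = 9)
  pos2 <- sort(mapply(ring_position, 20, 20, ns2$row, ns2$col))
  arc <- min(diff(c(pos2, pos2[1] + P)))
  expect_gte(arc, 0.4 * P)

  expect_identical(place_boundary_nodes(g, 7, seed = 3),
                   place_boundary_nodes(g, 7, seed = 3))
  expect_error(place_boundary_nodes(g, 1), "at least 2")
})

test_that("accumulation is seeded, converges, and matches single solves", {
  set.seed(42)
  R <- matrix(runif(400, 1, 5), 20, 20)
  g <- build_graph(grid_raster(R), 8)
  ns <- place_boundary_nodes(g, 6, seed = 1)
  m1 <- accumulate(g, ns, threshold = 0.999, seed = 2, min_pairs = 3)
  m2 <- accumulate(g, ns, threshold = 0.999, seed = 2, min_pairs = 3)
  expect_identical(raster_values(m1), raster_values(m2))
  expect_true(all(raster_values(m1) >= 0))
  tr <- attr(m1, "trace")
  expect_true(nrow(tr) >= 1)
  expect_true(attr(m1, "pairs_solved") <= choose(6, 2))

  # two nodes: exactly one pair, map equals that single solve
  ns2 <- place_boundary_nodes(g, 2, seed = 4)
  one <- accumulate(g, ns2, seed = 1)
  expect_equal(attr(one, "pairs_solved"), 1L)
  direct <- solve_pair(g, ns2$node[1], ns2$node[2])
  expect_equal(raster_values(one), raster_values(direct), tolerance = 1e-10)
})

test_that("converged maps on symmetric uniform landscapes are near-symmetric", {
  g <- build_graph(grid_raster(matrix(1, 25, 25)), 8)
  ns <- place_boundary_nodes(g, 12, seed = 0)
  m <- accumulate(g, ns, threshold = 0.999, seed = 0, min_pairs = 10)
  v <- raster_values(m)
  # compare the map with its 180-degree rotation away from the margin
  inner <- v[5:21, 5:21]
  rot <- inner[rev(seq_len(nrow(inner))), rev(seq_len(ncol(inner)))]
  expect_lt(median(abs(inner - rot) / (abs(inner) + abs(rot))), 0.10)
})

test_that("clipping drops buffer cells and keeps retained values", {
  g <- build_graph(grid_raster(matrix(1, 10, 10)), 4)
  ns <- place_boundary_nodes(g, 4, seed = 2)
  m <- accumulate(g, ns, seed = 3, min_pairs = 2)
  mask <- grid_raster(matrix(0, 10, 10))
  mask$values[3:8, 3:8] <- 1
  clipped <- clip_to_study_area(m, mask)
  expect_true(isTRUE(attr(clipped, "clipped")))
  expect_equal(sum(!is.na(raster_values(clipped))), 36)
  expect_equal(raster_values(clipped)[3:8, 3:8], raster_values(m)[3:8, 3:8])
  # all-ones mask is the identity
  allin <- clip_to_study_area(m, grid_raster(matrix(1, 10, 10)))
  expect_equal(raster_values(allin), raster_values(m))
})
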