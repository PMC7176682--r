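# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Smooth a matrix with a separable Gaussian-like kernel of half-width `radius`
# cells, padding edges by reflection. radius 0 returns the input.
smooth_matrix <- function(m, radius) {
  radius <- as.integer(radius)
  if (radius < 1L) return(m)
  radius <- min(radius, nrow(m) - 1L, ncol(m) - 1L)
  k <- stats::dnorm(seq(-2.5, 2.5, length.out = 2L * radius + 1L))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(radius:1, 1:nr, nr:(nr - radius + 1L))
  ci <- c(radius:1, 1:nc, nc:(nc - radius + 1L))
  mp <- m[ri, ci]
  f <- stats::filter(mp, k, sides = 2)          # smooths down columns
  f <- t(stats::filter(t(f), k, sides = 2))     # then across rows
  matrix(f[(radius + 1L):(radius + nr), (radius + 1L):(radius + nc)], nr, nc)
}

# Rasterize the straight segment between two (row, col) cells, one cell wide.
# Returns a two-column matrix of (row, col) indices (Bresenham).
trace_line <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  n <- max(dr, dc) + 1L
  rows <- round(seq(r0, r1, length.out = n))
  cols <- round(seq(c0, c1, length.out = n))
  cbind(rows, cols)
}
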