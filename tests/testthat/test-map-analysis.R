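test_that("standardization centres and scales by the population sd", {
  r <- grid_raster(matrix(c(0, 1, 2, 3), 2, 2))
  z <- standardize(r)
  # population sd of {0,1,2,3} is sqrt(1.25)
  expect_equal(as.vector(raster_values(z)),
               (c(0, 1, 2, 3) - 1.5) / sqrt(1.25), tolerance = 1e-12)
  v <- raster_values(z)
  expect_equal(mean(v), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-10)

  # NoData preserved, constant maps rejected
  r$values[1, 1] <- NA
  z2 <- standardize(r)
  expect_true(is.na(raster_values(z2)[1, 1]))
  expect_equal(mean(raster_values(z2), na.rm = TRUE), 0, tolerance = 1e-10)
  expect_error(standardize(grid_raster(matrix(5, 3, 3))), "zero variance")
})

test_that("classification uses z >= cutoff and is nested across cutoffs", {
  z <- grid_raster(matrix(c(-1, 0, 0.5, 1, 1.5, 2), 2, 3))
  c0 <- classify(z, 0); c1 <- classify(z, 1); c2 <- classify(z, 2)
  # ties are classified important
  expect_equal(raster_values(c1)[2, 2], 1)
  expect_equal(raster_values(c0)[1, 2], 1)
  # monotone nesting: important at 2 implies important at 1 implies at 0
  expect_true(all(raster_values(c2) <= raster_values(c1)))
  expect_true(all(raster_values(c1) <= raster_values(c0)))
})

test_that("classified fraction above z = 2 matches the normal tail", {
  set.seed(9)
  z <- grid_raster(matrix(rnorm(1e5), 250, 400))
  frac <- mean(raster_values(classify(standardize(z), 2)))
  expect_lt(abs(frac - pnorm(2, lower.tail = FALSE)), 0.003)
})

test_that("correlation and agreement matrices satisfy their invariants", {
  set.seed(4)
  a <- grid_raster(matrix(rnorm(1e4), 100, 100))
  b <- grid_raster(matrix(rnorm(1e4), 100, 100))
  neg <- a; neg$values <- -neg$values
  M <- correlation_matrix(list(a = a, b = b, neg = neg))
  expect_true(isSymmetric(M))
  expect_equal(diag(M), c(a = 1, b = 1, neg = 1))
  expect_equal(M["a", "neg"], -1, tolerance = 1e-12)
  expect_lt(abs(M["a", "b"]), 0.05)  # independent fields decorrelate

  ca <- classify(standardize(a), 0)
  cb <- classify(standardize(b), 0)
  comp <- ca; comp$values <- 1 - comp$values
  A <- agreement_matrix(list(ca = ca, cb = cb, comp = comp))
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(diag(A), c(ca = 1, cb = 1, comp = 1))
  expect_equal(A["ca", "comp"], 0)

  # direct count check: agreement is the fraction of equal cells
  x <- grid_raster(matrix(c(rep(1, 75), rep(0, 25)), 10, 10))
  y <- grid_raster(matrix(1, 10, 10))
  expect_equal(agreement_matrix(list(x, y))[1, 2], 0.75)

  # mask mismatch is an error
  a2 <- a; a2$values[1, 1] <- NA
  expect_error(correlation_matrix(list(a, a2)), "mask")
})

test_that("dissimilarity transforms invert similarity correctly", {
  m <- matrix(c(1, 0.94, 0.94, 1), 2, 2)
  D <- to_dissimilarity(m, "one_minus")
  expect_equal(D[1, 2], 0.06)
  expect_equal(diag(D), c(0, 0))
  Ds <- to_dissimilarity(m, "sqrt_one_minus")
  expect_equal(Ds[1, 2], sqrt(0.06))
  expect_equal(to_dissimilarity(matrix(c(1, -1, -1, 1), 2, 2))[1, 2], 2)
  expect_error(to_dissimilarity(matrix(c(1, 1.2, 1.2, 1), 2, 2)), "exceed")
})

test_that("db-RDA partitioning matches vegan on Euclidean configurations", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    D <- as.matrix(dist(X))
    d <- factorial_design()
    dsg <- data.frame(water = d$water_high, scaling = d$scaling_high,
                      h = d$h_F)
    mine <- varpart_dbrda(D, dsg, adjust = TRUE)
    vp <- vegan::varpart(dist(X), ~water, ~scaling, ~h, data = dsg)
    ref <- vp$part$indfract$Adj.R.square[1:3]
    expect_equal(mine$fractions$unique_pct, 100 * ref, tolerance = 1e-6)
  }
})

test_that("db-RDA partitioning recovers a constructed dominant factor", {
  # all maps share a base field; the water factor adds a field of equal
  # magnitude, the other two factors only weak noise
  d <- factorial_design()
  set.seed(3)
  base <- rnorm(300); sig <- rnorm(300); s2 <- rnorm(300); s3 <- rnorm(300)
  maps <- lapply(seq_len(8), function(i) {
    base + d$water_high[i] * sig + 0.05 * d$scaling_high[i] * s2 +
      0.05 * d$h_F[i] * s3 + 0.02 * rnorm(300)
  })
  r <- cor(do.call(cbind, maps))
  D <- to_dissimilarity(r, "one_minus")
  vp <- varpart_dbrda(D, data.frame(water = d$water_high,
                                    scaling = d$scaling_high, h = d$h_F),
                      adjust = FALSE)
  expect_gt(vp$fractions$unique_pct[1], 90)
  expect_lt(max(vp$fractions$unique_pct[2:3]), 10)
})

test_that("degenerate and closure cases behave as documented", {
  d <- factorial_design()
  dsg <- data.frame(water = d$water_high, scaling = d$scaling_high,
                    h = d$h_F)
  expect_warning(vp0 <- varpart_dbrda(matrix(0, 8, 8), dsg), "identical")
  expect_true(vp0$degenerate)
  expect_equal(vp0$fractions$unique_pct, rep(0, 3))
  expect_equal(vp0$unexplained_pct, 100)

  set.seed(8)
  D <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  vp <- varpart_dbrda(D, dsg, adjust = FALSE)
  expect_equal(sum(vp$fractions$unique_pct) + vp$unexplained_pct, 100,
               tolerance = 0.2)
})

test_that("the shipped correlation fixture is a valid design-ordered matrix", {
  r <- alberta_map_correlations()
  expect_equal(dim(unclass(r))[1:2], c(8L, 8L))
  expect_true(isSymmetric(unname(unclass(r))))
  expect_equal(unname(diag(unclass(r))), rep(1, 8))
  expect_equal(rownames(r), factorial_design()$map)
  expect_equal(min(r), 0.34)
  expect_equal(max(r - diag(8)), 0.94)
})
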