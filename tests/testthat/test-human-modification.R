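test_that("fuzzy sum matches hand-computed combinations", {
  expect_equal(fuzzy_sum(numeric(0)), 0)
  expect_equal(fuzzy_sum(0.3), 0.3)
  expect_equal(fuzzy_sum(c(0.5, 0.5)), 0.75)
  expect_equal(fuzzy_sum(c(0.2, 0.5, 0.7)), 1 - 0.8 * 0.5 * 0.3)
  expect_equal(fuzzy_sum(c(1, 0.37)), 1)
  expect_error(fuzzy_sum(c(0.2, 1.1)), "\\[0, 1\\]")
  expect_error(fuzzy_sum(c(-0.1)), "\\[0, 1\\]")
})

test_that("fuzzy sum is bounded, monotone, and permutation invariant", {
  set.seed(101)
  for (rep in seq_len(1000)) {
    h <- runif(sample(1:6, 1))
    H <- fuzzy_sum(h)
    expect_gte(H, max(h) - 1e-12)
    expect_lte(H, min(1, sum(h)) + 1e-12)
    expect_equal(fuzzy_sum(sample(h)), H, tolerance = 1e-12)
    expect_gte(fuzzy_sum(c(h, runif(1))), H - 1e-12)
  }
})

test_that("effective h selects or averages the regional catalog values", {
  ctl <- data.frame(category = c("a", "a"),
                    region = c("forest", "agriculture"),
                    h_F = c(0.4, 0.1), h_U = c(0.8, 0.3))
  class(ctl) <- c("footprint_catalog", "data.frame")
  expect_equal(effective_h(ctl, "a", "forest", "H_F"), 0.4)
  expect_equal(effective_h(ctl, "a", "forest", "H_U"), 0.8)
  expect_equal(effective_h(ctl, "a", "forest", "H_FU"), 0.6)
  expect_equal(effective_h(ctl, "a", "agriculture", "H_FU"), 0.2)
  expect_error(effective_h(ctl, "b", "forest", "H_F"), "no catalog entry")
})

test_that("modification surface applies the fuzzy sum with regional values", {
  b <- tiny_bundle(nrow = 24, ncol = 24, n_categories = 3, seed = 11,
                   coverage = 0.3)
  ctl <- tiny_catalog(3, seed = 4)
  H <- modification_surface(b, ctl, "H_F")
  v <- raster_values(H)
  expect_true(all(v >= 0 & v <= 1))

  # cells with no footprint have H = 0
  occ <- Reduce(`+`, lapply(b$footprints, raster_values))
  expect_true(all(v[occ == 0] == 0))

  # independent per-cell oracle on a sample of cells
  reg <- raster_values(b$region)
  set.seed(1)
  cells <- sample(length(v), 50)
  for (cell in cells) {
    rname <- names(region_codes())[reg[cell]]
    hs <- vapply(names(b$footprints), function(cat) {
      if (raster_values(b$footprints[[cat]])[cell] == 1)
        effective_h(ctl, cat, rname, "H_F") else NA_real_
    }, numeric(1))
    hs <- hs[!is.na(hs)]
    expect_equal(v[cell], 1 - prod(1 - hs), tolerance = 1e-12)
  }
})

test_that("single-footprint cells give H equal to the catalog value", {
  b <- tiny_bundle(nrow = 20, ncol = 20, n_categories = 2, seed = 3)
  ctl <- tiny_catalog(2, seed = 8)
  # isolate category 2 by zeroing category 1
  b$footprints[[1]]$values[] <- 0
  H <- modification_surface(b, ctl, "H_F")
  occ2 <- raster_values(b$footprints[[2]]) == 1
  reg <- raster_values(b$region)
  expected <- ifelse(reg == region_codes()[["forest"]],
                     effective_h(ctl, "cat02", "forest", "H_F"),
                     effective_h(ctl, "cat02", "agriculture", "H_F"))
  expect_equal(raster_values(H)[occ2], expected[occ2], tolerance = 1e-12)
})

test_that("H_FU averaging conventions agree exactly on single-footprint cells", {
  b <- tiny_bundle(nrow = 24, ncol = 24, n_categories = 3, seed = 5)
  ctl <- tiny_catalog(3, seed = 5)
  h_cat <- modification_surface(b, ctl, "H_FU", fu_average = "category")
  h_surf <- modification_surface(b, ctl, "H_FU", fu_average = "surface")
  occ <- Reduce(`+`, lapply(b$footprints, raster_values))
  single <- occ == 1
  expect_true(any(single))
  expect_equal(raster_values(h_cat)[single], raster_values(h_surf)[single],
               tolerance = 1e-12)
  # with one layer only, H_FU equals (h_F + h_U) / 2 everywhere
  hf <- modification_surface(b, ctl, "H_F")
  hu <- modification_surface(b, ctl, "H_U")
  expect_equal(raster_values(h_surf),
               (raster_values(hf) + raster_values(hu)) / 2,
               tolerance = 1e-12)
})

test_that("non-binary footprint layers are rejected", {
  b <- tiny_bundle(nrow = 10, ncol = 10, n_categories = 1, seed = 2)
  ctl <- tiny_catalog(1)
  b$footprints[[1]]$values[1, 1] <- 0.5
  expect_error(modification_surface(b, ctl, "H_F"), "binary")
})
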