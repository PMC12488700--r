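test_that("PCA band selection finds the one spatially varying band", {
  withr::with_seed(4, {
    data <- array(0.3, dim = c(8, 8, 12))
    data[, , 10] <- matrix(runif(64, 0, 1), 8, 8)
  })
  cube <- spectral_cube(data, seq(400, 950, length.out = 12))
  mask <- matrix(TRUE, 8, 8)
  sel <- pca_band_select(cube, mask, n_pcs = 3)
  expect_identical(sel$selected_band_indices[1], 10L)
  expect_gt(sel$explained_variance_ratio[1], 0.99)
  expect_equal(sum(sel$explained_variance_ratio), 1, tolerance = 1e-8)
  expect_identical(anyDuplicated(sel$selected_band_indices), 0L)

  # loading signs are irrelevant: a mirrored cube selects the same bands
  flipped <- spectral_cube(1.2 - data, cube$wavelengths)
  sel2 <- pca_band_select(flipped, mask, n_pcs = 3)
  expect_identical(sel2$selected_band_indices[1], 10L)
})

test_that("PCA band selection rejects degenerate inputs", {
  cube <- spectral_cube(array(0.2, dim = c(6, 6, 4)), c(500, 600, 700, 800))
  expect_error(pca_band_select(cube, matrix(FALSE, 6, 6)), "empty")
  expect_error(pca_band_select(cube, matrix(TRUE, 6, 6)),
               "spatially constant")
})

test_that("the hand-enumerated 2x2 co-occurrence example is exact", {
  img <- rbind(c(0, 1), c(0, 1))
  g <- compute_glcm(img, levels = 2, offsets = list(c(0L, 1L)))
  expect_equal(g[1, 2], 0.5)
  expect_equal(g[2, 1], 0.5)
  expect_equal(g[1, 1] + g[2, 2], 0)

  f <- glcm_features(g)
  expect_equal(f$con, 1)
  expect_equal(f$dis, 1)
  expect_equal(f$ent, log(2))
  expect_equal(f$mea, 0.5)
})

test_that("constant images give a single co-occurrence cell and zero texture", {
  g <- compute_glcm(matrix(0.7, 6, 6), levels = 8)
  expect_equal(g[1, 1], 1)
  expect_equal(sum(g), 1)
  f <- glcm_features(g)
  expect_equal(f$con, 0); expect_equal(f$dis, 0)
  expect_equal(f$ent, 0); expect_equal(f$mea, 0)
})

test_that("co-occurrence matrices normalize to 1 for random images", {
  for (s in 1:3) {
    img <- withr::with_seed(s, matrix(runif(400), 20, 20))
    expect_equal(sum(compute_glcm(img)), 1, tolerance = 1e-12)
  }
})

test_that("entropy is maximal for the uniform matrix", {
  L <- 4
  unif <- matrix(1 / L^2, L, L)
  expect_equal(glcm_features(unif)$ent, 2 * log(L))
  expect_error(glcm_features(unif * 2), "not normalized")
})

test_that("texture features are shift-invariant", {
  img <- withr::with_seed(6, matrix(runif(225), 15, 15))
  f1 <- glcm_features(compute_glcm(img))
  f2 <- glcm_features(compute_glcm(img + 5))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("the texture pipeline yields 4 features x 3 components", {
  g <- gen_cube(seed = 5, shape = c(32, 32), texture_contrast = 1.5,
                n_bands = 20)
  tex <- texture_pipeline(g$cube, g$mask)
  expect_identical(nrow(tex), 3L)
  expect_length(texture_vector(tex), 12L)
  expect_true(all(tex$con >= 0 & tex$dis >= 0 & tex$ent >= 0))

  # deterministic: no RNG involved
  expect_identical(tex, texture_pipeline(g$cube, g$mask))
})

test_that("a zero-contrast cube yields zero spatial texture", {
  g <- gen_cube(seed = 2, shape = c(24, 24), texture_contrast = 0,
                n_bands = 10)
  expect_warning(tex <- texture_pipeline(g$cube, g$mask),
                 "spatially constant")
  expect_equal(tex$con, rep(0, 3))
  expect_equal(tex$dis, rep(0, 3))
  expect_equal(tex$ent, rep(0, 3))
})

test_that("pipeline contrast increases with cube texture strength", {
  con_at <- function(tc) {
    g <- gen_cube(seed = 8, shape = c(32, 32), texture_contrast = tc,
                  n_bands = 16)
    mean(texture_pipeline(g$cube, g$mask)$con)
  }
  expect_lt(con_at(0.8), con_at(2.5))
})
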