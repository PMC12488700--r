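test_that("7:2:1 split sizes follow largest-remainder rounding", {
  s10 <- split_721(10, seed = 1)
  expect_identical(s10$sizes, c(7L, 2L, 1L))
  s508 <- split_721(508, seed = 1)
  expect_identical(s508$sizes, c(356L, 101L, 51L))

  all_idx <- c(s508$train, s508$validation, s508$test)
  expect_identical(sort(all_idx), 1:508)
  expect_identical(anyDuplicated(all_idx), 0L)

  expect_identical(split_721(508, seed = 9), split_721(508, seed = 9))
  expect_false(identical(split_721(508, seed = 9)$train,
                         split_721(508, seed = 10)$train))
  expect_error(split_721(5), "at least 10")
})

test_that("feature fusion concatenates aligned columns", {
  d <- gen_spectra(planted_band_spec(n_samples = 6, n_bands = 40, seed = 2))
  sub <- spectra_mat(d$spectra$values[, 1:34], d$spectra$wavelengths[1:34],
                     d$spectra$sample_ids)
  vi <- compute_vi_table(d$spectra)
  fused <- fuse_features(sub, vi)
  expect_identical(ncol(fused), 42L)             # 34 bands + 8 indices
  expect_identical(nrow(fused), 6L)

  tex <- tibble::tibble(sample_id = d$spectra$sample_ids,
                        !!!stats::setNames(as.list(as.data.frame(
                          matrix(rnorm(6 * 12), 6))), paste0("t", 1:12)))
  wide <- fuse_features(spectra_mat(matrix(rnorm(6 * 75), 6),
                                    seq(400, by = 2, length.out = 75),
                                    d$spectra$sample_ids), tex)
  expect_identical(ncol(wide), 87L)              # 75 bands + 12 textures

  expect_identical(fuse_features(sub, NULL), sub$values)

  bad <- vi; bad$sample_id <- paste0("x", seq_len(6))
  expect_error(fuse_features(sub, bad), "disagree")

  # extra features follow the spectral row order, not file order
  vi_shuffled <- vi[c(3, 1, 6, 2, 5, 4), ]
  expect_equal(fuse_features(sub, vi_shuffled), fused)
})

test_that("normalization statistics come from the training partition only", {
  withr::with_seed(3, {
    x <- matrix(rnorm(200 * 5, mean = 10), 200, 5)
    y <- x[, 1] + rnorm(200)
  })
  sp <- split_721(200, seed = 3)
  m <- train_model(x[sp$train, ], y[sp$train], x[sp$validation, ],
                   y[sp$validation], model_spec("PLSR"))
  expect_equal(m$normalizer$center, colMeans(x[sp$train, ]))
  expect_equal(m$normalizer$scale, apply(x[sp$train, ], 2, sd))
  expect_false(isTRUE(all.equal(m$normalizer$center, colMeans(x))))
})

test_that("PLSR nails a noiseless linear signal", {
  d <- gen_spectra(planted_band_spec(
    informative_band_indices = c(3L, 11L), coefficients = c(2, -1),
    noise_sd = 0, n_samples = 100, n_bands = 20, seed = 4))
  x <- d$spectra$values; y <- d$target
  sp <- split_721(100, seed = 4)
  m <- train_model(x[sp$train, ], y[sp$train], x[sp$validation, ],
                   y[sp$validation], model_spec("PLSR"))
  rep <- evaluate(m, x, y, sp, "planted")
  expect_gt(rep$r2_train, 0.999)
  expect_gt(rep$r2_test, 0.999)
})

test_that("the FNN recovers a smooth nonlinear surface", {
  withr::with_seed(11, {
    x <- cbind(runif(400, -2, 2), runif(400, -2, 2))
    y <- sin(3 * x[, 1]) + x[, 2]^2
  })
  sp <- split_721(400, seed = 4)
  m <- train_model(x[sp$train, ], y[sp$train], x[sp$validation, ],
                   y[sp$validation], model_spec("FNN", seed = 8))
  expect_gt(evaluate(m, x, y, sp, "sim")$r2_test, 0.9)
})

test_that("network training is seed-deterministic", {
  withr::with_seed(5, {
    x <- matrix(runif(150 * 12), 150, 12)
    y <- x[, 1] - 2 * x[, 5]^2 + rnorm(150, 0, 0.05)
  })
  sp <- split_721(150, seed = 5)
  fit_once <- function(fam) {
    m <- train_model(x[sp$train, ], y[sp$train], x[sp$validation, ],
                     y[sp$validation], model_spec(fam, seed = 13,
                                                  epochs = 60))
    predict(m, x[sp$test, ])
  }
  for (fam in c("FNN", "CNN")) {
    expect_identical(fit_once(fam), fit_once(fam))
  }
})

test_that("SVR fits and predicts through the shared interface", {
  withr::with_seed(6, {
    x <- matrix(runif(200 * 4), 200, 4)
    y <- exp(x[, 1]) + x[, 2] + rnorm(200, 0, 0.05)
  })
  sp <- split_721(200, seed = 6)
  m <- train_model(x[sp$train, ], y[sp$train], x[sp$validation, ],
                   y[sp$validation], model_spec("SVR"))
  expect_gt(evaluate(m, x, y, sp, "svr")$r2_test, 0.8)
})

test_that("evaluation reports satisfy the RPD identity and capping", {
  withr::with_seed(7, {
    x <- matrix(rnorm(120 * 3), 120, 3)
    y <- rnorm(120)
  })
  sp <- split_721(120, seed = 7)
  m <- train_model(x[sp$train, ], y[sp$train], x[sp$validation, ],
                   y[sp$validation], model_spec("SVR"))
  rep <- evaluate(m, x, y, sp, "noise")
  expect_equal(rep$rpd_test * rep$rmsep_test, sd(y[sp$test]),
               tolerance = 1e-9)
  expect_false(rep$rpd_capped)

  # an exact model has zero RMSEP: RPD is reported capped
  ident <- structure(
    list(spec = model_spec("PLSR"),
         normalizer = list(method = "none", center = 0, scale = 1),
         fitted = structure(list(coefficients = matrix(c(1, 0, 0), 3, 1),
                                 intercepts = 0, n_components = 1L,
                                 x_mean = rep(0, 3), x_scale = rep(1, 3),
                                 y_mean = 0),
                            class = "pls_model"),
         y_mean = 0, y_sd = 1, n_features = 3L),
    class = "hsip_model")
  rep2 <- evaluate(ident, x, x[, 1], sp, "identity")
  expect_true(rep2$rpd_capped)
  expect_equal(rep2$r2_test, 1)
})
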