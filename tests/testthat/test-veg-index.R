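nearest_band_idx <- function(sm, nm) which.min(abs(sm$wavelengths - nm))

# A tiny spectra matrix with hand-set bands at the default VI wavelengths.
vi_fixture <- function(values_by_wl) {
  wl <- as.numeric(names(values_by_wl))
  ord <- order(wl)
  spectra_mat(matrix(unlist(values_by_wl)[ord], nrow = 1), wl[ord])
}

test_that("reflectance_at resolves the nearest band with low-side ties", {
  sm <- spectra_mat(matrix(1:4, 1), c(560, 870.9, 873.0, 900))
  expect_identical(reflectance_at(sm, 871), sm$values[, 2])   # 870.9 wins
  expect_identical(reflectance_at(sm, 873), sm$values[, 3])
  expect_identical(reflectance_at(sm, 871.95), sm$values[, 2]) # midpoint tie
  expect_error(reflectance_at(sm, 2000), "outside")
})

test_that("index formulas match hand arithmetic", {
  sm <- vi_fixture(list(`450` = 0.05, `558` = 0.2, `718` = 0.25,
                        `720` = 0.2, `726` = 0.3, `871` = 0.6, `873` = 0.5))
  expect_equal(compute_vi(sm, "NDVI")$value, (0.6 - 0.2) / (0.6 + 0.2))
  expect_equal(compute_vi(sm, "CIgreen")$value, 0.6 / 0.2 - 1)
  expect_equal(compute_vi(sm, "NDRE")$value, (0.6 - 0.2) / (0.6 + 0.2))
  expect_equal(compute_vi(sm, "EVI")$value,
               2.5 * (0.6 - 0.3) / (0.5 + 6 * 0.3 - 7.5 * 0.05 + 1))
  expect_equal(compute_vi(sm, "MSRREG")$value,
               (0.6 / 0.25 - 1) / (sqrt(0.6 / 0.25) + 1))
  expect_equal(compute_vi(sm, "RDVIREG")$value,
               (0.5 - 0.3) / sqrt(0.5 + 0.3))

  # OSAVI with equal NIR and red-edge reflectance has a zero numerator
  sm0 <- vi_fixture(list(`726` = 0.5, `873` = 0.5))
  expect_equal(compute_vi(sm0, "OSAVIREG")$value, 0)
})

test_that("zero denominators are flagged with the sample id", {
  sm <- spectra_mat(matrix(c(0.5, 0, 0.4, 0.2), 2), c(558, 871),
                    sample_ids = c("ok", "bad"))
  expect_warning(out <- compute_vi(sm, "CIgreen"), "bad")
  expect_true(is.nan(out$value[2]))
  expect_equal(out$value[1], 0.4 / 0.5 - 1)
})

test_that("ratio-based indices are invariant to global reflectance scaling", {
  d <- gen_spectra(planted_band_spec(n_samples = 15, seed = 9))
  sm <- d$spectra
  scaled <- spectra_mat(sm$values * 3.7, sm$wavelengths, sm$sample_ids)
  for (idx in c("CIgreen", "CIrededge", "MSRREG", "NDRE", "NDVI")) {
    expect_equal(compute_vi(scaled, idx)$value, compute_vi(sm, idx)$value,
                 tolerance = 1e-12)
  }
  # bounds for nonnegative reflectance
  for (idx in c("NDVI", "NDRE")) {
    v <- compute_vi(sm, idx)$value
    expect_true(all(v >= -1 & v <= 1))
  }
  expect_true(all(compute_vi(sm, "CIgreen")$value >= -1))
})

test_that("band-pair optimization recovers a planted NDRE pair", {
  d <- gen_spectra(planted_band_spec(n_samples = 200, seed = 31))
  sm <- d$spectra
  nir <- reflectance_at(sm, 871)
  reg <- reflectance_at(sm, 720)
  target <- (nir - reg) / (nir + reg)
  res <- optimize_band_pair(sm, target, "NDRE")
  expect_gt(res$abs_correlation, 0.999)
  expect_equal(res$nm_a, sm$wavelengths[nearest_band_idx(sm, 871)])
  expect_equal(res$nm_b, sm$wavelengths[nearest_band_idx(sm, 720)])
})

test_that("optimized pair beats random manual pairs", {
  d <- gen_spectra(planted_band_spec(n_samples = 120, seed = 14))
  sm <- d$spectra
  res <- optimize_band_pair(sm, d$target, "NDRE")
  wl <- sm$wavelengths
  ia <- wl[wl >= 700 & wl <= 1000]
  ib <- wl[wl >= 680 & wl <= 750]
  rand_r <- withr::with_seed(14, {
    sapply(1:100, function(i) {
      v <- compute_vi(sm, "NDRE", nm_a = sample(ia, 1), nm_b = sample(ib, 1))
      suppressWarnings(abs(stats::cor(v$value, d$target)))
    })
  })
  # the regions overlap, so a random draw can pair a band with itself,
  # giving a constant (skipped) index
  expect_gte(res$abs_correlation, max(rand_r, na.rm = TRUE))
})

test_that("a noise target yields no spuriously strong pair", {
  d <- gen_spectra(planted_band_spec(n_samples = 200, seed = 77))
  noise <- withr::with_seed(78, rnorm(200))
  res <- optimize_band_pair(d$spectra, noise, "NDRE")
  expect_lt(res$abs_correlation, 0.35)
})

test_that("grid-identical NIR candidates resolve to the lower wavelength", {
  withr::with_seed(3, {
    reg_col <- runif(30, 0.2, 0.3)
    nir_col <- runif(30, 0.5, 0.6)
  })
  vals <- cbind(reg_col, nir_col, nir_col)   # two identical NIR bands
  sm <- spectra_mat(vals, c(720, 890, 910))
  target <- (nir_col - reg_col) / (nir_col + reg_col)
  res <- optimize_band_pair(sm, target, "NDRE")
  expect_equal(res$nm_a, 890)
})

test_that("constant targets and unknown indices are rejected", {
  d <- gen_spectra(planted_band_spec(n_samples = 20, seed = 2))
  expect_error(optimize_band_pair(d$spectra, rep(1, 20), "NDRE"),
               "zero variance")
  expect_error(compute_vi(d$spectra, "NOPE"), "unknown")
})
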