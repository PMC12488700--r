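make_sm <- function(m, wl = NULL) {
  spectra_mat(m, wl %||% seq(400, by = 10, length.out = ncol(m)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SNV centers and scales each spectrum", {
  sm <- make_sm(rbind(c(1, 2, 3), c(10, 30, 20)))
  out <- snv(sm)
  expect_equal(unname(out$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(out$values)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(out$values, 1, sd)), c(1, 1), tolerance = 1e-10)

  expect_error(snv(make_sm(rbind(c(5, 5, 5), c(1, 2, 3)))), "s1")
})

test_that("MSC matches its closed-form OLS correction", {
  withr::with_seed(5, {
    ref <- sort(runif(20, 0.1, 0.6))
    X <- rbind(ref,                 # identical to reference
               2 * ref + 1,         # affine transform of reference
               ref + rnorm(20, 0, 0.01))
  })
  sm <- make_sm(X)
  out <- msc(sm, reference = ref)
  expect_equal(unname(out$values[1, ]), unname(ref), tolerance = 1e-10)
  expect_equal(unname(out$values[2, ]), unname(ref), tolerance = 1e-10)

  # idempotent with the stored reference
  again <- msc(out, reference = attr(out, "msc_reference"))
  expect_equal(again$values, out$values, tolerance = 1e-10)

  expect_error(msc(sm, reference = ref[-1]), "length")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  wl <- seq(400, 790, by = 10)
  poly <- 2 + 0.05 * seq_along(wl) - 0.001 * seq_along(wl)^2
  sm <- make_sm(rbind(poly, rep(0.3, length(wl))), wl)
  out <- sg_smooth(sm, window = 7, polyorder = 2)
  expect_equal(unname(out$values[1, ]), unname(poly), tolerance = 1e-8)
  expect_equal(unname(out$values[2, ]), rep(0.3, length(wl)))

  expect_error(sg_smooth(sm, window = 4), "odd")
  expect_error(sg_smooth(sm, window = 101), "band count")
})

test_that("first derivative is exact for lines and accurate for sines", {
  wl <- seq(400, 599, by = 1)
  lin <- 0.001 * wl + 0.2
  sine <- 0.1 * sin(2 * pi * wl / 60) + 0.3
  sm <- make_sm(rbind(lin, sine, rep(0.4, length(wl))), wl)

  for (mode in c("sg_derivative", "finite_difference")) {
    out <- first_derivative(sm, mode = mode)
    interior <- 5:(length(wl) - 4)
    expect_equal(unname(out$values[1, interior]),
                 rep(0.001, length(interior)), tolerance = 1e-8)
    expect_equal(unname(out$values[3, ]), rep(0, length(wl)),
                 tolerance = 1e-12)
  }

  dsg <- first_derivative(sm, mode = "sg_derivative")
  truth <- 0.1 * (2 * pi / 60) * cos(2 * pi * wl / 60)
  interior <- 5:(length(wl) - 4)
  expect_lt(max(abs(dsg$values[2, interior] - truth[interior])),
            0.02 * max(abs(truth)))

  expect_error(first_derivative(make_sm(matrix(1:4, 2, 2))), "3 bands")
})

test_that("all pretreatments are row-independent", {
  d <- gen_spectra(planted_band_spec(n_samples = 12, n_bands = 40, seed = 6))
  sm <- d$spectra
  perm <- c(4, 1, 12, 7, 2, 9, 3, 11, 5, 10, 8, 6)
  permuted <- spectra_mat(sm$values[perm, ], sm$wavelengths,
                          sm$sample_ids[perm])
  for (m in c("snv", "sg", "fd")) {
    a <- preprocess(sm, m)$values[perm, ]
    b <- preprocess(permuted, m)$values
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
  # MSC with a frozen reference is also row-independent
  ref <- colMeans(sm$values)
  expect_equal(unname(msc(sm, ref)$values[perm, ]),
               unname(msc(permuted, ref)$values), tolerance = 1e-12)
})

test_that("pretreatments preserve matrix shape", {
  d <- gen_spectra(planted_band_spec(n_samples = 8, n_bands = 30, seed = 1))
  for (m in c("snv", "msc", "sg", "fd")) {
    out <- preprocess(d$spectra, m)
    expect_identical(dim(out$values), dim(d$spectra$values))
    expect_identical(out$wavelengths, d$spectra$wavelengths)
  }
})
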