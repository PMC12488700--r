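test_that("ENVI round trip is bit-identical and interleave-invariant", {
  cube <- tiny_cube(6, 4, 5)
  tmp <- withr::local_tempdir()
  paths <- purrr::map_chr(c("bsq", "bil", "bip"), function(il) {
    base <- file.path(tmp, paste0("cube_", il))
    write_envi(cube, base, interleave = il)
    base
  })
  readbacks <- purrr::map(paths, ~ read_envi(paste0(.x, ".hdr")))
  for (rb in readbacks) {
    expect_identical(rb$data, cube$data)
    expect_identical(rb$wavelengths, cube$wavelengths)
  }
  expect_identical(readbacks[[1]]$data, readbacks[[2]]$data)
  expect_identical(readbacks[[2]]$data, readbacks[[3]]$data)
})

test_that("float32 storage round-trips within single precision", {
  cube <- tiny_cube(4, 4, 3)
  tmp <- withr::local_tempdir()
  write_envi(cube, file.path(tmp, "f32"), data_type = 4)
  rb <- read_envi(file.path(tmp, "f32.hdr"))
  expect_equal(rb$data, cube$data, tolerance = 1e-6)
})

test_that("header inconsistencies are rejected", {
  cube <- tiny_cube(4, 4, 3)
  tmp <- withr::local_tempdir()
  base <- file.path(tmp, "bad")
  write_envi(cube, base)
  hdr <- readLines(paste0(base, ".hdr"))

  # wavelength list shorter than declared band count
  hdr_bad <- sub("wavelength = \\{ [^,]*, ", "wavelength = { ", hdr)
  writeLines(hdr_bad, paste0(base, ".hdr"))
  expect_error(read_envi(paste0(base, ".hdr")), "wavelength list")

  # missing required field
  writeLines(hdr[!grepl("^interleave", hdr)], paste0(base, ".hdr"))
  expect_error(read_envi(paste0(base, ".hdr")), "interleave")

  # byte count mismatch
  writeLines(hdr, paste0(base, ".hdr"))
  bin <- readBin(paste0(base, ".dat"), "raw",
                 n = file.info(paste0(base, ".dat"))$size)
  writeBin(bin[-(1:8)], paste0(base, ".dat"))
  expect_error(read_envi(paste0(base, ".hdr")), "size mismatch")
})

test_that("ROI mean spectrum matches brute-force averaging", {
  cube <- tiny_cube(5, 5, 3)
  # constant field
  const <- spectral_cube(array(0.4, dim = c(5, 5, 3)), c(500, 550, 600))
  mask <- matrix(FALSE, 5, 5); mask[2:3, 2:4] <- TRUE
  expect_equal(unname(extract_roi_mean_spectrum(const, mask)), rep(0.4, 3))

  # singleton mask returns that pixel's spectrum exactly
  m1 <- matrix(FALSE, 5, 5); m1[3, 4] <- TRUE
  expect_identical(unname(extract_roi_mean_spectrum(cube, m1)),
                   as.vector(cube$data[3, 4, ]))

  # 4-pixel mask equals the hand-summed per-band average
  m4 <- matrix(FALSE, 5, 5)
  px <- list(c(1, 1), c(2, 5), c(4, 3), c(5, 2))
  for (p in px) m4[p[1], p[2]] <- TRUE
  manual <- sapply(1:3, function(b) {
    mean(sapply(px, function(p) cube$data[p[1], p[2], b]))
  })
  expect_equal(unname(extract_roi_mean_spectrum(cube, m4)), manual)

  expect_error(extract_roi_mean_spectrum(cube, matrix(FALSE, 5, 5)),
               "empty")
  expect_error(extract_roi_mean_spectrum(cube, matrix(TRUE, 4, 5)),
               "shape")
})

test_that("ROI masks load from CSV grids and PNG images", {
  mask <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "mask.csv")
  utils::write.table(mask, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  expect_identical(read_roi_mask(csv), mask == 1)

  pngf <- file.path(tmp, "mask.png")
  png::writePNG(mask, pngf)
  expect_identical(read_roi_mask(pngf), mask == 1)

  utils::write.table(matrix(c(0, 2), 1), file.path(tmp, "bad.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_roi_mask(file.path(tmp, "bad.csv")), "0/1")
})

test_that("tabular spectra and targets round-trip with stable ids", {
  d <- gen_spectra(planted_band_spec(n_samples = 40, n_bands = 30, seed = 3))
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "spectra.csv")
  write_spectra_csv(d$spectra, f)
  rb <- read_spectra_csv(f)
  expect_equal(rb$values, d$spectra$values, tolerance = 1e-12)
  expect_equal(rb$wavelengths, d$spectra$wavelengths, tolerance = 1e-12)
  expect_identical(rb$sample_ids, d$spectra$sample_ids)

  ft <- file.path(tmp, "y.csv")
  write_targets_csv(d$target, ft, name = "spad")
  expect_equal(read_targets_csv(ft, "spad"), d$target, tolerance = 1e-12)

  # blank cell is reported with its location
  txt <- readLines(f)
  txt[3] <- sub("^([^,]*,[^,]*),[^,]*", "\\1,", txt[3])
  writeLines(txt, f)
  expect_error(read_spectra_csv(f), "row 2")
})
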