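#' Vegetation index definitions
#'
#' The eight supported indices with their default band-role wavelengths
#' (nm). `role_a`/`role_b` are the two roles the band-pair optimizer
#' varies: the near-infrared band and the second band (red edge, red or
#' green depending on the index). EVI additionally uses a fixed blue band
#' at 450 nm and, as published, a slightly different NIR wavelength in
#' its denominator (871 vs 873 nm); set `unify_nir = TRUE` in
#' [compute_vi()] to collapse the two.
#'
#' Note that the NDVI variant used here takes its "red" band at 720 nm, a
#' red-edge wavelength rather than a classical red band — implemented as
#' published for this instrument configuration.
#'
#' @return A tibble with columns `index`, `role_a`, `nm_a`, `role_b`,
#'   `nm_b`, `nm_nir2`, `nm_blue`.
#' @export
vi_definitions <- function() {
  tibble::tibble(
    index  = c("CIgreen", "CIrededge", "EVI", "MSRREG",
               "NDRE", "NDVI", "OSAVIREG", "RDVIREG"),
    role_a = "NIR",
    nm_a   = c(871, 871, 871, 871, 871, 871, 873, 873),
    role_b = c("G", "REG", "R", "REG", "REG", "R", "REG", "REG"),
    nm_b   = c(558, 718, 726, 718, 720, 720, 726, 727),
    nm_nir2 = c(NA, NA, 873, NA, NA, NA, NA, NA),
    nm_blue = c(NA, NA, 450, NA, NA, NA, NA, NA)
  )
}

#' Spectral search regions for band-pair optimization
#'
#' Default regions: red edge 680-750 nm, near-infrared 700-1,000 nm,
#' green 540-560 nm.
#'
#' @param red_edge,nir,green Numeric `c(lower, upper)` pairs in nm.
#' @return A named list of regions.
#' @export
region_spec <- function(red_edge = c(680, 750), nir = c(700, 1000),
                        green = c(540, 560)) {
  for (r in list(red_edge, nir, green)) {
    if (length(r) != 2 || r[1] >= r[2]) {
      stop("each region must be c(lower, upper) with lower < upper",
           call. = FALSE)
    }
  }
  list(red_edge = red_edge, nir = nir, green = green)
}

#' Reflectance at (or nearest to) a wavelength
#'
#' Returns the column of the band whose center is nearest the requested
#' wavelength; ties resolve to the lower wavelength.
#'
#' @param spectra A [spectra_mat()].
#' @param wavelength_nm Requested wavelength, within the grid range.
#' @return Numeric column vector (one value per sample).
#' @export
reflectance_at <- function(spectra, wavelength_nm) {
  spectra <- as_spectra_mat(spectra)
  spectra$values[, nearest_band(spectra$wavelengths, wavelength_nm)]
}

nearest_band <- function(wl, target) {
  if (target < min(wl) || target > max(wl)) {
    stop("wavelength ", target, " nm outside grid range [",
         min(wl), ", ", max(wl), "]", call. = FALSE)
  }
  d <- abs(wl - target)
  # ties -> lower wavelength (grid is increasing); tolerance absorbs
  # floating-point noise in the distances
  which(d <= min(d) + 1e-9)[1]
}

# Elementwise index formulas. nir2/blue only used by EVI.
vi_formula <- function(index, nir, b2, nir2 = NULL, blue = NULL,
                       sqrt_dialect = TRUE) {
  switch(index,
    CIgreen   = nir / b2 - 1,
    CIrededge = nir / b2 - 1,
    EVI       = 2.5 * (nir - b2) / (nir2 + 6 * b2 - 7.5 * blue + 1),
    MSRREG    = if (sqrt_dialect) {
      (nir / b2 - 1) / (sqrt(nir / b2) + 1)
    } else {
      (nir / b2 - 1) / (nir / b2 + 1)
    },
    NDRE      = (nir - b2) / (nir + b2),
    NDVI      = (nir - b2) / (nir + b2),
    OSAVIREG  = (1 + 0.16) * (nir - b2) / (nir + b2 + 0.16),
    RDVIREG   = if (sqrt_dialect) {
      (nir - b2) / sqrt(nir + b2)
    } else {
      (nir - b2) / (nir + b2)
    },
    stop("unknown vegetation index: ", index, call. = FALSE)
  )
}

#' Compute a vegetation index for every sample
#'
#' Evaluates the index formula elementwise at the definition's (or
#' user-supplied) band wavelengths, resolved to the nearest grid bands.
#' Samples with a zero denominator yield `NaN` and are reported by id in
#' a warning rather than silently.
#'
#' @param spectra A [spectra_mat()] of reflectance (not derivative)
#'   spectra.
#' @param index Index name; see [vi_definitions()].
#' @param nm_a,nm_b Optional overrides for the NIR and second-role
#'   wavelengths (nm).
#' @param sqrt_dialect Use the standard square-root forms of MSRREG and
#'   RDVIREG (default). `FALSE` reproduces the flattened radical-free
#'   reading, under which MSRREG collapses to NDRE's algebraic form.
#' @param unify_nir Use a single NIR band for both EVI NIR terms?
#' @return A tibble with columns `sample_id`, `index`, `value`.
#' @export
compute_vi <- function(spectra, index, nm_a = NULL, nm_b = NULL,
                       sqrt_dialect = TRUE, unify_nir = FALSE) {
  spectra <- as_spectra_mat(spectra)
  def <- vi_definitions()
  def <- def[def$index == index, ]
  if (nrow(def) == 0) stop("unknown vegetation index: ", index, call. = FALSE)
  nm_a <- nm_a %||% def$nm_a
  nm_b <- nm_b %||% def$nm_b
  nir <- reflectance_at(spectra, nm_a)
  b2 <- reflectance_at(spectra, nm_b)
  nir2 <- blue <- NULL
  if (index == "EVI") {
    nir2 <- if (unify_nir) nir else reflectance_at(spectra, def$nm_nir2)
    blue <- reflectance_at(spectra, def$nm_blue)
  }
  val <- vi_formula(index, nir, b2, nir2, blue, sqrt_dialect = sqrt_dialect)
  bad <- !is.finite(val)
  if (any(bad)) {
    warning(index, " undefined (zero denominator) for sample(s): ",
            paste(spectra$sample_ids[bad], collapse = ", "), call. = FALSE)
    val[bad] <- NaN
  }
  tibble::tibble(sample_id = spectra$sample_ids, index = index,
                 value = unname(val))
}

#' Compute all eight vegetation indices as a wide table
#'
#' @param spectra A [spectra_mat()].
#' @param bands Optional named list `list(index = c(nm_a, nm_b))` of
#'   optimized band pairs (e.g. from [optimize_band_pair()]).
#' @param sqrt_dialect Passed to [compute_vi()].
#' @return A wide tibble: `sample_id` plus one column per index.
#' @export
compute_vi_table <- function(spectra, bands = NULL, sqrt_dialect = TRUE) {
  spectra <- as_spectra_mat(spectra)
  out <- tibble::tibble(sample_id = spectra$sample_ids)
  for (idx in vi_definitions()$index) {
    pair <- bands[[idx]]
    out[[idx]] <- compute_vi(spectra, idx,
                             nm_a = pair[1], nm_b = pair[2],
                             sqrt_dialect = sqrt_dialect)$value
  }
  out
}

#' Optimize a vegetation index band pair against a target
#'
#' Exhaustively evaluates every pair of instrument bands within the
#' index's two role regions (NIR region for the NIR role; red-edge or
#' green region for the second role) and returns the pair maximizing the
#' absolute Pearson correlation between the computed index and the
#' target. The signed correlation is reported. Ties resolve to the lowest
#' NIR wavelength, then the lowest second wavelength; pairs whose index
#' is constant (undefined correlation) are skipped.
#'
#' @param spectra A [spectra_mat()].
#' @param target Numeric target vector (e.g. SPAD), one value per sample,
#'   with positive variance.
#' @param index Index name.
#' @param regions A [region_spec()].
#' @param sqrt_dialect Passed to the index formula.
#' @return A one-row tibble: `index`, `nm_a`, `nm_b`, `correlation`,
#'   `abs_correlation`, `n_pairs_evaluated`.
#' @export
optimize_band_pair <- function(spectra, target, index,
                               regions = region_spec(),
                               sqrt_dialect = TRUE) {
  spectra <- as_spectra_mat(spectra)
  target <- as.numeric(target)
  if (stats::sd(target) == 0) stop("target has zero variance", call. = FALSE)
  def <- vi_definitions()
  def <- def[def$index == index, ]
  if (nrow(def) == 0) stop("unknown vegetation index: ", index, call. = FALSE)
  wl <- spectra$wavelengths
  region_b <- switch(def$role_b, G = regions$green, regions$red_edge)
  ia <- which(wl >= regions$nir[1] & wl <= regions$nir[2])
  ib <- which(wl >= region_b[1] & wl <= region_b[2])
  if (!length(ia) || !length(ib)) {
    stop("a search region contains no instrument bands", call. = FALSE)
  }
  blue <- if (index == "EVI") reflectance_at(spectra, def$nm_blue) else NULL
  best <- NULL
  n_eval <- 0L
  for (a in ia) {
    nir <- spectra$values[, a]
    for (b in ib) {
      v <- vi_formula(index, nir, spectra$values[, b],
                      nir2 = nir, blue = blue, sqrt_dialect = sqrt_dialect)
      if (!all(is.finite(v)) || stats::sd(v) == 0) next
      r <- stats::cor(v, target)
      n_eval <- n_eval + 1L
      if (is.null(best) || abs(r) > best$abs_r + 1e-15) {
        best <- list(nm_a = wl[a], nm_b = wl[b], r = r, abs_r = abs(r))
      }
    }
  }
  if (is.null(best)) {
    stop("all candidate pairs were degenerate for ", index, call. = FALSE)
  }
  tibble::tibble(index = index, nm_a = best$nm_a, nm_b = best$nm_b,
                 correlation = best$r, abs_correlation = best$abs_r,
                 n_pairs_evaluated = n_eval)
}
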