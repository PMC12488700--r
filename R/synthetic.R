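#' Specification for planted-signal synthetic spectra
#'
#' Describes a synthetic dataset of leaf-like reflectance spectra in which
#' the regression target depends, by construction, on a known set of
#' "planted" informative bands. Used as ground truth for every
#' wavelength-selection test in the package.
#'
#' @param informative_band_indices Integer indices (1-based) of the bands
#'   the target depends on; unique and within `[1, n_bands]`. Defaults to
#'   five positions in the green, red-edge and NIR regions scaled to the
#'   grid.
#' @param coefficients Numeric coefficients, one per informative band.
#' @param noise_sd Standard deviation of the additive Gaussian target
#'   noise; must be >= 0.
#' @param n_samples Number of spectra to generate.
#' @param n_bands Number of bands; the wavelength grid is linearly spaced
#'   380-1,022 nm (the instrument convention the toolkit emulates).
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @return A `planted_band_spec` list.
#' @export
planted_band_spec <- function(informative_band_indices = NULL,
                              coefficients = c(30, -45, 40, 25, -30),
                              noise_sd = 0.3,
                              n_samples = 200L,
                              n_bands = 300L,
                              seed = 1L) {
  if (is.null(informative_band_indices)) {
    # green, red-edge shoulder/center and NIR positions, scaled to the grid
    # (indices 85/150/160/210/255 on the 300-band instrument layout)
    informative_band_indices <- unique(pmax(1L, as.integer(
      round(n_bands * c(85, 150, 160, 210, 255) / 300))))
    coefficients <- coefficients[seq_along(informative_band_indices)]
  }
  informative_band_indices <- as.integer(informative_band_indices)
  if (length(informative_band_indices) == 0) {
    stop("informative band set must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(informative_band_indices) ||
      any(informative_band_indices < 1L | informative_band_indices > n_bands)) {
    stop("informative band indices must be unique and within [1, n_bands]",
         call. = FALSE)
  }
  if (length(coefficients) != length(informative_band_indices)) {
    stop("coefficients must match informative band count", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(informative_band_indices = informative_band_indices,
         coefficients = as.numeric(coefficients),
         noise_sd = noise_sd,
         n_samples = as.integer(n_samples),
         n_bands = as.integer(n_bands),
         seed = as.integer(seed)),
    class = "planted_band_spec"
  )
}

# Parametric leaf-like base reflectance: low visible plateau with a green
# bump, logistic red-edge rise near 700 nm, NIR plateau.
leaf_base_curve <- function(wl, vis = 0.08, nir = 0.5, edge_center = 700,
                            edge_width = 14, green_bump = 0.04) {
  vis +
    (nir - vis) / (1 + exp(-(wl - edge_center) / edge_width)) +
    green_bump * exp(-(wl - 550)^2 / (2 * 15^2))
}

#' Generate planted-signal synthetic spectra
#'
#' Each spectrum is a parametric leaf-like base curve (visible plateau,
#' sigmoidal red-edge rise, NIR plateau) perturbed per sample by a random
#' amplitude factor, a red-edge shift, plateau-level jitter, a smooth
#' low-order random deviation, and iid measurement noise; reflectance is
#' clipped to `[0, 1.2]`. The target is a linear combination of the
#' planted bands plus Gaussian noise, so selection methods can be scored
#' against known truth.
#'
#' @param spec A [planted_band_spec()].
#' @return A list with elements `spectra` (a [spectra_mat()]) and
#'   `target` (named numeric vector).
#' @examples
#' d <- gen_spectra(planted_band_spec(n_samples = 20, seed = 7))
#' dim(as.matrix(d$spectra))
#' @export
gen_spectra <- function(spec) {
  stopifnot(inherits(spec, "planted_band_spec"))
  n <- spec$n_samples
  p <- spec$n_bands
  wl <- seq(380, 1022, length.out = p)
  with_seed(spec$seed, {
    amp <- stats::rnorm(n, 1, 0.02)
    shift <- stats::rnorm(n, 0, 2)
    nir <- stats::rnorm(n, 0.5, 0.01)
    vis <- stats::rnorm(n, 0.08, 0.003)
    n_harm <- 6L
    a <- matrix(stats::rnorm(n * n_harm, 0, 0.005), n, n_harm)
    ph <- matrix(stats::runif(n * n_harm, 0, 2 * pi), n, n_harm)
    u <- (wl - 380) / (1022 - 380)
    X <- matrix(0, n, p)
    for (i in seq_len(n)) {
      base <- leaf_base_curve(wl, vis = vis[i], nir = nir[i],
                              edge_center = 700 + shift[i])
      dev <- colSums(a[i, ] * sin(outer(2 * pi * seq_len(n_harm), u) + ph[i, ]))
      X[i, ] <- amp[i] * (base + dev)
    }
    X <- X + matrix(stats::rnorm(n * p, 0, 0.03), n, p)
    X <- pmin(pmax(X, 0), 1.2)
    y <- as.vector(X[, spec$informative_band_indices, drop = FALSE] %*%
                     spec$coefficients)
    if (spec$noise_sd > 0) y <- y + stats::rnorm(n, 0, spec$noise_sd)
    sm <- spectra_mat(X, wl)
    list(spectra = sm, target = stats::setNames(y, sm$sample_ids))
  })
}

#' Generate a textured synthetic plant cube with ROI mask
#'
#' Produces an elliptical plant blob on a dark flat background. Within the
#' mask, reflectance follows the leaf-like base curve modulated by a
#' vein-like ridge pattern (linear in strength) plus a bounded
#' fine-grained term growing quadratically with strength; both vanish
#' when `texture_contrast = 0`, so the masked region is then spatially
#' constant at every band. Reflectance is clipped to `[0, 1.2]`.
#'
#' @param seed Integer seed.
#' @param shape Spatial shape `c(lines, samples)`.
#' @param texture_contrast Non-negative strength of the vein/noise
#'   modulation; larger values give visibly sharper texture.
#' @param n_bands Number of bands on the 380-1,022 nm grid.
#' @return A list with elements `cube` (a [spectral_cube()]) and `mask`
#'   (logical matrix).
#' @export
gen_cube <- function(seed, shape = c(48L, 48L), texture_contrast = 1,
                     n_bands = 300L) {
  if (texture_contrast < 0) stop("texture_contrast must be >= 0", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L)) {
    stop("degenerate cube shape; need at least 8x8 pixels", call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  wl <- seq(380, 1022, length.out = n_bands)
  base <- leaf_base_curve(wl)
  with_seed(seed, {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- ((rr - (nr + 1) / 2) / (0.38 * nr))^2 +
            ((cc - (nc + 1) / 2) / (0.42 * nc))^2 <= 1

    # vein-like ridges: a midrib plus lateral sinusoidal veins
    n_veins <- 5L
    centers <- stats::runif(n_veins, 0.2, 0.8) * nc
    amps <- stats::runif(n_veins, 0.05, 0.15) * nc
    phases <- stats::runif(n_veins, 0, 2 * pi)
    V <- matrix(0, nr, nc)
    for (k in seq_len(n_veins)) {
      ck <- centers[k] + amps[k] * sin(2 * pi * rr / nr + phases[k])
      V <- pmax(V, exp(-(cc - ck)^2 / (2 * 2.5^2)))
    }
    V <- pmax(V, exp(-(rr - (nr + 1) / 2)^2 / (2 * 1.2^2)))  # midrib

    # vein ridges scale linearly with contrast (shape-invariant under the
    # GLCM's min-max quantization) while the bounded fine-grain term grows
    # quadratically, so stronger contrast yields a strictly noisier, sharper
    # texture mixture
    grain <- matrix(stats::rnorm(nr * nc), nr, nc)
    modulation <- 1 - 0.22 * texture_contrast * V +
      0.05 * texture_contrast^2 * tanh(grain)
    modulation[!mask] <- NA_real_

    data <- array(0.05, dim = c(nr, nc, n_bands))
    for (b in seq_len(n_bands)) {
      slab <- matrix(0.05, nr, nc)
      slab[mask] <- base[b] * modulation[mask]
      data[, , b] <- slab
    }
    data <- pmin(pmax(data, 0), 1.2)
    list(cube = spectral_cube(data, wl), mask = mask)
  })
}

#' Generate a fused spectral + texture dataset with known ground truth
#'
#' Simulates one textured plant cube per sample at a per-sample texture
#' strength, extracts the ROI mean spectrum and the PCA-guided GLCM
#' texture features, and builds a target that depends on both the
#' spectral shape and (nonlinearly) on the texture strength. A per-sample
#' global amplitude jitter deliberately confounds the overall reflectance
#' level, so the texture contribution to the target is recoverable from
#' the texture features but only weakly from the spectra — the ground
#' truth for fusion-benefit tests.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param n_bands Bands per cube (default 40, for speed).
#' @param shape Spatial cube shape (default `c(24, 24)`).
#' @param noise_sd Target noise standard deviation.
#' @return A list: `spectra` (a [spectra_mat()] of ROI mean spectra),
#'   `texture` (tibble of per-sample texture features with `sample_id`),
#'   `target` (named vector), `contrast` (the per-sample texture
#'   strengths).
#' @export
gen_fusion_dataset <- function(n_samples = 150L, seed = 1L, n_bands = 40L,
                               shape = c(24L, 24L), noise_sd = 0.2) {
  with_seed(seed, {
    tc <- stats::runif(n_samples, 0.5, 2.5)
    amp <- stats::rnorm(n_samples, 1, 0.15)
    sub_seeds <- sample.int(1e6, n_samples)
    eps <- stats::rnorm(n_samples, 0, noise_sd)
    wl <- seq(380, 1022, length.out = n_bands)
    b1 <- which.min(abs(wl - 760))
    b2 <- which.min(abs(wl - 560))
    X <- matrix(0, n_samples, n_bands)
    tex <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      g <- gen_cube(sub_seeds[i], shape = shape, texture_contrast = tc[i],
                    n_bands = n_bands)
      cube <- g$cube
      cube$data <- pmin(pmax(cube$data * amp[i], 0), 1.2)
      X[i, ] <- extract_roi_mean_spectrum(cube, g$mask)
      tex[[i]] <- texture_vector(texture_pipeline(cube, g$mask))
    }
    sm <- spectra_mat(X, wl)
    texture <- dplyr::bind_cols(
      tibble::tibble(sample_id = sm$sample_ids),
      tibble::as_tibble(do.call(rbind, tex))
    )
    y <- 40 * (X[, b1] - X[, b2]) + 8 * (tc - 1.5)^2 + eps
    list(spectra = sm, texture = texture,
         target = stats::setNames(y, sm$sample_ids), contrast = tc)
  })
}
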