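#' PCA-based representative band selection
#'
#' Principal component analysis (mean-centered, unscaled) of the
#' masked-pixels x bands matrix of a cube. For each of the first `n_pcs`
#' components the band with the largest absolute loading is selected as
#' that component's representative band; if a band repeats across
#' components, the next-highest-loading unused band is taken instead.
#'
#' @param cube A [spectral_cube()].
#' @param mask Logical ROI mask; must contain more pixels than `n_pcs`.
#' @param n_pcs Number of leading components (default 3).
#' @return A list: `selected_band_indices`, `selected_wavelengths`,
#'   `explained_variance_ratio` (all components),
#'   `cumulative_contribution` (sum over the first `n_pcs`),
#'   `pc_loadings` (bands x `n_pcs`).
#' @export
pca_band_select <- function(cube, mask, n_pcs = 3L) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  keep <- as.vector(as.matrix(mask) != 0)
  if (!any(keep)) stop("empty ROI mask", call. = FALSE)
  px <- matrix(cube$data, d[1] * d[2], d[3])[keep, , drop = FALSE]
  if (nrow(px) <= n_pcs) stop("need more masked pixels than components",
                              call. = FALSE)
  if (d[3] < n_pcs) stop("need at least n_pcs bands", call. = FALSE)
  if (all(apply(px, 2, stats::sd) == 0)) {
    stop("cube is spatially constant within the mask; PCA undefined",
         call. = FALSE)
  }
  pc <- stats::prcomp(px, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  sel <- integer(n_pcs)
  for (k in seq_len(n_pcs)) {
    ord <- order(abs(loadings[, k]), decreasing = TRUE)
    sel[k] <- ord[which(!ord %in% sel[seq_len(k - 1)])[1]]
  }
  list(selected_band_indices = sel,
       selected_wavelengths = cube$wavelengths[sel],
       explained_variance_ratio = evr,
       cumulative_contribution = sum(evr[seq_len(n_pcs)]),
       pc_loadings = loadings)
}

# Default co-occurrence offsets: distance 1 at 0, 45, 90 and 135 degrees,
# expressed as (row, column) displacements.
glcm_default_offsets <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Masked gray-level co-occurrence matrix
#'
#' The image is linearly quantized to `levels` gray levels over the
#' masked min-max intensity range (so the features are invariant to
#' adding a constant or rescaling the image). Pixel pairs are counted
#' only when both ends lie inside the mask; the matrix is symmetrized,
#' averaged over the offsets, and normalized to sum 1.
#'
#' @param image 2-D numeric matrix.
#' @param mask Logical matrix, same shape; defaults to the full image.
#' @param levels Number of gray levels (>= 2, default 64).
#' @param offsets List of `c(d_row, d_col)` displacements; defaults to
#'   distance 1 at the four standard orientations.
#' @return A `levels x levels` matrix summing to 1. Attribute
#'   `"gray_range"` records the quantization range.
#' @export
compute_glcm <- function(image, mask = NULL, levels = 64L,
                         offsets = glcm_default_offsets()) {
  image <- as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- as.matrix(mask) != 0
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (!length(offsets)) stop("offsets must be non-empty", call. = FALSE)
  vals <- image[mask]
  rng <- range(vals)
  q <- matrix(0L, nrow(image), ncol(image))
  if (rng[2] > rng[1]) {
    q[mask] <- pmin(as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) *
                                       levels)), levels - 1L)
  }
  nr <- nrow(image); nc <- ncol(image)
  counts <- matrix(0, levels, levels)
  total_pairs <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    m1 <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(m1)) next
    g1 <- q[r1, c1, drop = FALSE][m1]
    g2 <- q[r1 + dr, c1 + dc, drop = FALSE][m1]
    idx <- g1 * levels + g2 + 1L
    tab <- tabulate(idx, nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
    total_pairs <- total_pairs + length(g1)
  }
  if (total_pairs < 2) stop("fewer than 2 valid pixel pairs", call. = FALSE)
  counts <- counts + t(counts)          # symmetrize
  glcm <- counts / sum(counts)
  attr(glcm, "gray_range") <- rng
  glcm
}

#' GLCM texture features
#'
#' `MEA = sum_ij i * P(i,j)`, `CON = sum_ij (i-j)^2 * P(i,j)`,
#' `DIS = sum_ij |i-j| * P(i,j)`, `ENT = -sum_{P>0} P * log(P)`,
#' with gray levels indexed from 0. Entropy uses the natural logarithm by
#' default.
#'
#' @param glcm Normalized co-occurrence matrix (entries sum to 1).
#' @param log_base Base for the entropy logarithm (default `exp(1)`).
#' @return A one-row tibble with columns `mea`, `con`, `dis`, `ent`.
#' @export
glcm_features <- function(glcm, log_base = exp(1)) {
  glcm <- as.matrix(glcm)
  if (abs(sum(glcm) - 1) > 1e-6) {
    stop("GLCM is not normalized (sum deviates from 1)", call. = FALSE)
  }
  L <- nrow(glcm)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  pos <- glcm > 0
  tibble::tibble(
    mea = sum(i * glcm),
    con = sum((i - j)^2 * glcm),
    dis = sum(abs(i - j) * glcm),
    ent = -sum(glcm[pos] * log(glcm[pos], base = log_base))
  )
}

#' PCA-guided texture feature extraction for one cube
#'
#' Selects `n_pcs` representative bands by [pca_band_select()], computes
#' the masked GLCM of each band image and its four texture features,
#' returning `4 * n_pcs` features per cube (12 at the default of three
#' components).
#'
#' @param cube A [spectral_cube()].
#' @param mask Logical ROI mask.
#' @param n_pcs Number of representative bands (default 3).
#' @param levels,offsets GLCM settings; see [compute_glcm()].
#' @return A tibble with one row per component: `pc`, `band_index`,
#'   `wavelength_nm`, `mea`, `con`, `dis`, `ent`.
#' @export
texture_pipeline <- function(cube, mask, n_pcs = 3L, levels = 64L,
                             offsets = glcm_default_offsets()) {
  sel <- tryCatch(
    pca_band_select(cube, mask, n_pcs = n_pcs),
    error = function(e) {
      if (!grepl("spatially constant", conditionMessage(e))) stop(e)
      # a spatially constant ROI has no principal spatial structure;
      # fall back to evenly spaced representative bands
      warning("cube is spatially constant within the mask; ",
              "using evenly spaced representative bands", call. = FALSE)
      idx <- unique(round(seq(1, dim(cube$data)[3], length.out = n_pcs)))
      list(selected_band_indices = rep_len(idx, n_pcs))
    })
  purrr::map_dfr(seq_len(n_pcs), function(k) {
    b <- sel$selected_band_indices[k]
    feats <- glcm_features(compute_glcm(cube$data[, , b], mask,
                                        levels = levels, offsets = offsets))
    dplyr::bind_cols(
      tibble::tibble(pc = k, band_index = b,
                     wavelength_nm = cube$wavelengths[b]),
      feats
    )
  })
}

#' Flatten a texture table to a named feature vector
#'
#' @param tex Output of [texture_pipeline()].
#' @return Named numeric vector of length `4 * n_pcs`
#'   (`pc1_mea, pc1_con, ..., pc3_ent`).
#' @export
texture_vector <- function(tex) {
  out <- unlist(lapply(seq_len(nrow(tex)), function(k) {
    stats::setNames(as.numeric(tex[k, c("mea", "con", "dis", "ent")]),
                    paste0("pc", tex$pc[k], "_", c("mea", "con", "dis", "ent")))
  }))
  out
}
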