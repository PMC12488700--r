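#' Standard normal variate (SNV)
#'
#' Row-wise scatter correction: each spectrum is centered to mean 0 and
#' scaled to unit sample standard deviation (n-1 denominator).
#'
#' @param x A [spectra_mat()] (or coercible input; see [as_spectra_mat()]).
#' @return A [spectra_mat()] of the same shape.
#' @export
snv <- function(x) {
  x <- as_spectra_mat(x)
  v <- x$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  zero <- which(sdv == 0 | !is.finite(sdv))
  if (length(zero)) {
    stop("SNV undefined for constant spectrum of sample '",
         x$sample_ids[zero[1]], "'", call. = FALSE)
  }
  spectra_mat((v - mu) / sdv, x$wavelengths, x$sample_ids)
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares, `x ~ a + b * reference`, and corrected to `(x - a) / b`. By
#' default the reference is the column-wise mean spectrum of `x`; inside
#' model pipelines pass the reference fitted on the training partition so
#' validation/test rows reuse it.
#'
#' @param x A [spectra_mat()].
#' @param reference Optional numeric reference spectrum (length
#'   `n_bands`). The reference actually used is attached to the result as
#'   attribute `"msc_reference"`.
#' @return A corrected [spectra_mat()].
#' @export
msc <- function(x, reference = NULL) {
  x <- as_spectra_mat(x)
  v <- x$values
  if (is.null(reference)) reference <- colMeans(v)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(v)) {
    stop("MSC reference length ", length(reference),
         " does not match band count ", ncol(v), call. = FALSE)
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("MSC reference is constant", call. = FALSE)
  b <- as.vector(v %*% rc) / denom               # per-row OLS slope
  a <- rowMeans(v) - b * mean(reference)
  zero <- which(b == 0 | !is.finite(b))
  if (length(zero)) {
    stop("MSC slope is zero for sample '", x$sample_ids[zero[1]], "'",
         call. = FALSE)
  }
  out <- spectra_mat((v - a) / b, x$wavelengths, x$sample_ids)
  attr(out, "msc_reference") <- reference
  out
}

#' Savitzky-Golay smoothing
#'
#' Per-row local polynomial least-squares smoothing via
#' [signal::sgolayfilt()]. Output length equals input length; the filter's
#' edge rows perform one-sided polynomial fits, so no values are padded or
#' fabricated beyond the spectrum ends.
#'
#' @param x A [spectra_mat()].
#' @param window Odd filter length, strictly greater than `polyorder`.
#' @param polyorder Polynomial order, >= 1.
#' @return A smoothed [spectra_mat()].
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 2L) {
  x <- as_spectra_mat(x)
  check_sg(window, polyorder, n_bands(x))
  out <- t(apply(x$values, 1, signal::sgolayfilt, p = polyorder, n = window))
  spectra_mat(out, x$wavelengths, x$sample_ids)
}

check_sg <- function(window, polyorder, p) {
  if (window %% 2 == 0) stop("SG window must be odd", call. = FALSE)
  if (polyorder < 1) stop("SG polyorder must be >= 1", call. = FALSE)
  if (window <= polyorder) stop("SG window must exceed polyorder", call. = FALSE)
  if (window > p) {
    stop("SG window (", window, ") exceeds band count (", p, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' First derivative of spectra with respect to wavelength
#'
#' Default mode is the Savitzky-Golay first derivative (window 7,
#' polynomial order 2), which smooths while differentiating; a central
#' finite-difference mode is available. Units are reflectance per nm; the
#' band count is preserved in both modes.
#'
#' @param x A [spectra_mat()].
#' @param mode `"sg_derivative"` (default) or `"finite_difference"`.
#' @param window,polyorder Savitzky-Golay settings for the default mode.
#' @return A [spectra_mat()] of derivative spectra.
#' @export
first_derivative <- function(x, mode = c("sg_derivative", "finite_difference"),
                             window = 7L, polyorder = 2L) {
  x <- as_spectra_mat(x)
  mode <- match.arg(mode)
  wl <- x$wavelengths
  if (length(wl) < 3) stop("need at least 3 bands for a derivative", call. = FALSE)
  if (mode == "sg_derivative") {
    check_sg(window, polyorder, n_bands(x))
    h <- mean(diff(wl))
    out <- t(apply(x$values, 1, signal::sgolayfilt,
                   p = polyorder, n = window, m = 1, ts = h))
  } else {
    v <- x$values
    p <- ncol(v)
    out <- matrix(0, nrow(v), p)
    out[, 1] <- (v[, 2] - v[, 1]) / (wl[2] - wl[1])
    out[, p] <- (v[, p] - v[, p - 1]) / (wl[p] - wl[p - 1])
    mid <- 2:(p - 1)
    out[, mid] <- sweep(v[, mid + 1] - v[, mid - 1], 2,
                        wl[mid + 1] - wl[mid - 1], "/")
  }
  spectra_mat(out, wl, x$sample_ids)
}

#' Apply a named pretreatment
#'
#' Dispatcher over the four supported pretreatments plus `"raw"`
#' (identity), used by the preprocessing bake-off and the pipeline.
#'
#' @param x A [spectra_mat()].
#' @param method One of `"raw"`, `"snv"`, `"msc"`, `"sg"`, `"fd"`.
#' @param msc_reference Optional frozen MSC reference (training mean).
#' @param sg_window,sg_polyorder Savitzky-Golay settings for `"sg"`.
#' @param fd_mode Derivative mode for `"fd"`.
#' @return A pretreated [spectra_mat()].
#' @export
preprocess <- function(x, method = c("raw", "snv", "msc", "sg", "fd"),
                       msc_reference = NULL, sg_window = 11L,
                       sg_polyorder = 2L, fd_mode = "sg_derivative") {
  method <- match.arg(method)
  switch(method,
    raw = as_spectra_mat(x),
    snv = snv(x),
    msc = msc(x, reference = msc_reference),
    sg  = sg_smooth(x, window = sg_window, polyorder = sg_polyorder),
    fd  = first_derivative(x, mode = fd_mode)
  )
}
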