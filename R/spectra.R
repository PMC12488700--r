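#' Construct a spectra matrix
#'
#' The workhorse container for tabular reflectance data: an
#' `n_samples x n_bands` numeric matrix with band-center wavelengths (nm)
#' and sample identifiers. All preprocessing, wavelength-selection and
#' modelling functions accept this class (or a plain matrix plus a
#' `wavelengths` argument).
#'
#' @param values Numeric matrix, samples in rows, bands in columns.
#' @param wavelengths Numeric vector of band centers in nm, strictly
#'   increasing, one per column of `values`.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `"s1", "s2", ...`.
#' @return An object of class `spectra_mat`.
#' @examples
#' sm <- spectra_mat(matrix(runif(12), 3, 4), wavelengths = c(500, 550, 600, 650))
#' n_bands(sm)
#' @export
spectra_mat <- function(values, wavelengths, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths)) {
    stop("spectra_mat: ", ncol(values), " columns but ", length(wavelengths),
         " wavelengths", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("spectra_mat: wavelengths must be strictly increasing", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("spectra_mat: values must be finite and non-missing", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("spectra_mat: sample_ids length must equal row count", call. = FALSE)
  }
  rownames(values) <- sample_ids
  colnames(values) <- format_wl(wavelengths)
  structure(
    list(values = values, wavelengths = wavelengths, sample_ids = sample_ids),
    class = "spectra_mat"
  )
}

format_wl <- function(wl) sprintf("wl_%s", format(wl, trim = TRUE, digits = 10))

#' @export
print.spectra_mat <- function(x, ...) {
  cat(sprintf("<spectra_mat: %d samples x %d bands, %.1f-%.1f nm>\n",
              nrow(x$values), ncol(x$values),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as.matrix.spectra_mat <- function(x, ...) x$values

#' Number of bands / samples in a spectra matrix
#' @param x A `spectra_mat`.
#' @return Integer count.
#' @export
n_bands <- function(x) length(x$wavelengths)

#' @rdname n_bands
#' @export
n_samples <- function(x) nrow(x$values)

#' Convert a spectra matrix to a long tibble
#'
#' @param x A `spectra_mat`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `wavelength`, `reflectance`.
#' @export
spectra_to_tibble <- function(x, ...) {
  stopifnot(inherits(x, "spectra_mat"))
  tibble::tibble(
    sample_id = rep(x$sample_ids, times = n_bands(x)),
    wavelength = rep(x$wavelengths, each = n_samples(x)),
    reflectance = as.vector(x$values)
  )
}

#' Coerce input to a spectra matrix
#'
#' Accepts a `spectra_mat` (returned unchanged), a numeric matrix plus
#' `wavelengths`, or a wide data frame with a `sample_id` column and one
#' numeric column per band whose names encode the wavelength
#' (e.g. `"wl_550"` or `"550"`).
#'
#' @param x Input object.
#' @param wavelengths Wavelengths in nm when `x` is a bare matrix.
#' @return A `spectra_mat`.
#' @export
as_spectra_mat <- function(x, wavelengths = NULL) {
  if (inherits(x, "spectra_mat")) return(x)
  if (is.matrix(x)) {
    if (is.null(wavelengths)) {
      wavelengths <- parse_wl_names(colnames(x))
    }
    return(spectra_mat(x, wavelengths))
  }
  if (is.data.frame(x)) {
    ids <- if ("sample_id" %in% names(x)) as.character(x$sample_id) else NULL
    num <- x[setdiff(names(x), "sample_id")]
    wl <- if (is.null(wavelengths)) parse_wl_names(names(num)) else wavelengths
    return(spectra_mat(as.matrix(num), wl, ids))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to spectra_mat", call. = FALSE)
}

parse_wl_names <- function(nm) {
  if (is.null(nm)) stop("no wavelengths supplied and no column names to parse",
                        call. = FALSE)
  wl <- suppressWarnings(as.numeric(sub("^wl_", "", nm)))
  if (anyNA(wl)) stop("cannot parse wavelengths from column names", call. = FALSE)
  wl
}

# Internal: run code with a temporary RNG seed, restoring global state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
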