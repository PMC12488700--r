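#' Construct a hyperspectral cube
#'
#' A 3-D relative-reflectance array in canonical
#' `(lines x samples x bands)` order with band-center wavelengths in nm.
#'
#' @param data 3-D numeric array, `lines x samples x bands`.
#' @param wavelengths Strictly increasing numeric vector, one per band.
#' @param interleave_origin Interleave of the file the cube was read from
#'   (`"bsq"`, `"bil"` or `"bip"`); informational only.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths, interleave_origin = "bsq") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("spectral_cube: data must be a 3-D array", call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths)) {
    stop("spectral_cube: ", dim(data)[3], " bands but ",
         length(wavelengths), " wavelengths", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("spectral_cube: wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("spectral_cube: reflectance values must be finite", call. = FALSE)
  }
  interleave_origin <- match.arg(tolower(interleave_origin), c("bsq", "bil", "bip"))
  structure(
    list(data = data, wavelengths = wavelengths,
         interleave_origin = interleave_origin),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube: %d lines x %d samples x %d bands, %.1f-%.1f nm (%s)>\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$interleave_origin))
  invisible(x)
}

# ENVI 'data type' codes supported for reading/writing raw cubes.
.envi_dtypes <- list(
  `4` = list(what = "numeric", size = 4L),
  `5` = list(what = "numeric", size = 8L)
)

#' Read an ENVI-style hyperspectral cube
#'
#' Parses a plain-text ENVI header (`.hdr`) and its companion raw binary
#' cube, returning the data in canonical `(lines x samples x bands)` order
#' regardless of the stored interleave. Required header keys: `samples`,
#' `lines`, `bands`, `data type` (4 = 32-bit float, 5 = 64-bit float),
#' `interleave` (`bsq`, `bil` or `bip`) and a `wavelength = { ... }` list;
#' `byte order` defaults to little-endian.
#'
#' @param header_path Path to the `.hdr` file. The binary is looked up by
#'   stripping the `.hdr` extension (with or without a residual `.dat`).
#' @return A [spectral_cube()].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) {
    stop("header not found: ", header_path, call. = FALSE)
  }
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(hdr))
  if (length(missing)) {
    stop("ENVI header missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ns <- as.integer(hdr[["samples"]])
  nl <- as.integer(hdr[["lines"]])
  nb <- as.integer(hdr[["bands"]])
  interleave <- tolower(hdr[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }
  dt <- .envi_dtypes[[hdr[["data type"]]]]
  if (is.null(dt)) {
    stop("unsupported ENVI data type: ", hdr[["data type"]],
         " (supported: 4, 5)", call. = FALSE)
  }
  if (is.null(hdr[["wavelength"]])) {
    stop("ENVI header has no wavelength list", call. = FALSE)
  }
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != nb) {
    stop("header declares ", nb, " bands but wavelength list has ",
         length(wl), " entries", call. = FALSE)
  }
  endian <- if (identical(hdr[["byte order"]], "1")) "big" else "little"

  bin_path <- envi_binary_path(header_path)
  n_values <- as.double(ns) * nl * nb
  expected_bytes <- n_values * dt$size
  actual_bytes <- file.info(bin_path)$size
  if (!isTRUE(actual_bytes == expected_bytes)) {
    stop("binary size mismatch: header implies ", expected_bytes,
         " bytes but ", bin_path, " has ", actual_bytes, call. = FALSE)
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = dt$what, n = n_values, size = dt$size,
                      endian = endian)
  data <- switch(interleave,
    # BSQ: sample fastest, then line, then band
    bsq = aperm(array(raw_vals, dim = c(ns, nl, nb)), c(2, 1, 3)),
    # BIL: sample fastest, then band, then line
    bil = aperm(array(raw_vals, dim = c(ns, nb, nl)), c(3, 1, 2)),
    # BIP: band fastest, then sample, then line
    bip = aperm(array(raw_vals, dim = c(nb, ns, nl)), c(3, 2, 1))
  )
  spectral_cube(data, wl, interleave_origin = interleave)
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (cand in c(base, paste0(base, ".dat"), paste0(base, ".raw"))) {
    if (file.exists(cand) && cand != header_path) return(cand)
  }
  stop("companion binary for ", header_path, " not found", call. = FALSE)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # collapse brace-delimited lists onto single logical entries
  out <- list()
  # key = { multi, line, list }
  brace_pat <- "([A-Za-z ][A-Za-z0-9 _]*?)\\s*=\\s*\\{([^}]*)\\}"
  m <- gregexpr(brace_pat, txt)
  for (hit in regmatches(txt, m)[[1]]) {
    key <- tolower(trimws(sub(brace_pat, "\\1", hit)))
    val <- gsub("\\s+", " ", trimws(sub(brace_pat, "\\2", hit)))
    out[[key]] <- val
  }
  txt_flat <- gsub(brace_pat, "", txt)
  for (line in strsplit(txt_flat, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- tolower(trimws(kv[1]))
    val <- trimws(paste(kv[-1], collapse = "="))
    if (nzchar(key) && nzchar(val)) out[[key]] <- val
  }
  out
}

#' Write a hyperspectral cube as ENVI header + raw binary
#'
#' @param cube A [spectral_cube()].
#' @param path_base Path without extension; writes `<path_base>.hdr` and
#'   `<path_base>.dat`.
#' @param interleave Storage interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data-type code: 5 (64-bit float, default, lossless
#'   round trip) or 4 (32-bit float).
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, path_base, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  dt <- .envi_dtypes[[as.character(data_type)]]
  if (is.null(dt)) stop("unsupported data type: ", data_type, call. = FALSE)
  d <- dim(cube$data)
  nl <- d[1]; ns <- d[2]; nb <- d[3]
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1)))
  )
  bin_path <- paste0(path_base, ".dat")
  con <- file(bin_path, "wb")
  writeBin(vals, con, size = dt$size, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = { hsiphen reflectance cube }",
    paste0("samples = ", ns),
    paste0("lines = ", nl),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                 collapse = ", "), " }")
  )
  hdr_path <- paste0(path_base, ".hdr")
  writeLines(hdr, hdr_path)
  invisible(hdr_path)
}

#' Read a region-of-interest mask
#'
#' Accepts either a headerless CSV/TSV grid of 0/1 values or an 8-bit
#' grayscale PNG (pixels above half intensity are inside the ROI).
#'
#' @param path Path to a `.csv`/`.txt` 0/1 grid or a `.png` image.
#' @return A logical matrix (`lines x samples`).
#' @export
read_roi_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img > 0.5)
  }
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  if (!all(m %in% c(0, 1))) {
    stop("mask grid must contain only 0/1 values", call. = FALSE)
  }
  matrix(m == 1, nrow(m), ncol(m))
}

#' Mean ROI spectrum of a cube
#'
#' Per-band arithmetic mean of reflectance over the masked pixels — the
#' per-plant spectrum used for all downstream tabular analyses.
#'
#' @param cube A [spectral_cube()].
#' @param mask Logical matrix with the cube's spatial shape; at least one
#'   `TRUE` pixel.
#' @return Numeric vector of length `n_bands`, named by wavelength.
#' @export
extract_roi_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  mask <- as.matrix(mask)
  d <- dim(cube$data)
  if (!all(dim(mask) == d[1:2])) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match cube spatial shape ",
         paste(d[1:2], collapse = "x"), call. = FALSE)
  }
  keep <- as.vector(mask != 0)
  if (!any(keep)) stop("empty ROI mask", call. = FALSE)
  px <- matrix(cube$data, d[1] * d[2], d[3])[keep, , drop = FALSE]
  out <- colMeans(px)
  names(out) <- format_wl(cube$wavelengths)
  out
}

#' Read / write tabular spectra
#'
#' CSV layout: a `sample_id` column followed by one numeric column per
#' band, named by band-center wavelength in nm. Round trips are stable to
#' better than 1e-12 relative tolerance.
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns a [spectra_mat()].
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("spectra CSV must have a sample_id column", call. = FALSE)
  }
  num <- df[setdiff(names(df), "sample_id")]
  bad <- which(is.na(as.matrix(num)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("missing/non-numeric cell at row ", bad[1, 1], ", column '",
         names(num)[bad[1, 2]], "'", call. = FALSE)
  }
  spectra_mat(as.matrix(num), parse_wl_names(names(num)),
              as.character(df$sample_id))
}

#' @rdname read_spectra_csv
#' @param x A [spectra_mat()] to write.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_mat"))
  df <- tibble::as_tibble(x$values, .name_repair = "minimal")
  names(df) <- format(x$wavelengths, trim = TRUE, digits = 15)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-sample target tables
#'
#' CSV with a `sample_id` column and one or more numeric target columns
#' (e.g. `spad`, `biomass_g`).
#'
#' @param path File path.
#' @param column Target column to extract; defaults to the first numeric
#'   column.
#' @return Named numeric vector of targets.
#' @export
read_targets_csv <- function(path, column = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("target CSV must have a sample_id column", call. = FALSE)
  }
  cols <- setdiff(names(df), "sample_id")
  if (is.null(column)) column <- cols[1]
  if (!column %in% cols) stop("no target column '", column, "'", call. = FALSE)
  y <- df[[column]]
  if (anyNA(y)) {
    stop("missing value in target column '", column, "' at row ",
         which(is.na(y))[1], call. = FALSE)
  }
  stats::setNames(as.numeric(y), as.character(df$sample_id))
}

#' @rdname read_targets_csv
#' @param y Named numeric vector (names are sample ids).
#' @param name Column name to write the targets under.
#' @export
write_targets_csv <- function(y, path, name = "target") {
  df <- tibble::tibble(sample_id = names(y) %||% paste0("s", seq_along(y)))
  df[[name]] <- as.numeric(y)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
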