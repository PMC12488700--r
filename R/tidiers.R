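#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a selection result
#'
#' One row per selected band with its wavelength.
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `band_index`, `wavelength_nm`.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method_name,
                 band_index = x$selected_indices,
                 wavelength_nm = x$selected_wavelengths)
}

#' @rdname tidy.selection_result
#' @return `glance()` returns a one-row tibble: `method`, `n_selected`,
#'   `best_rmsecv`, `best_run`, `n_components`, `r2_fit`, `seed`.
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method_name,
                 n_selected = length(x$selected_indices),
                 best_rmsecv = x$best_rmsecv,
                 best_run = x$best_run,
                 n_components = x$n_components,
                 r2_fit = x$r2_fit,
                 seed = x$seed)
}

#' Tidy a PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return One row per predictor: `term`, `estimate` (regression
#'   coefficient at the fitted component count).
#' @export
tidy.pls_model <- function(x, ...) {
  co <- pls_coefficients(x)
  tibble::tibble(term = names(co) %||% paste0("x", seq_along(co)),
                 estimate = unname(co))
}

#' @rdname tidy.pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_predictors = nrow(x$coefficients))
}

#' Plot spectra as reflectance curves
#'
#' @param object A [spectra_mat()].
#' @param max_curves At most this many sample curves are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_mat <- function(object, max_curves = 30L, ...) {
  df <- spectra_to_tibble(object)
  keep <- utils::head(object$sample_ids, max_curves)
  df <- dplyr::filter(df, .data$sample_id %in% keep)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$reflectance,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' Plot a selection result
#'
#' RMSECV trace over sampling runs/iterations with the winning run
#' marked, plus a rug of the selected wavelengths.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_result <- function(object, ...) {
  tr <- tibble::tibble(run = seq_along(object$rmsecv_trace),
                       rmsecv = object$rmsecv_trace)
  ggplot2::ggplot(tr, ggplot2::aes(.data$run, .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_run, linetype = 2) +
    ggplot2::labs(title = object$method_name,
                  x = "sampling run / iteration", y = "RMSECV") +
    ggplot2::theme_minimal()
}

#' Plot selected wavelengths of one or more selection results
#'
#' @param ... One or more `selection_result` objects.
#' @return A ggplot object with one row per method.
#' @export
plot_selected_bands <- function(...) {
  res <- list(...)
  df <- purrr::map_dfr(res, tidy)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$method)) +
    ggplot2::geom_point(shape = 108, size = 4) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' R-squared per partition for each feature set / model family row.
#'
#' @param object An `eval_report` tibble (possibly several stacked rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  label = paste(.data$family, .data$feature_set_name)),
    cols = c("r2_train", "r2_val", "r2_test"),
    names_to = "partition", values_to = "r2")
  df$partition <- sub("^r2_", "", df$partition)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$r2,
                                   fill = .data$partition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
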