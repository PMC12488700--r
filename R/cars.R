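#' Exponentially decreasing retained-band count (EDF schedule)
#'
#' The number of wavelengths CARS force-retains at sampling run `i` of
#' `n_runs`, following the exponentially decreasing function
#' `round(p * a * exp(-k * i))` whose constants are fixed by the boundary
#' conditions: all `p` bands at run 1 and exactly 2 bands at the final
#' run. The result is clipped to `[2, p]`.
#'
#' @param run_index Run number `i`, in `1..n_runs`.
#' @param n_runs Total number of sampling runs (>= 2).
#' @param p_bands Number of spectral bands (>= 2).
#' @return Integer retained count.
#' @export
edf_retain_count <- function(run_index, n_runs, p_bands) {
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  if (p_bands < 2) stop("p_bands must be >= 2", call. = FALSE)
  if (any(run_index < 1 | run_index > n_runs)) {
    stop("run_index out of range", call. = FALSE)
  }
  k <- log(p_bands / 2) / (n_runs - 1)
  cnt <- round(p_bands * exp(-k * (run_index - 1)))
  as.integer(pmin(pmax(cnt, 2L), p_bands))
}

# SelectionResult constructor shared by CARS and DRSA-CARS.
new_selection_result <- function(method_name, selected_indices, wavelengths,
                                 rmsecv_trace, best_run, best_rmsecv, seed,
                                 n_components = NA_integer_, r2_fit = NA_real_,
                                 extra = list()) {
  selected_indices <- sort(unique(as.integer(selected_indices)))
  structure(
    c(list(method_name = method_name,
           selected_indices = selected_indices,
           selected_wavelengths = wavelengths[selected_indices],
           rmsecv_trace = as.numeric(rmsecv_trace),
           best_run = as.integer(best_run),
           best_rmsecv = as.numeric(best_rmsecv),
           n_components = n_components,
           r2_fit = r2_fit,
           seed = as.integer(seed)),
      extra),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result [%s]: %d bands, best RMSECV %.5g (run %d)>\n",
              x$method_name, length(x$selected_indices), x$best_rmsecv,
              x$best_run))
  invisible(x)
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Classical CARS: over `n_runs` Monte Carlo sampling runs, a PLS model is
#' fitted to a random subsample of the observations on the current working
#' set of bands; bands are ranked by the absolute value of their PLS
#' regression coefficients; an exponentially decreasing schedule
#' ([edf_retain_count()]) enforces forced removal of the lowest-weight
#' bands; and adaptive reweighted sampling (weighted draws proportional to
#' the coefficient magnitudes) forms the next run's working set. The
#' subset evaluated at each run is the post-forced-removal set, scored by
#' [rmsecv()] on the full sample set with one fixed fold assignment; the
#' subset with the minimum RMSECV wins (ties: fewer bands, then the
#' earlier run).
#'
#' @param x Preprocessed [spectra_mat()] or numeric matrix.
#' @param y Response vector.
#' @param n_runs Number of sampling runs (default 200).
#' @param max_components PLS component ceiling (default 10).
#' @param mc_ratio Fraction of samples drawn (without replacement) per
#'   run; default 0.8.
#' @param k_folds Folds for the RMSECV scoring (default 5).
#' @param seed Integer seed governing subsampling, reweighted sampling
#'   and fold assignment.
#' @return A `selection_result` with fields `selected_indices`,
#'   `selected_wavelengths`, `rmsecv_trace`, `best_run`, `best_rmsecv`,
#'   `n_selected_trace`, `candidate_union` (union of the best-decile run
#'   subsets, used by DRSA-CARS refine mode) and `subsets`.
#' @export
run_cars <- function(x, y, n_runs = 200L, max_components = 10L,
                     mc_ratio = 0.8, k_folds = 5L, seed = 1L) {
  sm <- as_spectra_mat(x)
  X <- sm$values
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 20) stop("CARS needs at least 20 samples", call. = FALSE)
  if (p < 2) stop("CARS needs at least 2 bands", call. = FALSE)
  n_mc <- max(2L, round(mc_ratio * n))

  with_seed(seed, {
    folds <- sample(rep_len(seq_len(k_folds), n))
    working <- seq_len(p)
    trace <- numeric(n_runs)
    subsets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      rows <- sample.int(n, n_mc)
      a <- min(max_components, length(working), n_mc - 1L)
      fit <- suppressWarnings(
        fit_pls(X[rows, working, drop = FALSE], y[rows], n_components = a)
      )
      w <- abs(pls_coefficients(fit))
      if (all(w == 0)) {
        warning("all-zero PLS coefficients at run ", i,
                "; falling back to uniform weights", call. = FALSE)
        w <- rep(1, length(working))
      }
      keep <- min(edf_retain_count(i, n_runs, p), length(working))
      forced <- working[order(w, decreasing = TRUE)[seq_len(keep)]]
      subsets[[i]] <- sort(forced)
      trace[i] <- rmsecv(X[, forced, drop = FALSE], y,
                         n_components_max = max_components,
                         folds = folds)$rmsecv_value
      # adaptive reweighted sampling forms the next working set
      wf <- w[match(forced, working)]
      if (all(wf == 0)) wf <- rep(1, length(forced))
      drawn <- unique(sample(forced, size = keep, replace = TRUE, prob = wf))
      if (length(drawn) < 2L) {
        drawn <- forced[order(wf, decreasing = TRUE)[seq_len(2L)]]
      }
      working <- sort(drawn)
    }
    sizes <- lengths(subsets)
    ord <- order(trace, sizes, seq_len(n_runs))
    best <- ord[1]
    sel <- subsets[[best]]
    cv <- rmsecv(X[, sel, drop = FALSE], y, n_components_max = max_components,
                 folds = folds)
    good <- which(trace <= stats::quantile(trace, 0.1))
    candidate_union <- sort(unique(c(unlist(subsets[good]), sel)))
    new_selection_result(
      "CARS", sel, sm$wavelengths, trace, best, trace[best], seed,
      n_components = cv$best_n_components,
      extra = list(n_selected_trace = sizes,
                   candidate_union = candidate_union,
                   subsets = subsets,
                   folds = folds)
    )
  })
}
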