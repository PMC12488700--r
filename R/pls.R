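#' Fit a PLS1 regression model (SIMPLS)
#'
#' Single-response partial least squares fitted with the SIMPLS
#' algorithm. Predictors are mean-centered (and optionally scaled to unit
#' standard deviation); the response is mean-centered. Regression
#' coefficients for every component count `1..n_components` are retained,
#' which makes component selection by cross-validation cheap.
#'
#' If the predictor matrix runs out of rank before `n_components`
#' directions are extracted, the model is truncated with a warning.
#'
#' @param x Numeric matrix (samples x predictors) or [spectra_mat()].
#' @param y Numeric response vector.
#' @param n_components Number of latent components, between 1 and
#'   `min(n_samples - 1, n_predictors)`.
#' @param scale Scale predictor columns to unit variance? Default `FALSE`
#'   (the classical convention for CARS-style coefficient ranking).
#' @return An object of class `pls_model` with elements
#'   `coefficients` (matrix, predictors x components), `intercepts`,
#'   `n_components`, `x_mean`, `x_scale`, `y_mean`.
#' @export
fit_pls <- function(x, y, n_components, scale = FALSE) {
  if (inherits(x, "spectra_mat")) x <- x$values
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y sizes disagree", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  a_max <- min(n - 1L, p)
  if (n_components < 1 || n_components > a_max) {
    stop("n_components must be in [1, ", a_max, "]", call. = FALSE)
  }
  x_mean <- colMeans(x)
  x_scale <- if (scale) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else {
    rep(1, p)
  }
  x0 <- sweep(sweep(x, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  y0 <- y - y_mean

  A <- as.integer(n_components)
  R <- matrix(0, p, A)   # weight vectors (X-block)
  V <- matrix(0, p, A)   # orthonormal loading basis
  q <- numeric(A)        # y loadings
  s <- crossprod(x0, y0)
  a_used <- 0L
  for (a in seq_len(A)) {
    r <- s
    t <- x0 %*% r
    tnorm <- sqrt(sum(t^2))
    if (!is.finite(tnorm) || tnorm < 1e-12) {
      warning("rank exhausted after ", a - 1L,
              " components; model truncated", call. = FALSE)
      break
    }
    t <- t / tnorm
    r <- r / tnorm
    p_a <- crossprod(x0, t)
    q[a] <- sum(y0 * t)
    v <- p_a
    if (a > 1) {
      vv <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - vv %*% crossprod(vv, p_a)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    V[, a] <- v
    a_used <- a
  }
  if (a_used == 0L) {
    # degenerate: no usable direction (e.g. constant y); all-zero coefficients
    a_used <- 1L
  }
  R <- R[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  # nested coefficient paths: B_a = R[, 1:a] %*% q[1:a], on the original scale
  coefs <- apply(R * rep(q, each = p), 1, cumsum)
  coefs <- if (a_used == 1L) matrix(coefs, p, 1L) else t(coefs)
  coefs <- coefs / x_scale
  intercepts <- y_mean - as.vector(x_mean %*% coefs)
  structure(
    list(coefficients = coefs, intercepts = intercepts,
         n_components = a_used, x_mean = x_mean, x_scale = x_scale,
         y_mean = y_mean),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d predictors, %d component(s)>\n",
              nrow(x$coefficients), x$n_components))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix or [spectra_mat()] with the training predictor
#'   layout.
#' @param n_components Component count to predict with (defaults to the
#'   fitted maximum). If `n_components` is a vector, a matrix with one
#'   column per requested count is returned.
#' @param ... Unused.
#' @return Numeric vector (or matrix) of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  if (inherits(newdata, "spectra_mat")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  a <- n_components %||% object$n_components
  a <- pmin(as.integer(a), object$n_components)
  out <- newdata %*% object$coefficients[, a, drop = FALSE]
  out <- sweep(out, 2, object$intercepts[a], "+")
  if (length(a) == 1L) as.vector(out) else out
}

#' Extract PLS regression coefficients
#'
#' @param model A `pls_model`.
#' @param n_components Component count (defaults to the fitted maximum).
#' @return Numeric coefficient vector, one entry per predictor.
#' @export
pls_coefficients <- function(model, n_components = NULL) {
  a <- min(n_components %||% model$n_components, model$n_components)
  model$coefficients[, a]
}

# Balanced k-fold assignment, seeded.
make_folds <- function(n, k, seed) {
  if (k < 2) stop("k_folds must be >= 2", call. = FALSE)
  if (k > n) stop("k_folds (", k, ") exceeds sample count (", n, ")",
                  call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated RMSE over PLS component counts
#'
#' k-fold cross-validation of PLS1 over component counts
#' `1..n_components_max`; returns the count minimizing the CV RMSE
#' (RMSECV) and that minimum. Fold assignment is seeded and reproducible;
#' a precomputed fold vector can be passed instead, which the selection
#' algorithms use so that every candidate subset is scored on identical
#' folds.
#'
#' @param x Predictor matrix or [spectra_mat()].
#' @param y Response vector.
#' @param n_components_max Largest component count to consider
#'   (default 10).
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param folds Optional integer fold vector in `1..k_folds`, overriding
#'   `seed`.
#' @return A list: `best_n_components`, `rmsecv_value`,
#'   `rmsecv_by_ncomp` (vector over component counts).
#' @export
rmsecv <- function(x, y, n_components_max = 10L, k_folds = 5L, seed = 1L,
                   folds = NULL) {
  if (inherits(x, "spectra_mat")) x <- x$values
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (is.null(folds)) folds <- make_folds(n, k_folds, seed)
  k <- max(folds)
  a_max <- min(n_components_max, ncol(x), n - ceiling(n / k) - 1L)
  a_max <- max(a_max, 1L)
  sse <- numeric(a_max)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- suppressWarnings(
      fit_pls(x[tr, , drop = FALSE], y[tr],
              n_components = min(a_max, sum(tr) - 1L, ncol(x)))
    )
    pred <- predict(fit, x[!tr, , drop = FALSE],
                    n_components = seq_len(a_max))
    pred <- matrix(pred, nrow = sum(!tr))
    sse <- sse + colSums((pred - y[!tr])^2)
  }
  rmse_a <- sqrt(sse / n)
  best <- which.min(rmse_a)   # ties resolve to the smaller component count
  list(best_n_components = as.integer(best),
       rmsecv_value = rmse_a[best],
       rmsecv_by_ncomp = rmse_a)
}

#' Regression evaluation metrics
#'
#' `r2 = 1 - SS_res/SS_tot` (not squared correlation),
#' `rmse = sqrt(mean((y - yhat)^2))`, and, when requested,
#' `rpd = sd(y_true) / rmse` with the n-1 denominator, so the identity
#' `rpd * rmse = sd(y_true)` holds by construction.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @param compute_rpd Also compute the residual prediction deviation?
#' @return A one-row tibble with columns `r2`, `rmse` and (optionally)
#'   `rpd`.
#' @export
eval_metrics <- function(y_true, y_pred, compute_rpd = FALSE) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("y_true has zero variance; r2/rpd undefined", call. = FALSE)
  }
  rmse <- sqrt(mean((y_true - y_pred)^2))
  out <- tibble::tibble(r2 = 1 - sum((y_true - y_pred)^2) / ss_tot,
                        rmse = rmse)
  if (compute_rpd) out$rpd <- stats::sd(y_true) / rmse
  out
}
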