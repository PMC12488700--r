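#' Seeded 7:2:1 train/validation/test split
#'
#' Random permutation split with partition sizes obtained by
#' largest-remainder rounding of the ratios (ties go to the earlier
#' partition), so the three sizes always sum to `n_samples`.
#'
#' @param n_samples Number of samples (>= 10).
#' @param seed Integer seed.
#' @param ratios Partition ratios, default `c(0.7, 0.2, 0.1)`.
#' @return A list of class `split_spec`: `train`, `validation`, `test`
#'   (disjoint integer index vectors), `sizes`, `seed`.
#' @export
split_721 <- function(n_samples, seed = 1L, ratios = c(0.7, 0.2, 0.1)) {
  if (n_samples < 10) stop("need at least 10 samples to split", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  raw <- n_samples * ratios
  sizes <- floor(raw)
  short <- n_samples - sum(sizes)
  if (short > 0) {
    # largest remainder; ties go to the earlier partition (rounded to
    # absorb floating-point noise in n * ratio)
    rem <- round(raw - sizes, 9)
    extra <- order(-rem, seq_along(rem))[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_seed(seed, sample.int(n_samples))
  bounds <- cumsum(sizes)
  structure(
    list(train = sort(perm[seq_len(bounds[1])]),
         validation = sort(perm[(bounds[1] + 1):bounds[2]]),
         test = sort(perm[(bounds[2] + 1):bounds[3]]),
         sizes = as.integer(sizes), seed = as.integer(seed)),
    class = "split_spec"
  )
}

#' Fuse a spectral band subset with extra features
#'
#' Column-wise concatenation of the selected-band reflectance matrix with
#' a per-sample feature table (vegetation indices or texture features),
#' aligned by sample id. Column provenance is encoded in the names
#' (`wl_*` for bands, the table's own names for extras).
#'
#' @param spectral_subset A [spectra_mat()] already restricted to the
#'   selected bands (or a plain matrix with sample-id rownames).
#' @param extra_features A data frame with a `sample_id` column and
#'   numeric feature columns, or `NULL`/zero-column for identity.
#' @return A numeric matrix, `n_samples x (n_bands + n_extra)`.
#' @export
fuse_features <- function(spectral_subset, extra_features = NULL) {
  if (inherits(spectral_subset, "spectra_mat")) {
    m <- spectral_subset$values
    ids <- spectral_subset$sample_ids
  } else {
    m <- as.matrix(spectral_subset)
    ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  }
  if (is.null(extra_features) ||
      ncol(as.data.frame(extra_features)) <= 1) {
    return(m)
  }
  ef <- as.data.frame(extra_features)
  if (!"sample_id" %in% names(ef)) {
    stop("extra_features must have a sample_id column", call. = FALSE)
  }
  pos <- match(ids, as.character(ef$sample_id))
  if (anyNA(pos)) {
    stop("sample ids of the spectral subset and extra features disagree",
         call. = FALSE)
  }
  extra <- as.matrix(ef[pos, setdiff(names(ef), "sample_id"), drop = FALSE])
  storage.mode(extra) <- "double"
  cbind(m, extra)
}

#' Model specification
#'
#' Families: `"PLSR"` (SIMPLS, components chosen by RMSECV up to
#' `n_components`), `"SVR"` (radial-kernel epsilon-SVR via
#' \pkg{e1071}), `"FNN"` (two hidden layers 64/32, ReLU, Adam, early
#' stopping), `"CNN"` (two 1-D conv blocks of 16/32 channels, kernel 5,
#' global average pooling, dense 32). Normalization statistics are always
#' fitted on the training partition only.
#'
#' @param family One of `"PLSR"`, `"SVR"`, `"FNN"`, `"CNN"`.
#' @param normalization `"zscore"` (default), `"minmax"` or `"none"`.
#' @param seed Seed for the stochastic trainers (mandatory for FNN/CNN).
#' @param n_components PLSR component ceiling.
#' @param cost,svr_epsilon SVR hyperparameters.
#' @param hidden FNN hidden layer sizes.
#' @param channels,kernel CNN convolution channels and kernel size.
#' @param dense CNN dense layer size.
#' @param epochs,learning_rate,patience,batch_size Network training
#'   settings.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("PLSR", "SVR", "FNN", "CNN"),
                       normalization = c("zscore", "minmax", "none"),
                       seed = 1L, n_components = 10L,
                       cost = 10, svr_epsilon = 0.1,
                       hidden = c(64L, 32L),
                       channels = c(16L, 32L), kernel = 5L, dense = 32L,
                       epochs = 500L, learning_rate = 1e-3,
                       patience = 30L, batch_size = 32L) {
  structure(
    list(family = match.arg(family),
         normalization = match.arg(normalization),
         seed = as.integer(seed), n_components = as.integer(n_components),
         cost = cost, svr_epsilon = svr_epsilon, hidden = as.integer(hidden),
         channels = as.integer(channels), kernel = as.integer(kernel),
         dense = as.integer(dense), epochs = as.integer(epochs),
         learning_rate = learning_rate, patience = as.integer(patience),
         batch_size = as.integer(batch_size)),
    class = "model_spec"
  )
}

fit_normalizer <- function(x, method) {
  switch(method,
    zscore = {
      mu <- colMeans(x)
      s <- apply(x, 2, stats::sd)
      s[s == 0 | !is.finite(s)] <- 1
      list(method = "zscore", center = mu, scale = s)
    },
    minmax = {
      lo <- apply(x, 2, min)
      hi <- apply(x, 2, max)
      rng <- hi - lo
      rng[rng == 0] <- 1
      list(method = "minmax", center = lo, scale = rng)
    },
    none = list(method = "none", center = 0, scale = 1)
  )
}

apply_normalizer <- function(norm, x) {
  if (norm$method == "none") return(x)
  sweep(sweep(x, 2, norm$center), 2, norm$scale, "/")
}

#' Train a regression model on a train/validation pair
#'
#' Fits the requested family with normalization statistics computed on
#' the training partition only; the validation partition drives early
#' stopping for the network families. Deterministic given the spec's
#' seed.
#'
#' @param x_train,y_train Training predictors (matrix) and targets.
#' @param x_val,y_val Validation partition (required, non-empty).
#' @param spec A [model_spec()].
#' @return A fitted object of class `hsip_model` with a `predict` method.
#' @export
train_model <- function(x_train, y_train, x_val, y_val, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (nrow(x_val) < 1) stop("validation set is empty", call. = FALSE)
  norm <- fit_normalizer(x_train, spec$normalization)
  xt <- apply_normalizer(norm, x_train)
  xv <- apply_normalizer(norm, x_val)
  y_mu <- mean(y_train); y_sd <- stats::sd(y_train)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1

  fitted <- switch(spec$family,
    PLSR = {
      a_max <- min(spec$n_components, ncol(xt), nrow(xt) - 2L)
      cv <- rmsecv(xt, y_train, n_components_max = a_max, k_folds = 5L,
                   seed = spec$seed)
      suppressWarnings(fit_pls(xt, y_train, n_components = cv$best_n_components))
    },
    SVR = e1071::svm(x = xt, y = y_train, type = "eps-regression",
                     kernel = "radial", cost = spec$cost,
                     epsilon = spec$svr_epsilon, scale = FALSE),
    FNN = net_train(xt, (y_train - y_mu) / y_sd, xv, (y_val - y_mu) / y_sd,
                    arch = list(kind = "fnn", hidden = spec$hidden),
                    epochs = spec$epochs, lr = spec$learning_rate,
                    batch_size = spec$batch_size, patience = spec$patience,
                    seed = spec$seed)$layers,
    CNN = net_train(xt, (y_train - y_mu) / y_sd, xv, (y_val - y_mu) / y_sd,
                    arch = list(kind = "cnn", channels = spec$channels,
                                kernel = spec$kernel, hidden = spec$dense),
                    epochs = spec$epochs, lr = spec$learning_rate,
                    batch_size = spec$batch_size, patience = spec$patience,
                    seed = spec$seed)$layers
  )
  structure(
    list(spec = spec, normalizer = norm, fitted = fitted,
         y_mean = y_mu, y_sd = y_sd, n_features = ncol(x_train)),
    class = "hsip_model"
  )
}

#' @export
predict.hsip_model <- function(object, newdata, ...) {
  x <- apply_normalizer(object$normalizer, as.matrix(newdata))
  switch(object$spec$family,
    PLSR = predict(object$fitted, x),
    SVR  = as.vector(stats::predict(object$fitted, x)),
    FNN  = ,
    CNN  = net_predict(object$fitted, x) * object$y_sd + object$y_mean
  )
}

#' @export
print.hsip_model <- function(x, ...) {
  cat(sprintf("<hsip_model: %s on %d features (%s-normalized)>\n",
              x$spec$family, x$n_features, x$spec$normalization))
  invisible(x)
}

#' Evaluate a fitted model across the three partitions
#'
#' Computes R-squared and RMSE on the training, validation and test
#' partitions and the residual prediction deviation on the test
#' partition, in the conventional report layout (the validation-column
#' RMSE is the hold-out validation error). A perfect test fit yields an
#' infinite RPD, reported capped at `rpd_cap` with `rpd_capped = TRUE`.
#'
#' @param model A fitted `hsip_model`.
#' @param x Full predictor matrix.
#' @param y Full target vector.
#' @param split A [split_721()] result.
#' @param feature_set_name Label for the feature set evaluated.
#' @param rpd_cap Cap for an infinite RPD (default 1e6).
#' @return A one-row tibble of class `eval_report`: `feature_set_name`,
#'   `family`, `r2_train`, `rmse_train`, `r2_val`, `rmsecv_val`,
#'   `r2_test`, `rmsep_test`, `rpd_test`, `rpd_capped`, partition sizes.
#' @export
evaluate <- function(model, x, y, split, feature_set_name = "features",
                     rpd_cap = 1e6) {
  stopifnot(inherits(split, "split_spec"))
  x <- as.matrix(x)
  part <- function(idx) {
    eval_metrics(y[idx], predict(model, x[idx, , drop = FALSE]))
  }
  tr <- part(split$train)
  va <- part(split$validation)
  te_pred <- predict(model, x[split$test, , drop = FALSE])
  te <- eval_metrics(y[split$test], te_pred, compute_rpd = TRUE)
  capped <- !is.finite(te$rpd)
  out <- tibble::tibble(
    feature_set_name = feature_set_name,
    family = model$spec$family,
    r2_train = tr$r2, rmse_train = tr$rmse,
    r2_val = va$r2, rmsecv_val = va$rmse,
    r2_test = te$r2, rmsep_test = te$rmse,
    rpd_test = if (capped) rpd_cap else te$rpd,
    rpd_capped = capped,
    n_train = length(split$train),
    n_val = length(split$validation),
    n_test = length(split$test)
  )
  class(out) <- c("eval_report", class(out))
  out
}
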