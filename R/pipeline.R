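#' Selection-comparison summary arithmetic
#'
#' The headline comparison between a baseline selector (CARS) and a
#' refined selector (DRSA-CARS): the percent reduction in selected-band
#' count, `100 * (n_baseline - n_refined) / n_baseline`, and the relative
#' R-squared improvement, `100 * (r2_refined - r2_baseline) /
#' r2_baseline`.
#'
#' @param n_baseline,n_refined Selected-band counts.
#' @param r2_baseline,r2_refined Optional R-squared of the models built
#'   on each subset.
#' @return A one-row tibble: `n_baseline`, `n_refined`,
#'   `pct_reduction`, `r2_baseline`, `r2_refined`, `r2_gain_pct`.
#' @export
selection_summary <- function(n_baseline, n_refined,
                              r2_baseline = NA_real_, r2_refined = NA_real_) {
  tibble::tibble(
    n_baseline = n_baseline, n_refined = n_refined,
    pct_reduction = 100 * (n_baseline - n_refined) / n_baseline,
    r2_baseline = r2_baseline, r2_refined = r2_refined,
    r2_gain_pct = 100 * (r2_refined - r2_baseline) / r2_baseline
  )
}

#' Published reference selection benchmark
#'
#' Selected-band counts, test RMSEP and R-squared reported by a published
#' hyperspectral growth-monitoring field study of *Lamiophlomis rotata*
#' comparing classical CARS against DRSA-CARS for SPAD and aboveground
#' biomass. Shipped so the package's summary arithmetic
#' ([selection_summary()]) can be exercised against fixed published
#' inputs; the underlying field data are not available.
#'
#' @return A tibble with columns `task`, `method`, `rmsep`, `r2`,
#'   `n_selected`.
#' @export
lrotata_benchmark <- function() {
  tibble::tibble(
    task = rep(c("SPAD", "biomass"), each = 2),
    method = rep(c("CARS", "DRSA-CARS"), 2),
    rmsep = c(6.9894, 6.2113, 0.1626, 0.1478),
    r2 = c(0.4632, 0.5761, 0.3347, 0.4502),
    n_selected = c(140L, 34L, 106L, 75L)
  )
}

#' Preprocessing bake-off
#'
#' Applies each pretreatment, splits 7:2:1 with a common seed, fits a
#' fixed-parameter PLSR (5 components by default) on the training
#' partition, and reports the three-partition metrics per method, ranked
#' by test-set R-squared. The MSC reference is fitted on the training
#' partition and reused for validation/test.
#'
#' @param x A [spectra_mat()] of raw spectra.
#' @param y Target vector.
#' @param methods Character vector of pretreatments (>= 1 entries), from
#'   `"raw"`, `"snv"`, `"msc"`, `"sg"`, `"fd"`.
#' @param n_components Fixed PLSR component count (default 5).
#' @param seed Split seed.
#' @return A tibble with one row per method: `method`, `rank`,
#'   `r2_train`, `rmse_train`, `r2_val`, `rmsecv_val`, `r2_test`,
#'   `rmsep_test`, `rpd_test`.
#' @export
compare_preprocessing <- function(x, y, methods = c("snv", "msc", "sg", "fd"),
                                  n_components = 5L, seed = 1L) {
  x <- as_spectra_mat(x)
  y <- as.numeric(y)
  if (length(methods) < 1) stop("need at least one method", call. = FALSE)
  split <- split_721(n_samples(x), seed = seed)
  rows <- purrr::map_dfr(methods, function(m) {
    ref <- if (m == "msc") {
      colMeans(x$values[split$train, , drop = FALSE])
    } else {
      NULL
    }
    xp <- preprocess(x, method = m, msc_reference = ref)
    a <- min(n_components, ncol(xp$values), length(split$train) - 2L)
    fit <- suppressWarnings(
      fit_pls(xp$values[split$train, , drop = FALSE], y[split$train],
              n_components = a)
    )
    met <- function(idx, rpd = FALSE) {
      eval_metrics(y[idx], predict(fit, xp$values[idx, , drop = FALSE]),
                   compute_rpd = rpd)
    }
    tr <- met(split$train); va <- met(split$validation)
    te <- met(split$test, rpd = TRUE)
    tibble::tibble(method = m,
                   r2_train = tr$r2, rmse_train = tr$rmse,
                   r2_val = va$r2, rmsecv_val = va$rmse,
                   r2_test = te$r2, rmsep_test = te$rmse,
                   rpd_test = te$rpd)
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$r2_test))
  dplyr::mutate(rows, rank = dplyr::row_number(), .after = "method")
}

#' Pipeline configuration
#'
#' A single top-level `run_seed` fans out to per-stage seeds by fixed
#' offsets (split +101, CARS +202, DRSA +303, models +404), so each stage
#' is independently reproducible.
#'
#' @param run_seed Top-level seed.
#' @param preprocess_method Pretreatment before selection (default
#'   `"fd"`).
#' @param cars_runs,mc_ratio CARS settings.
#' @param drsa Optional [drsa_config()] overrides (the seed is always
#'   derived from `run_seed`).
#' @param families Model families to fit (default PLSR and FNN).
#' @param max_components,k_folds Shared PLS settings.
#' @param out_dir Optional directory for JSON reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(run_seed = 1L, preprocess_method = "fd",
                            cars_runs = 200L, mc_ratio = 0.8,
                            drsa = NULL, families = c("PLSR", "FNN"),
                            max_components = 10L, k_folds = 5L,
                            out_dir = NULL) {
  structure(
    list(run_seed = as.integer(run_seed),
         preprocess_method = preprocess_method,
         cars_runs = as.integer(cars_runs), mc_ratio = mc_ratio,
         drsa = drsa, families = families,
         max_components = as.integer(max_components),
         k_folds = as.integer(k_folds), out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage_seeds <- function(run_seed) {
  list(split = run_seed + 101L, cars = run_seed + 202L,
       drsa = run_seed + 303L, models = run_seed + 404L)
}

#' Run the full growth-monitoring workflow
#'
#' Preprocess, select wavelengths with CARS and DRSA-CARS, optimize and
#' compute vegetation indices, extract texture features from per-sample
#' cubes when supplied, fuse feature sets, fit the requested models on a
#' 7:2:1 split, and summarize the CARS vs DRSA-CARS comparison
#' (selected counts, percent reduction, relative R-squared gain).
#'
#' @param spectra A [spectra_mat()] of raw reflectance spectra.
#' @param target Numeric target vector aligned with the spectra.
#' @param cubes Optional list of [spectral_cube()] objects, one per
#'   sample, for texture extraction.
#' @param masks Optional list of ROI masks matching `cubes`.
#' @param config A [pipeline_config()].
#' @return A list of class `hsiphen_run`: `selection` (CARS and
#'   DRSA-CARS `selection_result`s), `vi_bands`, `features`
#'   (named list of feature matrices), `eval` (stacked eval-report
#'   tibble), `summary` (selection comparison), `provenance`.
#' @export
run_full <- function(spectra, target, cubes = NULL, masks = NULL,
                     config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spectra <- as_spectra_mat(spectra)
  y <- as.numeric(target)
  seeds <- stage_seeds(config$run_seed)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  xp <- run_stage("preprocess",
                  preprocess(spectra, method = config$preprocess_method))
  cars <- run_stage("cars", run_cars(
    xp, y, n_runs = config$cars_runs, mc_ratio = config$mc_ratio,
    max_components = config$max_components, k_folds = config$k_folds,
    seed = seeds$cars))
  cfg <- config$drsa %||% drsa_config()
  cfg$seed <- seeds$drsa
  drsa <- run_stage("drsa_cars", drsa_cars_select(
    xp, y, cfg = cfg, cars_result = cars,
    max_components = config$max_components, k_folds = config$k_folds))

  vi_bands <- run_stage("vi_optimize", {
    purrr::map_dfr(vi_definitions()$index, function(idx) {
      optimize_band_pair(spectra, y, idx)
    })
  })
  pairs <- stats::setNames(
    purrr::map(seq_len(nrow(vi_bands)),
               function(i) c(vi_bands$nm_a[i], vi_bands$nm_b[i])),
    vi_bands$index)
  vi_table <- run_stage("vi_compute", compute_vi_table(spectra, bands = pairs))

  texture_table <- NULL
  if (!is.null(cubes)) {
    texture_table <- run_stage("texture", {
      purrr::map_dfr(seq_along(cubes), function(i) {
        tv <- texture_vector(texture_pipeline(cubes[[i]], masks[[i]]))
        dplyr::bind_cols(tibble::tibble(sample_id = spectra$sample_ids[i]),
                         tibble::as_tibble(as.list(tv)))
      })
    })
  }

  sub <- xp$values[, drsa$selected_indices, drop = FALSE]
  features <- list(spectral = fuse_features(sub, NULL),
                   fused_vi = fuse_features(sub, vi_table))
  if (!is.null(texture_table)) {
    features$fused_texture <- fuse_features(sub, texture_table)
  }

  split <- split_721(n_samples(spectra), seed = seeds$split)
  eval_tbl <- run_stage("models", {
    purrr::map_dfr(names(features), function(fname) {
      purrr::map_dfr(config$families, function(fam) {
        xm <- features[[fname]]
        model <- train_model(xm[split$train, , drop = FALSE], y[split$train],
                             xm[split$validation, , drop = FALSE],
                             y[split$validation],
                             spec = model_spec(fam, seed = seeds$models))
        evaluate(model, xm, y, split, feature_set_name = fname)
      })
    })
  })

  # R-squared of full-data PLS fits on each subset, for the comparison
  cars_fit <- suppressWarnings(fit_pls(
    xp$values[, cars$selected_indices, drop = FALSE], y,
    n_components = max(1L, cars$n_components)))
  r2_cars <- eval_metrics(
    y, predict(cars_fit, xp$values[, cars$selected_indices, drop = FALSE]))$r2
  summary <- dplyr::bind_cols(
    selection_summary(length(cars$selected_indices),
                      length(drsa$selected_indices),
                      r2_baseline = r2_cars, r2_refined = drsa$r2_fit),
    tibble::tibble(rmsecv_baseline = cars$best_rmsecv,
                   rmsecv_refined = drsa$best_rmsecv)
  )

  provenance <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    run_seed = config$run_seed,
    stage_seeds = seeds,
    n_samples = n_samples(spectra),
    n_bands = n_bands(spectra)
  )
  out <- structure(
    list(selection = list(cars = cars, drsa_cars = drsa),
         vi_bands = vi_bands, vi_table = vi_table,
         texture_table = texture_table, features = features,
         split = split, eval = eval_tbl, summary = summary,
         provenance = provenance),
    class = "hsiphen_run"
  )
  if (!is.null(config$out_dir)) write_run_reports(out, config$out_dir)
  out
}

#' @export
print.hsiphen_run <- function(x, ...) {
  cat("<hsiphen_run>\n")
  cat(sprintf("  CARS: %d bands (RMSECV %.5g) | DRSA-CARS: %d bands (RMSECV %.5g)\n",
              x$summary$n_baseline, x$summary$rmsecv_baseline,
              x$summary$n_refined, x$summary$rmsecv_refined))
  cat(sprintf("  feature reduction: %.1f%% | relative R2 gain: %.1f%%\n",
              x$summary$pct_reduction, x$summary$r2_gain_pct))
  cat(sprintf("  models evaluated: %d rows over %d feature sets\n",
              nrow(x$eval), length(x$features)))
  invisible(x)
}

# Serialize the run's tabular artifacts as deterministic JSON reports.
write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- run$provenance
  wr <- function(obj, name) {
    jsonlite::write_json(c(list(provenance = prov), obj),
                         file.path(out_dir, name),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  sel_json <- function(s) {
    list(method = s$method_name, selected_indices = s$selected_indices,
         selected_wavelengths = s$selected_wavelengths,
         best_rmsecv = s$best_rmsecv, best_run = s$best_run,
         n_components = s$n_components, seed = s$seed,
         rmsecv_trace = s$rmsecv_trace)
  }
  wr(list(cars = sel_json(run$selection$cars),
          drsa_cars = sel_json(run$selection$drsa_cars)), "selection.json")
  wr(list(vi_bands = run$vi_bands), "vi_bands.json")
  wr(list(eval = run$eval), "eval.json")
  wr(list(summary = run$summary), "summary.json")
  invisible(out_dir)
}
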