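#' Exploration probability of the dynamic reptile search algorithm
#'
#' Exponential decay `exp(-lambda * t / t_max)` controlling the
#' probability that an individual performs an exploration (walking)
#' behavior rather than an exploitation (hunting) behavior at iteration
#' `t`. Equals 1 at `t = 0` and `exp(-lambda)` at `t = t_max`.
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Total iterations (> 0).
#' @param lambda_decay Decay rate (> 0).
#' @return Probability in `(0, 1]`.
#' @export
p_explore <- function(t, t_max, lambda_decay) {
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (any(t < 0 | t > t_max)) stop("t out of [0, t_max]", call. = FALSE)
  exp(-lambda_decay * t / t_max)
}

#' Dynamic disturbance factor ES
#'
#' `ES = 2 * r * (1 - t / t_max)` with `r` drawn uniformly from
#' `{-1, 0, 1}`; perturbs individuals during the belly-walking behavior
#' and shrinks linearly to 0 as the run ends.
#'
#' @param t,t_max Iteration and total iterations.
#' @param r Optional override for the random sign (for testing);
#'   otherwise drawn from the current RNG stream.
#' @return A value in `{-2(1 - t/t_max), 0, +2(1 - t/t_max)}`.
#' @export
es_factor <- function(t, t_max, r = NULL) {
  if (is.null(r)) r <- sample(c(-1, 0, 1), 1L)
  2 * r * (1 - t / t_max)
}

#' Derived quantities of the DRSA behavior equations
#'
#' Computes the reduction term `R = (best - x_r) / (best + epsilon)`, the
#' percentage-difference term
#' `P = alpha + (x - mean_x) / (best * (ub - lb) + epsilon)` and the
#' hunting operator `eta = best * P` used by the four behavior updates.
#' All arguments may be vectors over dimensions.
#'
#' @param best Best-so-far coordinate(s) `Best_j`.
#' @param x Current coordinate(s) `x_{i,j}`.
#' @param x_r Coordinate(s) of a random other individual.
#' @param mean_x Mean of the current individual's position vector.
#' @param lb,ub Bounds of the dimension(s).
#' @param alpha Sensitivity parameter for exploration accuracy.
#' @param epsilon Small positive guard against division by zero.
#' @return List with elements `R`, `P`, `eta`.
#' @export
drsa_components <- function(best, x, x_r, mean_x, lb, ub,
                            alpha = 0.1, epsilon = 1e-10) {
  R <- (best - x_r) / (best + epsilon)
  P <- alpha + (x - mean_x) / (best * (ub - lb) + epsilon)
  list(R = R, P = P, eta = best * P)
}

#' One DRSA behavior update (unclipped)
#'
#' The four reptilian position updates:
#' high walking `best - eta * beta - R * u`;
#' belly walking `best * x_r * ES * u`;
#' coordination hunting `best * P * u`;
#' cooperation hunting `best - eta * epsilon - R * u`.
#'
#' @param behavior One of `"high_walk"`, `"belly_walk"`, `"coord_hunt"`,
#'   `"coop_hunt"`.
#' @param best,x_r Best-so-far and random-peer coordinates.
#' @param R,P,eta Derived quantities from [drsa_components()].
#' @param es Disturbance factor from [es_factor()].
#' @param u Uniform(0,1) draw(s).
#' @param beta Exploration control parameter.
#' @param epsilon Division guard, reused as the cooperation-hunting
#'   multiplier exactly as the update equations specify.
#' @return Updated coordinate value(s), not yet clipped to bounds.
#' @export
drsa_behavior_value <- function(behavior, best, x_r, R, P, eta, es, u,
                                beta = 0.005, epsilon = 1e-10) {
  switch(match.arg(behavior,
                   c("high_walk", "belly_walk", "coord_hunt", "coop_hunt")),
    high_walk  = best - eta * beta - R * u,
    belly_walk = best * x_r * es * u,
    coord_hunt = best * P * u,
    coop_hunt  = best - eta * epsilon - R * u
  )
}

#' DRSA optimizer configuration
#'
#' @param pop_size Population size (>= 2, default 30).
#' @param t_max Iterations (default 100).
#' @param lambda_decay Exploration-probability decay rate (default 3):
#'   the exploration probability then spans 1 to about 0.05 over a run.
#' @param alpha,beta Sensitivity/control parameters of the hunting and
#'   walking operators (defaults 0.1 and 0.005).
#' @param epsilon Division guard (default 1e-10).
#' @param lower_bound,upper_bound Scalar or per-dimension bounds.
#' @param seed Integer seed (mandatory).
#' @param threshold Decoding threshold for band selection in `(0, 1)`.
#' @param parsimony_weight Subset-size penalty weight `gamma >= 0` used by
#'   [drsa_cars_select()].
#' @param per_dimension_behavior Draw the behavior independently per
#'   dimension instead of once per individual per iteration?
#' @return A `drsa_config` list.
#' @export
drsa_config <- function(pop_size = 30L, t_max = 100L, lambda_decay = 3,
                        alpha = 0.1, beta = 0.005, epsilon = 1e-10,
                        lower_bound = 0, upper_bound = 1, seed = 1L,
                        threshold = 0.5, parsimony_weight = 0.05,
                        per_dimension_behavior = FALSE) {
  if (pop_size < 2) stop("pop_size must be >= 2", call. = FALSE)
  if (t_max < 1) stop("t_max must be >= 1", call. = FALSE)
  if (lambda_decay <= 0) stop("lambda_decay must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)",
                                             call. = FALSE)
  if (parsimony_weight < 0) stop("parsimony_weight must be >= 0", call. = FALSE)
  structure(
    list(pop_size = as.integer(pop_size), t_max = as.integer(t_max),
         lambda_decay = lambda_decay, alpha = alpha, beta = beta,
         epsilon = epsilon, lower_bound = lower_bound,
         upper_bound = upper_bound, seed = as.integer(seed),
         threshold = threshold, parsimony_weight = parsimony_weight,
         per_dimension_behavior = per_dimension_behavior),
    class = "drsa_config"
  )
}

#' Run the dynamic reptile search algorithm
#'
#' Minimizes `fitness_fn` over a box-bounded continuous search space.
#' Positions are initialized uniformly within the bounds; at each
#' iteration every individual draws a behavior — an exploration (walking)
#' behavior with probability [p_explore()], otherwise an exploitation
#' (hunting) behavior, uniformly within each pair — and updates every
#' coordinate by the corresponding equation, clipped to the bounds. The
#' best-so-far solution is elitist and never worsens.
#'
#' @param fitness_fn Function mapping a numeric vector of length
#'   `n_dims` to a finite scalar to be minimized.
#' @param n_dims Dimensionality of the search space.
#' @param cfg A [drsa_config()].
#' @param init_positions Optional matrix (`pop_size x n_dims`) of starting
#'   positions; rows beyond the supplied ones are drawn uniformly.
#' @return A list: `best_position`, `best_fitness`, `trace`
#'   (per-iteration best fitness, non-increasing), `best_history`
#'   (iteration x dims matrix of the best-so-far position),
#'   `behavior_counts` (iteration x 2 matrix of walking/hunting draws).
#' @export
run_drsa <- function(fitness_fn, n_dims, cfg = drsa_config(),
                     init_positions = NULL) {
  stopifnot(inherits(cfg, "drsa_config"))
  d <- as.integer(n_dims)
  lb <- rep_len(cfg$lower_bound, d)
  ub <- rep_len(cfg$upper_bound, d)
  if (any(lb >= ub)) stop("lower_bound must be < upper_bound", call. = FALSE)
  np <- cfg$pop_size
  eval_fit <- function(v) {
    f <- fitness_fn(v)
    if (!is.finite(f)) {
      stop("non-finite fitness at position [",
           paste(signif(v, 4), collapse = ", "), "]", call. = FALSE)
    }
    f
  }
  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(np * d), np, d)
    pos <- sweep(sweep(pos, 2, ub - lb, "*"), 2, lb, "+")
    if (!is.null(init_positions)) {
      init_positions <- as.matrix(init_positions)
      m <- min(nrow(init_positions), np)
      pos[seq_len(m), ] <- pmin(pmax(init_positions[seq_len(m), , drop = FALSE],
                                     rep(lb, each = m)), rep(ub, each = m))
    }
    fitness <- apply(pos, 1, eval_fit)
    best_idx <- which.min(fitness)
    best_pos <- pos[best_idx, ]
    best_fit <- fitness[best_idx]
    trace <- numeric(cfg$t_max)
    best_history <- matrix(0, cfg$t_max, d)
    behavior_counts <- matrix(0L, cfg$t_max, 2,
                              dimnames = list(NULL, c("walk", "hunt")))
    walk_set <- c("high_walk", "belly_walk")
    hunt_set <- c("coord_hunt", "coop_hunt")
    for (t in seq_len(cfg$t_max)) {
      pex <- p_explore(t, cfg$t_max, cfg$lambda_decay)
      for (i in seq_len(np)) {
        n_draw <- if (cfg$per_dimension_behavior) d else 1L
        explores <- stats::runif(n_draw) < pex
        behavior <- ifelse(explores, sample(walk_set, n_draw, replace = TRUE),
                           sample(hunt_set, n_draw, replace = TRUE))
        behavior_counts[t, 1] <- behavior_counts[t, 1] + sum(explores)
        behavior_counts[t, 2] <- behavior_counts[t, 2] + sum(!explores)
        r_idx <- sample(seq_len(np)[-i], 1L)
        es <- es_factor(t, cfg$t_max)
        xi <- pos[i, ]
        comp <- drsa_components(best_pos, xi, pos[r_idx, ], mean(xi), lb, ub,
                                alpha = cfg$alpha, epsilon = cfg$epsilon)
        u <- stats::runif(d)
        newx <- numeric(d)
        bh <- rep_len(behavior, d)
        for (b in unique(bh)) {
          jj <- bh == b
          newx[jj] <- drsa_behavior_value(
            b, best_pos[jj], pos[r_idx, jj], comp$R[jj], comp$P[jj],
            comp$eta[jj], es, u[jj], beta = cfg$beta, epsilon = cfg$epsilon)
        }
        pos[i, ] <- pmin(pmax(newx, lb), ub)
        fitness[i] <- eval_fit(pos[i, ])
      }
      it_best <- which.min(fitness)
      if (fitness[it_best] < best_fit) {
        best_fit <- fitness[it_best]
        best_pos <- pos[it_best, ]
      }
      trace[t] <- best_fit
      best_history[t, ] <- best_pos
    }
    list(best_position = best_pos, best_fitness = best_fit, trace = trace,
         best_history = best_history, behavior_counts = behavior_counts)
  })
}

# Decode a continuous position into a band subset; an empty decode is
# repaired by forcing the band with the largest position value.
decode_bands <- function(position, threshold) {
  sel <- which(position > threshold)
  if (length(sel) == 0L) sel <- which.max(position)
  sel
}

#' DRSA-CARS wavelength selection
#'
#' Couples the dynamic reptile search algorithm to the CARS framework to
#' search for a compact wavelength subset. Each individual is a
#' continuous vector in `[0, 1]^d`; band `j` is selected when the
#' coordinate exceeds `cfg$threshold`. The fitness of a decoded subset is
#' its cross-validated PLS RMSECV multiplied by the parsimony factor
#' `(1 + gamma * k / d)` where `k` is the subset size, so accuracy and
#' compactness are balanced (set `parsimony_weight = 0` for pure-RMSECV
#' fitness).
#'
#' In *refine* mode (a `cars_result` is supplied) the search space is the
#' candidate band pool recorded by [run_cars()] — the union of the
#' best-decile run subsets — and the CARS-optimal subset is injected as
#' one initial individual. Without a `cars_result` the search runs
#' standalone over the full band range.
#'
#' @param x Preprocessed [spectra_mat()] or numeric matrix.
#' @param y Response vector.
#' @param cfg A [drsa_config()]; `seed` governs folds, initialization and
#'   all optimizer draws.
#' @param cars_result Optional `selection_result` from [run_cars()].
#' @param max_components,k_folds PLS settings for the RMSECV fitness.
#' @return A `selection_result` with `method_name = "DRSA-CARS"`. The
#'   `rmsecv_trace` records the unpenalized RMSECV of the best-so-far
#'   subset at each iteration; `best_rmsecv` is the RMSECV of the
#'   returned subset (the trace minimum when `parsimony_weight = 0`).
#'   `r2_fit` holds the R-squared of the final full-data PLS fit on the
#'   selected bands.
#' @export
drsa_cars_select <- function(x, y, cfg = drsa_config(), cars_result = NULL,
                             max_components = 10L, k_folds = 5L) {
  sm <- as_spectra_mat(x)
  X <- sm$values
  y <- as.numeric(y)
  candidates <- if (!is.null(cars_result)) {
    stopifnot(inherits(cars_result, "selection_result"))
    cars_result$candidate_union
  } else {
    seq_len(ncol(X))
  }
  d <- length(candidates)
  if (d < 2) stop("need at least 2 candidate bands", call. = FALSE)
  folds <- make_folds(nrow(X), k_folds, cfg$seed)
  gamma <- cfg$parsimony_weight

  cache <- new.env(parent = emptyenv())
  raw_rmsecv <- function(cols) {
    key <- paste(cols, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- rmsecv(X[, candidates[cols], drop = FALSE], y,
                  n_components_max = max_components, folds = folds)$rmsecv_value
    cache[[key]] <- val
    val
  }
  fitness_fn <- function(pos) {
    cols <- decode_bands(pos, cfg$threshold)
    raw_rmsecv(cols) * (1 + gamma * length(cols) / d)
  }

  init <- NULL
  if (!is.null(cars_result)) {
    enc <- ifelse(candidates %in% cars_result$selected_indices,
                  (1 + cfg$threshold) / 2, cfg$threshold / 2)
    init <- matrix(enc, 1L, d)
  }
  cfg_box <- cfg
  cfg_box$lower_bound <- 0
  cfg_box$upper_bound <- 1
  opt <- run_drsa(fitness_fn, d, cfg_box, init_positions = init)

  trace <- vapply(seq_len(cfg$t_max), function(t) {
    raw_rmsecv(decode_bands(opt$best_history[t, ], cfg$threshold))
  }, numeric(1))
  cols <- decode_bands(opt$best_position, cfg$threshold)
  sel <- sort(candidates[cols])
  cv <- rmsecv(X[, sel, drop = FALSE], y, n_components_max = max_components,
               folds = folds)
  fit <- suppressWarnings(
    fit_pls(X[, sel, drop = FALSE], y,
            n_components = min(cv$best_n_components, length(sel),
                               nrow(X) - 1L))
  )
  r2 <- eval_metrics(y, predict(fit, X[, sel, drop = FALSE]))$r2
  new_selection_result(
    "DRSA-CARS", sel, sm$wavelengths, trace,
    best_run = cfg$t_max, best_rmsecv = cv$rmsecv_value, seed = cfg$seed,
    n_components = cv$best_n_components, r2_fit = r2,
    extra = list(candidate_pool = candidates,
                 optimizer_trace = opt$trace,
                 behavior_counts = opt$behavior_counts,
                 folds = folds,
                 mode = if (is.null(cars_result)) "standalone" else "refine")
  )
}
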