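#' Model specification for fitting
#'
#' Three candidate models of crowded orientation matching:
#' * `pooling4` — weighted population pooling with early noise, late noise and
#'   independent flanker weights for the 30- and 90-degree conditions;
#' * `pooling3` — the same with one shared flanker weight;
#' * `noise2` — early noise plus flanker-triggered added noise `beta`, with no
#'   pooling stage.
#'
#' @param kind One of `"pooling4"`, `"pooling3"`, `"noise2"`.
#' @return A list of class `model_spec` with `kind`, `n_params`, `par_names`,
#'   `lower` and `upper` bounds.
#' @export
model_spec <- function(kind = c("pooling4", "pooling3", "noise2")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    pooling4 = list(par_names = c("early_noise", "late_noise", "wf30", "wf90"),
                    lower = c(0, 0, 0, 0), upper = c(Inf, Inf, 1, 1)),
    pooling3 = list(par_names = c("early_noise", "late_noise", "wf"),
                    lower = c(0, 0, 0), upper = c(Inf, Inf, 1)),
    noise2 = list(par_names = c("early_noise", "beta"),
                  lower = c(0, 0), upper = c(Inf, Inf))
  )
  structure(c(list(kind = kind, n_params = length(spec$par_names)), spec),
            class = "model_spec")
}

par_to_params <- function(par, spec) {
  switch(spec$kind,
    pooling4 = pooling_params(par[1], par[2], par[3], par[4]),
    pooling3 = pooling_params(par[1], par[2], par[3], par[3]),
    noise2 = noise_only_params(par[1], par[2])
  )
}

# Clamp a raw parameter vector into the spec's bounds; the penalty (scaled
# total excursion) is added to the objective so the simplex is steered back
# into bounds rather than erroring.
clamp_par <- function(par, spec) {
  lo <- pmax(par, spec$lower)
  cl <- pmin(lo, spec$upper)
  list(par = cl, penalty = 1e3 * sum(abs(par - cl)))
}

# Common-random-number noise fields: one early and one late field per
# condition, drawn in a fixed order from `seed` so every objective evaluation
# within a fit sees identical noise. The ambient RNG state is restored.
crn_fields <- function(sim_n, seed, grid = orientation_grid(), sigma = 30) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draw <- function() smooth_noise_fields(sim_n, grid, sigma)
  list(
    unflanked = list(E = draw(), L = empty_field(grid)),
    f30 = list(E = draw(), L = draw()),
    f90 = list(E = draw(), L = draw())
  )
}

# 36-bin model proportions for one folded condition (1-degree grid assumed,
# so channel index maps to bin index arithmetically).
cond_model_props <- function(params, kind, sim_n, fields, grid, sigma = 30) {
  err <- simulate_errors_batch(params, kind, sim_n, fields,
                               grid = grid, sigma = sigma)
  tabulate(error_bin_index(err), nbins = 36) / sim_n
}

data_props <- function(data) {
  conds <- c("unflanked", "f30", "f90")
  if (!all(conds %in% unique(data$condition))) {
    stop("data histograms must cover conditions unflanked, f30 and f90")
  }
  out <- lapply(conds, function(cn) {
    h <- data[data$condition == cn, ]
    h <- h[order(h$bin_left), ]
    if (nrow(h) != 36) stop("expected 36 bins for condition ", cn)
    h$proportion
  })
  names(out) <- conds
  out
}

#' Simulation-based least-squares objective
#'
#' Simulates `sim_n` trials per folded condition at the given parameters with
#' noise fields drawn from `seed` (common random numbers), bins the errors,
#' and returns the summed squared difference from the data proportions.
#' Deterministic for fixed `(par, seed)`; parameters outside the model bounds
#' are clamped and penalized.
#'
#' @param data Histogram tibble covering conditions `unflanked`, `f30`, `f90`.
#' @param par Numeric parameter vector in the order of the model's
#'   `par_names`.
#' @param model A [model_spec()] or its kind string.
#' @param sim_n Simulated trials per condition (default 1,000).
#' @param seed Integer seed fixing the noise fields.
#' @return A non-negative scalar.
#' @export
objective <- function(data, par, model, sim_n = 1000, seed = 1) {
  if (is.character(model)) model <- model_spec(model)
  grid <- orientation_grid()
  fields <- crn_fields(sim_n, seed, grid)
  dp <- data_props(data)
  objective_core(par, model, dp, sim_n, fields, grid)
}

objective_core <- function(par, model, dp, sim_n, fields, grid, sigma = 30) {
  if (any(!is.finite(par))) return(1e6)
  cl <- clamp_par(par, model)
  params <- par_to_params(cl$par, model)
  tot <- cl$penalty
  for (kind in c("unflanked", "f30", "f90")) {
    m <- cond_model_props(params, kind, sim_n, fields[[kind]], grid, sigma)
    tot <- tot + sum((dp[[kind]] - m)^2)
  }
  tot
}

#' Default coarse-search grids
#'
#' Steps over early noise, late noise and flanker weights used by the
#' grid-search stage. Children's data motivate wider noise ranges than
#' adults'.
#'
#' @param model A [model_spec()] or kind string.
#' @param group `"adult"` or one of the child groups (wider noise ranges).
#' @return Named list of numeric vectors, one per free parameter.
#' @export
default_param_grid <- function(model, group = "adult") {
  if (is.character(model)) model <- model_spec(model)
  child <- group %in% c("child_typical", "child_amblyopic")
  early <- seq(0.1, if (child) 2.5 else 1.5, by = 0.2)
  late <- seq(0.2, if (child) 4.2 else 3.0, by = 0.4)
  w <- seq(0, 1, by = 0.1)
  switch(model$kind,
    pooling4 = list(early_noise = early, late_noise = late, wf30 = w, wf90 = w),
    pooling3 = list(early_noise = early, late_noise = late, wf = w),
    noise2 = list(early_noise = early, beta = late)
  )
}

#' Coarse grid-search stage of the fit
#'
#' Evaluates the common-random-numbers objective over the full factorial grid
#' and returns the minimizing parameter vector (first in lexicographic order
#' on ties). The least-squares error is additive over conditions and the
#' unflanked term depends only on the early noise, so the factorial minimum is
#' found by decomposition without evaluating every cell from scratch.
#'
#' @param data Histogram tibble covering `unflanked`, `f30`, `f90`.
#' @param model A [model_spec()] or kind string.
#' @param grid_spec Named list of grid values per parameter
#'   (default [default_param_grid()]).
#' @param sim_n Simulated trials per condition per evaluation.
#' @param seed Integer seed for the common random numbers.
#' @param group Group label passed to [default_param_grid()].
#' @return Named numeric vector of the best grid point, with attribute
#'   `"lse"`.
#' @export
coarse_grid_fit <- function(data, model, grid_spec = NULL, sim_n = 1000,
                            seed = 1, group = "adult") {
  if (is.character(model)) model <- model_spec(model)
  if (is.null(grid_spec)) grid_spec <- default_param_grid(model, group)
  if (!identical(names(grid_spec), model$par_names)) {
    stop("grid_spec names must be ", paste(model$par_names, collapse = ", "))
  }
  if (any(lengths(grid_spec) == 0)) stop("empty parameter grid")
  ogrid <- orientation_grid()
  fields <- crn_fields(sim_n, seed, ogrid)
  dp <- data_props(data)

  cond_lse <- function(params, kind) {
    m <- cond_model_props(params, kind, sim_n, fields[[kind]], ogrid)
    sum((dp[[kind]] - m)^2)
  }

  early <- grid_spec$early_noise
  lse_u <- vapply(early, function(g) {
    cond_lse(par_to_params(c(g, 0, 0, 0)[seq_len(model$n_params)], model),
             "unflanked")
  }, numeric(1))

  best <- list(val = Inf, par = NULL)
  consider <- function(val, par) {
    if (val < best$val) best <<- list(val = val, par = par)
  }

  if (model$kind == "pooling4") {
    for (i in seq_along(early)) for (l in grid_spec$late_noise) {
      l30 <- vapply(grid_spec$wf30, function(w)
        cond_lse(pooling_params(early[i], l, w, 0), "f30"), numeric(1))
      l90 <- vapply(grid_spec$wf90, function(w)
        cond_lse(pooling_params(early[i], l, 0, w), "f90"), numeric(1))
      consider(lse_u[i] + min(l30) + min(l90),
               c(early_noise = early[i], late_noise = l,
                 wf30 = grid_spec$wf30[which.min(l30)],
                 wf90 = grid_spec$wf90[which.min(l90)]))
    }
  } else if (model$kind == "pooling3") {
    for (i in seq_along(early)) for (l in grid_spec$late_noise) {
      lw <- vapply(grid_spec$wf, function(w) {
        p <- pooling_params(early[i], l, w, w)
        cond_lse(p, "f30") + cond_lse(p, "f90")
      }, numeric(1))
      consider(lse_u[i] + min(lw),
               c(early_noise = early[i], late_noise = l,
                 wf = grid_spec$wf[which.min(lw)]))
    }
  } else {
    for (i in seq_along(early)) for (b in grid_spec$beta) {
      p <- noise_only_params(early[i], b)
      consider(lse_u[i] + cond_lse(p, "f30") + cond_lse(p, "f90"),
               c(early_noise = early[i], beta = b))
    }
  }
  structure(best$par, lse = best$val)
}

#' Simplex refinement stage of the fit
#'
#' Nelder-Mead minimization of the common-random-numbers objective, seeded at
#' the coarse-grid best. Weights are kept in \eqn{[0, 1]} and noise magnitudes
#' non-negative by clamping (with penalty) inside the objective. The returned
#' fit never has a larger objective value than its initialization.
#'
#' @param data Histogram tibble covering `unflanked`, `f30`, `f90`.
#' @param init Named numeric initial parameter vector.
#' @param model A [model_spec()] or kind string.
#' @param sim_n Simulated trials per condition per evaluation.
#' @param seed Integer seed for the common random numbers.
#' @param maxit Maximum simplex iterations.
#' @return An object of class `crowding_fit`: list with `model`, `par`,
#'   `lse`, `aic`, `sim_n`, `seed`, `init`, `init_lse` and `convergence`.
#' @export
refine_fit <- function(data, init, model, sim_n = 1000, seed = 1,
                       maxit = 300) {
  if (is.character(model)) model <- model_spec(model)
  ogrid <- orientation_grid()
  fields <- crn_fields(sim_n, seed, ogrid)
  dp <- data_props(data)
  fn <- function(par) objective_core(par, model, dp, sim_n, fields, ogrid)
  f0 <- fn(init)
  if (!is.finite(f0)) stop("objective is not finite at the initial point")
  opt <- optim(init, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  if (opt$value <= f0) {
    par <- clamp_par(as.vector(opt$par), model)$par
    val <- opt$value
  } else {
    par <- clamp_par(as.vector(init), model)$par
    val <- f0
  }
  names(par) <- model$par_names
  structure(
    list(model = model, par = par, lse = val,
         aic = aic_from_lse(val, model$n_params),
         sim_n = sim_n, seed = seed,
         init = init, init_lse = f0, convergence = opt$convergence),
    class = "crowding_fit"
  )
}

#' AIC from a least-squares error
#'
#' Least-squares (Gaussian-error) form of the Akaike information criterion:
#' `n * log(LSE / n) + 2k`, with `n` the total number of fitted bins
#' (36 bins in each of the three folded conditions, so 108 by default). Only
#' differences in AIC across models fitted to the same data are meaningful;
#' lower is better.
#'
#' @param lse_value Positive least-squares error.
#' @param k Number of free parameters.
#' @param n_points Number of fitted bins.
#' @return The AIC value; `-Inf` (with a warning) when `lse_value` is zero.
#' @export
aic_from_lse <- function(lse_value, k, n_points = 108) {
  stopifnot(lse_value >= 0, k >= 0, n_points > 0)
  if (lse_value == 0) {
    warning("zero least-squares error; AIC is -Inf")
    return(-Inf)
  }
  n_points * log(lse_value / n_points) + 2 * k
}

#' Two-stage fit of one model
#'
#' Coarse grid search followed by Nelder-Mead refinement, both minimizing the
#' simulation-based least-squares error under common random numbers.
#'
#' @inheritParams coarse_grid_fit
#' @param maxit Maximum simplex iterations for the refinement stage.
#' @return A `crowding_fit` (see [refine_fit()]); the coarse-stage best is
#'   kept in `$init`.
#' @export
fit_model <- function(data, model, grid_spec = NULL, sim_n = 1000, seed = 1,
                      group = "adult", maxit = 300) {
  init <- coarse_grid_fit(data, model, grid_spec = grid_spec, sim_n = sim_n,
                          seed = seed, group = group)
  refine_fit(data, init, model, sim_n = sim_n, seed = seed, maxit = maxit)
}

#' Fit and compare the candidate models
#'
#' Runs the two-stage fit for the four-parameter pooling, three-parameter
#' pooling and two-parameter noise models on the same data and seed, and
#' compares them by AIC.
#'
#' @inheritParams fit_model
#' @param models Character vector of model kinds to fit.
#' @return An object of class `crowding_comparison`: list with `fits` (named
#'   list of `crowding_fit`s), `table` (tibble of model, k, lse, aic,
#'   delta_aic) and `winner` (kind with the lowest AIC).
#' @export
fit_and_compare <- function(data, models = c("pooling4", "pooling3", "noise2"),
                            sim_n = 1000, seed = 1, group = "adult",
                            maxit = 300) {
  fits <- lapply(models, function(m)
    fit_model(data, m, sim_n = sim_n, seed = seed, group = group,
              maxit = maxit))
  names(fits) <- models
  tab <- tibble::tibble(
    model = models,
    k = vapply(fits, function(f) f$model$n_params, numeric(1)),
    lse = vapply(fits, function(f) f$lse, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  structure(list(fits = fits, table = tab,
                 winner = tab$model[which.min(tab$aic)]),
            class = "crowding_comparison")
}

#' Mean model curve and 95% simulation envelope
#'
#' Re-runs the fitted model to produce, for each condition and bin, the mean
#' simulated proportion and the 2.5%/97.5% quantiles across `n_iter`
#' iterations of `trials_per_iter` trials each. Bin probabilities are
#' estimated once from a large simulation and per-iteration histograms drawn
#' as multinomial samples of those probabilities, which is distributionally
#' identical to re-simulating each iteration.
#'
#' @param fit A `crowding_fit`, or a parameter object
#'   ([pooling_params()]/[noise_only_params()]).
#' @param n_iter Number of model iterations (default 1,000).
#' @param trials_per_iter Trials per condition per iteration (default 1,000).
#' @param p_sim_n Trials used to estimate the underlying bin probabilities.
#' @param seed Optional seed.
#' @return Tibble with `condition`, `bin_center`, `mean`, `lo`, `hi`.
#' @export
model_envelope <- function(fit, n_iter = 1000, trials_per_iter = 1000,
                           p_sim_n = 20000, seed = NULL) {
  params <- if (inherits(fit, "crowding_fit")) {
    par_to_params(fit$par, fit$model)
  } else fit
  if (!is.null(seed)) set.seed(seed)
  grid <- orientation_grid()
  purrr::map_dfr(c("unflanked", "f30", "f90"), function(kind) {
    err <- simulate_condition(params, kind, n_trials = p_sim_n, grid = grid)
    p <- tabulate(error_bin_index(err), nbins = 36) / p_sim_n
    draws <- stats::rmultinom(n_iter, trials_per_iter, p) / trials_per_iter
    tibble::tibble(
      condition = kind,
      bin_center = seq(-175, 175, by = 10),
      mean = rowMeans(draws),
      lo = apply(draws, 1, stats::quantile, probs = 0.025),
      hi = apply(draws, 1, stats::quantile, probs = 0.975)
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy crowding_fit
#' @export
tidy.crowding_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @method glance crowding_fit
#' @export
glance.crowding_fit <- function(x, ...) {
  tibble::tibble(model = x$model$kind, k = x$model$n_params, lse = x$lse,
                 aic = x$aic, sim_n = x$sim_n, seed = x$seed,
                 convergence = x$convergence)
}

#' @method tidy crowding_comparison
#' @export
tidy.crowding_comparison <- function(x, ...) x$table

#' @method glance crowding_comparison
#' @export
glance.crowding_comparison <- function(x, ...) {
  tibble::tibble(winner = x$winner, n_models = nrow(x$table),
                 best_aic = min(x$table$aic))
}

#' @export
print.crowding_fit <- function(x, ...) {
  cat("<crowding_fit>", x$model$kind, "\n")
  cat("  params:", paste(sprintf("%s = %.3f", names(x$par), x$par),
                         collapse = ", "), "\n")
  cat(sprintf("  LSE = %.5f, AIC = %.2f (sim_n = %d, seed = %d)\n",
              x$lse, x$aic, x$sim_n, x$seed))
  invisible(x)
}

#' @export
print.crowding_comparison <- function(x, ...) {
  cat("<crowding_comparison> winner:", x$winner, "\n")
  print(x$table)
  invisible(x)
}
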