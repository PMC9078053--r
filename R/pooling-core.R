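#' @useDynLib crowdpool, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rnorm runif optim mvfft sd fft qnorm pnorm dnorm uniroot
NULL

#' Parameters of the weighted population-pooling model
#'
#' Four free parameters: early noise (magnitude of the smooth Gaussian noise
#' added to the target population response, in units of the unit-height tuning
#' peak), late noise (same, for the flanker population response), and one
#' flanker weight per crowded condition (30- and 90-degree target-flanker
#' differences). The target weight is always one minus the flanker weight.
#'
#' @param early_noise,late_noise Non-negative noise magnitudes.
#' @param wf30,wf90 Flanker weights in \eqn{[0, 1]}.
#' @return An object of class `pooling_params`.
#' @export
pooling_params <- function(early_noise = 0.45, late_noise = 1.0,
                           wf30 = 0.5, wf90 = 0.35) {
  stopifnot(early_noise >= 0, late_noise >= 0,
            wf30 >= 0, wf30 <= 1, wf90 >= 0, wf90 <= 1)
  structure(list(early_noise = unname(early_noise),
                 late_noise = unname(late_noise),
                 wf30 = unname(wf30), wf90 = unname(wf90)),
            class = c("pooling_params", "crowding_params"))
}

#' Parameters of the noise-only model
#'
#' Two free parameters: the early noise shared with the pooling model, and
#' `beta`, the magnitude of the extra noise injected when flankers are present.
#' The flanker orientation itself is ignored by this model.
#'
#' @param early_noise,beta Non-negative noise magnitudes.
#' @return An object of class `noise_only_params`.
#' @export
noise_only_params <- function(early_noise = 0.45, beta = 1.0) {
  stopifnot(early_noise >= 0, beta >= 0)
  structure(list(early_noise = unname(early_noise), beta = unname(beta)),
            class = c("noise_only_params", "crowding_params"))
}

#' Flanker condition (post-folding convention)
#'
#' @param kind One of `"unflanked"`, `"f30"` (flankers offset +30 degrees) or
#'   `"f90"` (+90 degrees).
#' @return An object of class `flanker_condition` with fields `kind` and
#'   `offset` (`NA` for unflanked).
#' @export
flanker_condition <- function(kind = c("unflanked", "f30", "f90")) {
  kind <- match.arg(kind)
  offset <- switch(kind, unflanked = NA_real_, f30 = 30, f90 = 90)
  structure(list(kind = kind, offset = offset), class = "flanker_condition")
}

#' Smooth Gaussian noise fields
#'
#' Draws i.i.d. standard-normal values per channel and circularly convolves
#' them with the Gaussian tuning kernel (bandwidth `sigma`), then standardizes
#' back to unit per-channel standard deviation. The result is a smooth random
#' field whose correlation length matches the tuning bandwidth, so decision
#' statistics do not depend on the channel spacing, and whose magnitude
#' parameter is expressed in units of the tuning-curve peak.
#'
#' @param n Number of independent fields (columns).
#' @param grid An [orientation_grid()].
#' @param sigma Tuning bandwidth in degrees used as the smoothing kernel.
#' @return A numeric matrix with one row per channel and `n` columns.
#' @export
smooth_noise_fields <- function(n, grid = orientation_grid(), sigma = 30) {
  K <- length(grid$theta)
  z <- matrix(rnorm(K * n), nrow = K, ncol = n)
  k <- exp(-circ_dist(grid$theta, grid$theta[1])^2 / (2 * sigma^2))
  sm <- Re(mvfft(mvfft(z) * as.vector(fft(k)), inverse = TRUE)) / K
  sm / sqrt(sum(k^2))
}

#' Population response to an oriented stimulus
#'
#' Gaussian tuning profile over the orientation channels, centered on the
#' stimulus orientation `mu` with bandwidth `sigma` (default 30 degrees,
#' matching V1 orientation selectivity) and peak height `alpha` (default 1),
#' plus a smooth Gaussian noise field of magnitude `noise_mag`. With
#' `noise_mag = 0` the deterministic tuning profile is returned.
#'
#' @param mu Stimulus orientation in degrees.
#' @param sigma Tuning bandwidth in degrees (> 0).
#' @param alpha Peak response height (> 0).
#' @param noise_mag Noise magnitude (>= 0).
#' @param grid An [orientation_grid()].
#' @return A tibble of class `population_response` with columns `channel_deg`
#'   and `activity`.
#' @export
#' @examples
#' y <- population_response(0)
#' y$activity[y$channel_deg == 0] # exactly 1
population_response <- function(mu, sigma = 30, alpha = 1, noise_mag = 0,
                                grid = orientation_grid()) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be positive")
  if (!is.numeric(noise_mag) || noise_mag < 0) stop("`noise_mag` must be >= 0")
  vals <- tuning_profile(mu, grid, sigma = sigma, alpha = alpha)
  if (noise_mag > 0) {
    vals <- vals + noise_mag * smooth_noise_fields(1, grid, sigma = sigma)[, 1]
  }
  new_population_response(grid, vals)
}

tuning_profile <- function(mu, grid, sigma = 30, alpha = 1) {
  alpha * exp(-circ_dist(grid$theta, mu)^2 / (2 * sigma^2))
}

new_population_response <- function(grid, values) {
  out <- tibble::tibble(channel_deg = grid$theta, activity = values)
  attr(out, "spacing") <- grid$spacing
  class(out) <- c("population_response", class(out))
  out
}

pr_grid <- function(y) {
  structure(list(theta = y$channel_deg, spacing = attr(y, "spacing")),
            class = "orientation_grid")
}

#' Weighted pooling of target and flanker population responses
#'
#' Channelwise weighted sum `(1 - wf) * y_t + wf * y_f`: the crowding stage of
#' the pooling model.
#'
#' @param y_t,y_f [population_response()] objects on identical grids.
#' @param wf Flanker weight in \eqn{[0, 1]}.
#' @return A `population_response` of the pooled activities.
#' @export
pool_responses <- function(y_t, y_f, wf) {
  if (!is.numeric(wf) || wf < 0 || wf > 1) stop("`wf` must lie in [0, 1]")
  if (nrow(y_t) != nrow(y_f) ||
      !isTRUE(all.equal(y_t$channel_deg, y_f$channel_deg))) {
    stop("`y_t` and `y_f` must share the same orientation grid")
  }
  new_population_response(pr_grid(y_t),
                          (1 - wf) * y_t$activity + wf * y_f$activity)
}

#' Noise-only alternative to pooling
#'
#' Adds a fresh smooth Gaussian noise field of magnitude `beta` to the target
#' population response; the flanker identity plays no role.
#'
#' @param y_t A [population_response()].
#' @param beta Noise magnitude (>= 0).
#' @param sigma Smoothing bandwidth of the noise field in degrees.
#' @return A `population_response`.
#' @export
noise_only_response <- function(y_t, beta, sigma = 30) {
  if (!is.numeric(beta) || beta < 0) stop("`beta` must be >= 0")
  g <- pr_grid(y_t)
  vals <- y_t$activity
  if (beta > 0) vals <- vals + beta * smooth_noise_fields(1, g, sigma)[, 1]
  new_population_response(g, vals)
}

#' Maximum-readout decision
#'
#' Returns the orientation of the maximally active channel; exact ties are
#' broken uniformly at random among the tied channels.
#'
#' @param y_c A [population_response()].
#' @return The decided orientation in degrees.
#' @export
decide_orientation <- function(y_c) {
  v <- y_c$activity
  if (length(v) == 0 || anyNA(v) || any(!is.finite(v))) {
    stop("population response must be non-empty and finite")
  }
  idx <- which(v == max(v))
  if (length(idx) > 1) idx <- idx[sample.int(length(idx), 1)]
  y_c$channel_deg[idx]
}

#' Simulate one orientation-matching trial
#'
#' The target sits at 0 on the error axis, so the decided orientation is the
#' response error. For the pooling model the flanker response uses the late
#' noise and the pooled response uses the condition's flanker weight; for the
#' noise-only model the flanked conditions add `beta`-scaled noise instead.
#' Unflanked trials pass the target response through unchanged.
#'
#' @param params A [pooling_params()] or [noise_only_params()] object.
#' @param condition A [flanker_condition()] or its `kind` string.
#' @param sigma Tuning bandwidth in degrees.
#' @param grid An [orientation_grid()].
#' @return The response error in degrees.
#' @export
simulate_trial <- function(params, condition, sigma = 30,
                           grid = orientation_grid()) {
  if (is.character(condition)) condition <- flanker_condition(condition)
  y_t <- population_response(0, sigma = sigma,
                             noise_mag = params$early_noise, grid = grid)
  if (condition$kind == "unflanked") {
    return(decide_orientation(y_t))
  }
  if (inherits(params, "pooling_params")) {
    y_f <- population_response(condition$offset, sigma = sigma,
                               noise_mag = params$late_noise, grid = grid)
    wf <- if (condition$kind == "f30") params$wf30 else params$wf90
    decide_orientation(pool_responses(y_t, y_f, wf))
  } else if (inherits(params, "noise_only_params")) {
    decide_orientation(noise_only_response(y_t, params$beta, sigma = sigma))
  } else {
    stop("unknown parameter object")
  }
}

# Coefficients (a, b, c, d) of the combined response
#   a * target_profile + b * flanker_profile + c * E + d * L
# for one folded condition under either model.
model_coefs <- function(params, kind) {
  if (inherits(params, "pooling_params")) {
    if (kind == "unflanked") {
      c(a = 1, b = 0, c = params$early_noise, d = 0)
    } else {
      wf <- if (kind == "f30") params$wf30 else params$wf90
      c(a = 1 - wf, b = wf, c = (1 - wf) * params$early_noise,
        d = wf * params$late_noise)
    }
  } else if (inherits(params, "noise_only_params")) {
    d <- if (kind == "unflanked") 0 else params$beta
    c(a = 1, b = 0, c = params$early_noise, d = d)
  } else {
    stop("unknown parameter object")
  }
}

# Batch simulation for one folded condition given pre-drawn noise fields.
# Returns response errors in degrees. `fields` is a list with matrices E and
# L (either may be a 0-column matrix when unused).
simulate_errors_batch <- function(params, kind, n_trials, fields,
                                  grid = orientation_grid(), sigma = 30) {
  co <- model_coefs(params, kind)
  st <- tuning_profile(0, grid, sigma = sigma)
  offset <- switch(kind, unflanked = 0, f30 = 30, f90 = 90,
                   stop("unknown condition kind: ", kind))
  sf <- if (kind == "unflanked") numeric(length(st)) else
    tuning_profile(offset, grid, sigma = sigma)
  E <- if (co[["c"]] > 0) fields$E else empty_field(grid)
  L <- if (co[["d"]] > 0) fields$L else empty_field(grid)
  idx <- decide_pool_batch(st, sf, E, L,
                           co[["a"]], co[["b"]], co[["c"]], co[["d"]],
                           as.integer(n_trials))
  grid$theta[idx]
}

empty_field <- function(grid) matrix(0, nrow = length(grid$theta), ncol = 0)

#' Simulate many trials of one flanker condition
#'
#' @param params A [pooling_params()] or [noise_only_params()] object.
#' @param condition A [flanker_condition()] or its `kind` string.
#' @param n_trials Number of trials (>= 1). The model-fitting pipeline uses
#'   1,000 per condition.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @param sigma Tuning bandwidth in degrees.
#' @param grid An [orientation_grid()].
#' @return A numeric vector of `n_trials` response errors in degrees.
#' @export
simulate_condition <- function(params, condition, n_trials = 1000,
                               seed = NULL, sigma = 30,
                               grid = orientation_grid()) {
  stopifnot(n_trials >= 1)
  if (is.character(condition)) condition <- flanker_condition(condition)
  if (!is.null(seed)) set.seed(seed)
  co <- model_coefs(params, condition$kind)
  fields <- list(
    E = if (co[["c"]] > 0) smooth_noise_fields(n_trials, grid, sigma) else
      empty_field(grid),
    L = if (co[["d"]] > 0) smooth_noise_fields(n_trials, grid, sigma) else
      empty_field(grid)
  )
  simulate_errors_batch(params, condition$kind, n_trials, fields,
                        grid = grid, sigma = sigma)
}
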