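#' Generative parameter norms per observer group
#'
#' Means and ranges of the best-fitting pooling-model parameters for each
#' group (adults at four eccentricities in the near periphery; typically
#' developing and amblyopic children at the fovea), used as the sampling
#' distributions for synthetic observers. Adult early-noise means are
#' reported only as a band across eccentricities (0.44-0.47, individual range
#' 0.32-0.64), represented here as mean 0.45 with that range at every
#' eccentricity.
#'
#' @return Tibble with columns `group`, `eccentricity` (`NA` for children),
#'   `param`, `mean`, `lo`, `hi`.
#' @export
cohort_parameter_table <- function() {
  adult <- function(ecc, param, mean, lo, hi) {
    tibble::tibble(group = "adult", eccentricity = ecc, param = param,
                   mean = mean, lo = lo, hi = hi)
  }
  child <- function(group, param, mean, lo, hi) {
    tibble::tibble(group = group, eccentricity = NA_real_, param = param,
                   mean = mean, lo = lo, hi = hi)
  }
  dplyr::bind_rows(
    adult(c(2.5, 5, 10, 15), "early_noise", rep(0.45, 4),
          rep(0.32, 4), rep(0.64, 4)),
    adult(c(2.5, 5, 10, 15), "late_noise", c(1.47, 1.16, 1.01, 1.12),
          c(0.61, 0.51, 0.59, 0.41), c(3.67, 2.49, 2.19, 2.15)),
    adult(c(2.5, 5, 10, 15), "wf30", c(0.48, 0.46, 0.58, 0.55),
          c(0.20, 0.03, 0.35, 0.33), c(0.93, 0.85, 0.91, 0.94)),
    adult(c(2.5, 5, 10, 15), "wf90", c(0.32, 0.43, 0.51, 0.55),
          c(0.05, 0.15, 0.21, 0.18), c(0.79, 0.65, 0.88, 0.94)),
    child("child_typical", "early_noise", 0.80, 0.40, 1.68),
    child("child_typical", "late_noise", 1.62, 0.40, 3.04),
    child("child_typical", "wf30", 0.52, 0.10, 0.85),
    child("child_typical", "wf90", 0.32, 0.05, 0.67),
    child("child_amblyopic", "early_noise", 0.92, 0.40, 2.54),
    child("child_amblyopic", "late_noise", 2.13, 0.79, 4.14),
    child("child_amblyopic", "wf30", 0.53, 0.00, 0.91),
    child("child_amblyopic", "wf90", 0.33, 0.05, 0.86)
  )
}

#' Mean adult peripheral acuity norms
#'
#' Group-mean gap-size (acuity) thresholds for adults at the four tested
#' eccentricities, used to size matching-task stimuli: the matching target
#' uses a gap of 3x acuity, a diameter of 5x the gap, and a center-to-center
#' target-flanker separation of 1.1x the diameter.
#'
#' @return Tibble with `eccentricity` (deg) and `acuity_arcmin`.
#' @export
adult_acuity_norms <- function() {
  tibble::tibble(eccentricity = c(2.5, 5, 10, 15),
                 acuity_arcmin = c(2.32, 3.68, 6.95, 11.36))
}

# Truncated normal on [lo, hi] with SD = range/4 whose *truncated* mean
# equals `target_mean`. Centering the location parameter at the target mean
# would bias the truncated mean for asymmetric ranges, so the location is
# solved for instead.
rtrunc_mean <- function(n, target_mean, lo, hi) {
  s <- (hi - lo) / 4
  tmean <- function(mu) {
    a <- (lo - mu) / s; b <- (hi - mu) / s
    z <- pnorm(b) - pnorm(a)
    mu + s * (dnorm(a) - dnorm(b)) / z
  }
  mu <- uniroot(function(m) tmean(m) - target_mean,
                interval = c(lo - 2 * s, hi + 2 * s), tol = 1e-10)$root
  u <- runif(n, pnorm((lo - mu) / s), pnorm((hi - mu) / s))
  pmin(pmax(mu + s * qnorm(u), lo), hi)
}

#' Sample generative parameters for a synthetic observer
#'
#' Each pooling parameter is drawn independently from a truncated normal
#' honoring the group's printed mean and range (SD = range/4, truncated to
#' the range, location chosen so the truncated mean equals the printed mean).
#'
#' @param group `"adult"`, `"child_typical"` or `"child_amblyopic"`.
#' @param eccentricity Required for adults: one of 2.5, 5, 10, 15 (degrees).
#' @param seed Optional integer seed.
#' @return A [pooling_params()] object.
#' @export
sample_observer_params <- function(group, eccentricity = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  norms <- cohort_parameter_table()
  if (group == "adult") {
    if (is.null(eccentricity) || !eccentricity %in% c(2.5, 5, 10, 15)) {
      stop("adults require `eccentricity` in {2.5, 5, 10, 15}")
    }
    norms <- norms[norms$group == "adult" &
                     norms$eccentricity == eccentricity, ]
  } else if (group %in% c("child_typical", "child_amblyopic")) {
    norms <- norms[norms$group == group, ]
  } else {
    stop("unknown group: ", group)
  }
  draw <- function(p) {
    r <- norms[norms$param == p, ]
    rtrunc_mean(1, r$mean, r$lo, r$hi)
  }
  pooling_params(early_noise = draw("early_noise"),
                 late_noise = draw("late_noise"),
                 wf30 = draw("wf30"), wf90 = draw("wf90"))
}

matching_conditions <- c("unflanked", "+30", "-30", "+90", "-90")

#' Children's orientation-matching trial schedule
#'
#' Twelve trials in each of the five flanker conditions (unflanked, +/-30,
#' +/-90 degrees), 60 trials total, in randomized order, viewed foveally.
#' Target orientations are uniform within +/-45 degrees of vertical.
#'
#' @param seed Optional integer seed.
#' @return Tibble with columns `trial`, `block`, `eccentricity` (`NA`:
#'   foveal), `condition`, `target_deg`.
#' @export
children_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- sample(rep(matching_conditions, each = 12))
  tibble::tibble(
    trial = seq_along(cond), block = 1L, eccentricity = NA_real_,
    condition = cond, target_deg = runif(60, -45, 45)
  )
}

#' Adults' orientation-matching trial schedule
#'
#' Five blocks of 100 trials at each of four eccentricities (2.5, 5, 10, 15
#' degrees), with 20 trials per flanker condition per block: 2,000 trials in
#' total. Trial order is randomized within block.
#'
#' @param seed Optional integer seed.
#' @return Tibble with columns `trial`, `block`, `eccentricity`, `condition`,
#'   `target_deg`.
#' @export
adult_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- tidyr::expand_grid(eccentricity = c(2.5, 5, 10, 15),
                            block = 1:5) |>
    dplyr::rowwise() |>
    dplyr::reframe(condition = sample(rep(matching_conditions, each = 20)),
                   eccentricity = .data$eccentricity, block = .data$block)
  out$target_deg <- runif(nrow(out), -45, 45)
  out$trial <- seq_len(nrow(out))
  out[, c("trial", "block", "eccentricity", "condition", "target_deg")]
}

#' Construct a synthetic observer
#'
#' Bundles a group, generative pooling (or noise-only) parameters, a matching
#' trial schedule and a seed that makes the observer's data reproducible.
#'
#' @param group `"adult"`, `"child_typical"` or `"child_amblyopic"`.
#' @param eccentricity For adults, the single eccentricity this observer's
#'   parameters refer to. The adult schedule still spans all four; see
#'   [generate_dataset()].
#' @param params Optional generative parameters; sampled from the group norms
#'   when `NULL`.
#' @param observer_id Identifier carried into the trial table.
#' @param seed Integer seed controlling sampling and response generation.
#' @return An object of class `simulated_observer`.
#' @export
simulated_observer <- function(group, eccentricity = NULL, params = NULL,
                               observer_id = "obs1", seed = 1) {
  set.seed(seed)
  if (is.null(params)) {
    params <- sample_observer_params(group, eccentricity)
  }
  schedule <- if (group == "adult") {
    s <- adult_schedule()
    if (!is.null(eccentricity)) s[s$eccentricity == eccentricity, ] else s
  } else {
    children_schedule()
  }
  structure(list(observer_id = observer_id, group = group,
                 eccentricity = eccentricity, params = params,
                 schedule = schedule, seed = seed),
            class = "simulated_observer")
}

#' Generate a per-trial response table for a synthetic observer
#'
#' Drives the observer's generative model over its trial schedule. Negative-
#' offset conditions are simulated by negating the flanker offset, so the
#' generative model is mirror symmetric by construction. Reproducible from
#' the observer's seed.
#'
#' @param observer A [simulated_observer()].
#' @return Tibble with columns `observer_id`, `group`, `eccentricity`,
#'   `condition`, `target_deg`, `response_deg`.
#' @export
generate_dataset <- function(observer) {
  stopifnot(inherits(observer, "simulated_observer"))
  set.seed(observer$seed + 1L)
  sched <- observer$schedule
  params <- observer$params
  grid <- orientation_grid()
  err <- numeric(nrow(sched))
  for (cn in unique(sched$condition)) {
    rows <- which(sched$condition == cn)
    kind <- switch(cn, unflanked = "unflanked",
                   "+30" = , "-30" = "f30", "+90" = , "-90" = "f90")
    e <- simulate_condition(params, kind, n_trials = length(rows),
                            grid = grid)
    # mirror-symmetric generation: negative offsets flip the error axis
    if (substr(cn, 1, 1) == "-") e <- wrap_angle(-e)
    err[rows] <- e
  }
  tibble::tibble(
    observer_id = observer$observer_id,
    group = observer$group,
    eccentricity = sched$eccentricity,
    condition = sched$condition,
    target_deg = sched$target_deg,
    response_deg = wrap_angle(sched$target_deg + err)
  )
}
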