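#' Simulated 4AFC psychometric observer
#'
#' Weibull psychometric function for a four-alternative forced-choice task:
#' `p(correct) = 0.25 + (0.75 - lapse) * (1 - exp(-(gap / threshold)^slope))`.
#'
#' @param threshold_arcmin Gap size (arcmin) at the Weibull location (where
#'   the function has risen to ~63% of its range above chance).
#' @param slope Weibull slope (beta).
#' @param lapse Lapse rate in \eqn{[0, 0.05]}.
#' @return An object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(threshold_arcmin, slope = 3.5,
                                  lapse = 0.01) {
  stopifnot(threshold_arcmin > 0, slope > 0, lapse >= 0, lapse <= 0.05)
  structure(list(threshold_arcmin = threshold_arcmin, slope = slope,
                 guess = 0.25, lapse = lapse),
            class = "psychometric_observer")
}

#' Probability of a correct 4AFC response
#'
#' @param gap Gap size(s) in arcmin (> 0).
#' @param observer A [psychometric_observer()].
#' @return Probability of a correct response, monotone increasing in `gap`
#'   from the 0.25 guessing floor.
#' @export
observer_p_correct <- function(gap, observer) {
  if (any(gap <= 0)) stop("`gap` must be positive")
  with(observer,
       guess + (1 - guess - lapse) *
         (1 - exp(-(gap / threshold_arcmin)^slope)))
}

#' Gap size at which an observer reaches a performance level
#'
#' Inverts the observer's psychometric function; this is the quantity a
#' staircase converging at `level` estimates.
#'
#' @param observer A [psychometric_observer()].
#' @param level Target proportion correct (between guess rate and ceiling).
#' @return Gap size in arcmin.
#' @export
gap_at_level <- function(observer, level) {
  rng <- 1 - observer$guess - observer$lapse
  q <- (level - observer$guess) / rng
  if (q <= 0 || q >= 1) stop("`level` outside the observer's range")
  observer$threshold_arcmin * (-log(1 - q))^(1 / observer$slope)
}

# log10 offset from the Weibull location at which the *assumed* psychometric
# function crosses `level` (QUEST places trials and reads thresholds out at
# the staircase's convergence level).
quest_level_offset <- function(level, slope, guess = 0.25, lapse = 0.01) {
  q <- (level - guess) / (1 - guess - lapse)
  log10(-log(1 - q)) / slope
}

#' Tailored QUEST staircase run against a simulated observer
#'
#' Bayesian adaptive staircase over log10 gap size with the tailoring used
#' for testing children: three practice trials at twice a nominal acuity,
#' an easier trial (gap at twice the current threshold estimate) on every
#' fifth trial, and an early exit when the standard deviation of the
#' running threshold estimates over the preceding eight trials falls below
#' 0.03 log units; otherwise the run stops at `max_trials` trials. Practice
#' and easy trials update the posterior. The acuity task converges at 62.5%
#' correct, the crowding-extent task at 80%.
#'
#' @param observer A [psychometric_observer()].
#' @param task `"acuity"` (62.5% convergence) or `"crowding"` (80%).
#' @param nominal_acuity_arcmin Gap size used for the practice trials
#'   (doubled); stands in for the orthoptic acuity estimate.
#' @param seed Optional integer seed.
#' @param max_trials Trial cap excluding practice (default 60).
#' @param prior_sd Prior SD over log10 threshold (log units).
#' @param grain Posterior grid step (log units).
#' @param assumed_slope,assumed_lapse Psychometric shape assumed by the
#'   staircase's likelihood.
#' @return A list of class `quest_run`: `threshold_arcmin` (gap estimate at
#'   the convergence level), `log10_threshold`, `n_trials` (excluding
#'   practice), `exit_status` (`"sd_criterion"` or `"max_trials"`), `level`,
#'   and `history` (tibble: trial, type, gap, correct, estimate).
#' @export
tailored_quest_run <- function(observer, task = c("acuity", "crowding"),
                               nominal_acuity_arcmin = observer$threshold_arcmin,
                               seed = NULL, max_trials = 60,
                               prior_sd = 0.5, grain = 0.002,
                               assumed_slope = 3.5, assumed_lapse = 0.01) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  level <- if (task == "acuity") 0.625 else 0.80
  eps <- quest_level_offset(level, assumed_slope, lapse = assumed_lapse)

  t_guess <- log10(nominal_acuity_arcmin)
  tgrid <- seq(t_guess - 2.5, t_guess + 2.5, by = grain)
  log_post <- dnorm(tgrid, mean = t_guess, sd = prior_sd, log = TRUE)

  p_assumed <- function(x, t) {
    0.25 + (0.75 - assumed_lapse) * (1 - exp(-10^(assumed_slope * (x - t))))
  }
  update <- function(x, correct) {
    p <- p_assumed(x, tgrid)
    log_post <<- log_post + if (correct) log(p) else log1p(-p)
    log_post <<- log_post - max(log_post)
  }
  post_mean <- function() {
    w <- exp(log_post)
    sum(tgrid * w) / sum(w)
  }
  run_trial <- function(gap) runif(1) < observer_p_correct(gap, observer)

  history <- list()
  # three practice trials at twice the nominal acuity
  for (i in 1:3) {
    gap <- 2 * nominal_acuity_arcmin
    correct <- run_trial(gap)
    update(log10(gap), correct)
    history[[length(history) + 1]] <- list(
      trial = i - 4L, type = "practice", gap = gap, correct = correct,
      estimate = 10^(post_mean() + eps))
  }

  estimates <- numeric(0) # running threshold estimates, log10 units
  n <- 0
  exit_status <- "max_trials"
  while (n < max_trials) {
    n <- n + 1
    est_gap <- 10^(post_mean() + eps)
    type <- if (n %% 5 == 0) "easy" else "quest"
    gap <- if (type == "easy") 2 * est_gap else est_gap
    correct <- run_trial(gap)
    update(log10(gap), correct)
    est <- post_mean() + eps
    estimates <- c(estimates, est)
    history[[length(history) + 1]] <- list(
      trial = n, type = type, gap = gap, correct = correct,
      estimate = 10^est)
    if (n >= 8 && sd(utils::tail(estimates, 8)) < 0.03) {
      exit_status <- "sd_criterion"
      break
    }
  }

  final <- post_mean() + eps
  structure(list(
    threshold_arcmin = 10^final, log10_threshold = final,
    n_trials = n, exit_status = exit_status, level = level,
    history = dplyr::bind_rows(lapply(history, tibble::as_tibble))
  ), class = "quest_run")
}

#' Crowding extent from a gap-size threshold
#'
#' The target diameter is five times the gap size and the center-to-center
#' target-flanker separation is 1.1 times the diameter, so the extent is
#' `1.1 * 5 * gap`, converted from arcmin to degrees.
#'
#' @param gap_threshold_arcmin Gap-size threshold in arcmin (> 0).
#' @return Center-to-center separation in degrees of visual angle.
#' @export
crowding_extent_from_gap <- function(gap_threshold_arcmin) {
  if (any(gap_threshold_arcmin <= 0)) stop("gap threshold must be positive")
  1.1 * 5 * gap_threshold_arcmin / 60
}

#' Matching-task size-selection rule
#'
#' Stimuli in the matching task aim for a gap size of 3x the acuity
#' threshold, falling back to 2.5x, 2x or 1.5x where the implied
#' target-flanker separation (1.1 x 5 x gap) would exceed the observer's
#' crowding extent. If even 1.5x exceeds the extent, 1.5 is returned with a
#' warning.
#'
#' @param acuity_gap_arcmin Acuity gap-size threshold in arcmin (> 0).
#' @param extent_deg Crowding extent in degrees (> 0).
#' @return The selected multiplier: 3, 2.5, 2 or 1.5.
#' @export
matching_size_rule <- function(acuity_gap_arcmin, extent_deg) {
  if (acuity_gap_arcmin <= 0 || extent_deg <= 0) {
    stop("inputs must be positive")
  }
  for (m in c(3, 2.5, 2, 1.5)) {
    if (crowding_extent_from_gap(m * acuity_gap_arcmin) <= extent_deg) {
      return(m)
    }
  }
  warning("crowding extent below even the 1.5x separation; using 1.5")
  1.5
}
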