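# Independent oracles and small fixture builders used across the suite.

# Brute-force argmax of the analytic noiseless pooled profile on a dense
# orientation grid (independent of the package's channel machinery).
brute_pooled_argmax <- function(wf, offset, sigma = 30, step = 0.01) {
  th <- seq(-180, 180 - step, by = step)
  d0 <- pmin(abs(th), 360 - abs(th))
  d1 <- pmin(abs(th - offset), 360 - abs(th - offset))
  f <- (1 - wf) * exp(-d0^2 / (2 * sigma^2)) +
    wf * exp(-d1^2 / (2 * sigma^2))
  th[which.max(f)]
}

# Histograms for all three folded conditions simulated from given params.
simulated_histograms <- function(params, n_per_cond, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(lapply(c("unflanked", "f30", "f90"), function(k)
    bin_errors(simulate_condition(params, k, n_per_cond), condition = k)))
}

# Local maxima of a 36-bin circular histogram (indices of bins strictly
# greater than both circular neighbours after light smoothing).
circular_modes <- function(prop, min_height = 0.02) {
  sm <- (prop + c(prop[-1], prop[1]) + c(prop[36], prop[-36])) / 3
  nxt <- c(sm[-1], sm[1]); prv <- c(sm[36], sm[-36])
  which(sm >= nxt & sm > prv & sm >= min_height)
}
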