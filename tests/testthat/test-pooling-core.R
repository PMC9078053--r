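test_that("noiseless tuning profile matches the closed-form Gaussian", {
  y <- population_response(0, sigma = 30, alpha = 1, noise_mag = 0)
  expect_equal(y$activity[y$channel_deg == 0], 1) # peak height alpha
  expect_equal(y$activity[y$channel_deg == 30], exp(-0.5), tolerance = 1e-12)
  expect_equal(y$activity[y$channel_deg == -30], exp(-0.5), tolerance = 1e-12)
  # circular distance: value at -180 equals value at distance 180
  expect_equal(y$activity[y$channel_deg == -180],
               exp(-180^2 / (2 * 30^2)), tolerance = 1e-12)
  expect_error(population_response(0, sigma = -1), "sigma")
  expect_error(population_response(0, sigma = 0), "sigma")
})

test_that("pooling is the channelwise weighted sum with identity edge cases", {
  y_t <- population_response(0)
  y_f <- population_response(30)
  expect_equal(pool_responses(y_t, y_f, 0)$activity, y_t$activity)
  expect_equal(pool_responses(y_t, y_f, 1)$activity, y_f$activity)
  yc <- pool_responses(y_t, y_f, 0.5)
  expect_equal(yc$activity, 0.5 * y_t$activity + 0.5 * y_f$activity)
  expect_equal(decide_orientation(yc), 15) # symmetric midpoint
  y5 <- population_response(0, grid = orientation_grid(5))
  expect_error(pool_responses(y_t, y5, 0.5), "grid")
  expect_error(pool_responses(y_t, y_f, 1.5), "wf")
})

test_that("noise-only response ignores flankers and approaches uniformity at large beta", {
  y_t <- population_response(0)
  expect_equal(noise_only_response(y_t, 0)$activity, y_t$activity)
  # beta = 100 drowns the signal: decided orientations ~ uniform over bins
  set.seed(42)
  p <- noise_only_params(early_noise = 0, beta = 100)
  err <- simulate_condition(p, "f90", n_trials = 10000)
  counts <- bin_errors(err)$count
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("decision stage returns the argmax and breaks exact ties uniformly", {
  y <- population_response(7, noise_mag = 0)
  expect_equal(decide_orientation(y), 7)

  # two exactly equal maxima at 0 and 90
  g <- orientation_grid()
  v <- numeric(360)
  v[g$theta == 0] <- 1; v[g$theta == 90] <- 1
  tie <- crowdpool:::new_population_response(g, v)
  set.seed(1)
  picks <- replicate(400, decide_orientation(tie))
  expect_setequal(unique(picks), c(0, 90))
  expect_gt(mean(picks == 0), 0.4)
  expect_lt(mean(picks == 0), 0.6)

  bad <- crowdpool:::new_population_response(g, rep(NA_real_, 360))
  expect_error(decide_orientation(bad), "finite")
})

test_that("noiseless trials are deterministic: assimilation midpoint and zero errors", {
  p <- pooling_params(0, 0, wf30 = 0.5, wf90 = 0.5)
  expect_equal(simulate_trial(p, "f30"), 15)
  p0 <- pooling_params(0, 0, wf30 = 0, wf90 = 0)
  for (k in c("unflanked", "f30", "f90")) {
    expect_equal(simulate_trial(p0, k), 0)
  }
  n0 <- noise_only_params(0, 0)
  for (k in c("unflanked", "f30", "f90")) {
    expect_equal(simulate_trial(n0, k), 0)
  }
  # target peak dominates when wf90 < 0.5: readout stays by the target
  p34 <- pooling_params(0, 0, wf30 = 0.34, wf90 = 0.34)
  got <- simulate_trial(p34, "f90")
  expect_lte(abs(got - brute_pooled_argmax(0.34, 90)), 0.51)
  expect_lt(abs(got), 5)
})

test_that("simulate_condition returns n reproducible errors", {
  p <- pooling_params(0.45, 1.0, 0.5, 0.4)
  e1 <- simulate_condition(p, "f30", n_trials = 1000, seed = 3)
  e2 <- simulate_condition(p, "f30", n_trials = 1000, seed = 3)
  expect_length(e1, 1000)
  expect_identical(e1, e2)
  # degenerate noiseless case: every error is the midpoint
  pn <- pooling_params(0, 0, wf30 = 0.5, wf90 = 0.5)
  expect_true(all(simulate_condition(pn, "f30", 50) == 15))
})

test_that("noiseless pooled argmax matches the dense-grid analytic oracle", {
  for (offset in c(30, 90)) {
    kind <- if (offset == 30) "f30" else "f90"
    for (wf in seq(0, 1, by = 0.1)) {
      p <- pooling_params(0, 0, wf30 = wf, wf90 = wf)
      got <- simulate_trial(p, kind)
      oracle <- brute_pooled_argmax(wf, offset)
      if (offset == 90 && abs(wf - 0.5) < 1e-9) {
        # two tied, mirror-image global maxima: either is a valid readout
        expect_true(abs(got - oracle) <= 0.51 ||
                      abs((90 - got) - oracle) <= 0.51)
      } else {
        expect_lte(abs(got - oracle), 0.51) # within channel resolution
      }
    }
  }
  expect_equal(simulate_trial(pooling_params(0, 0, 0.5, 0.5), "f30"), 15)
})

test_that("30-degree pooled profile is unimodal with argmax monotone in wf", {
  prev <- -Inf
  for (wf in seq(0, 1, by = 0.05)) {
    y <- pool_responses(population_response(0), population_response(30), wf)
    v <- y$activity
    peak <- decide_orientation(y)
    expect_gte(peak, prev)
    prev <- peak
    expect_gte(peak, 0); expect_lte(peak, 30)
    # unimodal: activity non-increasing with circular distance from the peak
    modes <- sum(v > c(v[-1], v[1]) & v > c(v[360], v[-360]))
    expect_equal(modes, 1)
  }
})

test_that("90-degree flanker-side response mass is non-decreasing in wf90", {
  masses <- vapply(c(0.2, 0.35, 0.5, 0.65), function(wf) {
    p <- pooling_params(0.45, 1.0, 0.5, wf)
    err <- simulate_condition(p, "f90", n_trials = 3000, seed = 11)
    mean(err > 45 & err <= 135)
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("noiseless decisions shift with the stimulus orientation (circular symmetry)", {
  for (mu in c(-180, -170, -45, 0, 13, 90, 179)) {
    y <- population_response(mu, noise_mag = 0)
    expect_equal(wrap_angle(decide_orientation(y) - mu), 0)
  }
  # shifting mu by a multiple of the spacing shifts the profile exactly
  y0 <- population_response(0)$activity
  y37 <- population_response(37)$activity
  expect_equal(y37, y0[((seq_len(360) - 1 - 37) %% 360) + 1])
})

test_that("batch C++ decision path agrees with an R argmax on shared noise fields", {
  grid <- orientation_grid()
  set.seed(99)
  n <- 50
  E <- smooth_noise_fields(n, grid)
  L <- smooth_noise_fields(n, grid)
  p <- pooling_params(0.45, 1.0, wf30 = 0.5, wf90 = 0.4)
  co <- crowdpool:::model_coefs(p, "f30")
  st <- crowdpool:::tuning_profile(0, grid)
  sf <- crowdpool:::tuning_profile(30, grid)
  got <- crowdpool:::simulate_errors_batch(p, "f30", n, list(E = E, L = L),
                                           grid = grid)
  M <- co[["a"]] * st + co[["b"]] * sf
  want <- vapply(seq_len(n), function(i) {
    grid$theta[which.max(M + co[["c"]] * E[, i] + co[["d"]] * L[, i])]
  }, numeric(1))
  expect_equal(got, want)
})

test_that("smooth noise fields have unit variance and the tuning correlation length", {
  set.seed(5)
  F <- smooth_noise_fields(400, orientation_grid())
  expect_equal(sd(as.vector(F)), 1, tolerance = 0.03)
  # channels 30 deg apart correlate like the kernel autocorrelation, far ones do not
  r30 <- cor(F[1, ], F[31, ])
  r180 <- cor(F[1, ], F[181, ])
  expect_gt(r30, 0.4)
  expect_lt(abs(r180), 0.2)
})
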