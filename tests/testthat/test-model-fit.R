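# Noiseless generating parameters give degenerate (deterministic) data, so
# the objective at the truth is exactly zero: a self-match oracle.
noiseless_truth <- pooling_params(0, 0, wf30 = 0.5, wf90 = 0.4)
noiseless_hist <- simulated_histograms(noiseless_truth, 100, seed = 1)

test_that("objective is deterministic under a fixed seed and zero at a noiseless self-match", {
  v1 <- objective(noiseless_hist, c(0, 0, 0.5, 0.4), "pooling4",
                  sim_n = 400, seed = 5)
  v2 <- objective(noiseless_hist, c(0, 0, 0.5, 0.4), "pooling4",
                  sim_n = 400, seed = 5)
  expect_identical(v1, v2)
  expect_equal(v1, 0)

  # out-of-bounds parameters are clamped with a penalty, not an error
  v3 <- objective(noiseless_hist, c(0, 0, 1.4, 0.4), "pooling4",
                  sim_n = 400, seed = 5)
  expect_gt(v3, objective(noiseless_hist, c(0, 0, 1, 0.4), "pooling4",
                          sim_n = 400, seed = 5))
  expect_equal(objective(noiseless_hist, c(NA, 0, 0.5, 0.4), "pooling4",
                         sim_n = 400, seed = 5), 1e6)
})

test_that("objective at the generating parameters beats strongly perturbed weights", {
  set.seed(20)
  truth <- pooling_params(0.45, 1.0, 0.5, 0.4)
  hist <- simulated_histograms(truth, 200)
  diffs <- vapply(1:20, function(s) {
    objective(hist, c(0.45, 1.0, 0.5, 0.4), "pooling4", sim_n = 500,
              seed = s) -
      objective(hist, c(0.45, 1.0, 0.9, 0.8), "pooling4", sim_n = 500,
                seed = s)
  }, numeric(1))
  expect_lt(median(diffs), 0)
})

test_that("coarse grid search returns the factorial minimum (first on ties)", {
  single <- list(early_noise = 0.3, late_noise = 1, wf30 = 0.5, wf90 = 0.4)
  got <- coarse_grid_fit(noiseless_hist, "pooling4", grid_spec = single,
                         sim_n = 200, seed = 2)
  expect_equal(unname(got[1:4]), c(0.3, 1, 0.5, 0.4))

  # noiseless self-consistency: a grid containing the truth recovers the
  # identifiable weight exactly (wf90 < 0.5 is degenerate without noise:
  # every such weight leaves the readout at the target)
  gs <- list(early_noise = 0, late_noise = 0,
             wf30 = seq(0, 1, 0.25), wf90 = seq(0, 1, 0.2))
  best <- coarse_grid_fit(noiseless_hist, "pooling4", grid_spec = gs,
                          sim_n = 300, seed = 2)
  expect_equal(best[["wf30"]], 0.5)
  expect_lt(best[["wf90"]], 0.5)
  expect_equal(attr(best, "lse"), 0)

  expect_error(coarse_grid_fit(noiseless_hist, "pooling4",
                               grid_spec = c(single[-1],
                                             list(early_noise = numeric(0))),
                               sim_n = 100, seed = 2), "names")
})

test_that("simplex refinement never degrades the initialization", {
  init <- c(early_noise = 0, late_noise = 0, wf30 = 0.5, wf90 = 0.4)
  expect_warning(
    fit0 <- refine_fit(noiseless_hist, init, "pooling4", sim_n = 300,
                       seed = 2, maxit = 40),
    "-Inf") # a perfect noiseless fit degenerates the AIC, by design
  expect_identical(fit0$aic, -Inf)
  expect_equal(fit0$lse, 0)
  expect_equal(unname(fit0$par), unname(init))

  set.seed(21)
  truth <- pooling_params(0.45, 1.0, 0.5, 0.4)
  hist <- simulated_histograms(truth, 200)
  init2 <- c(early_noise = 0.5, late_noise = 1.4, wf30 = 0.7, wf90 = 0.2)
  fit <- refine_fit(hist, init2, "pooling4", sim_n = 400, seed = 9,
                    maxit = 150)
  expect_lte(fit$lse, fit$init_lse)
  expect_true(all(fit$par[c("wf30", "wf90")] >= 0 &
                    fit$par[c("wf30", "wf90")] <= 1))
})

test_that("AIC follows the least-squares form n log(LSE/n) + 2k", {
  expect_equal(aic_from_lse(1.0, 4), 108 * log(1 / 108) + 8)
  # equal LSE: four parameters cost exactly 4 AIC over two
  expect_equal(aic_from_lse(0.37, 4) - aic_from_lse(0.37, 2), 4)
  # monotone in LSE at fixed k
  ls <- c(0.01, 0.05, 0.2, 1, 3)
  expect_true(all(diff(vapply(ls, aic_from_lse, numeric(1), k = 3)) > 0))
  expect_warning(v <- aic_from_lse(0, 2), "-Inf")
  expect_identical(v, -Inf)
})

test_that("fit_and_compare ranks models and reports antisymmetric AIC differences", {
  set.seed(31)
  truth <- pooling_params(0.45, 1.2, 0.6, 0.35)
  hist <- simulated_histograms(truth, 200)
  cmp <- fit_and_compare(hist, models = c("pooling4", "noise2"),
                         sim_n = 500, seed = 14, maxit = 100)
  expect_named(cmp$fits, c("pooling4", "noise2"))
  tab <- tidy(cmp)
  expect_equal(nrow(tab), 2)
  d <- diff(tab$aic)
  expect_equal(tab$aic[2] - tab$aic[1], d) # antisymmetry is definitional
  expect_equal(cmp$winner, "pooling4")     # pooling data favor pooling
  expect_equal(min(tab$delta_aic), 0)

  f <- cmp$fits$pooling4
  td <- tidy(f)
  expect_equal(td$term, c("early_noise", "late_noise", "wf30", "wf90"))
  gl <- glance(f)
  expect_equal(gl$k, 4)
  expect_equal(gl$lse, f$lse)
})

test_that("model envelope brackets the data-generating proportions", {
  p <- pooling_params(0.45, 1.0, 0.5, 0.4)
  env <- model_envelope(p, n_iter = 300, trials_per_iter = 500,
                        p_sim_n = 4000, seed = 6)
  expect_equal(nrow(env), 108)
  expect_true(all(env$lo <= env$mean & env$mean <= env$hi))
  # per-condition proportions integrate to ~1
  tot <- tapply(env$mean, env$condition, sum)
  expect_true(all(abs(tot - 1) < 0.02))
})
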