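test_that("errors are circular differences wrapped to (-180, 180]", {
  expect_equal(compute_error(10, 0), 10)
  expect_equal(compute_error(45, 30), 15)
  expect_equal(compute_error(-179, 179), 2) # wraparound forced by circularity
  expect_equal(compute_error(179, -179), -2)
  expect_equal(compute_error(0, 180), 180)  # antipode maps to +180
})

test_that("sign folding reverses negative-offset conditions only", {
  expect_equal(fold_sign(-12, "-"), 12)
  expect_equal(fold_sign(-12, "+"), -12)
  expect_equal(fold_sign(-12, "none"), -12)
  expect_equal(fold_sign(180, "-"), 180) # -180 wraps back to +180

  # folding a mirror-symmetric dataset gives two identical error lists
  set.seed(8)
  err_pos <- round(runif(500, -179, 180))
  err_neg <- wrap_angle(-err_pos)
  expect_equal(sort(fold_sign(err_pos, "+")), sort(fold_sign(err_neg, "-")))
})

test_that("binning follows the 36-bin half-open convention and conserves counts", {
  h <- bin_errors(15)
  expect_equal(nrow(h), 36)
  expect_equal(h$count[h$bin_left == 10], 1)
  expect_equal(sum(h$count), 1)

  # edges: left-closed, right-open; +180 wraps into the [-180, -170) bin
  h2 <- bin_errors(c(10, 19.999, 20, -180, 180, 179.9))
  expect_equal(h2$count[h2$bin_left == 10], 2)
  expect_equal(h2$count[h2$bin_left == 20], 1)
  expect_equal(h2$count[h2$bin_left == -180], 2)
  expect_equal(h2$count[h2$bin_left == 170], 1)

  set.seed(3)
  e <- runif(1234, -179.99, 180)
  hh <- bin_errors(e)
  expect_equal(sum(hh$count), 1234)           # lossless
  expect_equal(sum(hh$proportion), 1, tolerance = 1e-9)

  h0 <- bin_errors(numeric(0))
  expect_true(all(h0$count == 0))
  expect_true(all(is.nan(h0$proportion)))
})

test_that("boxcar smoothing is circular, mass-preserving, and uniform-invariant", {
  u <- bin_errors(seq(-175, 175, by = 10)) # one count per bin
  expect_equal(boxcar_smooth(u)$proportion, u$proportion)

  # unit mass spreads 1/3 to each circular neighbour, including across the seam
  h <- bin_errors(-175)
  s <- boxcar_smooth(h)
  expect_equal(s$proportion[1], 1 / 3)
  expect_equal(s$proportion[2], 1 / 3)
  expect_equal(s$proportion[36], 1 / 3)
  expect_equal(sum(s$proportion), sum(h$proportion), tolerance = 1e-12)

  # repeated smoothing flattens unimodal histograms monotonically
  set.seed(2)
  hh <- bin_errors(rnorm(2000, 0, 25))
  peaks <- numeric(6)
  for (i in 1:6) {
    peaks[i] <- max(hh$proportion)
    hh <- boxcar_smooth(hh)
  }
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("least-squares error compares proportion histograms across conditions", {
  set.seed(4)
  a <- dplyr::bind_rows(lapply(c("unflanked", "f30", "f90"), function(k)
    bin_errors(runif(100, -179, 180), condition = k)))
  expect_equal(lse(a, a), 0)

  b <- dplyr::bind_rows(lapply(c("unflanked", "f30", "f90"), function(k)
    bin_errors(runif(100, -179, 180), condition = k)))
  expect_equal(lse(a, b), lse(b, a))

  # two bins of one condition differing by 0.1 each -> 2 * 0.01
  d <- a
  i <- which(d$condition == "f30")[1:2]
  d$proportion[i] <- d$proportion[i] + c(0.1, -0.1)
  expect_equal(lse(a, d), 0.02, tolerance = 1e-12)

  only2 <- a[a$condition != "f90", ]
  expect_error(lse(a, only2), "conditions")
})

test_that("fold_trials maps the five presentation conditions onto three folded ones", {
  tr <- tibble::tibble(
    condition = c("unflanked", "+30", "-30", "+90", "-90"),
    target_deg = c(0, 10, 10, -20, -20),
    response_deg = c(5, 22, -2, 70, -110)
  )
  f <- fold_trials(tr)
  expect_equal(f$condition_folded,
               c("unflanked", "f30", "f30", "f90", "f90"))
  expect_equal(f$error_deg, c(5, 12, 12, 90, 90))
  expect_error(fold_trials(dplyr::mutate(tr, condition = "+45")),
               "unknown condition")

  h <- matching_histograms(f)
  expect_equal(sort(unique(h$condition)), c("f30", "f90", "unflanked"))
  expect_equal(sum(h$count), nrow(tr))
})
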