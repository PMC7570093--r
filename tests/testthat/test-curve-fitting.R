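test_that("r_squared matches hand-computed cases and rejects degenerate input", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 3)), 0.5)   # SSE=1, SST=2
  expect_error(r_squared(c(1, 1, 1), c(1, 1, 2)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("noiseless Gordon-Taylor data are refit exactly", {
  gt <- gt_params(65.2, 4.68)
  d <- noiseless_dataset(gt = gt, tg_ws = c(0.80, 0.85, 0.90, 0.95, 1.0))
  f <- fit_gordon_taylor(d)
  expect_true(f$converged)
  expect_equal(f$params$tgs, 65.2, tolerance = 1e-6)
  expect_equal(f$params$k, 4.68, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("noiseless Chen data are refit exactly, including the extreme printed parameter sets", {
  for (pars in list(c(0.0954, 0.1668), c(0.0085, 0.1595))) {
    ch <- chen_params(pars[1], pars[2])
    d <- noiseless_dataset(chen = ch, tm_ws = seq(0.1, 0.7, by = 0.1))
    f <- fit_chen(d)
    expect_true(f$converged)
    expect_equal(f$params$e, pars[1], tolerance = 1e-6)
    expect_equal(f$params$b, pars[2], tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("random parameter draws inside the observed ranges are recovered from noiseless data", {
  set.seed(21)
  for (i in 1:100) {
    gt <- gt_params(runif(1, 10, 160), runif(1, 2.9, 10.4))
    ch <- chen_params(runif(1, 0.008, 0.111), runif(1, 0.05, 0.30))
    d <- noiseless_dataset(gt = gt, chen = ch)
    fg <- fit_gordon_taylor(d)
    fc <- fit_chen(d)
    expect_equal(fg$params$tgs, gt$tgs, tolerance = 1e-6)
    expect_equal(fg$params$k, gt$k, tolerance = 1e-6)
    expect_equal(fc$params$e, ch$e, tolerance = 1e-6)
    expect_equal(fc$params$b, ch$b, tolerance = 1e-6)
  }
})

test_that("the fitted optimum is never worse than the generating parameters", {
  set.seed(22)
  for (i in 1:20) {
    gt <- gt_params(runif(1, 10, 160), runif(1, 2.9, 10.4))
    ch <- chen_params(runif(1, 0.008, 0.111), runif(1, 0.05, 0.30))
    d <- noiseless_dataset(gt = gt, chen = ch)
    d$tg_points$tg <- d$tg_points$tg + rnorm(6, 0, 1)
    d$tm_points$tm <- d$tm_points$tm + rnorm(6, 0, 1)
    fg <- fit_gordon_taylor(d)
    sse_truth_g <- sum((gordon_taylor_tg(d$tg_points$ws, gt) - d$tg_points$tg)^2)
    expect_lte(fg$sse, sse_truth_g + 1e-8)
    fc <- fit_chen(d)
    sse_truth_c <- sum((chen_tm(d$tm_points$ws, ch) - d$tm_points$tm)^2)
    expect_lte(fc$sse, sse_truth_c + 1e-8)
  }
})

test_that("noisy Gordon-Taylor estimates are unbiased within Monte-Carlo spread", {
  truth <- gt_params(10.4, 2.90)
  grid <- seq(0.75, 1, length.out = 10)
  tgs_h <- k_h <- numeric(200)
  for (s in 1:200) {
    set.seed(s)
    tg <- gordon_taylor_tg(grid, truth) + rnorm(10, 0, 1)
    f <- fit_gordon_taylor(thermal_dataset("m", tg_points = data.frame(ws = grid, tg = tg)))
    tgs_h[s] <- f$params$tgs
    k_h[s] <- f$params$k
  }
  # >= 90% of estimates within 3 Monte-Carlo sd of truth
  expect_gte(mean(abs(tgs_h - 10.4) < 3 * sd(tgs_h)), 0.90)
  expect_gte(mean(abs(k_h - 2.90) < 3 * sd(k_h)), 0.90)
  # and the spread itself is small at 1 degC noise
  expect_lt(sd(tgs_h), 2)
  expect_lt(sd(k_h), 0.2)
})

test_that("degenerate or underdetermined fit inputs error", {
  d <- thermal_dataset("x", tg_points = data.frame(ws = rep(0.9, 4), tg = 1:4))
  expect_error(fit_gordon_taylor(d), "degenerate")
  d2 <- thermal_dataset("x", tm_points = data.frame(ws = c(0.1, 0.2), tm = c(-1, -3)))
  expect_error(fit_chen(d2), "at least 3")
  expect_error(fit_gordon_taylor(thermal_dataset("x")), "at least 3")
  # all data beyond any admissible freezing-curve domain
  d3 <- thermal_dataset("x", tm_points = data.frame(ws = c(0.99999, 0.999999, 1),
                                                    tm = c(-40, -50, -60)))
  expect_error(fit_chen(d3), "domain")
})
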