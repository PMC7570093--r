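test_that("average_transition is the plain mean and rejects empty input", {
  expect_equal(average_transition(-42.8), -42.8)
  expect_equal(average_transition(c(-48.3, -42.3)), -45.3)
  expect_error(average_transition(numeric()), "non-empty")
  expect_error(average_transition(c(-40, NA)), "non-empty numeric")
})

test_that("solve_ws_prime reproduces the printed maximal-freeze-concentration fractions", {
  # |solved - printed| <= 0.001 (3-decimal rounding) for every row except
  # experiment 5, whose printed ws' is inconsistent with its own (E, B, Tm')
  # by ~0.004 regardless of solver
  for (i in setdiff(ref_fixtures$parameters$experiment, 5)) {
    r <- ref_params(i)
    ws <- solve_ws_prime(r$chen, r$tm_prime)
    expect_lt(abs(ws - r$ws_prime), 0.001)
  }
  r5 <- ref_params(5)
  expect_lt(abs(solve_ws_prime(r5$chen, r5$tm_prime) - r5$ws_prime), 0.005)
})

test_that("solve_ws_prime inverts the freezing curve to high precision", {
  set.seed(31)
  for (i in 1:50) {
    ch <- chen_params(runif(1, 0.005, 0.2), runif(1, 0, 0.4))
    t <- runif(1, -60, -1)
    ws <- solve_ws_prime(ch, t)
    expect_equal(chen_tm(ws, ch), t, tolerance = 1e-6)
    expect_true(ws > 0 && ws < chen_ws_max(ch))
  }
})

test_that("ws' decreases strictly as Tm' rises (less depression, less concentration)", {
  ch <- chen_params(0.0954, 0.1668)
  tms <- seq(-50, -5, length.out = 12)
  ws <- vapply(tms, function(t) solve_ws_prime(ch, t), numeric(1))
  expect_true(all(diff(ws) < 0))
})

test_that("solve_ws_prime rejects temperatures without freezing-point depression", {
  ch <- chen_params(0.0954, 0.1668)
  expect_error(solve_ws_prime(ch, 0), "below tw")
  expect_error(solve_ws_prime(ch, 2), "below tw")
})

test_that("build_state_diagram assembles a consistent diagram from fits and observations", {
  r <- ref_params(3)
  d <- noiseless_dataset(gt = r$gt, chen = r$chen)
  dg <- build_state_diagram(fit_gordon_taylor(d), fit_chen(d),
                            tg_prime_obs = r$tg_prime,
                            tm_prime_obs = r$tm_prime)
  expect_s3_class(dg, "state_diagram")
  expect_equal(dg$mfcc$ws_prime, 0.796, tolerance = 1e-3)
  expect_equal(chen_tm(dg$mfcc$ws_prime, dg$chen), dg$mfcc$tm_prime,
               tolerance = 1e-6)
  # missing Tm' observations are fatal; missing Tg' is not
  expect_error(build_state_diagram(fit_gordon_taylor(d), fit_chen(d),
                                   tm_prime_obs = numeric()),
               "tm_prime")
  dg2 <- build_state_diagram(fit_gordon_taylor(d), fit_chen(d),
                             tm_prime_obs = r$tm_prime)
  expect_true(is.na(dg2$mfcc$tg_prime))
})

test_that("a noiseless round trip reproduces the generating MFCC", {
  r <- ref_params(6)
  ws_p <- 0.79
  tm_p <- chen_tm(ws_p, r$chen)
  d <- noiseless_dataset(gt = r$gt, chen = r$chen)
  dg <- build_state_diagram(fit_gordon_taylor(d), fit_chen(d),
                            tg_prime_obs = -46.6, tm_prime_obs = tm_p)
  expect_equal(dg$mfcc$ws_prime, ws_p, tolerance = 1e-6)
  expect_equal(dg$mfcc$tm_prime, tm_p)
  expect_equal(dg$mfcc$tg_prime, -46.6)
})

test_that("the curve table covers [0,1] and blanks the freezing curve beyond its domain", {
  r <- ref_params(1)
  dg <- state_diagram(r$gt, r$chen,
                      mfcc(r$tg_prime, r$tm_prime,
                           solve_ws_prime(r$chen, r$tm_prime)))
  t2 <- tabulate_curves(dg, 2)
  expect_equal(t2$ws, c(0, 1))
  tab <- tabulate_curves(dg, 101)
  expect_equal(nrow(tab), 101)
  mid <- tab[tab$ws == 0.5, ]
  expect_equal(mid$tg, gordon_taylor_tg(0.5, r$gt))
  expect_equal(mid$tm, chen_tm(0.5, r$chen))
  beyond <- tab$ws > chen_ws_max(r$chen)
  expect_true(all(is.na(tab$tm[beyond])))
  expect_true(all(is.finite(tab$tg)))
})

test_that("state_diagram enforces MFCC/freezing-curve consistency unless disabled", {
  r <- ref_params(1)
  expect_error(state_diagram(r$gt, r$chen, mfcc(-55.9, -42.8, 0.80)),
               "inconsistent")
  dg <- state_diagram(r$gt, r$chen, mfcc(-55.9, -42.8, 0.80), check = FALSE)
  expect_s3_class(dg, "state_diagram")
  expect_error(mfcc(-10, -42.8, 0.7), "must not exceed")
  m4 <- mfcc(-9.5, -9.5, 0.801)   # Tg' = Tm' when undetected-but-printed
  expect_equal(m4$tg_prime, m4$tm_prime)
})
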