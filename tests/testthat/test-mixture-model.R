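test_that("the candidate term set has 6 linear and 15 pairwise terms", {
  expect_length(mixture_linear_terms(), 6)
  expect_length(mixture_interaction_terms(), 15)
  expect_length(all_mixture_terms(), 21)
  expect_equal(all_mixture_terms()[7], "XFXG")   # pairwise order follows the polynomial
})

test_that("design_matrix builds product columns and never an intercept", {
  M <- design_matrix(ref_fixtures$design)
  expect_equal(dim(M), c(25L, 21L))
  # pure-fructose vertex: XF column 1, everything else 0
  expect_equal(unname(M[1, "XF"]), 1)
  expect_equal(unname(sum(M[1, colnames(M) != "XF"])), 0)
  # interior blend: product column is the elementwise product
  expect_equal(unname(M[5, "XFXP"]), 0.283 * 0.075)
  expect_equal(unname(M[5, "XFXP"]), 0.021225)
  # any run with no maltodextrin has a zero XGXM column
  expect_true(all(M[ref_fixtures$design$XM == 0, "XGXM"] == 0))
  expect_error(design_matrix(ref_fixtures$design, c("XF", "XQXZ")), "unknown term")
})

test_that("no-intercept least squares interpolates noiseless responses exactly", {
  truth <- c(XF = -43, XG = -42, XS = -33, XP = -73, XA = 14, XM = -11,
             XPXM = 134.61, XAXM = -172.4)
  y <- as.numeric(design_matrix(ref_fixtures$design, names(truth)) %*% truth)
  m <- fit_mixture_model(ref_fixtures$design, y, names(truth))
  expect_equal(unname(m$coefficients), unname(truth), tolerance = 1e-8)
  expect_equal(m$anova$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$anova$sd, 0, tolerance = 1e-8)
  expect_equal(m$anova$cv, 0, tolerance = 1e-8)
  expect_equal(m$anova$p_value, 0)
})

test_that("refitting the printed onset-of-melting model reproduces its coefficients and ANOVA", {
  terms <- ref_fixtures$models$tm_prime$terms
  y <- ref_fixtures$parameters$tm_prime
  m <- fit_mixture_model(ref_fixtures$design, y, terms, "tm_prime")
  expect_equal(unname(m$coefficients[["XF"]]), -42.92, tolerance = 0.01)
  expect_equal(m$anova$r_squared, 0.994, tolerance = 0.001)
  expect_equal(m$anova$cv, 2.02, tolerance = 0.01)
  expect_equal(m$anova$sd, 0.69, tolerance = 0.01)
  expect_lt(m$anova$p_value, 1e-4)
})

test_that("underdetermined or rank-deficient mixture fits error informatively", {
  small <- ref_fixtures$design[1:5, ]
  expect_error(fit_mixture_model(small, rnorm(5), mixture_linear_terms()),
               "underdetermined")
  expect_error(fit_mixture_model(ref_fixtures$design, rnorm(24)),
               "one response per design run")
  expect_error(anova_stats(ref_fixtures$models$tm_prime, ref_fixtures$design,
                           rep(1, 25)), "zero variance")
})

test_that("backward pruning keeps linear terms, drops only nonsignificant interactions", {
  lin <- stats::setNames(c(-43, -42, -33, -73, 14, -11), mixture_linear_terms())
  # a strong pectin-maltodextrin interaction with low noise is always kept
  kept <- 0L
  for (s in 1:20) {
    y <- generate_design_study(uniform_models(c(lin, XPXM = 134.61)),
                               ref_fixtures$design, noise_sd = 0.01,
                               seed = 100 + s)$tgs
    m <- prune_model(ref_fixtures$design, y)
    expect_true(all(mixture_linear_terms() %in% m$terms))
    ints <- m$coef_table[!(m$coef_table$term %in% mixture_linear_terms()), ]
    if (nrow(ints)) expect_true(all(ints$p <= 0.10))
    dfres <- m$n_obs - length(m$terms)
    expect_true(dfres >= 25 - 21 && dfres <= 25 - 6)
    if ("XPXM" %in% m$terms) kept <- kept + 1L
  }
  expect_gte(kept, 18L)
  # linear-only responses: selection on this ill-conditioned design keeps
  # some spurious interactions, but full pruning does occur and every
  # retained interaction clears the threshold
  fully <- 0L
  for (s in 1:20) {
    y <- generate_design_study(uniform_models(lin), ref_fixtures$design,
                               noise_sd = 0.1, seed = s)$tgs
    m <- prune_model(ref_fixtures$design, y)
    n_int <- sum(m$terms %in% mixture_interaction_terms())
    if (n_int == 0L) fully <- fully + 1L
  }
  expect_gte(fully, 3L)
})

test_that("alpha = 1 disables pruning and returns the full candidate model", {
  y <- ref_fixtures$parameters$tm_prime
  m <- prune_model(ref_fixtures$design, y, alpha = 1.0)
  expect_setequal(m$terms, all_mixture_terms())
})

test_that("vertex predictions equal the linear coefficients exactly", {
  tm_mod <- ref_fixtures$models$tm_prime
  expect_equal(predict_response(tm_mod, composition(1, 0, 0, 0, 0, 0)), -42.92)
  tgs_mod <- ref_fixtures$models$tgs
  expect_equal(predict_response(tgs_mod, composition(0, 0, 1, 0, 0, 0)), 58.68)
})

test_that("predicted diagrams along the maltodextrin sweep behave as the blending models say", {
  base <- composition(0.283, 0.283, 0.283, 0.075, 0.075, 0, tol = 0.002)
  # at xm = 0 the Tm' prediction matches the measured blend within model error
  d0 <- predict_state_diagram(base, 0, ref_fixtures$models)
  expect_equal(d0$mfcc$tm_prime, -38.7, tolerance = 1.0)
  xms <- seq(0, 0.6, by = 0.1)
  tmp <- vapply(xms, function(x)
    predict_state_diagram(base, x, ref_fixtures$models)$mfcc$tm_prime,
    numeric(1))
  expect_true(all(diff(tmp) > 0))
  # the freezing curve flattens with maltodextrin: less depression at ws = 0.5
  d3 <- predict_state_diagram(base, 0.3, ref_fixtures$models)
  d6 <- predict_state_diagram(base, 0.6, ref_fixtures$models)
  expect_gt(chen_tm(0.5, d6$chen), chen_tm(0.5, d3$chen))
  expect_error(predict_state_diagram(base, 1.0, ref_fixtures$models), "xm")
  expect_error(predict_state_diagram(base, 0.3, ref_fixtures$models[-2]),
               "missing model")
})
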