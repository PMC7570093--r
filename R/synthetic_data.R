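#' Specification for a synthetic moisture-series study
#'
#' Defines the ground truth and measurement structure for a simulated
#' DSC moisture series: the generating glass-transition and
#' freezing-curve parameters, the solids-fraction grids at which Tg and
#' Tm are "measured", the replicate structure and noise levels of the
#' Tg'/Tm' observations, and a seed fixing the whole realization.
#'
#' Defaults emulate the measurement structure of an annealed DSC study
#' of a sugar-rich system: 6 moisture levels spanning 27-90% water
#' (wet basis) for the freezable domain (ws 0.10-0.73) and 6 levels in
#' the unfreezable domain (ws 0.80-1.00), with additive homoscedastic
#' Gaussian noise of 1 degC on curve temperatures and 1.5 degC on the
#' prime transitions.  The default ground-truth parameters are those of
#' a pure-fructose system (tgs = 10.4 degC, k = 2.90, e = 0.0954,
#' b = 0.1668, ws' = 0.739).
#'
#' @param gt Generating [gt_params()].
#' @param chen Generating [chen_params()].
#' @param tg_ws_grid,tm_ws_grid Solids-fraction grids for the two
#'   curves; `tm_ws_grid` must lie inside the Chen domain.
#' @param noise_sd_tg,noise_sd_tm,noise_sd_primes Gaussian noise
#'   standard deviations, degC (>= 0).
#' @param n_prime_replicates Number of Tg'/Tm' replicate observations.
#' @param ws_prime True solids fraction at maximum ice formation; the
#'   true Tm' is the freezing curve evaluated there.
#' @param tg_prime True Tg' (degC); independent of the glass-transition
#'   curve, as measured values generally are.
#' @param seed Integer seed fixing the realization.
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(gt = gt_params(10.4, 2.90),
                           chen = chen_params(0.0954, 0.1668),
                           tg_ws_grid = seq(0.80, 1.00, length.out = 6),
                           tm_ws_grid = seq(0.10, 0.73, length.out = 6),
                           noise_sd_tg = 1.0, noise_sd_tm = 1.0,
                           noise_sd_primes = 1.5,
                           n_prime_replicates = 6,
                           ws_prime = 0.739,
                           tg_prime = -55.9,
                           seed = 1L) {
  stopifnot(inherits(gt, "gt_params"), inherits(chen, "chen_params"),
            noise_sd_tg >= 0, noise_sd_tm >= 0, noise_sd_primes >= 0,
            n_prime_replicates >= 1)
  if (any(tm_ws_grid >= chen_ws_max(chen))) {
    stop(sprintf("tm_ws_grid extends beyond the Chen domain (ws_max = %.4f)",
                 chen_ws_max(chen)), call. = FALSE)
  }
  if (!(ws_prime > 0 && ws_prime < chen_ws_max(chen))) {
    stop("ws_prime must lie inside the Chen domain", call. = FALSE)
  }
  tm_prime <- chen_tm(ws_prime, chen)
  structure(list(gt = gt, chen = chen,
                 tg_ws_grid = tg_ws_grid, tm_ws_grid = tm_ws_grid,
                 noise_sd_tg = noise_sd_tg, noise_sd_tm = noise_sd_tm,
                 noise_sd_primes = noise_sd_primes,
                 n_prime_replicates = as.integer(n_prime_replicates),
                 truth = list(gt = gt, chen = chen,
                              mfcc = mfcc(tg_prime, tm_prime, ws_prime)),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic thermal dataset
#'
#' Evaluates the generating curves on the grids, adds seeded Gaussian
#' noise, and draws replicate Tg'/Tm' observations around their true
#' values.  The same seed always yields an identical dataset.  The
#' ground truth is attached as attribute `"truth"`.
#'
#' @param spec A [generator_spec()].
#' @param sample_id Identifier for the emitted dataset.
#' @return A [thermal_dataset()].
#' @examples
#' d <- generate_thermal_dataset(generator_spec(seed = 7))
#' fit_chen(d)
#' @export
generate_thermal_dataset <- function(spec, sample_id = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  tg <- gordon_taylor_tg(spec$tg_ws_grid, spec$gt) +
    stats::rnorm(length(spec$tg_ws_grid), 0, spec$noise_sd_tg)
  tm <- chen_tm(spec$tm_ws_grid, spec$chen) +
    stats::rnorm(length(spec$tm_ws_grid), 0, spec$noise_sd_tm)
  tr <- spec$truth$mfcc
  tgp <- tr$tg_prime +
    stats::rnorm(spec$n_prime_replicates, 0, spec$noise_sd_primes)
  tmp <- tr$tm_prime +
    stats::rnorm(spec$n_prime_replicates, 0, spec$noise_sd_primes)
  out <- thermal_dataset(sample_id,
                         tg_points = data.frame(ws = spec$tg_ws_grid, tg = tg),
                         tm_points = data.frame(ws = spec$tm_ws_grid, tm = tm),
                         tg_prime_obs = tgp, tm_prime_obs = tmp)
  attr(out, "truth") <- spec$truth
  out
}

#' Generate a synthetic design-response study
#'
#' Evaluates each of the seven response models at every design
#' composition and adds seeded Gaussian noise, emulating a full
#' composition-design study with known ground truth.
#'
#' @param models Named list of `"mixture_model"`s covering
#'   [mixture_responses()].
#' @param design A [mixture_design()].
#' @param noise_sd Scalar, or named vector per response, of Gaussian
#'   noise standard deviations (response units).
#' @param seed Integer seed.
#' @return Data frame: `experiment` plus one column per response.
#' @export
generate_design_study <- function(models, design, noise_sd = 0, seed = 1L) {
  design <- mixture_design(as.data.frame(design))
  resp <- mixture_responses()
  missing <- setdiff(resp, names(models))
  if (length(missing)) {
    stop(sprintf("missing model(s) for response(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, length(resp)), resp)
  }
  set.seed(as.integer(seed))
  n <- nrow(design)
  out <- data.frame(experiment = design$experiment)
  for (r in resp) {
    mu <- as.numeric(design_matrix(design, models[[r]]$terms) %*%
                       models[[r]]$coefficients)
    out[[r]] <- mu + stats::rnorm(n, 0, noise_sd[[r]])
  }
  out
}
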