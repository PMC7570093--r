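#' Gordon-Taylor parameter set
#'
#' Parameters of the Gordon-Taylor plasticization model for the glass
#' transition of a solids-water binary: Tg(ws) is the K-weighted mean of
#' the anhydrous-solids transition `tgs` and the amorphous-water
#' transition `tgw` (fixed at -135 degC unless overridden).
#'
#' @param tgs Anhydrous-solids glass transition temperature (degC).
#' @param k Interaction constant (dimensionless, > 0), the strength of
#'   the water-solids interaction.
#' @param tgw Glass transition of amorphous water (degC); -135 by
#'   convention and never fitted.
#' @return A list of class `"gt_params"`.
#' @examples
#' gt_params(tgs = 10.4, k = 2.90)   # pure fructose
#' @export
gt_params <- function(tgs, k, tgw = -135) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(tgs) || length(tgs) != 1L || is.na(tgs)) {
    stop("tgs must be a single number", call. = FALSE)
  }
  if (tgs <= tgw) {
    stop(sprintf("tgs (%.3g) must exceed tgw (%.3g)", tgs, tgw),
         call. = FALSE)
  }
  structure(list(tgs = tgs, k = k, tgw = tgw), class = "gt_params")
}

#' Chen freezing-point-depression parameter set
#'
#' Parameters of the Chen model for the equilibrium freezing point of a
#' solids-water system.  `e` is the water-to-solids molecular mass
#' ratio, `b` the ratio of unfreezable water to total solids.  `beta`
#' (molar freezing point constant of water, 1860 kg K/kgmol) and
#' `lambda_w` (molecular mass of water, 18.015 kg/kgmol) are physical
#' constants.
#'
#' @param e Water-to-solids molecular mass ratio (> 0).
#' @param b Unfreezable-water-to-solids ratio, in \[0, 1).
#' @param tw Freezing temperature of pure water (degC), default 0.
#' @param beta Molar freezing point constant of water (kg K/kgmol).
#' @param lambda_w Molecular mass of water (kg/kgmol).
#' @return A list of class `"chen_params"`.
#' @examples
#' chen_params(e = 0.0954, b = 0.1668)   # pure fructose
#' @export
chen_params <- function(e, b, tw = 0, beta = 1860, lambda_w = 18.015) {
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || e <= 0) {
    stop("e must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0 || b >= 1) {
    stop("b must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(is.numeric(tw), length(tw) == 1L, beta > 0, lambda_w > 0)
  structure(list(e = e, b = b, tw = tw, beta = beta, lambda_w = lambda_w),
            class = "chen_params")
}

#' Gordon-Taylor glass transition temperature
#'
#' Evaluates Tg(ws) = (ws * tgs + k (1 - ws) tgw) / (ws + k (1 - ws)).
#' The expression is a weighted mean of two temperatures and is
#' therefore affine-invariant: evaluating in degC or Kelvin gives the
#' same result.
#'
#' @param ws Solids mass fraction(s) in \[0, 1\]; vectorized.
#' @param params A [gt_params()] object.
#' @return Glass transition temperature(s), degC.
#' @examples
#' p <- gt_params(10.4, 2.90)
#' gordon_taylor_tg(c(0, 0.739, 1), p)
#' @export
gordon_taylor_tg <- function(ws, params) {
  stopifnot(inherits(params, "gt_params"))
  if (!is.numeric(ws) || anyNA(ws) || any(ws < 0) || any(ws > 1)) {
    stop("ws must lie in [0, 1]", call. = FALSE)
  }
  with(params, (ws * tgs + k * (1 - ws) * tgw) / (ws + k * (1 - ws)))
}

#' Chen freezing point
#'
#' Evaluates Tm(ws) = tw + (beta / lambda_w) *
#' log((1 - ws - b ws) / (1 - ws - b ws + e ws)).  Strictly decreasing
#' in ws and equal to `tw` at ws = 0; diverges to -Inf as ws approaches
#' the domain boundary [chen_ws_max()].
#'
#' @param ws Solids mass fraction(s), `0 <= ws < chen_ws_max(params)`;
#'   vectorized.
#' @param params A [chen_params()] object.
#' @return Freezing temperature(s), degC.
#' @examples
#' p <- chen_params(0.0954, 0.1668)
#' chen_tm(c(0, 0.3, 0.739), p)
#' @export
chen_tm <- function(ws, params) {
  stopifnot(inherits(params, "chen_params"))
  ws_max <- chen_ws_max(params)
  if (!is.numeric(ws) || anyNA(ws) || any(ws < 0)) {
    stop("ws must be numeric and >= 0", call. = FALSE)
  }
  if (any(ws >= ws_max)) {
    stop(sprintf(
      "ws = %.4g is at or beyond the model domain boundary ws_max = %.6g (log argument <= 0)",
      max(ws), ws_max), call. = FALSE)
  }
  with(params, {
    u <- 1 - ws - b * ws
    tw + (beta / lambda_w) * log(u / (u + e * ws))
  })
}

#' Domain boundary of the Chen freezing curve
#'
#' The solids fraction 1 / (1 + b) above which the unfrozen-water term
#' 1 - ws - b ws becomes non-positive and the freezing curve is
#' undefined.
#'
#' @param params A [chen_params()] object.
#' @return A solids mass fraction in (0, 1\].
#' @export
chen_ws_max <- function(params) {
  stopifnot(inherits(params, "chen_params"))
  1 / (1 + params$b)
}

#' @export
print.gt_params <- function(x, ...) {
  cat(sprintf("Gordon-Taylor parameters: tgs = %.4g degC, k = %.4g, tgw = %g degC\n",
              x$tgs, x$k, x$tgw))
  invisible(x)
}

#' @export
print.chen_params <- function(x, ...) {
  cat(sprintf(
    "Chen parameters: e = %.4g, b = %.4g (ws_max = %.4f), tw = %g degC\n",
    x$e, x$b, chen_ws_max(x), x$tw))
  invisible(x)
}
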