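#' Average a set of replicate transition temperatures
#'
#' Tg' and Tm' vary little across moisture levels in the annealed
#' freezable-water domain, so a sample's characteristic values are the
#' unweighted arithmetic means of the replicate observations.
#'
#' @param observations Non-empty numeric vector (degC).
#' @return The mean, degC.
#' @export
average_transition <- function(observations) {
  if (!is.numeric(observations) || length(observations) == 0L ||
      anyNA(observations)) {
    stop("need a non-empty numeric vector of observations", call. = FALSE)
  }
  mean(observations)
}

#' Maximal-freeze-concentration condition
#'
#' The (Tg', Tm', ws') triple characterizing the maximally
#' freeze-concentrated unfrozen phase.  `tg_prime` may be `NA` when the
#' transition is not detected (it can overlap the ice-melting onset in
#' high-maltodextrin systems).
#'
#' @param tg_prime Glass transition of the freeze-concentrated phase
#'   (degC) or `NA`.
#' @param tm_prime Onset-of-ice-melting temperature (degC).
#' @param ws_prime Solids mass fraction at maximum ice formation, in
#'   (0, 1).
#' @return A list of class `"mfcc"`.
#' @export
mfcc <- function(tg_prime, tm_prime, ws_prime) {
  stopifnot(is.numeric(tm_prime), length(tm_prime) == 1L, !is.na(tm_prime),
            is.numeric(ws_prime), length(ws_prime) == 1L)
  if (!(ws_prime > 0 && ws_prime < 1)) {
    stop("ws_prime must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.na(tg_prime) && tg_prime > tm_prime + 1e-9) {
    stop(sprintf("tg_prime (%.3g) must not exceed tm_prime (%.3g)",
                 tg_prime, tm_prime), call. = FALSE)
  }
  structure(list(tg_prime = as.numeric(tg_prime), tm_prime = tm_prime,
                 ws_prime = ws_prime), class = "mfcc")
}

#' @export
print.mfcc <- function(x, ...) {
  cat(sprintf("MFCC: Tg' = %s degC, Tm' = %.4g degC, ws' = %.4f\n",
              if (is.na(x$tg_prime)) "not detected" else
                sprintf("%.4g", x$tg_prime),
              x$tm_prime, x$ws_prime))
  invisible(x)
}

#' Solids fraction at maximum ice formation by curve intersection
#'
#' Finds the unique ws in (0, ws_max) at which the Chen freezing curve
#' equals the averaged onset-of-melting temperature Tm'.  The curve is
#' strictly decreasing from tw at ws = 0 to -Inf at the domain
#' boundary, so a bracketed root search (Brent, tolerance 1e-12 on ws)
#' converges unconditionally; the root is verified to reproduce
#' `tm_prime` within 1e-6 degC.
#'
#' @param chen A [chen_params()] object.
#' @param tm_prime Averaged onset-of-melting temperature (degC), must
#'   be below `chen$tw`.
#' @return The solids mass fraction ws'.
#' @examples
#' solve_ws_prime(chen_params(0.0954, 0.1668), -42.8)   # ~ 0.739
#' @export
solve_ws_prime <- function(chen, tm_prime) {
  stopifnot(inherits(chen, "chen_params"),
            is.numeric(tm_prime), length(tm_prime) == 1L, !is.na(tm_prime))
  if (tm_prime >= chen$tw) {
    stop(sprintf("tm_prime (%.3g) must be below tw (%.3g): no freezing-point depression to invert",
                 tm_prime, chen$tw), call. = FALSE)
  }
  ws_max <- chen_ws_max(chen)
  f <- function(w) chen_tm(w, chen) - tm_prime
  lo <- 1e-9; hi <- ws_max - 1e-9
  # pull hi off the singularity until the bracket is finite and signed
  flo <- f(lo); fhi <- f(hi)
  while (!is.finite(fhi) && hi > lo) { hi <- lo + (hi - lo) * 0.999; fhi <- f(hi) }
  if (!is.finite(flo) || flo * fhi > 0) {
    stop("no sign change in the bracket: tm_prime is not reached by the freezing curve",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(chen_tm(root, chen) - tm_prime) > 1e-6) {
    stop("root finding did not reach the 1e-6 degC tolerance", call. = FALSE)
  }
  root
}

#' Complete state diagram of one sample
#'
#' Bundles the composition, fitted Gordon-Taylor and Chen parameter
#' sets, and the maximal-freeze-concentration condition.
#'
#' @param gt A [gt_params()] object.
#' @param chen A [chen_params()] object.
#' @param mfcc An [mfcc()] object.
#' @param composition Optional [composition()].
#' @param check If `TRUE`, require the MFCC to be consistent with the
#'   freezing curve (chen_tm(ws') = Tm' within 1e-6 degC); disable for
#'   diagrams assembled from independently predicted responses.
#' @return A list of class `"state_diagram"`.
#' @export
state_diagram <- function(gt, chen, mfcc, composition = NULL, check = TRUE) {
  stopifnot(inherits(gt, "gt_params"), inherits(chen, "chen_params"),
            inherits(mfcc, "mfcc"))
  if (check) {
    dev <- abs(chen_tm(mfcc$ws_prime, chen) - mfcc$tm_prime)
    if (dev > 1e-6) {
      stop(sprintf("MFCC inconsistent with freezing curve: |Tm(ws') - Tm'| = %.3g degC",
                   dev), call. = FALSE)
    }
  }
  structure(list(composition = composition, gt = gt, chen = chen,
                 mfcc = mfcc), class = "state_diagram")
}

#' @export
print.state_diagram <- function(x, ...) {
  cat("State diagram\n")
  print(x$gt); print(x$chen); print(x$mfcc)
  invisible(x)
}

#' Assemble a state diagram from fitted curves and prime observations
#'
#' Averages the Tg'/Tm' replicates, intersects the averaged Tm' with
#' the fitted freezing curve to obtain ws', and bundles everything.
#' Tg' is carried as the measured average and is not recomputed from
#' the glass-transition curve (the two are not forced to agree).
#'
#' @param gt_fit,chen_fit Converged `"fit_result"` objects from
#'   [fit_gordon_taylor()] and [fit_chen()].
#' @param tg_prime_obs Replicate Tg' observations (may be empty: Tg'
#'   recorded as `NA`).
#' @param tm_prime_obs Replicate Tm' observations (required).
#' @param composition Optional [composition()].
#' @return A `"state_diagram"`.
#' @export
build_state_diagram <- function(gt_fit, chen_fit, tg_prime_obs = numeric(),
                                tm_prime_obs, composition = NULL) {
  stopifnot(inherits(gt_fit, "fit_result"), inherits(chen_fit, "fit_result"))
  if (!gt_fit$converged || !chen_fit$converged) {
    stop("both curve fits must have converged", call. = FALSE)
  }
  if (length(tm_prime_obs) == 0L) {
    stop("tm_prime observations are required to locate the maximal-freeze-concentration condition",
         call. = FALSE)
  }
  tm_p <- average_transition(tm_prime_obs)
  tg_p <- if (length(tg_prime_obs)) average_transition(tg_prime_obs) else NA_real_
  ws_p <- solve_ws_prime(chen_fit$params, tm_p)
  state_diagram(gt_fit$params, chen_fit$params,
                mfcc(tg_p, tm_p, ws_p), composition = composition)
}

#' Tabulate the glass-transition and freezing curves
#'
#' Evaluates both curves on an even ws grid over \[0, 1\].  The
#' freezing-curve column is `NA` at and beyond the Chen domain boundary
#' ws_max = 1 / (1 + b).
#'
#' @param diagram A `"state_diagram"`.
#' @param n_points Number of grid points (>= 2).
#' @return Data frame with columns `ws`, `tg`, `tm`.
#' @export
tabulate_curves <- function(diagram, n_points = 101) {
  stopifnot(inherits(diagram, "state_diagram"),
            is.numeric(n_points), n_points >= 2)
  ws <- seq(0, 1, length.out = as.integer(n_points))
  tg <- gordon_taylor_tg(ws, diagram$gt)
  ws_max <- chen_ws_max(diagram$chen)
  tm <- rep(NA_real_, length(ws))
  ok <- ws < ws_max - 1e-12
  if (any(ok)) tm[ok] <- chen_tm(ws[ok], diagram$chen)
  data.frame(ws = ws, tg = tg, tm = tm)
}

#' Export a state diagram's curve table as CSV
#'
#' @param diagram A `"state_diagram"`.
#' @param path Output CSV path.
#' @param n_points Grid resolution.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(diagram, path, n_points = 101) {
  utils::write.csv(tabulate_curves(diagram, n_points), path,
                   row.names = FALSE)
  invisible(path)
}
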