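#' Coefficient of determination
#'
#' R^2 = 1 - SSE/SST with SST taken about the mean of the observations.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return A scalar; 1 for a perfect fit, 0 for the mean-only fit.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 3))   # 0.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observations have zero variance; R^2 undefined",
                     call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

.new_fit_result <- function(params, observed, predicted, converged, niter,
                            message = "") {
  structure(list(params = params,
                 r_squared = r_squared(observed, predicted),
                 residuals = observed - predicted,
                 n_obs = length(observed),
                 sse = sum((observed - predicted)^2),
                 converged = converged,
                 niter = niter,
                 message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Nonlinear least-squares fit: n = %d, R^2 = %.4f, SSE = %.4g, %s\n",
              x$n_obs, x$r_squared, x$sse,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

# Bounded Levenberg-Marquardt with deterministic multi-start fallback.
# resid_fn(par) -> residual vector; jitters are multiplicative factors
# applied to the distance of the start from the lower bound.
.lm_multistart <- function(resid_fn, start, lower, upper,
                           ftol = 1e-10, maxiter = 500) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                     ptol = 1e-12)
  one <- function(p0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, sse = fit$deviance, info = fit$info,
         niter = fit$niter, message = fit$message,
         converged = fit$info %in% 1:3)
  }
  best <- one(start)
  if (!is.null(best) && best$converged) return(best)
  jitters <- c(0.5, 2, 0.25, 4, 1.5)
  for (j in jitters) {
    p0 <- pmin(pmax(lower + (start - lower) * j, lower + 1e-8),
               upper - 1e-8)
    cand <- one(p0)
    if (is.null(cand)) next
    if (cand$converged) return(cand)
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  if (is.null(best)) stop("optimizer failed from every start", call. = FALSE)
  best
}

#' Fit the Gordon-Taylor equation to moisture-series Tg data
#'
#' Unweighted nonlinear least squares for (tgs, k) on the `tg_points`
#' of a dataset, with tgw held at its fixed value.  Initialization uses
#' the largest observed Tg for tgs and k = 4; bounds tgs in (-50, 250)
#' degC, k in (0.1, 50).  On non-convergence the fit is retried from
#' jittered starts and, failing that, returned flagged.
#'
#' @param data A [thermal_dataset()] with >= 3 `tg_points`.
#' @param tgw Amorphous-water glass transition (degC), fixed.
#' @return A `"fit_result"`: `params` ([gt_params()]), `r_squared`,
#'   `residuals`, `n_obs`, `sse`, `converged`, `niter`.
#' @export
fit_gordon_taylor <- function(data, tgw = -135) {
  stopifnot(inherits(data, "thermal_dataset"))
  pts <- data$tg_points
  if (is.null(pts) || nrow(pts) < 3L) {
    stop("need at least 3 (ws, tg) points to fit 2 parameters",
         call. = FALSE)
  }
  ws <- pts$ws; tg <- pts$tg
  if (length(unique(ws)) < 2L) {
    stop("degenerate design: all ws values are equal", call. = FALSE)
  }
  lower <- c(tgs = -50, k = 0.1)
  upper <- c(tgs = 250, k = 50)
  start <- c(tgs = min(max(max(tg), -49), 249), k = 4)
  fn <- function(p) {
    pp <- gt_params(max(p[1], tgw + 1e-6), p[2], tgw = tgw)
    gordon_taylor_tg(ws, pp) - tg
  }
  sol <- .lm_multistart(fn, start, lower, upper)
  params <- gt_params(as.numeric(sol$par[1]), as.numeric(sol$par[2]),
                      tgw = tgw)
  .new_fit_result(params, tg, gordon_taylor_tg(ws, params),
                  sol$converged, sol$niter, sol$message)
}

#' Fit the Chen equation to moisture-series freezing-point data
#'
#' Unweighted nonlinear least squares for (e, b) on the `tm_points` of
#' a dataset.  The search is constrained so the log argument stays
#' positive at every data point: b is bounded above by
#' min(0.99, (1 - max ws) / max ws).  Initialization e = 0.05,
#' b = 0.15.
#'
#' @param data A [thermal_dataset()] with >= 3 `tm_points`.
#' @param tw Pure-water freezing temperature (degC), fixed.
#' @return A `"fit_result"` whose `params` is a [chen_params()].
#' @export
fit_chen <- function(data, tw = 0) {
  stopifnot(inherits(data, "thermal_dataset"))
  pts <- data$tm_points
  if (is.null(pts) || nrow(pts) < 3L) {
    stop("need at least 3 (ws, tm) points to fit 2 parameters",
         call. = FALSE)
  }
  ws <- pts$ws; tm <- pts$tm
  if (length(unique(ws)) < 2L) {
    stop("degenerate design: all ws values are equal", call. = FALSE)
  }
  b_upper <- min(0.99, (1 - max(ws)) / max(ws) - 1e-6)
  if (b_upper <= 0) {
    stop("data contain ws so high that no b in [0, 1) keeps the freezing-curve domain valid",
         call. = FALSE)
  }
  lower <- c(e = 1e-4, b = 0)
  upper <- c(e = 1, b = b_upper)
  start <- c(e = 0.05, b = min(0.15, b_upper / 2))
  fn <- function(p) {
    u <- 1 - ws - p[2] * ws
    bad <- u <= 0 | u + p[1] * ws <= 0
    r <- numeric(length(ws))
    r[bad] <- 1e6
    if (any(!bad)) {
      pp <- chen_params(max(p[1], 1e-12), min(p[2], 0.9999), tw = tw)
      r[!bad] <- chen_tm(ws[!bad], pp) - tm[!bad]
    }
    r
  }
  sol <- .lm_multistart(fn, start, lower, upper)
  params <- chen_params(as.numeric(sol$par[1]), as.numeric(sol$par[2]),
                        tw = tw)
  .new_fit_result(params, tm, chen_tm(ws, params),
                  sol$converged, sol$niter, sol$message)
}
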