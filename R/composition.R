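#' Six-component solute composition
#'
#' A dry-basis solute composition of a fruit-juice model system:
#' mass fractions of fructose (XF), glucose (XG), sucrose (XS), pectin
#' (XP), citric acid (XA) and maltodextrin (XM), summing to 1.
#'
#' @param xf,xg,xs,xp,xa,xm Dry-basis mass fractions in \[0, 1\].
#' @param tol Tolerance on the sum-to-one constraint.  The default is
#'   strict; printed design tables rounded to 3 decimals need a looser
#'   tolerance (e.g. 0.002).
#' @return A named numeric vector of class `"composition"` with
#'   components `XF, XG, XS, XP, XA, XM`.
#' @examples
#' composition(1, 0, 0, 0, 0, 0)                       # pure fructose
#' composition(0.283, 0.283, 0.283, 0.075, 0.075, 0)   # juice-like blend
#' @export
composition <- function(xf, xg, xs, xp, xa, xm, tol = 1e-9) {
  x <- c(XF = xf, XG = xg, XS = xs, XP = xp, XA = xa, XM = xm)
  if (anyNA(x) || !is.numeric(x)) {
    stop("composition fractions must be numeric and non-missing", call. = FALSE)
  }
  if (any(x < 0) || any(x > 1)) {
    stop("each mass fraction must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf("mass fractions must sum to 1 (got %.6f, tol %g)",
                 sum(x), tol), call. = FALSE)
  }
  structure(x, class = "composition")
}

#' Coerce a vector or one-row table to a composition
#'
#' @param x A numeric vector of length 6 (in XF, XG, XS, XP, XA, XM
#'   order, or carrying those names) or a one-row data frame with those
#'   columns.
#' @param tol Passed to [composition()].
#' @return A `"composition"` object.
#' @export
as_composition <- function(x, tol = 1e-9) {
  nm <- c("XF", "XG", "XS", "XP", "XA", "XM")
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[, nm, drop = FALSE])
  }
  if (!is.null(names(x)) && all(nm %in% names(x))) x <- x[nm]
  if (length(x) != 6L) stop("need 6 mass fractions", call. = FALSE)
  composition(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]], tol = tol)
}

#' @export
print.composition <- function(x, digits = 4, ...) {
  cat("Solute composition (dry-basis mass fractions):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}
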