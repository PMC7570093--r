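#' Scheffe mixture-model term sets
#'
#' The candidate model for a six-component mixture has no intercept, 6
#' linear blending terms and 15 pairwise (binary blending) products, 21
#' terms in all.  Term labels concatenate component labels: `XF`,
#' `XFXG`, ...
#'
#' @return Character vectors of term labels.
#' @export
mixture_linear_terms <- function() c("XF", "XG", "XS", "XP", "XA", "XM")

#' @rdname mixture_linear_terms
#' @export
mixture_interaction_terms <- function() {
  comps <- mixture_linear_terms()
  out <- character(0)
  for (i in 1:5) for (j in (i + 1):6) {
    out <- c(out, paste0(comps[i], comps[j]))
  }
  out
}

#' @rdname mixture_linear_terms
#' @export
all_mixture_terms <- function() c(mixture_linear_terms(),
                                  mixture_interaction_terms())

#' Responses modeled over the composition design
#' @return The seven response names: the two glass-curve parameters,
#'   the two freezing-curve parameters and the MFCC triple.
#' @export
mixture_responses <- function() {
  c("tgs", "k", "e", "b", "tg_prime", "tm_prime", "ws_prime")
}

#' A mixture experimental design
#'
#' @param df Data frame with column `experiment` plus the six
#'   mass-fraction columns `XF, XG, XS, XP, XA, XM`; optionally
#'   `run_order`.  Each row must sum to 1 within `tol` (printed designs
#'   are rounded to 3 decimals).
#' @param tol Sum-to-one tolerance per run.
#' @return The data frame, classed `"mixture_design"`.
#' @export
mixture_design <- function(df, tol = 0.002) {
  df <- as.data.frame(df)
  need <- c("experiment", mixture_linear_terms())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("design is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(df[, mixture_linear_terms()])
  if (any(X < 0) || any(X > 1)) {
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  }
  bad <- which(abs(rowSums(X) - 1) > tol)
  if (length(bad)) {
    stop(sprintf("design run %s does not sum to 1 within %g",
                 paste(df$experiment[bad], collapse = ", "), tol),
         call. = FALSE)
  }
  class(df) <- c("mixture_design", "data.frame")
  df
}

# term label -> column of products, given a runs x 6 fraction matrix
.term_column <- function(X, term) {
  comps <- mixture_linear_terms()
  if (term %in% comps) return(X[, term])
  a <- substr(term, 1, 2); b <- substr(term, 3, 4)
  if (!(a %in% comps && b %in% comps)) {
    stop(sprintf("unknown mixture term '%s'", term), call. = FALSE)
  }
  X[, a] * X[, b]
}

#' Design matrix for a Scheffe mixture model
#'
#' One column per term; a pairwise term's column is the elementwise
#' product of the two component columns.  Never includes an intercept.
#'
#' @param design A [mixture_design()] (or data frame with the six
#'   fraction columns).
#' @param terms Term labels drawn from [all_mixture_terms()].
#' @return A runs x terms numeric matrix.
#' @export
design_matrix <- function(design, terms = all_mixture_terms()) {
  bad <- setdiff(terms, all_mixture_terms())
  if (length(bad)) {
    stop(sprintf("unknown term(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(design)[, mixture_linear_terms()])
  M <- vapply(terms, function(t) .term_column(X, t), numeric(nrow(X)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, terms))
  M
}

.new_mixture_model <- function(response_name, terms, coefficients, anova,
                               coef_table = NULL, n_obs = NA_integer_) {
  stopifnot(length(terms) == length(coefficients))
  structure(list(response_name = response_name,
                 terms = terms,
                 coefficients = stats::setNames(as.numeric(coefficients), terms),
                 anova = anova,
                 coef_table = coef_table,
                 n_obs = n_obs),
            class = "mixture_model")
}

#' Construct a mixture model from known coefficients
#'
#' Used for published models and for synthetic-data generators; no
#' fitting is performed.
#'
#' @param response_name One of [mixture_responses()].
#' @param coefficients Named numeric vector, names from
#'   [all_mixture_terms()].
#' @param anova Optional list with elements `p_value`, `r_squared`,
#'   `sd`, `cv`.
#' @return A `"mixture_model"`.
#' @export
mixture_model <- function(response_name, coefficients, anova = NULL) {
  terms <- names(coefficients)
  bad <- setdiff(terms, all_mixture_terms())
  if (is.null(terms) || length(bad)) {
    stop("coefficients must be named with valid mixture terms",
         call. = FALSE)
  }
  .new_mixture_model(response_name, terms, coefficients, anova)
}

#' ANOVA statistics of a fitted mixture model
#'
#' Computes the four summary statistics reported with each model:
#' the regression F-test p-value (sums of squares about the response
#' mean, df p - 1 and n - p), R^2 about the mean, residual standard
#' deviation sqrt(SSE / (n - p)), and the coefficient of variation
#' 100 * sd / |mean(response)|.
#'
#' @param model A `"mixture_model"`.
#' @param design The [mixture_design()] used for the fit.
#' @param responses The response vector used for the fit.
#' @return List with `p_value`, `r_squared`, `sd`, `cv`.
#' @export
anova_stats <- function(model, design, responses) {
  stopifnot(inherits(model, "mixture_model"))
  n <- length(responses); p <- length(model$terms)
  if (n <= p) stop("need more runs than model terms", call. = FALSE)
  pred <- as.numeric(design_matrix(design, model$terms) %*% model$coefficients)
  sst <- sum((responses - mean(responses))^2)
  if (sst == 0) stop("responses have zero variance", call. = FALSE)
  sse <- sum((responses - pred)^2)
  sd <- sqrt(sse / (n - p))
  f <- ((sst - sse) / (p - 1)) / (sse / (n - p))
  p_value <- if (sse == 0) 0 else stats::pf(f, p - 1, n - p, lower.tail = FALSE)
  list(p_value = p_value,
       r_squared = 1 - sse / sst,
       sd = sd,
       cv = 100 * sd / abs(mean(responses)))
}

#' Fit a Scheffe mixture polynomial by no-intercept least squares
#'
#' Ordinary least squares of one response on the given term columns,
#' with no intercept (Scheffe convention).  Coefficient standard
#' errors, t statistics and two-sided p-values (n - p df) are attached,
#' along with the four [anova_stats()] summaries.
#'
#' @param design A [mixture_design()].
#' @param responses Numeric vector, one value per run.
#' @param terms Term labels; default the full 21-term candidate set.
#' @param response_name Stored label for the response.
#' @return A `"mixture_model"`.
#' @export
fit_mixture_model <- function(design, responses,
                              terms = all_mixture_terms(),
                              response_name = "response") {
  n <- nrow(as.data.frame(design))
  if (length(responses) != n) {
    stop("need exactly one response per design run", call. = FALSE)
  }
  p <- length(terms)
  if (n < p) {
    stop(sprintf("underdetermined fit: %d runs for %d terms", n, p),
         call. = FALSE)
  }
  M <- design_matrix(design, terms)
  qrM <- qr(M)
  if (qrM$rank < p) {
    dropped <- terms[qrM$pivot[(qrM$rank + 1):p]]
    stop(sprintf("design matrix is rank deficient; collinear term(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm.fit(M, responses)
  beta <- fit$coefficients
  res <- fit$residuals
  dfres <- n - p
  coef_table <- NULL
  if (dfres > 0) {
    sigma2 <- sum(res^2) / dfres
    XtXinv <- solve(crossprod(M))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
    coef_table <- data.frame(term = terms, estimate = as.numeric(beta),
                             se = se, t = tval, p = pval,
                             row.names = NULL)
  }
  mdl <- .new_mixture_model(response_name, terms, beta, anova = NULL,
                            coef_table = coef_table, n_obs = n)
  if (dfres > 0) mdl$anova <- anova_stats(mdl, design, responses)
  mdl
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Mixture model for '%s': %d terms\n", x$response_name,
              length(x$terms)))
  print(round(x$coefficients, 4))
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA: p = %.4g, R^2 = %.4f, SD = %.4g, CV = %.3f%%\n",
                x$anova$p_value, x$anova$r_squared, x$anova$sd, x$anova$cv))
  }
  invisible(x)
}

#' Backward pruning of nonsignificant blending interactions
#'
#' Starts from the full 21-term model and repeatedly removes the
#' pairwise interaction with the largest coefficient p-value above
#' `alpha`, refitting after each removal, until every remaining
#' interaction is significant at `alpha`.  The six linear blending
#' terms are never removed (every reported model keeps them).
#'
#' @param design A [mixture_design()] with more runs than terms.
#' @param responses Response vector.
#' @param alpha Retention threshold on the coefficient p-value
#'   (default 0.10).
#' @param response_name Stored label.
#' @return The pruned `"mixture_model"`.
#' @export
prune_model <- function(design, responses, alpha = 0.10,
                        response_name = "response") {
  terms <- all_mixture_terms()
  lin <- mixture_linear_terms()
  repeat {
    mdl <- fit_mixture_model(design, responses, terms, response_name)
    ct <- mdl$coef_table
    if (is.null(ct)) return(mdl)     # saturated fit: no inference possible
    cand <- ct[!(ct$term %in% lin) & is.finite(ct$p), ]
    if (!nrow(cand) || max(cand$p) <= alpha) return(mdl)
    worst <- cand$term[which.max(cand$p)]
    terms <- setdiff(terms, worst)
  }
}

#' Evaluate a mixture model at a composition
#'
#' Dot product of the model coefficients with the term values of the
#' composition; at a pure-component vertex this returns that
#' component's linear coefficient exactly.
#'
#' @param model A `"mixture_model"`.
#' @param composition A [composition()].
#' @return The predicted response value.
#' @export
predict_response <- function(model, composition) {
  stopifnot(inherits(model, "mixture_model"),
            inherits(composition, "composition"))
  X <- matrix(unclass(composition), nrow = 1,
              dimnames = list(NULL, mixture_linear_terms()))
  vals <- vapply(model$terms, function(t) .term_column(X, t), numeric(1))
  sum(model$coefficients * vals)
}

#' Predict a full state diagram from solute composition
#'
#' Blends a maltodextrin-free base composition with a maltodextrin
#' fraction `xm` (the base fractions are scaled by 1 - xm, preserving
#' their ratios), evaluates the seven composition-response models, and
#' assembles the predicted state diagram: Gordon-Taylor parameters
#' (tgs, k), Chen parameters (e, b) and the MFCC (Tg', Tm', ws').  The
#' MFCC here comes from its own response models, so it is not forced
#' onto the predicted freezing curve.
#'
#' @param base A [composition()] with `XM = 0`.
#' @param xm Maltodextrin mass fraction in \[0, 1).
#' @param models Named list of `"mixture_model"`s covering all of
#'   [mixture_responses()].
#' @return A `"state_diagram"` (consistency check disabled).
#' @export
predict_state_diagram <- function(base, xm, models) {
  stopifnot(inherits(base, "composition"))
  if (base[["XM"]] != 0) {
    stop("base composition must have XM = 0", call. = FALSE)
  }
  if (!is.numeric(xm) || length(xm) != 1L || is.na(xm) || xm < 0 || xm >= 1) {
    stop("xm must lie in [0, 1)", call. = FALSE)
  }
  missing <- setdiff(mixture_responses(), names(models))
  if (length(missing)) {
    stop(sprintf("missing model(s) for response(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- unclass(base) * (1 - xm)
  x[["XM"]] <- xm
  comp <- as_composition(x, tol = 0.002)   # printed designs round to 3 dp
  pred <- vapply(mixture_responses(),
                 function(r) predict_response(models[[r]], comp),
                 numeric(1))
  state_diagram(gt = gt_params(pred[["tgs"]], pred[["k"]]),
                chen = chen_params(pred[["e"]], pred[["b"]]),
                mfcc = mfcc(pred[["tg_prime"]], pred[["tm_prime"]],
                            pred[["ws_prime"]]),
                composition = comp, check = FALSE)
}
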