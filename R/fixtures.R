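#' Bundled reference tables of the maltodextrin/fruit-juice study
#'
#' Loads the three study tables shipped with the package as plain CSV:
#' the 25-run six-component D-optimal composition design, the per-run
#' fitted curve parameters and maximal-freeze-concentration values
#' (Tgs, K, E, B with their R^2, and Tg', Tm', ws'), and the seven
#' pruned solute-composition models with their ANOVA summaries.  Shape
#' and invariants are validated at load: 25 rows in the first two
#' tables, every design run summing to 1 within printed rounding
#' (0.002), and every model term drawn from the 21 admissible Scheffe
#' terms.
#'
#' The E model is transcribed verbatim although its XF coefficient
#' (0.946) is inconsistent with the measured pure-fructose E of 0.0954
#' - almost certainly a typesetting loss of a leading zero in the
#' source table - and its XM coefficient (-0.0003) appears truncated;
#' treat that model as qualitative only.
#'
#' @return A list with elements:
#' \describe{
#'   \item{design}{[mixture_design()] with 25 runs.}
#'   \item{parameters}{Data frame: `experiment, tgs, k, r2_gt, e, b,
#'     r2_chen, tg_prime, tm_prime, ws_prime`.}
#'   \item{models}{Named list of `"mixture_model"`s (one per response
#'     in [mixture_responses()]) carrying the printed coefficients and
#'     ANOVA values.}
#'   \item{model_anova}{Data frame of the printed ANOVA summaries,
#'     with the p-value kept as printed (`p_label`, e.g. "<0.0001").}
#' }
#' @export
load_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "statediagram")
    if (p == "") stop(sprintf("bundled fixture '%s' not found", f),
                      call. = FALSE)
    p
  }
  design <- utils::read.csv(path("table1_design.csv"))
  params <- utils::read.csv(path("table2_parameters.csv"))
  terms <- utils::read.csv(path("table3_model_terms.csv"))
  anova <- utils::read.csv(path("table3_model_anova.csv"),
                           colClasses = c(p_label = "character"))

  if (nrow(design) != 25L || nrow(params) != 25L) {
    stop("fixture shape mismatch: design and parameter tables must have 25 rows",
         call. = FALSE)
  }
  design <- mixture_design(design, tol = 0.002)
  if (!identical(sort(unique(terms$response)), sort(mixture_responses()))) {
    stop("fixture shape mismatch: model table must cover the seven responses",
         call. = FALSE)
  }
  bad <- setdiff(terms$term, all_mixture_terms())
  if (length(bad)) {
    stop(sprintf("fixture contains invalid mixture term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  models <- lapply(mixture_responses(), function(r) {
    sub <- terms[terms$response == r, ]
    an <- anova[anova$response == r, ]
    p_num <- if (an$p_label == "<0.0001") 1e-4 else as.numeric(an$p_label)
    mixture_model(r, stats::setNames(sub$coefficient, sub$term),
                  anova = list(p_value = p_num, r_squared = an$r_squared,
                               sd = an$sd, cv = an$cv))
  })
  names(models) <- mixture_responses()
  list(design = design, parameters = params, models = models,
       model_anova = anova)
}

#' Chen parameter set from a reference-table row
#'
#' Convenience accessor: builds the [chen_params()] (and optionally
#' checks) for one experiment of the bundled parameter table.
#'
#' @param parameters The `parameters` element of [load_fixtures()].
#' @param experiment Experiment number (1-25).
#' @return A list with `gt` ([gt_params()]), `chen` ([chen_params()]),
#'   `tg_prime`, `tm_prime`, `ws_prime` as printed.
#' @export
fixture_row <- function(parameters, experiment) {
  row <- parameters[parameters$experiment == experiment, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no unique row for experiment %s", experiment),
         call. = FALSE)
  }
  list(gt = gt_params(row$tgs, row$k),
       chen = chen_params(row$e, row$b),
       tg_prime = row$tg_prime, tm_prime = row$tm_prime,
       ws_prime = row$ws_prime)
}
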