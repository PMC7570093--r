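# Shared helpers: reference parameter sets and noiseless dataset builders.

ref_fixtures <- load_fixtures()

# parameter sets used repeatedly (pure fructose, pure sucrose,
# high-maltodextrin, fructose/pectin/maltodextrin blend)
ref_params <- function(experiment) fixture_row(ref_fixtures$parameters, experiment)

# noiseless moisture-series dataset straight from the model equations,
# built without the package generator so generator tests stay independent
noiseless_dataset <- function(gt = NULL, chen = NULL,
                              tg_ws = seq(0.80, 1, length.out = 6),
                              tm_ws = seq(0.10, 0.70, length.out = 6)) {
  tg_points <- if (!is.null(gt)) {
    data.frame(ws = tg_ws, tg = gordon_taylor_tg(tg_ws, gt))
  }
  tm_points <- if (!is.null(chen)) {
    data.frame(ws = tm_ws, tm = chen_tm(tm_ws, chen))
  }
  thermal_dataset("noiseless", tg_points = tg_points, tm_points = tm_points)
}

# all-seven model list sharing one generator (for design-study helpers)
uniform_models <- function(coefficients) {
  m <- mixture_model("y", coefficients)
  stats::setNames(rep(list(m), 7), mixture_responses())
}
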