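#!/usr/bin/env Rscript
# Validates the full pipeline on synthetic moisture series with known
# ground truth: noiseless data must be recovered exactly, and with 1 degC
# measurement noise the intersection-derived ws' should stay within 0.01
# of truth in nearly all runs for the steep pure-fructose freezing curve.
# The same experiment with a flat high-maltodextrin-like curve shows why
# the study itself cautions against the intersection method there.

suppressPackageStartupMessages(library(statediagram))
dir.create("results", showWarnings = FALSE)

run_mc <- function(spec_for, n_runs = 200) {
  errs <- vapply(seq_len(n_runs), function(s) {
    d <- generate_thermal_dataset(spec_for(s))
    dg <- build_state_diagram(fit_gordon_taylor(d), fit_chen(d),
                              d$tg_prime_obs, d$tm_prime_obs)
    abs(dg$mfcc$ws_prime - attr(d, "truth")$mfcc$ws_prime)
  }, numeric(1))
  c(frac_within_001 = mean(errs < 0.01), median_err = median(errs),
    max_err = max(errs))
}

# steep curve: pure-fructose parameters (generator defaults)
steep <- run_mc(function(s) generator_spec(noise_sd_tm = 1,
                                           noise_sd_primes = 1, seed = s))
# flat curve: low-E system, same noise
flat <- run_mc(function(s) generator_spec(
  gt = gt_params(60.3, 5.59), chen = chen_params(0.0371, 0.1280),
  ws_prime = 0.807, tg_prime = -46.6,
  noise_sd_tm = 1, noise_sd_primes = 1, seed = s))

out <- rbind(data.frame(curve = "steep (fructose-like, E=0.0954)", t(steep)),
             data.frame(curve = "flat (maltodextrin-like, E=0.0371)", t(flat)))
write.csv(out, "results/ws_prime_recovery.csv", row.names = FALSE)
print(out, row.names = FALSE)
cat("\nws' recovery is reliable where the freezing curve is steep near the\n")
cat("intersection and degrades where it is flat - the known weakness of the\n")
cat("intersection method for high-molecular-weight systems.\n")
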