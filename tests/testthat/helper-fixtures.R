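# Shared fixtures: the illustrative Weibull survival curve (scale 12.89 years,
# shape 3.75) used throughout the worked examples, and a small simulated
# censored dataset.

wm_fix <- weibull_model(12.89, 3.75)

sim_small <- function(model = 1, n = 400, seed = 1234, ...) {
  simulate_study(model, n = n, seed = seed, ...)
}

fit_levels <- function(d) {
  lapply(split(d, d$covariate),
         function(dd) fit_weibull(dd$time, dd$status, level = dd$covariate[1]))
}
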