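# Shared fixtures built in code.

# full two-acclimation default panel config
two_acclimation_config <- function(n_replicates = 5, noise = 0.02,
                                   seed = 1, qi_slope = NULL) {
  strains <- c(default_panel("LL"), default_panel("HL"))
  if (!is.null(qi_slope)) {
    strains <- lapply(strains, function(s) { s$qi_slope <- qi_slope; s })
  }
  panel_config(strains, n_replicates = n_replicates,
               noise_rel_sd = noise, seed = seed)
}

# the six-point single-curve worked example for the retention rules
filter_example_points <- function() {
  data.frame(step_index = 1:6,
             E = c(50, 100, 200, 350, 500, 700),
             sigma = c(500, 490, 450, 420, 415, 414),
             y_npq = c(0.00, 0.05, 0.20, 0.35, 0.45, 0.50))
}
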