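# Shared fixtures: noiseless and noisy synthetic designs used across tests.

quiet_noise <- function() noise_model(sd_mult = 0, baseline = 0,
                                      sd_loading = 0)

ext_design <- function(k1 = 12.0, k2 = 0.7, k3 = 0.118, p_gly0 = 0.4,
                       times = c(0.05, 0.1, 0.2, 0.33, 0.5, 0.75, 1),
                       replicates = 1, noise = quiet_noise(), seed = 11L,
                       condition = "ext") {
  experiment_design("extension", condition, rate_constants(k1, k2, k3),
                    p_gly0, times, replicates, noise, seed)
}

hyd_design <- function(k2 = log(2) / 72, p_gly0 = 0.5,
                       times = c(0, 12, 24, 48, 72, 96),
                       replicates = 1, noise = quiet_noise(), seed = 13L,
                       condition = "hyd") {
  experiment_design("hydrolysis_acidic", condition,
                    rate_constants(0, k2, 0), p_gly0, times, replicates,
                    noise, seed)
}

lig_design <- function(k1 = 1.81, k2 = 0.3, k3 = 0.004, p_gly0 = 0.5,
                       times = c(0.05, 0.1, 0.25, 0.5, 1, 2),
                       replicates = 1, noise = quiet_noise(), seed = 17L,
                       condition = "lig") {
  experiment_design("ligation", condition, rate_constants(k1, k2, k3),
                    p_gly0, times, replicates, noise, seed)
}

ext_timecourse <- function(...) {
  g <- gen_extension_experiment(ext_design(...))
  to_timecourse(g$table, band_map("extension"))
}

# exact first-order decay time course for fit_kobs tests
decay_tc <- function(k, times = seq(0, 1, 0.1), p0 = 1) {
  data.frame(t_h = times, primer = p0 * exp(-k * times))
}
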