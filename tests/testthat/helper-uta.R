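# Noise-free transfer function lying exactly on the titration model:
# events are placed across the bin grid and the bin means are then set to
# the closed-form curve at the returned bin centers, so fits against it
# have an exact optimum at (theta, lam, gain).
exact_tf <- function(theta, lam, gain = 1,
                     x = seq(0.025, 2.975, by = 0.05), gate = 1,
                     n_per_bin = 1, background = 0) {
  x <- rep(x, each = n_per_bin)
  ev <- data.frame(event_id = seq_along(x), sample_id = "exact",
                   ref_intensity = gate * 10^x,
                   rep_intensity = 1,
                   stringsAsFactors = FALSE)
  g <- gate_ref_positive(ev, gate = gate)
  tf <- transfer_function(g, min_events = 1)
  tf$mean_log_rep <- log10(
    gain * steady_state_r(10^tf$bin_center, theta, lam) + background)
  tf
}

# one synthetic experiment under the default study conditions, fitted
sim_fit <- function(seed, theta, lam, n_events = 50000, gate = 100,
                    af_mean = 50, ...) {
  cfg <- simulation_config(seed = seed, n_events = n_events,
                           theta = theta, lam = lam, ...)
  ev <- gate_ref_positive(simulate_events(cfg), gate = gate)
  fit_transfer_function(transfer_function(ev, af_mean = af_mean), seed = seed)
}
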