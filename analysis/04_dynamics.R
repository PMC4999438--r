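#!/usr/bin/env Rscript
# Stimulus-locked network dynamics under 40 Hz drive: control versus
# prolonged I-to-E inhibition (tau_ie = 25 ms), plus the synthetic
# beat-skipping/amplitude-reduction dissociation.
# Finding: under prolonged inhibition excitatory cells skip drive cycles
# (population spike count falls ~4x and the locked histograms develop a
# cycle asymmetry), raising 20 Hz EEG power by orders of magnitude while
# 40 Hz power falls; because different cells skip different cycles, the
# two-cycle population average stays nearly symmetric at this scale. The
# synthetic pulse trains isolate the two mechanisms exactly: suppressing
# every other pulse transfers power 40 -> 20 Hz, while halving all pulse
# amplitudes lowers 40 Hz power and creates no 20 Hz component.

library(szgamma)
dir.create("results", showWarnings = FALSE)

sim <- simulation_config(duration_ms = 3000, transient_ms = 500)
mini <- network_config(e_grid = c(12, 12), i_grid = c(6, 6), seed = 1)
stim <- stimulus_spec("periodic", 40, 3000)

for (cond in c("control", "tau_ie25")) {
  net <- build_network(mini)
  if (cond == "tau_ie25")
    net <- apply_parameter_vector(net, parameter_vector(tau_ie = 25))
  res <- run_simulation(net, stim, sim)
  eeg <- compute_eeg(res)
  sla <- stimulus_locked_average(eeg, res$thalamic_train, n_cycles = 2,
                                 transient_ms = 500)
  write.csv(data.frame(t_ms = seq_along(sla$avg) - 0.5, eeg = sla$avg),
            sprintf("results/locked_eeg_%s.csv", cond), row.names = FALSE)
  for (pop in c("E", "I")) {
    h <- spike_histogram(res$spikes[res$spikes$population == pop, ],
                         res$thalamic_train, bin_ms = 1, transient_ms = 500)
    write.csv(data.frame(t_ms = h$bin_centers_ms, count = h$counts),
              sprintf("results/locked_hist_%s_%s.csv", pop, cond),
              row.names = FALSE)
  }
  ps <- power_spectrum(eeg, window = c(500, 3000))
  cat(sprintf("%-9s P40 = %.3g  P20 = %.3g  (first/second cycle peak ratio %.2f)\n",
              cond, band_power(ps, 40), band_power(ps, 20),
              max(sla$avg[1:25]) / max(sla$avg[26:50])))
}

## synthetic dissociation (mechanism-level, independent of the network)
plain <- power_spectrum(generate_cycle_skipping_eeg(40, 10000, skip_every = Inf))
skip <- power_spectrum(generate_cycle_skipping_eeg(40, 10000, skip_every = 2))
half <- power_spectrum(generate_cycle_skipping_eeg(40, 10000,
                                                   skip_every = Inf,
                                                   amplitude = 0.5))
out <- data.frame(
  signal = c("plain", "skip_every_2", "half_amplitude"),
  p40 = c(band_power(plain, 40), band_power(skip, 40), band_power(half, 40)),
  p20 = c(band_power(plain, 20), band_power(skip, 20), band_power(half, 20)))
write.csv(out, "results/skipping_dissociation.csv", row.names = FALSE)
print(out, digits = 3)
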