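#!/usr/bin/env Rscript
# Frequency encoding: steady S occupancy versus pulse rate, against the
# discrete-time saturating leaky integrator.
#
# Both printed O6-S13 parameter sets are driven with 5 ms pulses from -80
# to 0 mV at 2-100 Hz plus the constant-depolarisation limit. The S
# occupancy settles into a frequency-dependent oscillation band; the
# mathematical integrator (tau_leak = 435 ms, y_inc = 0.2) tracks the set-1
# model closely at low rates and parts ways under sustained input, where
# it saturates near its plateau while the channel model relaxes to
# P_S_inf ~ 0.7.

library(navlti)
dir.create("results", showWarnings = FALSE)

freqs <- c(2, 5, 10, 20, 50, 100)

run_set <- function(set, duration) {
  model <- make_lti_model(os_set = set)
  fr <- frequency_response(model, freqs, pulse_ms = 5, V_hold = -80,
                           V_pulse = 0, duration = duration)
  fr_const <- frequency_response(model, 200, pulse_ms = 5, duration = 2000)
  fr_const$freq_hz <- Inf   # constant-depolarisation limit
  rbind(fr, fr_const)
}

fr1 <- run_set("set1", 8000)
fr2 <- run_set("set2", 12000)   # slower leak needs a longer settle
write.csv(cbind(os_set = "set1", fr1), "results/frequency_response_set1.csv",
          row.names = FALSE)
write.csv(cbind(os_set = "set2", fr2), "results/frequency_response_set2.csv",
          row.names = FALSE)

params <- leaky_integrator_params(tau_leak = 435, dt = 0.05, y_inc = 0.2,
                                  t_p = 5)
cmp_in <- fr1
cmp_in$freq_hz[is.infinite(cmp_in$freq_hz)] <- 200   # pulse = period
cmp <- compare_ps_vs_integrator(cmp_in, params, pulse_ms = 5)
write.csv(cmp, "results/integrator_comparison_set1.csv", row.names = FALSE)

cat("set 1 steady P_S band by frequency:\n")
print(fr1[, c("freq_hz", "ps_min", "ps_max", "ps_mean")], digits = 3)
cat(sprintf("\n100 Hz oscillation: %.3f - %.3f\n",
            fr1$ps_min[fr1$freq_hz == 100], fr1$ps_max[fr1$freq_hz == 100]))
cat(sprintf("integrator rms deviation of steady means: %.4f\n",
            attr(cmp, "rms")))
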