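#!/usr/bin/env Rscript
# Step 3 — simulate fusiform-cell recordings and extract every biophysical
# feature: XE991-sensitive tail current and G-V Boltzmann parameters,
# ZD7288-sensitive sag ratio, onset and steady-state input resistance,
# resting potential (TTX), spontaneous firing rate.

suppressPackageStartupMessages(library(fusiform))
dir.create("results", showWarnings = FALSE)

presets <- preset_states()
presets_ns <- preset_states(spike_on = FALSE)
pl <- protocol_library()

rows <- lapply(names(presets), function(nm) {
  cell <- presets[[nm]]
  cell_ns <- presets_ns[[nm]]

  pre <- simulate(cell_ns, pl$gv_ramp)
  post <- simulate(cell_ns, pl$gv_ramp, drug_state(xe991 = TRUE))
  fit <- fit_boltzmann(ramp_to_GV(subtract_traces(pre, post)))

  ta <- simulate(cell_ns, pl$kcnq_deactivation)
  tb <- simulate(cell_ns, pl$kcnq_deactivation, drug_state(xe991 = TRUE))
  tail_amp <- tail_current_amplitude(subtract_traces(ta, tb))$amplitude

  sag <- zd_sensitive_sag(
    simulate(cell, pl$sag_step, drug_state(ttx = TRUE)),
    simulate(cell, pl$sag_step, drug_state(ttx = TRUE, zd7288 = TRUE)))

  rin <- input_resistance(lapply(pl$rin_family, function(pr)
    simulate(cell, pr, drug_state(ttx = TRUE))))

  gap4 <- protocol_library(gap_free_s = 4)$gap_free
  rmp <- resting_potential(simulate(cell, gap4, drug_state(ttx = TRUE)))
  rate <- firing_rate(simulate(cell, pl$gap_free))

  data.frame(preset = nm,
             v_half_mV = fit$v_half, g_max_nS = fit$g_max, slope_mV = fit$k,
             tail_pA = tail_amp, zd_sag_pct = sag,
             rin_onset_MOhm = rin$onset_MOhm,
             rin_steady_MOhm = rin$steady_state_MOhm,
             rmp_mV = rmp, firing_Hz = rate)
})
features <- do.call(rbind, rows)
write_ratio_table(features, "results/ephys_features.csv")
print(features, digits = 4)

cat("\nKey contrasts:\n")
cat(sprintf("  KCNQ half-activation: sham %.1f mV vs 4-day %.1f mV (depolarized shift)\n",
            features$v_half_mV[features$preset == "control"],
            features$v_half_mV[features$preset == "noise_4day"]))
cat(sprintf("  ZD-sensitive sag: control %.1f%%, tinnitus %.1f%%, non-tinnitus %.1f%%\n",
            features$zd_sag_pct[features$preset == "control"],
            features$zd_sag_pct[features$preset == "tinnitus_day7"],
            features$zd_sag_pct[features$preset == "non_tinnitus_day7"]))
cat(sprintf("  RMP: control %.1f mV vs non-tinnitus %.1f mV (hyperpolarized)\n",
            features$rmp_mV[features$preset == "control"],
            features$rmp_mV[features$preset == "non_tinnitus_day7"]))
cat("Wrote results/ephys_features.csv\n")
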