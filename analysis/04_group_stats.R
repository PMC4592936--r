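#!/usr/bin/env Rscript
# Step 4 — group-level statistics with the normality-gated decision tree.
#
# Simulates per-cell sag measurements for three groups of cells (control,
# tinnitus, non-tinnitus) by jittering the HCN conductance across cells
# (log-normal, ~15% CV, emulating biological scatter), then compares groups
# with the Lilliefors-gated test choice and the incidence comparison.

suppressPackageStartupMessages(library(fusiform))
set.seed(2026)

presets <- preset_states(spike_on = FALSE)
pl <- protocol_library()
sag_one <- function(cell, jitter) {
  cell$g_hcn <- cell$g_hcn * jitter
  zd_sensitive_sag(simulate(cell, pl$sag_step),
                   simulate(cell, pl$sag_step, drug_state(zd7288 = TRUE)))
}
sample_group <- function(cell, n) {
  vapply(exp(rnorm(n, -0.15^2 / 2, 0.15)), function(j) sag_one(cell, j), 0)
}

groups <- list(
  control = sample_group(presets$control, 8),
  tinnitus = sample_group(presets$tinnitus_day7, 6),
  non_tinnitus = sample_group(presets$non_tinnitus_day7, 8)
)
cat("Per-group ZD-sensitive sag (mean +/- SEM):\n")
for (nm in names(groups)) {
  g <- groups[[nm]]
  cat(sprintf("  %-13s %.1f +/- %.1f %% (n = %d)\n", nm, mean(g),
              sd(g) / sqrt(length(g)), length(g)))
}

res <- compare_groups(groups, seed = 11)
print(res)

pair <- compare_groups(groups[c("control", "non_tinnitus")], seed = 12)
cat("Control vs non-tinnitus: ")
print(pair)

inc <- compare_incidence(11, 21, 0, 19)
cat(sprintf("Incidence, noise-exposed vs sham: %.1f%% vs %.1f%%, Fisher p = %.3g\n",
            inc$incidence_pct[1], inc$incidence_pct[2], inc$p_value))

out <- data.frame(
  comparison = c("three_group_sag", "control_vs_non_tinnitus_sag"),
  test = c(res$test, pair$test), branch = c(res$branch, pair$branch),
  statistic = c(res$statistic, pair$statistic),
  p_value = c(res$p_value, pair$p_value)
)
write_ratio_table(out, "results/group_stats.csv")
cat("Wrote results/group_stats.csv\n")
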