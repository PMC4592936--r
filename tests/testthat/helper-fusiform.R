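# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force implementation of the sorted-jump exclusion rule:
# walk the sorted list linearly, drop everything from the first >0.5 jump on.
oracle_jump_filter <- function(ratios, max_jump = 0.5, max_excluded = 5) {
  if (length(ratios) == 0)
    return(list(retained = numeric(0), n_excluded = 0L, dropped = TRUE))
  s <- sort(ratios)
  keep <- rep(TRUE, length(s))
  for (i in seq_along(s)[-1]) {
    if (s[i] - s[i - 1] > max_jump) {
      keep[i:length(s)] <- FALSE
      break
    }
  }
  n_excl <- sum(!keep)
  list(retained = s[keep], n_excluded = as.integer(n_excl),
       dropped = n_excl > max_excluded)
}

# Exhaustive enumeration of Fisher's exact two-sided p for a 2x2 table with
# fixed margins (small n only).
oracle_fisher_p <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  xs <- max(0, k - n2):min(n1, k)
  probs <- vapply(xs, function(x) {
    choose(n1, x) * choose(n2, k - x) / choose(n1 + n2, k)
  }, 0)
  p_obs <- probs[xs == k1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal voltage-clamp trace object for feature-extraction unit tests.
fake_vc_trace <- function(command, signal, dt = 0.025,
                          segments = data.frame(duration_ms = length(command) * dt,
                                                from = command[1],
                                                to = command[length(command)])) {
  structure(list(
    signal = signal, command = command,
    time_ms = seq_along(command) * dt, dt = dt, mode = "voltage_clamp",
    protocol = structure(list(mode = "voltage_clamp", segments = segments,
                              bias_to = NULL, dt = dt),
                         class = "clamp_protocol"),
    currents = NULL, spike_times = NULL
  ), class = "ephys_trace")
}

# Profile with fully controlled latent ratios (no sampling), for noise-free
# pipeline checks.
fixed_profile <- function(mouse_id = "M1", gap_pre = 0.67, gap_post = 0.67,
                          ppi_pre = 0.6, ppi_post = 0.6,
                          startle_scale = 100, trial_noise_sd = 0,
                          baseline_sd = 0.5, artifact_rate = 0) {
  f <- as.character(startle_frequencies)
  mk <- function(pre, post) {
    m <- cbind(pre = rep(pre, length.out = 6), post = rep(post, length.out = 6))
    rownames(m) <- f
    m
  }
  structure(list(
    mouse_id = mouse_id, cohort = "control",
    latent_gap_ratio = mk(gap_pre, gap_post),
    latent_ppi_ratio = mk(ppi_pre, ppi_post),
    latent_delta = NULL,
    startle_scale = startle_scale, trial_noise_sd = trial_noise_sd,
    baseline_artifact_rate = artifact_rate, baseline_sd = baseline_sd
  ), class = "mouse_profile")
}

small_protocols <- function() protocol_library(gap_free_s = 4)
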