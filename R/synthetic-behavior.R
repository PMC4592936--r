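#' @useDynLib fusiform, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd qnorm pnorm lm coef median aov TukeyHSD
#'   t.test wilcox.test kruskal.test fisher.test binom.test approx uniroot
#' @importFrom utils head tail write.csv read.csv
NULL

#' Background frequencies used in the startle battery (kHz)
#' @export
startle_frequencies <- c(10, 12, 16, 20, 24, 32)

#' Frequencies at which tinnitus-like gap-detection deficits are modeled (kHz)
#' @export
high_frequencies <- c(20, 24, 32)

#' Configuration for a synthetic startle-test cohort
#'
#' Bundles the study-design constants of the gap/prepulse-inhibition battery
#' with the statistical parameters of the simulated animals. The control
#' change-score (post minus pre) distribution of final gap-startle ratios is
#' Normal(`control_delta_mu`, `control_delta_sigma`); the generator splits this
#' variance into a latent between-mouse component and the measurement
#' component implied by the trial-level noise model, so the *pipeline-level*
#' change scores recover the configured Gaussian.
#'
#' @param n_control,n_tinnitus,n_non_tinnitus number of mice per cohort.
#' @param control_delta_mu,control_delta_sigma mean and SD of the control
#'   distribution of per-frequency changes in final gap-startle ratio.
#' @param tinnitus_effect named numeric vector of additive latent shifts in the
#'   post-exposure gap ratio of tinnitus-cohort mice, one entry per high
#'   frequency (kHz names).
#' @param trial_noise_sd log-scale SD of the multiplicative trial-to-trial
#'   noise on startle peak-to-peak amplitude (0 disables noise).
#' @param baseline_artifact_rate probability that a trial's baseline window
#'   carries a movement artifact (baseline SD inflated 10x).
#' @param startle_scale expected no-gap startle peak-to-peak amplitude (AU).
#' @param baseline_sd SD of baseline force movement (AU).
#' @param seed integer seed controlling every random draw.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 21, n_tinnitus = 11, n_non_tinnitus = 10,
                          control_delta_mu = -0.02, control_delta_sigma = 0.15,
                          tinnitus_effect = c("20" = 0.20, "24" = 0.25, "32" = 0.35),
                          trial_noise_sd = 0.15,
                          baseline_artifact_rate = 0.02,
                          startle_scale = 100,
                          baseline_sd = 0.5,
                          seed = 1L) {
  stopifnot(control_delta_sigma >= 0,
            n_control >= 1, n_tinnitus >= 0, n_non_tinnitus >= 0,
            trial_noise_sd >= 0, baseline_artifact_rate >= 0,
            baseline_artifact_rate <= 1, startle_scale > 0)
  if (!all(names(tinnitus_effect) %in% as.character(high_frequencies)))
    stop("tinnitus_effect must be named by high frequencies (20/24/32 kHz)")
  structure(list(
    n_control = n_control, n_tinnitus = n_tinnitus,
    n_non_tinnitus = n_non_tinnitus,
    control_delta_mu = control_delta_mu,
    control_delta_sigma = control_delta_sigma,
    tinnitus_effect = tinnitus_effect,
    trial_noise_sd = trial_noise_sd,
    baseline_artifact_rate = baseline_artifact_rate,
    startle_scale = startle_scale,
    baseline_sd = baseline_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Measurement variance of a final per-frequency change score implied by the
# multiplicative log-normal trial noise, for a typical latent ratio `latent`
# and `n_eff` retained pair ratios per phase (12 pairs x 3 rounds).  A pair
# ratio is latent * exp(s*(Z1 - Z2)), so Var = latent^2 e^{2s^2}(e^{2s^2}-1).
delta_measurement_var <- function(trial_noise_sd, latent = 0.67, n_eff = 36) {
  s2 <- 2 * trial_noise_sd^2
  2 * latent^2 * exp(s2) * (expm1(s2)) / n_eff
}

# Latent between-mouse SD so that latent + measurement variance matches the
# configured control_delta_sigma.
latent_delta_sd <- function(config) {
  v <- config$control_delta_sigma^2 -
    delta_measurement_var(config$trial_noise_sd)
  sqrt(max(v, 0))
}

clip_ratio <- function(x) pmin(pmax(x, 1e-3), 1.2)

#' Latent startle profile for one simulated mouse
#'
#' Draws the per-frequency latent gap-startle and PPI ratios for both test
#' phases. Control and non-tinnitus mice receive pre/post changes drawn from
#' the control Gaussian; tinnitus mice additionally receive the configured
#' positive shift at 20-32 kHz, with low-frequency changes folded below the
#' control mean so the gap-detection deficit is confined to high frequencies.
#'
#' @param mouse_id character id.
#' @param cohort one of `"control"`, `"tinnitus"`, `"non_tinnitus"`.
#' @param config a [cohort_config()].
#' @return an object of class `mouse_profile` holding latent ratio matrices
#'   (frequency x phase) and the latent gap change scores.
#' @export
mouse_profile <- function(mouse_id, cohort = c("control", "tinnitus", "non_tinnitus"),
                          config = cohort_config()) {
  cohort <- match.arg(cohort)
  f <- as.character(startle_frequencies)
  sd_lat <- latent_delta_sd(config)
  pre_gap <- clip_ratio(rnorm(6, 0.67, 0.05))
  pre_ppi <- clip_ratio(rnorm(6, 0.60, 0.06))
  names(pre_gap) <- names(pre_ppi) <- f

  draw_delta <- function() rnorm(6, config$control_delta_mu, sd_lat)
  delta <- draw_delta()
  names(delta) <- f
  if (cohort == "tinnitus") {
    # confine the deficit to high frequencies: fold low-frequency changes
    # below the control mean, add the configured shift at high frequencies
    low <- setdiff(f, names(config$tinnitus_effect))
    delta[low] <- config$control_delta_mu - abs(delta[low] - config$control_delta_mu)
    delta[names(config$tinnitus_effect)] <-
      delta[names(config$tinnitus_effect)] + config$tinnitus_effect
    thr <- config$control_delta_mu + 2 * config$control_delta_sigma
    while (!any(delta[names(config$tinnitus_effect)] > thr)) {
      d2 <- draw_delta()
      names(d2) <- f
      delta[names(config$tinnitus_effect)] <-
        d2[names(config$tinnitus_effect)] + config$tinnitus_effect
    }
  }
  delta_ppi <- rnorm(6, 0, 0.05)
  names(delta_ppi) <- f

  gap <- cbind(pre = pre_gap, post = clip_ratio(pre_gap + delta))
  ppi <- cbind(pre = pre_ppi, post = clip_ratio(pre_ppi + delta_ppi))
  structure(list(
    mouse_id = mouse_id, cohort = cohort,
    latent_gap_ratio = gap, latent_ppi_ratio = ppi,
    latent_delta = delta,
    startle_scale = config$startle_scale,
    trial_noise_sd = config$trial_noise_sd,
    baseline_artifact_rate = config$baseline_artifact_rate,
    baseline_sd = config$baseline_sd
  ), class = "mouse_profile")
}

# Deterministic startle transient: damped sinusoid sampled at `fs_khz`,
# normalized to unit peak-to-peak, starting at the stimulus onset.
startle_shape <- function(n_post, fs_khz = 1, freq_hz = 40, decay_ms = 50) {
  t <- seq_len(n_post) / fs_khz            # ms after onset
  s <- exp(-t / decay_ms) * sin(2 * pi * freq_hz * t / 1000)
  s / (max(s) - min(s))
}

#' Generate a single startle-trial waveform
#'
#' Builds one force waveform: Gaussian baseline movement before the startle
#' stimulus, then a damped-sinusoid startle transient whose expected
#' peak-to-peak amplitude is `startle_scale` times the latent ratio
#' (gap/prepulse trials) or times 1 (no-gap/startle-only trials), with
#' multiplicative log-normal trial noise of unit mean.
#'
#' @param trial_type one of `"gap"`, `"no_gap"`, `"prepulse"`, `"startle_only"`.
#' @param frequency_khz background/prepulse frequency; must be a battery
#'   frequency.
#' @param phase `"pre"` or `"post"`.
#' @param profile a [mouse_profile()].
#' @param seed optional seed.
#' @param trial_ms,onset_ms,fs_khz trial length, stimulus onset, sampling rate.
#' @param baseline_ms width of the baseline window preceding the onset.
#' @param artifact force the baseline-artifact state instead of drawing it.
#' @return an object of class `startle_trial` with fields `waveform`,
#'   `onset_index`, `baseline_window`, `fs_khz` and trial metadata.
#' @export
generate_startle_waveform <- function(trial_type, frequency_khz, phase, profile,
                                      seed = NULL, trial_ms = 500, onset_ms = 300,
                                      fs_khz = 1, baseline_ms = 100,
                                      artifact = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trial_type <- match.arg(trial_type, c("gap", "no_gap", "prepulse", "startle_only"))
  phase <- match.arg(phase, c("pre", "post"))
  fk <- as.character(frequency_khz)
  if (!fk %in% rownames(profile$latent_gap_ratio))
    stop("unknown frequency: ", frequency_khz, " kHz")
  ratio <- switch(trial_type,
                  gap = profile$latent_gap_ratio[fk, phase],
                  prepulse = profile$latent_ppi_ratio[fk, phase],
                  1.0)
  s <- profile$trial_noise_sd
  mult <- if (s > 0) exp(rnorm(1, -s^2 / 2, s)) else 1
  amp <- profile$startle_scale * ratio * mult

  n_pre <- onset_ms * fs_khz
  n_post <- (trial_ms - onset_ms) * fs_khz
  if (is.null(artifact)) artifact <- runif(1) < profile$baseline_artifact_rate
  b_sd <- profile$baseline_sd * if (artifact) 10 else 1
  wave <- c(rnorm(n_pre, 0, b_sd), amp * startle_shape(n_post, fs_khz))
  structure(list(
    waveform = wave,
    fs_khz = fs_khz,
    onset_index = n_pre + 1L,
    baseline_window = seq.int(n_pre - baseline_ms * fs_khz + 1L, n_pre),
    trial_type = trial_type, frequency_khz = frequency_khz, phase = phase,
    artifact = artifact
  ), class = "startle_trial")
}

session_trial_plan <- function() {
  gap <- expand.grid(frequency_khz = startle_frequencies, rep = 1:12)
  ppi <- expand.grid(frequency_khz = startle_frequencies, rep = 1:5)
  plan <- rbind(
    data.frame(measure = "gap", frequency_khz = gap$frequency_khz),
    data.frame(measure = "ppi", frequency_khz = ppi$frequency_khz)
  )
  plan[sample.int(nrow(plan)), , drop = FALSE]
}

#' Generate one full startle-test session (three rounds)
#'
#' Each round holds 72 gap/no-gap pairs (12 per background frequency) and 30
#' prepulse/startle-only pairs (5 per frequency); trials within a pair
#' alternate (reference trial first, probe trial second, i.e. no-gap then gap).
#' Pair order within a round is randomized.
#'
#' @param profile a [mouse_profile()].
#' @param phase `"pre"` or `"post"`.
#' @param seed optional seed.
#' @param trial_ms,onset_ms,fs_khz,baseline_ms waveform geometry, as in
#'   [generate_startle_waveform()].
#' @return an object of class `startle_session`: a list with `trials` (one row
#'   per trial: round_index, pair_id, trial_type, frequency_khz, ...) and
#'   `waveforms` (matrix, one row per trial).
#' @export
generate_session <- function(profile, phase, seed = NULL,
                             trial_ms = 500, onset_ms = 300, fs_khz = 1,
                             baseline_ms = 100) {
  if (!is.null(seed)) set.seed(seed)
  phase <- match.arg(phase, c("pre", "post"))
  n_pre <- onset_ms * fs_khz
  n_post <- (trial_ms - onset_ms) * fs_khz
  shape <- startle_shape(n_post, fs_khz)

  rounds <- lapply(1:3, function(r) {
    plan <- session_trial_plan()
    ref <- ifelse(plan$measure == "gap", "no_gap", "startle_only")
    probe <- ifelse(plan$measure == "gap", "gap", "prepulse")
    data.frame(
      round_index = r,
      pair_id = rep(paste0(phase, "_r", r, "_p", seq_len(nrow(plan))), each = 2),
      measure = rep(plan$measure, each = 2),
      frequency_khz = rep(plan$frequency_khz, each = 2),
      trial_type = as.vector(rbind(ref, probe)),
      stringsAsFactors = FALSE
    )
  })
  trials <- do.call(rbind, rounds)
  trials$mouse_id <- profile$mouse_id
  trials$phase <- phase
  n <- nrow(trials)

  fk <- as.character(trials$frequency_khz)
  ratio <- rep(1, n)
  is_gap <- trials$trial_type == "gap"
  is_pp <- trials$trial_type == "prepulse"
  ratio[is_gap] <- profile$latent_gap_ratio[fk[is_gap], phase]
  ratio[is_pp] <- profile$latent_ppi_ratio[fk[is_pp], phase]
  s <- profile$trial_noise_sd
  mult <- if (s > 0) exp(rnorm(n, -s^2 / 2, s)) else rep(1, n)
  amp <- profile$startle_scale * ratio * mult
  trials$artifact <- runif(n) < profile$baseline_artifact_rate
  b_sd <- profile$baseline_sd * ifelse(trials$artifact, 10, 1)

  base <- matrix(rnorm(n * n_pre), n, n_pre) * b_sd
  waveforms <- cbind(base, amp %o% shape)
  structure(list(
    trials = trials,
    waveforms = waveforms,
    fs_khz = fs_khz,
    onset_index = n_pre + 1L,
    baseline_window = seq.int(n_pre - baseline_ms * fs_khz + 1L, n_pre)
  ), class = "startle_session")
}

#' Generate a complete synthetic cohort (pre- and post-exposure sessions)
#'
#' Deterministic given `config$seed`. Control and non-tinnitus mice draw all
#' latent per-frequency changes from the control Gaussian; tinnitus-cohort
#' mice get the configured high-frequency shift and are guaranteed at least
#' one high-frequency latent change above the nominal mu + 2 sigma threshold.
#'
#' @param config a [cohort_config()].
#' @return an object of class `startle_cohort`: `profiles` (named list of
#'   [mouse_profile()]s) and `sessions` (per mouse, `$pre` and `$post`
#'   [generate_session()] outputs).
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  ids <- c(
    if (config$n_control > 0) sprintf("C%02d", seq_len(config$n_control)),
    if (config$n_tinnitus > 0) sprintf("T%02d", seq_len(config$n_tinnitus)),
    if (config$n_non_tinnitus > 0) sprintf("N%02d", seq_len(config$n_non_tinnitus))
  )
  cohorts <- c(
    rep("control", config$n_control),
    rep("tinnitus", config$n_tinnitus),
    rep("non_tinnitus", config$n_non_tinnitus)
  )
  profiles <- vector("list", length(ids))
  sessions <- vector("list", length(ids))
  names(profiles) <- names(sessions) <- ids
  for (i in seq_along(ids)) {
    profiles[[i]] <- mouse_profile(ids[i], cohorts[i], config)
    sessions[[i]] <- list(
      pre = generate_session(profiles[[i]], "pre"),
      post = generate_session(profiles[[i]], "post")
    )
  }
  structure(list(config = config, profiles = profiles, sessions = sessions),
            class = "startle_cohort")
}

#' Draw control-cohort change scores directly from the Gaussian null
#'
#' Convenience generator for null-calibration studies: per-mouse,
#' per-frequency changes in final gap-startle ratio drawn from
#' Normal(`mu`, `sigma`), the distribution the full pipeline produces for
#' control animals.
#'
#' @param n_mice number of mice.
#' @param mu,sigma Gaussian parameters of the control change distribution.
#' @param frequencies tested frequencies (kHz).
#' @param seed optional seed.
#' @return data.frame with columns `mouse_id`, `frequency_khz`, `delta`.
#' @export
simulate_control_deltas <- function(n_mice = 21, mu = -0.02, sigma = 0.15,
                                    frequencies = startle_frequencies,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- length(frequencies)
  data.frame(
    mouse_id = rep(sprintf("C%02d", seq_len(n_mice)), each = nf),
    frequency_khz = rep(frequencies, n_mice),
    delta = rnorm(n_mice * nf, mu, sigma)
  )
}

#' Write a cohort to disk as plain-text CSV files
#'
#' One `trials.csv` of trial metadata plus one waveform CSV per session
#' (columns `time_ms` then one column per trial), under `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (id in names(cohort$sessions)) {
    for (ph in c("pre", "post")) {
      s <- cohort$sessions[[id]][[ph]]
      tr <- s$trials
      tr$waveform_file <- sprintf("%s_%s.csv", id, ph)
      tr$trial_index <- seq_len(nrow(tr))
      meta[[paste(id, ph)]] <- tr
      w <- data.frame(time_ms = seq_len(ncol(s$waveforms)) / s$fs_khz,
                      t(s$waveforms))
      names(w) <- c("time_ms", sprintf("trial_%03d", seq_len(nrow(s$waveforms))))
      write.csv(w, file.path(dir, tr$waveform_file[1]), row.names = FALSE)
    }
  }
  write.csv(do.call(rbind, meta), file.path(dir, "trials.csv"),
            row.names = FALSE)
  invisible(dir)
}
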