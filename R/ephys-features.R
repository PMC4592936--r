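# Extraction of the standard fusiform-cell biophysical features from clamp
# traces: drug-subtracted tail currents, conductance-voltage Boltzmann fits,
# HCN sag ratio, onset/steady-state input resistance, resting potential,
# spike detection and averaged-spike parameters.

stopifnot_same_protocol <- function(a, b) {
  if (a$mode != b$mode || a$dt != b$dt ||
      length(a$signal) != length(b$signal) ||
      !isTRUE(all.equal(a$command, b$command, tolerance = 1e-9)))
    stop("traces differ in protocol or sampling; cannot combine")
}

#' Pointwise difference of two traces (pre-drug minus post-drug)
#'
#' The standard drug-subtraction operation: e.g. pre minus post XE991
#' isolates the KCNQ current.
#'
#' @param pre_drug,post_drug `ephys_trace` objects from the same protocol.
#' @return an `ephys_trace` whose `signal` is the pointwise difference.
#' @export
subtract_traces <- function(pre_drug, post_drug) {
  stopifnot_same_protocol(pre_drug, post_drug)
  out <- pre_drug
  out$signal <- pre_drug$signal - post_drug$signal
  out$currents <- NULL
  out
}

segment_bounds <- function(trace) {
  # sample index ranges of the protocol segments
  n <- round(trace$protocol$segments$duration_ms / trace$dt)
  end <- cumsum(n)
  data.frame(start = c(1, head(end, -1) + 1), end = end)
}

#' Tail-current amplitude from the deactivation protocol
#'
#' For the -30 to -50 mV step protocol: amplitude is the current shortly
#' after step onset (median over a post-settle window) minus the steady
#' current at the end of the step. The alternative peak-minus-baseline
#' reading (instantaneous current minus the pre-step holding current) is
#' also returned.
#'
#' @param diff_trace a (typically XE991-subtracted) voltage-clamp trace from
#'   the `kcnq_deactivation` protocol.
#' @param settle_window window after step onset for the instantaneous
#'   current (ms).
#' @param steady_window length of the end-of-step steady window (ms).
#' @return list: `amplitude` (pA), `alt_amplitude`, `instantaneous`,
#'   `steady`, `holding`, and the windows used.
#' @export
tail_current_amplitude <- function(diff_trace, settle_window = c(20, 60),
                                   steady_window = 100) {
  if (diff_trace$mode != "voltage_clamp") stop("expected a voltage-clamp trace")
  b <- segment_bounds(diff_trace)
  if (nrow(b) < 2) stop("deactivation step segment not found")
  step <- b[nrow(b), ]
  dt <- diff_trace$dt
  iw <- step$start + round(settle_window / dt)
  if (iw[2] > step$end) stop("settle window extends past the step segment")
  sw <- seq(step$end - round(steady_window / dt) + 1, step$end)
  inst <- median(diff_trace$signal[seq(iw[1], iw[2])])
  steady <- mean(diff_trace$signal[sw])
  hold <- mean(diff_trace$signal[seq(max(1, step$start - round(500 / dt)),
                                     step$start - 1)])
  list(amplitude = inst - steady, alt_amplitude = inst - hold,
       instantaneous = inst, steady = steady, holding = hold,
       settle_window = settle_window, steady_window = steady_window)
}

#' Conductance-voltage curve from a slow ramp
#'
#' Converts a (drug-subtracted) ramp current to chord conductance by Ohm's
#' law, G = I/(V - V_r), with points within `guard_mV` of the reversal
#' excluded. Samples are binned on the command voltage; with an up-down ramp
#' the two branches fall in the same bins, cancelling first-order kinetic
#' lag.
#'
#' @param diff_trace voltage-clamp `ephys_trace` (current in pA).
#' @param v_rev reversal potential (mV); -85.5 mV for potassium.
#' @param span voltage span used for the curve (mV).
#' @param guard_mV exclusion half-width around `v_rev`.
#' @param bin_mV voltage bin width.
#' @return data.frame of class `gv_curve`: `v` (bin center, mV), `g` (nS),
#'   `n` (samples per bin); attribute `n_dropped` counts guard exclusions.
#' @export
ramp_to_GV <- function(diff_trace, v_rev = -85.5, span = c(-80, 0),
                       guard_mV = 5, bin_mV = 0.5) {
  if (diff_trace$mode != "voltage_clamp") stop("expected a voltage-clamp trace")
  v <- diff_trace$command
  i <- diff_trace$signal
  dv <- c(0, diff(v))
  moving <- dv != 0                     # ramp samples only, not holds
  use <- moving & v >= span[1] & v <= span[2]
  guard <- use & abs(v - v_rev) < guard_mV
  use <- use & !guard
  if (!any(use)) stop("no usable ramp samples in the requested span")
  g <- i[use] / (v[use] - v_rev)
  bin <- round(v[use] / bin_mV) * bin_mV
  branch <- ifelse(dv[use] > 0, "ascending", "descending")
  # average within each ramp branch first, then across branches, so the
  # first-order kinetic lag cancels regardless of per-bin sample counts
  agg <- aggregate(g, list(v = bin, branch = branch), mean)
  per_bin <- aggregate(agg$x, list(v = agg$v), mean)
  cnt <- aggregate(g, list(v = bin), length)
  out <- data.frame(v = per_bin$v, g = per_bin$x,
                    n = cnt$x[match(per_bin$v, cnt$v)])
  attr(out, "n_dropped") <- sum(guard)
  class(out) <- c("gv_curve", "data.frame")
  out
}

#' Fit a Boltzmann activation function to a conductance-voltage curve
#'
#' Least-squares fit of `G(V) = G_max / (1 + exp(-(V - V_half)/k))` with
#' multi-start Levenberg-Marquardt initialization. Non-convergence (or a
#' curve with no rising phase) is flagged, never silently defaulted.
#'
#' @param gv a [ramp_to_GV()] data.frame (columns `v`, `g`).
#' @param starts_v_half,starts_k initialization grids.
#' @return object of class `boltzmann_fit`: `g_max` (nS), `v_half` (mV), `k`
#'   (mV), `residual_norm`, `converged`, `fit` (the nls object or NULL).
#' @export
fit_boltzmann <- function(gv, starts_v_half = NULL, starts_k = c(4, 6, 10)) {
  stopifnot(nrow(gv) >= 8)
  v <- gv$v
  g <- gv$g
  if (diff(range(g)) < 1e-8 * max(1, max(abs(g)))) {
    return(structure(list(g_max = NA_real_, v_half = NA_real_, k = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          fit = NULL), class = "boltzmann_fit"))
  }
  if (is.null(starts_v_half))
    starts_v_half <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  best <- NULL
  for (v0 in starts_v_half) for (k0 in starts_k) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        g ~ gmax / (1 + exp(-(v - vhalf) / k)),
        start = list(gmax = max(g) * 1.05, vhalf = v0, k = k0),
        lower = c(gmax = 1e-6, vhalf = -150, k = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(g_max = NA_real_, v_half = NA_real_, k = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          fit = NULL), class = "boltzmann_fit"))
  }
  cf <- coef(best$fit)
  structure(list(g_max = unname(cf["gmax"]), v_half = unname(cf["vhalf"]),
                 k = unname(cf["k"]), residual_norm = sqrt(best$rss),
                 converged = TRUE, fit = best$fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Boltzmann fit: did not converge\n")
  } else {
    cat(sprintf("Boltzmann fit: G_max = %.3g nS, V_half = %.4g mV, k = %.3g mV\n",
                x$g_max, x$v_half, x$k))
  }
  invisible(x)
}

find_step_segment <- function(trace) {
  b <- segment_bounds(trace)
  seg_vals <- trace$protocol$segments
  dev <- abs((seg_vals$from + seg_vals$to) / 2 -
               (seg_vals$from[1] + seg_vals$to[1]) / 2)
  dev[1] <- -Inf                      # the step is never the opening hold
  b[which.max(dev), ]
}

#' Sag measurement from a hyperpolarizing current step
#'
#' V_peak is the largest membrane-potential deflection from the pre-step
#' baseline during the step; V_ss the mean deflection over the final
#' `ss_window` ms of the step; sag ratio = (V_peak - V_ss)/V_peak x 100.
#'
#' @param trace current-clamp `ephys_trace` from the `sag_step` protocol.
#' @param ss_window end-of-step window for the steady-state deflection (ms).
#' @return list of class `sag_measurement`: `v_peak`, `v_ss` (mV,
#'   deflection magnitudes), `sag_ratio` (percent), `baseline_mV`.
#' @export
sag_ratio <- function(trace, ss_window = 100) {
  if (trace$mode != "current_clamp") stop("expected a current-clamp trace")
  step <- find_step_segment(trace)
  dt <- trace$dt
  base <- mean(trace$signal[seq(max(1, step$start - round(200 / dt)),
                                step$start - 1)])
  seg_v <- trace$signal[seq(step$start, step$end)]
  defl <- base - seg_v                      # positive for hyperpolarization
  v_peak <- max(defl)
  if (v_peak <= 0) stop("no hyperpolarizing deflection in the step segment")
  v_ss <- mean(tail(defl, round(ss_window / dt)))
  structure(list(v_peak = v_peak, v_ss = v_ss,
                 sag_ratio = (v_peak - v_ss) / v_peak * 100,
                 baseline_mV = base),
            class = "sag_measurement")
}

#' ZD7288-sensitive sag ratio
#'
#' @param pre,post current-clamp sag traces before and after ZD7288.
#' @return sag ratio difference, pre minus post (percentage points).
#' @export
zd_sensitive_sag <- function(pre, post) {
  sag_ratio(pre)$sag_ratio - sag_ratio(post)$sag_ratio
}

#' Onset and steady-state input resistance from a current-step family
#'
#' For each step, the onset voltage is the mean over the 100 ms starting at
#' the peak of the voltage response, and the steady-state voltage the mean
#' over the final 250 ms of the step; each resistance is the least-squares
#' slope of the voltage-current relationship (MOhm).
#'
#' @param traces list of 7 current-clamp traces (-60 to +60 pA, 20 pA steps).
#' @param onset_window,ss_window window lengths (ms).
#' @return list of class `rin_measurement`: `onset_MOhm`,
#'   `steady_state_MOhm`, `per_step` (data.frame of per-step currents and
#'   mean deflections).
#' @export
input_resistance <- function(traces, onset_window = 100, ss_window = 250) {
  if (length(traces) != 7)
    stop("expected 7 step traces, got ", length(traces))
  rows <- lapply(traces, function(tr) {
    step <- find_step_segment(tr)
    dt <- tr$dt
    base_v <- mean(tr$signal[seq(max(1, step$start - round(200 / dt)),
                                 step$start - 1)])
    base_i <- tr$command[step$start - 1]
    i_step <- mean(tr$command[seq(step$start, step$end)]) - base_i
    seg_v <- tr$signal[seq(step$start, step$end)] - base_v
    pk <- which.max(abs(seg_v))
    onset <- mean(seg_v[seq(pk, min(length(seg_v), pk + round(onset_window / dt) - 1))])
    ss <- mean(tail(seg_v, round(ss_window / dt)))
    data.frame(current_pA = i_step, onset_mV = onset, steady_mV = ss)
  })
  per_step <- do.call(rbind, rows)
  slope <- function(y) unname(coef(lm(y ~ per_step$current_pA))[2])
  structure(list(
    onset_MOhm = slope(per_step$onset_mV) * 1000,
    steady_state_MOhm = slope(per_step$steady_mV) * 1000,
    per_step = per_step
  ), class = "rin_measurement")
}

#' Resting membrane potential from a gap-free recording
#'
#' Mean voltage over the analysis window; errors if spikes are present
#' (the measurement presumes TTX).
#'
#' @param trace current-clamp `ephys_trace` at I = 0.
#' @param discard_ms initial transient to discard.
#' @return RMP (mV).
#' @export
resting_potential <- function(trace, discard_ms = 2000) {
  if (trace$mode != "current_clamp") stop("expected a current-clamp trace")
  if (length(detect_spikes(trace)) > 0)
    stop("spikes detected: block spiking (TTX) before measuring RMP")
  keep <- trace$time_ms > discard_ms
  mean(trace$signal[keep])
}

#' Detect spikes in a current-clamp trace
#'
#' Upward crossings of a detection level, with crossings within the
#' refractory window merged.
#'
#' @param trace current-clamp `ephys_trace` (or numeric vector with `dt`).
#' @param level detection level (mV).
#' @param refractory_ms merge window (ms).
#' @param dt sample interval when `trace` is a bare numeric vector.
#' @return numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, level = -20, refractory_ms = 2, dt = NULL) {
  if (inherits(trace, "ephys_trace")) {
    v <- trace$signal
    dt <- trace$dt
  } else {
    v <- trace
    if (is.null(dt)) stop("dt required for a bare numeric trace")
  }
  up <- which(v[-1] >= level & v[-length(v)] < level)
  if (length(up) == 0) return(numeric(0))
  t <- up * dt
  keep <- c(TRUE, diff(t) > refractory_ms)
  t[keep]
}

#' Mean firing rate
#'
#' @param trace current-clamp `ephys_trace`.
#' @param ... passed to [detect_spikes()].
#' @return rate in Hz (count over recording duration).
#' @export
firing_rate <- function(trace, ...) {
  length(detect_spikes(trace, ...)) / (max(trace$time_ms) / 1000)
}

#' Average consecutive spontaneous spikes aligned at the negative peak
#'
#' Takes the first `n` spikes, finds each spike's fast-afterhyperpolarization
#' negative peak, and averages windows aligned on it.
#'
#' @param trace current-clamp `ephys_trace` with at least `n` spikes.
#' @param n number of consecutive spikes to average.
#' @param pre_ms,post_ms window around the negative peak.
#' @param ... passed to [detect_spikes()].
#' @return list of class `avg_spike`: `time_ms` (0 at the negative peak),
#'   `v` (mV), `n`, `dt`.
#' @export
average_spike <- function(trace, n = 20, pre_ms = 12, post_ms = 12, ...) {
  st <- detect_spikes(trace, ...)
  if (length(st) < n)
    stop("need at least ", n, " spikes, found ", length(st))
  dt <- trace$dt
  v <- trace$signal
  search <- round(8 / dt)          # negative peak within 8 ms of detection
  wpre <- round(pre_ms / dt)
  wpost <- round(post_ms / dt)
  waves <- lapply(st[seq_len(n)], function(t0) {
    i0 <- round(t0 / dt)
    j <- i0 + which.min(v[seq(i0, min(length(v), i0 + search))]) - 1
    if (j - wpre < 1 || j + wpost > length(v)) return(NULL)
    v[seq(j - wpre, j + wpost)]
  })
  waves <- waves[!vapply(waves, is.null, TRUE)]
  if (length(waves) < n) stop("not enough complete spike windows")
  structure(list(time_ms = seq(-wpre, wpost) * dt,
                 v = Reduce(`+`, waves) / length(waves),
                 n = length(waves), dt = dt),
            class = "avg_spike")
}

smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

#' Spike parameters from an averaged spike waveform
#'
#' Threshold is the voltage at which the depolarization slope first exceeds
#' `slope_threshold` (10 V/s); amplitude is peak minus threshold; fAHP is
#' threshold minus the negative peak; half-height width is measured at
#' threshold plus half the amplitude (linear interpolation of the crossing
#' times); the extreme depolarization and hyperpolarization slopes are also
#' reported. dV/dt is computed by central differences after light
#' moving-average smoothing.
#'
#' @param avg an [average_spike()] result (or list with `v`, `dt`).
#' @param slope_threshold threshold-detection slope (V/s; 1 V/s = 1 mV/ms).
#' @param smooth_ms moving-average width applied before differentiation.
#' @return list of class `spike_params`: `threshold_mV`, `amplitude_mV`,
#'   `half_height_width_ms`, `fahp_mV`, `max_depol_slope_Vps`,
#'   `min_hyperpol_slope_Vps`, `peak_mV`.
#' @export
spike_parameters <- function(avg, slope_threshold = 10, smooth_ms = 0.2) {
  v <- avg$v
  dt <- avg$dt
  vs <- smooth_ma(v, max(1, round(smooth_ms / dt)))
  ok <- !is.na(vs)
  dvdt <- rep(NA_real_, length(vs))
  idx <- which(ok)
  core <- idx[c(-1, -length(idx))]
  dvdt[core] <- (vs[core + 1] - vs[core - 1]) / (2 * dt)  # mV/ms = V/s
  pk <- which.max(v)
  neg <- which.min(v[seq(pk, length(v))]) + pk - 1
  # upstroke: from the pre-peak minimum to the peak
  up_start <- which.min(v[seq_len(pk)])
  up <- seq(up_start, pk)
  cross <- up[which(dvdt[up] > slope_threshold)[1]]
  if (is.na(cross)) stop("no upstroke exceeding the slope threshold")
  threshold <- v[cross]
  amplitude <- v[pk] - threshold
  if (amplitude <= 0) stop("nonpositive spike amplitude")
  fahp <- threshold - v[neg]
  half_v <- threshold + amplitude / 2
  t_up <- interp_crossing(v, half_v, seq(up_start, pk), dt, rising = TRUE)
  t_down <- interp_crossing(v, half_v, seq(pk, neg), dt, rising = FALSE)
  structure(list(
    threshold_mV = threshold, amplitude_mV = amplitude,
    half_height_width_ms = t_down - t_up, fahp_mV = fahp,
    max_depol_slope_Vps = max(dvdt[up], na.rm = TRUE),
    min_hyperpol_slope_Vps = min(dvdt[seq(pk, neg)], na.rm = TRUE),
    peak_mV = v[pk]
  ), class = "spike_params")
}

interp_crossing <- function(v, level, idx, dt, rising = TRUE) {
  s <- v[idx]
  hit <- if (rising) which(s[-1] >= level & s[-length(s)] < level)
  else which(s[-1] <= level & s[-length(s)] > level)
  if (length(hit) == 0) stop("half-height level not crossed")
  i <- idx[hit[1]]
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  (i + frac) * dt
}

#' @importFrom stats aggregate quantile residuals
NULL
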