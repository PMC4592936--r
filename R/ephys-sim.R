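# Single-compartment conductance-based fusiform-cell simulator: leak,
# Boltzmann-gated KCNQ (M-current) and HCN (Ih) conductances with first-order
# kinetics, an optional extra linear (inward-rectifier-like) conductance, an
# exponential integrate-and-fire spike mechanism, a clamp-protocol engine and
# pharmacology switches.

#' Fusiform-cell model parameters
#'
#' @param C_m membrane capacitance (pF).
#' @param g_leak,E_leak leak conductance (nS) and reversal (mV).
#' @param g_kcnq,v_half_kcnq,k_kcnq,tau_kcnq KCNQ maximal conductance (nS),
#'   Boltzmann half-activation (mV), slope (mV) and time constant (ms).
#' @param E_k potassium reversal potential (mV).
#' @param g_hcn,v_half_hcn,k_hcn,tau_hcn HCN parameters; activation is
#'   negative-going (open fraction `1/(1+exp((V - v_half)/k))`).
#' @param E_hcn HCN reversal potential (mV).
#' @param g_extra,E_extra extra linear conductance (nS) and reversal (mV),
#'   used to model an inward-rectifier-like leak.
#' @param spike_on enable the exponential integrate-and-fire spike mechanism.
#' @param delta_t,v_t,v_cut,v_reset,v_peak,t_ref EIF sharpness (mV), soft
#'   threshold (mV), numerical cut-off (mV), reset (mV), displayed spike peak
#'   (mV) and refractory period (ms).
#' @param noise_sd SD of an Ornstein-Uhlenbeck noise current (pA; 0 = off).
#' @param noise_tau OU correlation time (ms).
#' @return object of class `cell_params`.
#' @export
cell_params <- function(C_m = 60, g_leak = 10, E_leak = -65,
                        g_kcnq = 39.1, v_half_kcnq = -28.3, k_kcnq = 6,
                        tau_kcnq = 130, E_k = -85.5,
                        g_hcn = 10, v_half_hcn = -90, k_hcn = 8,
                        tau_hcn = 400, E_hcn = -30,
                        g_extra = 0, E_extra = -85.5,
                        spike_on = TRUE, delta_t = 2, v_t = -62.57,
                        v_cut = -15, v_reset = -72, v_peak = 8, t_ref = 2,
                        noise_sd = 0, noise_tau = 5) {
  stopifnot(C_m > 0, g_leak >= 0, g_kcnq >= 0, g_hcn >= 0, g_extra >= 0,
            tau_kcnq > 0, tau_hcn > 0, k_kcnq > 0, k_hcn > 0, noise_sd >= 0)
  structure(list(
    C_m = C_m, g_leak = g_leak, E_leak = E_leak,
    g_kcnq = g_kcnq, v_half_kcnq = v_half_kcnq, k_kcnq = k_kcnq,
    tau_kcnq = tau_kcnq, E_k = E_k,
    g_hcn = g_hcn, v_half_hcn = v_half_hcn, k_hcn = k_hcn,
    tau_hcn = tau_hcn, E_hcn = E_hcn,
    g_extra = g_extra, E_extra = E_extra,
    spike_on = spike_on, delta_t = delta_t, v_t = v_t, v_cut = v_cut,
    v_reset = v_reset, v_peak = v_peak, t_ref = t_ref,
    noise_sd = noise_sd, noise_tau = noise_tau
  ), class = "cell_params")
}

#' Pharmacology switches
#'
#' @param xe991 block KCNQ (maximal conductance to 0).
#' @param zd7288 block HCN (maximal conductance to 0).
#' @param ttx block spiking (spike mechanism, including its depolarizing
#'   drive, off).
#' @param retigabine KCNQ opener: hyperpolarizing shift of the KCNQ
#'   half-activation voltage.
#' @param retigabine_shift shift magnitude (mV, applied as a negative shift).
#' @return object of class `drug_state`.
#' @export
drug_state <- function(xe991 = FALSE, zd7288 = FALSE, ttx = FALSE,
                       retigabine = FALSE, retigabine_shift = -10) {
  structure(list(xe991 = xe991, zd7288 = zd7288, ttx = ttx,
                 retigabine = retigabine,
                 retigabine_shift = retigabine_shift),
            class = "drug_state")
}

apply_drugs <- function(cell, drug) {
  if (drug$xe991) cell$g_kcnq <- 0
  if (drug$zd7288) cell$g_hcn <- 0
  if (drug$ttx) cell$spike_on <- FALSE
  if (drug$retigabine) cell$v_half_kcnq <- cell$v_half_kcnq + drug$retigabine_shift
  cell
}

boltzmann_act <- function(V, v_half, k) 1 / (1 + exp(-(V - v_half) / k))
boltzmann_inact <- function(V, v_half, k) 1 / (1 + exp((V - v_half) / k))

# Steady-state ionic current at voltage V with gates at equilibrium
# (spike drive excluded).
steady_current <- function(cell, V) {
  cell$g_leak * (V - cell$E_leak) +
    cell$g_extra * (V - cell$E_extra) +
    cell$g_kcnq * boltzmann_act(V, cell$v_half_kcnq, cell$k_kcnq) * (V - cell$E_k) +
    cell$g_hcn * boltzmann_inact(V, cell$v_half_hcn, cell$k_hcn) * (V - cell$E_hcn)
}

# Resting potential of the passive (spike-off) cell: zero of the steady-state
# current. Unique because every term is increasing-through-zero near rest.
steady_voltage <- function(cell, lower = -120, upper = -20) {
  uniroot(function(v) steady_current(cell, v), c(lower, upper),
          tol = 1e-10)$root
}

#' Clamp protocols
#'
#' A protocol is a list of segments; each segment holds `duration_ms` and a
#' command that is either constant (`value`) or a linear ramp (`from`/`to`).
#' Current-clamp commands are in pA, voltage-clamp commands in mV. When
#' `bias_to` is set (current clamp), the bias current holding the cell at
#' that voltage is computed from the model's steady state and added to every
#' command value.
#'
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param segments data.frame with columns `duration_ms`, `from`, `to`.
#' @param bias_to optional holding potential (mV, current clamp only).
#' @param dt sampling/integration step (ms).
#' @return object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(mode = c("voltage_clamp", "current_clamp"),
                           segments, bias_to = NULL, dt = 0.025) {
  mode <- match.arg(mode)
  stopifnot(all(segments$duration_ms > 0), dt > 0, dt <= 0.025)
  structure(list(mode = mode, segments = segments, bias_to = bias_to,
                 dt = dt), class = "clamp_protocol")
}

seg <- function(duration_ms, value) {
  data.frame(duration_ms = duration_ms, from = value, to = value)
}
ramp_seg <- function(duration_ms, from, to) {
  data.frame(duration_ms = duration_ms, from = from, to = to)
}

#' Standard protocol library
#'
#' * `kcnq_deactivation`: voltage clamp, hold -30 mV for 5 s then step to
#'   -50 mV for 1 s (tail-current protocol).
#' * `gv_ramp`: voltage clamp, hold at the ramp start then a slow
#'   (10 mV/s) ramp up and back down over `ramp_span`; ascending and
#'   descending branches let the analysis cancel first-order kinetic lag.
#' * `sag_step`: current clamp, bias to -75 mV, -550 pA step for 2 s.
#' * `rin_family`: current clamp, -60 to +60 pA in 20 pA steps, 2 s each
#'   (returned as a list of 7 single-step protocols).
#' * `gap_free`: current clamp, I = 0, `gap_free_s` seconds.
#'
#' @param ramp_span voltage span of the G-V ramp (mV).
#' @param ramp_rate ramp speed (mV/s).
#' @param gap_free_s gap-free recording length (s).
#' @param dt integration step (ms).
#' @return named list of [clamp_protocol()] objects (`rin_family` is a list).
#' @export
protocol_library <- function(ramp_span = c(-90, 0), ramp_rate = 10,
                             gap_free_s = 10, dt = 0.025) {
  ramp_ms <- abs(diff(ramp_span)) / ramp_rate * 1000
  list(
    kcnq_deactivation = clamp_protocol(
      "voltage_clamp",
      rbind(seg(5000, -30), seg(1000, -50)), dt = dt),
    gv_ramp = clamp_protocol(
      "voltage_clamp",
      rbind(seg(2000, ramp_span[1]),
            ramp_seg(ramp_ms, ramp_span[1], ramp_span[2]),
            ramp_seg(ramp_ms, ramp_span[2], ramp_span[1])), dt = dt),
    sag_step = clamp_protocol(
      "current_clamp",
      rbind(seg(1000, 0), seg(2000, -550), seg(1000, 0)),
      bias_to = -75, dt = dt),
    rin_family = lapply(seq(-60, 60, by = 20), function(i)
      clamp_protocol("current_clamp",
                     rbind(seg(500, 0), seg(2000, i), seg(500, 0)),
                     dt = dt)),
    gap_free = clamp_protocol(
      "current_clamp", seg(gap_free_s * 1000, 0), dt = dt)
  )
}

build_command <- function(protocol) {
  dt <- protocol$dt
  unlist(lapply(seq_len(nrow(protocol$segments)), function(i) {
    s <- protocol$segments[i, ]
    n <- round(s$duration_ms / dt)
    if (s$from == s$to) rep(s$from, n) else seq(s$from, s$to, length.out = n)
  }), use.names = FALSE)
}

pack_params <- function(cell) {
  p <- c(Cm = cell$C_m, gL = cell$g_leak, EL = cell$E_leak,
    gK = cell$g_kcnq, VhK = cell$v_half_kcnq, kK = cell$k_kcnq,
    tauK = cell$tau_kcnq, EK = cell$E_k,
    gH = cell$g_hcn, VhH = cell$v_half_hcn, kH = cell$k_hcn,
    tauH = cell$tau_hcn, EH = cell$E_hcn,
    gX = cell$g_extra, EX = cell$E_extra,
    spike_on = as.numeric(cell$spike_on),
    DeltaT = cell$delta_t, VT = cell$v_t, Vcut = cell$v_cut,
    Vreset = cell$v_reset, Vpeak = cell$v_peak, t_ref = cell$t_ref)
  # parameter fields may carry stray names (e.g. from named preset lookups)
  names(p) <- c("Cm", "gL", "EL", "gK", "VhK", "kK", "tauK", "EK",
                "gH", "VhH", "kH", "tauH", "EH", "gX", "EX", "spike_on",
                "DeltaT", "VT", "Vcut", "Vreset", "Vpeak", "t_ref")
  p
}

ou_noise <- function(n, dt, sd, tau) {
  if (sd == 0) return(numeric(0))
  a <- exp(-dt / tau)
  innov <- rnorm(n, 0, sd * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Simulate a clamp protocol
#'
#' Integrates `C_m dV/dt = -(I_leak + I_extra + I_KCNQ + I_HCN) + I_spike +
#' I_inj` with first-order Boltzmann gates, by fixed-step exponential-Euler
#' (gates) / forward-Euler (voltage) at `protocol$dt <= 0.025 ms`. In voltage
#' clamp the membrane follows the command and the total and channel-resolved
#' currents are reported; in current clamp the membrane voltage and spike
#' times are reported. Initial state is the steady state of the first command
#' value.
#'
#' @param cell a [cell_params()].
#' @param protocol a [clamp_protocol()].
#' @param drug a [drug_state()].
#' @param seed seed for the optional noise current.
#' @return object of class `ephys_trace`: `time_ms`, `signal` (pA in voltage
#'   clamp, mV in current clamp), `command`, `mode`, `dt`, `spike_times`
#'   (current clamp), `currents` (voltage clamp: data.frame of channel
#'   currents), and the resolved `cell`, `protocol`, `drug`.
#' @export
simulate <- function(cell, protocol, drug = drug_state(), seed = NULL) {
  stopifnot(inherits(cell, "cell_params"), inherits(protocol, "clamp_protocol"))
  cell <- apply_drugs(cell, drug)
  cmd <- build_command(protocol)
  dt <- protocol$dt
  p <- pack_params(cell)
  if (protocol$mode == "voltage_clamp") {
    v0 <- cmd[1]
    res <- sim_voltage_clamp(cmd, dt, p,
                             boltzmann_act(v0, cell$v_half_kcnq, cell$k_kcnq),
                             boltzmann_inact(v0, cell$v_half_hcn, cell$k_hcn))
    out <- list(signal = res$I_total,
                currents = data.frame(I_kcnq = res$I_kcnq, I_hcn = res$I_hcn,
                                      I_leak = res$I_leak),
                spike_times = NULL)
  } else {
    bias <- 0
    if (!is.null(protocol$bias_to)) {
      vhold <- protocol$bias_to
      bias <- steady_current(cell, vhold)
      v0 <- vhold
    } else {
      v0 <- steady_voltage(cell)
    }
    cmd <- cmd + bias
    if (!is.null(seed)) set.seed(seed)
    noise <- ou_noise(length(cmd), dt, cell$noise_sd, cell$noise_tau)
    res <- sim_current_clamp(cmd, dt, p, v0,
                             boltzmann_act(v0, cell$v_half_kcnq, cell$k_kcnq),
                             boltzmann_inact(v0, cell$v_half_hcn, cell$k_hcn),
                             noise)
    out <- list(signal = res$V, currents = NULL,
                spike_times = res$spike_times)
  }
  structure(c(out, list(
    time_ms = seq_along(cmd) * dt, command = cmd, mode = protocol$mode,
    dt = dt, cell = cell, protocol = protocol, drug = drug
  )), class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("ephys_trace: %s, %.1f ms at dt = %g ms", x$mode,
              max(x$time_ms), x$dt))
  if (!is.null(x$spike_times)) cat(sprintf(", %d spikes", length(x$spike_times)))
  cat("\n")
  invisible(x)
}

#' Calibrated per-cohort parameter presets
#'
#' Returns model parameterizations reproducing the study's four cell groups:
#'
#' * `control`: sham-exposed; KCNQ half-activation -28.3 mV and maximal
#'   conductance 39.1 nS; HCN level giving a ZD7288-sensitive sag ratio near
#'   15.5%; resting potential (under TTX) -64.2 mV.
#' * `noise_4day`: 4 days post noise exposure; depolarized KCNQ
#'   half-activation (-20.3 mV, 37.7 nS), control-level HCN, and an extra
#'   inward-rectifier-like leak hyperpolarizing the resting potential to
#'   -67.7 mV.
#' * `tinnitus_day7`: persistent KCNQ deficit (depolarized half-activation)
#'   with control-level HCN (sag near 14.1%).
#' * `non_tinnitus_day7`: recovered (control) KCNQ with HCN reduced to a sag
#'   ratio near 8.3% and resting potential -67.5 mV.
#'
#' HCN conductances were calibrated with [calibrate_hcn_gmax()] against the
#' group sag-ratio values; leak reversals are solved at run time so each
#' preset's passive resting potential lands exactly on its target.
#'
#' @param spike_on enable the spike mechanism in the returned presets.
#' @return named list of [cell_params()].
#' @export
preset_states <- function(spike_on = TRUE) {
  base <- function(...) cell_params(spike_on = spike_on, ...)
  p <- list(
    control = base(g_kcnq = 39.1, v_half_kcnq = -28.3,
                   g_hcn = .preset_ghcn["control"]),
    noise_4day = base(g_kcnq = 37.7, v_half_kcnq = -20.3,
                      g_hcn = .preset_ghcn["control"], g_extra = 0),
    tinnitus_day7 = base(g_kcnq = 37.7, v_half_kcnq = -20.3,
                         g_hcn = .preset_ghcn["tinnitus"]),
    non_tinnitus_day7 = base(g_kcnq = 39.1, v_half_kcnq = -28.3,
                             g_hcn = .preset_ghcn["non_tinnitus"])
  )
  targets <- c(control = -64.2, noise_4day = -67.7,
               tinnitus_day7 = -64.2, non_tinnitus_day7 = -67.5)
  for (nm in names(p)) {
    p[[nm]] <- set_resting_potential(p[[nm]], targets[[nm]],
                                     via = if (nm == "noise_4day") "g_extra" else "E_leak")
  }
  p
}

# HCN maximal conductances (nS) from calibrate_hcn_gmax() against the group
# ZD7288-sensitive sag ratios (15.5 / 14.1 / 8.3 %).
.preset_ghcn <- c(control = 1.2255, tinnitus = 1.1042, non_tinnitus = 0.6293)

#' Pin a preset's passive resting potential
#'
#' Solves for the leak reversal (or an extra inward-rectifier-like
#' conductance with reversal at E_K) so the spike-off steady state sits at
#' `target_mV`.
#'
#' @param cell a [cell_params()].
#' @param target_mV desired resting potential (mV).
#' @param via `"E_leak"` or `"g_extra"`.
#' @return modified `cell_params`.
#' @export
set_resting_potential <- function(cell, target_mV, via = c("E_leak", "g_extra")) {
  via <- match.arg(via)
  V <- target_mV
  other <- cell$g_kcnq * boltzmann_act(V, cell$v_half_kcnq, cell$k_kcnq) * (V - cell$E_k) +
    cell$g_hcn * boltzmann_inact(V, cell$v_half_hcn, cell$k_hcn) * (V - cell$E_hcn)
  if (via == "E_leak") {
    cell$g_extra <- 0
    cell$E_leak <- V + other / cell$g_leak
  } else {
    need <- -(cell$g_leak * (V - cell$E_leak) + other)
    g <- need / (V - cell$E_extra)
    if (g < 0) stop("cannot reach ", target_mV,
                    " mV with a positive extra conductance")
    cell$g_extra <- g
  }
  cell
}

#' Calibrate the HCN maximal conductance against a target sag ratio
#'
#' Searches over the HCN maximal conductance so that the ZD7288-sensitive
#' sag ratio under the standard -550 pA step protocol matches `target_pct`.
#'
#' @param cell a [cell_params()] (its `g_hcn` is the value being replaced).
#' @param target_pct target ZD7288-sensitive sag ratio (percent).
#' @param interval search interval for the conductance (nS).
#' @return the calibrated `cell_params`.
#' @export
calibrate_hcn_gmax <- function(cell, target_pct, interval = c(0.1, 60)) {
  proto <- protocol_library()$sag_step
  f <- function(g) {
    cell$g_hcn <- g
    zd_sensitive_sag(
      simulate(cell, proto),
      simulate(cell, proto, drug_state(zd7288 = TRUE))
    ) - target_pct
  }
  cell$g_hcn <- uniroot(f, interval, tol = 1e-3)$root
  cell
}

#' Calibrate the KCNQ maximal conductance against a target tail amplitude
#'
#' The tail-current amplitude under the deactivation protocol is linear in
#' the KCNQ maximal conductance, so one simulation fixes the scale. This
#' provides a separate calibration context for tail-current measurements:
#' printed tail amplitudes and ramp-derived maximal conductances reflect
#' different recording conditions and are not reproduced by a single
#' conductance scale.
#'
#' @param cell a [cell_params()].
#' @param target_pA desired XE991-sensitive tail amplitude (pA).
#' @return the calibrated `cell_params`.
#' @export
calibrate_kcnq_gmax_for_tail <- function(cell, target_pA) {
  proto <- protocol_library()$kcnq_deactivation
  a <- simulate(cell, proto)
  b <- simulate(cell, proto, drug_state(xe991 = TRUE))
  amp <- tail_current_amplitude(subtract_traces(a, b))$amplitude
  cell$g_kcnq <- cell$g_kcnq * target_pA / amp
  cell
}
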