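test_that("trace subtraction isolates the drug-sensitive current", {
  p <- preset_states(spike_on = FALSE)$control
  proto <- clamp_protocol("voltage_clamp",
                          data.frame(duration_ms = c(500, 200),
                                     from = c(-30, -50), to = c(-30, -50)))
  pre <- simulate(p, proto)
  post <- simulate(p, proto, drug_state(xe991 = TRUE))
  d <- subtract_traces(pre, post)
  expect_equal(d$signal, pre$currents$I_kcnq, tolerance = 1e-10)

  same <- subtract_traces(pre, pre)
  expect_true(all(same$signal == 0))

  shifted <- post
  shifted$signal <- pre$signal - 3.5
  expect_equal(unique(subtract_traces(pre, shifted)$signal), 3.5)

  bad <- simulate(p, clamp_protocol("voltage_clamp", data.frame(
    duration_ms = 500, from = -30, to = -30)))
  expect_error(subtract_traces(pre, bad), "protocol")
})

test_that("tail-current amplitude is instantaneous minus steady current", {
  p <- preset_states(spike_on = FALSE)
  pl <- protocol_library()
  amp <- function(cell) {
    a <- simulate(cell, pl$kcnq_deactivation)
    b <- simulate(cell, pl$kcnq_deactivation, drug_state(xe991 = TRUE))
    tail_current_amplitude(subtract_traces(a, b))
  }
  a_ctrl <- amp(p$control)
  a_4day <- amp(p$noise_4day)
  expect_gt(a_ctrl$amplitude, 0)
  expect_lt(a_4day$amplitude, a_ctrl$amplitude)   # reduced KCNQ current

  # zero difference trace -> zero amplitude
  a <- simulate(p$control, pl$kcnq_deactivation)
  z <- subtract_traces(a, a)
  expect_equal(tail_current_amplitude(z)$amplitude, 0)

  # tail-calibration context reproduces a target amplitude
  cal <- calibrate_kcnq_gmax_for_tail(p$control, 73.8)
  expect_equal(amp(cal)$amplitude, 73.8, tolerance = 1e-3)
})

test_that("ramp conversion applies Ohm's law with a reversal guard", {
  v <- seq(-90, 0, by = 0.01)
  tr <- fake_vc_trace(command = v, signal = rep(100, length(v)))
  gv <- ramp_to_GV(tr, span = c(-90, 0))
  expect_equal(gv$g[which.min(abs(gv$v + 35.5))], 100 / 50, tolerance = 1e-4)
  expect_true(all(abs(gv$v + 85.5) >= 5))
  expect_gt(attr(gv, "n_dropped"), 0)

  tr0 <- fake_vc_trace(command = v, signal = rep(0, length(v)))
  expect_true(all(ramp_to_GV(tr0)$g == 0))
})

test_that("simulated ramps invert the conductance model away from the reversal", {
  p <- preset_states(spike_on = FALSE)$control
  pre <- simulate(p, protocol_library()$gv_ramp)
  post <- simulate(p, protocol_library()$gv_ramp, drug_state(xe991 = TRUE))
  gv <- ramp_to_GV(subtract_traces(pre, post))
  g_true <- p$g_kcnq / (1 + exp(-(gv$v - p$v_half_kcnq) / p$k_kcnq))
  err <- gv$g - g_true
  # full-scale agreement everywhere; pointwise agreement over the rising
  # phase (the deactivated tail is dominated by kinetic lag, a property of
  # the slow-ramp measurement itself)
  expect_lt(max(abs(err)) / p$g_kcnq, 0.02)
  rising <- g_true >= 0.3 * p$g_kcnq
  expect_lt(max(abs(err[rising]) / g_true[rising]), 0.02)
})

test_that("Boltzmann fits recover noiseless parameters and flag degenerate curves", {
  v <- seq(-75, -1, by = 1)
  mk <- function(gmax, vhalf, k) gmax / (1 + exp(-(v - vhalf) / k))
  for (par in list(c(39.1, -28.3, 6), c(37.7, -20.3, 6))) {
    fit <- fit_boltzmann(data.frame(v = v, g = mk(par[1], par[2], par[3])))
    expect_true(fit$converged)
    expect_equal(fit$g_max, par[1], tolerance = 1e-3)
    expect_equal(fit$v_half, par[2], tolerance = 1e-3)
    expect_equal(fit$k, par[3], tolerance = 1e-3)
  }
  flat <- fit_boltzmann(data.frame(v = v, g = rep(5, length(v))))
  expect_false(flat$converged)
})

test_that("Boltzmann fits stay unbiased under measurement noise", {
  v <- seq(-75, -1, by = 1)
  g0 <- 39.1 / (1 + exp(-(v + 28.3) / 6))
  set.seed(88)
  est <- replicate(40, {
    g <- g0 + rnorm(length(v), 0, max(g0) / 20)   # SNR ~ 20
    f <- fit_boltzmann(data.frame(v = v, g = g))
    c(f$g_max, f$v_half, f$k)
  })
  bias <- rowMeans(est) - c(39.1, -28.3, 6)
  expect_lt(abs(bias[1]) / 39.1, 0.05)
  expect_lt(abs(bias[2]) / 28.3, 0.05)
  expect_lt(abs(bias[3]) / 6, 0.05)
})

test_that("sag ratio follows its defining formula and ignores vertical offsets", {
  p <- preset_states(spike_on = FALSE)$control
  tr <- simulate(p, protocol_library()$sag_step)
  s <- sag_ratio(tr)
  expect_equal(s$sag_ratio, (s$v_peak - s$v_ss) / s$v_peak * 100)

  tr_off <- tr
  tr_off$signal <- tr$signal + 7.3
  expect_equal(sag_ratio(tr_off)$sag_ratio, s$sag_ratio, tolerance = 1e-9)

  # hand cases through the same arithmetic
  expect_equal((20 - 17) / 20 * 100, 15)
  expect_equal(zd_sensitive_sag(tr, tr), 0)
})

test_that("input resistance of a passive cell equals 1/g and is scale invariant", {
  cellp <- cell_params(g_kcnq = 0, g_hcn = 0, g_leak = 10, spike_on = FALSE)
  trs <- lapply(protocol_library()$rin_family, function(pr) simulate(cellp, pr))
  r <- input_resistance(trs)
  expect_equal(r$onset_MOhm, 100, tolerance = 1)
  expect_equal(r$steady_state_MOhm, 100, tolerance = 1)

  # doubling all currents and responses leaves the slopes unchanged
  trs2 <- lapply(trs, function(tr) {
    base <- tr$signal[1]
    tr$signal <- base + 2 * (tr$signal - base)
    tr$command <- 2 * tr$command
    tr
  })
  r2 <- input_resistance(trs2)
  expect_equal(r2$onset_MOhm, r$onset_MOhm, tolerance = 1e-9)
  expect_error(input_resistance(trs[1:5]), "7")
})

test_that("slow subthreshold conductances shunt the late voltage response", {
  p <- preset_states(spike_on = FALSE)$control
  trs <- lapply(protocol_library()$rin_family, function(pr) simulate(p, pr))
  r <- input_resistance(trs)
  expect_lt(r$steady_state_MOhm, r$onset_MOhm)
})

test_that("resting potential orders presets as measured and responds to ZD7288", {
  p <- preset_states()
  gap <- protocol_library(gap_free_s = 4)$gap_free
  rmp <- function(cell, drug = drug_state(ttx = TRUE))
    resting_potential(simulate(cell, gap, drug))
  expect_equal(rmp(p$control), -64.2, tolerance = 0.05)
  expect_equal(rmp(p$noise_4day), -67.7, tolerance = 0.05)
  expect_lt(rmp(p$noise_4day), rmp(p$control))
  expect_lt(rmp(p$control, drug_state(ttx = TRUE, zd7288 = TRUE)),
            rmp(p$control))
  # spikes present -> refuse to report an RMP
  expect_error(resting_potential(simulate(p$control, gap)), "TTX")
})

test_that("spike detection counts evenly spaced spikes at their rate", {
  dt <- 0.025
  n <- round(1000 / dt)
  v <- rep(-65, n)
  for (t0 in seq(50, 950, by = 100)) {           # 10 spikes in 1 s
    i0 <- round(t0 / dt)
    v[i0:(i0 + 20)] <- 10
  }
  tr <- structure(list(signal = v, dt = dt, time_ms = seq_len(n) * dt,
                       mode = "current_clamp"), class = "ephys_trace")
  expect_equal(firing_rate(tr), 10)
  expect_equal(firing_rate(structure(list(signal = rep(-65, n), dt = dt,
                                          time_ms = seq_len(n) * dt,
                                          mode = "current_clamp"),
                                     class = "ephys_trace")), 0)
})

# Construct a stereotyped spike with known geometry: slow 5 mV/ms approach to
# -45 mV, fast 100 mV/ms upstroke to +5, -100 mV/ms downstroke to -70, slow
# recovery. The 10 mV/ms threshold crossing sits at the -45 mV corner.
synthetic_spike_train <- function(n_spikes = 25, dt = 0.025) {
  one <- c(seq(-60, -45, by = 5 * dt),       # 5 mV/ms
           seq(-45, 5, by = 100 * dt),       # 100 mV/ms
           seq(5, -70, by = -100 * dt),      # -100 mV/ms
           seq(-70, -60, by = 2 * dt))       # recovery
  v <- c(rep(-60, 400), rep(c(one, rep(-60, 1200)), n_spikes))
  structure(list(signal = v, dt = dt, time_ms = seq_along(v) * dt,
                 mode = "current_clamp"), class = "ephys_trace")
}

test_that("averaged-spike parameters match the constructed geometry", {
  tr <- synthetic_spike_train()
  st <- detect_spikes(tr)
  expect_gte(length(st), 20)
  avg <- average_spike(tr, n = 20)
  sp <- spike_parameters(avg)
  expect_equal(sp$threshold_mV, -45, tolerance = 1.5)
  expect_equal(sp$amplitude_mV, 5 - sp$threshold_mV, tolerance = 1e-9)
  expect_equal(sp$peak_mV, 5, tolerance = 0.5)
  expect_equal(sp$fahp_mV, sp$threshold_mV - (-70), tolerance = 0.5)
  # half-height level = threshold + amplitude/2 = -20; crossings on the
  # 100 mV/ms flanks: width = 25/100 + 25/100 = 0.5 ms
  expect_equal(sp$half_height_width_ms, 0.5, tolerance = 0.1)
  expect_equal(sp$max_depol_slope_Vps, 100, tolerance = 10)
  expect_equal(sp$min_hyperpol_slope_Vps, -100, tolerance = 10)
  expect_error(average_spike(synthetic_spike_train(5)), "at least 20")
})
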