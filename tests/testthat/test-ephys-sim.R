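test_that("leak-only cell settles at the leak reversal and respects reversal potentials", {
  cellp <- cell_params(g_kcnq = 0, g_hcn = 0, spike_on = FALSE, E_leak = -65)
  tr <- simulate(cellp, clamp_protocol("current_clamp", data.frame(
    duration_ms = 1000, from = 0, to = 0)))
  expect_equal(resting_potential(tr, discard_ms = 500), -65, tolerance = 1e-9)

  # voltage clamp at E_K: zero KCNQ current
  cellk <- cell_params(spike_on = FALSE)
  trk <- simulate(cellk, clamp_protocol("voltage_clamp", data.frame(
    duration_ms = 200, from = -85.5, to = -85.5)))
  expect_equal(max(abs(trk$currents$I_kcnq)), 0)
})

test_that("KCNQ activation follows the Boltzmann steady state", {
  # clamp at -30 mV with V_half = -28.3, k = 6: V sits 1.7 mV below the
  # half-activation point, so m_inf = 1/(1+exp(1.7/6)) = 0.430
  cellp <- cell_params(g_hcn = 0, g_leak = 1e-9, spike_on = FALSE)
  tr <- simulate(cellp, clamp_protocol("voltage_clamp", data.frame(
    duration_ms = 2000, from = -30, to = -30)))
  m_inf <- 1 / (1 + exp(-(-30 + 28.3) / 6))
  expect_equal(m_inf, 0.430, tolerance = 1e-3)
  i_expect <- 39.1 * m_inf * (-30 + 85.5)
  expect_equal(tail(tr$currents$I_kcnq, 1), i_expect, tolerance = 1e-6)
})

test_that("voltage-clamp current equals the analytic channel sum at steady state", {
  cellp <- cell_params(spike_on = FALSE)
  tr <- simulate(cellp, clamp_protocol("voltage_clamp", data.frame(
    duration_ms = 3000, from = -50, to = -50)))
  m <- 1 / (1 + exp(-(-50 - cellp$v_half_kcnq) / cellp$k_kcnq))
  h <- 1 / (1 + exp((-50 - cellp$v_half_hcn) / cellp$k_hcn))
  analytic <- cellp$g_leak * (-50 - cellp$E_leak) +
    cellp$g_kcnq * m * (-50 - cellp$E_k) +
    cellp$g_hcn * h * (-50 - cellp$E_hcn)
  expect_equal(tail(tr$signal, 1), analytic, tolerance = 1e-3 * abs(analytic))
})

test_that("protocol library encodes the published clamp parameters", {
  pl <- protocol_library()
  expect_equal(pl$kcnq_deactivation$segments$duration_ms, c(5000, 1000))
  expect_equal(pl$kcnq_deactivation$segments$from, c(-30, -50))
  expect_length(pl$rin_family, 7)
  expect_equal(pl$sag_step$segments$from[2], -550)
  expect_equal(pl$sag_step$segments$duration_ms[2], 2000)
  expect_equal(pl$sag_step$bias_to, -75)
  # 10 mV/s ramp: 90 mV span in 9 s
  expect_equal(pl$gv_ramp$segments$duration_ms[2], 9000)
})

test_that("halving the integration step changes reported features by less than 0.5%", {
  cellp <- preset_states(spike_on = FALSE)$control
  for (dt in c(0.025, 0.0125)) {
    pl <- protocol_library(dt = dt)
    s <- sag_ratio(simulate(cellp, pl$sag_step))
    r <- resting_potential(simulate(cellp, clamp_protocol(
      "current_clamp", data.frame(duration_ms = 3000, from = 0, to = 0),
      dt = dt)), discard_ms = 1500)
    if (dt == 0.025) {
      s0 <- s$sag_ratio
      r0 <- r
    } else {
      expect_lt(abs(s$sag_ratio - s0) / abs(s0), 0.005)
      expect_lt(abs(r - r0) / abs(r0), 0.005)
    }
  }
})

test_that("sag ratio increases strictly with the HCN conductance", {
  cellp <- cell_params(spike_on = FALSE)
  pl <- protocol_library()
  sags <- vapply(c(0.3, 0.8, 1.5, 3), function(g) {
    cellp$g_hcn <- g
    sag_ratio(simulate(cellp, pl$sag_step))$sag_ratio
  }, 0)
  expect_true(all(diff(sags) > 0))
})

test_that("pharmacology switches act on the right conductances", {
  p <- preset_states(spike_on = FALSE)$control
  pl <- protocol_library()
  tr_zd <- simulate(p, pl$sag_step, drug_state(zd7288 = TRUE))
  expect_lt(sag_ratio(tr_zd)$sag_ratio, 0.5)    # no HCN, no sag
  tr_xe <- simulate(p, pl$kcnq_deactivation, drug_state(xe991 = TRUE))
  expect_equal(max(abs(tr_xe$currents$I_kcnq)), 0)
})

test_that("spontaneous firing slows under retigabine and leak-driven hyperpolarization", {
  p <- preset_states()
  pl <- protocol_library(gap_free_s = 8)
  r_ctrl <- firing_rate(simulate(p$control, pl$gap_free))
  expect_gt(r_ctrl, 10)
  expect_lt(r_ctrl, 20)
  r_rtg <- firing_rate(simulate(p$control, pl$gap_free,
                                drug_state(retigabine = TRUE)))
  expect_lt(r_rtg, r_ctrl)
  r_4day <- firing_rate(simulate(p$noise_4day, pl$gap_free))
  expect_lt(r_4day, r_ctrl)
  # tinnitus preset: hyperactive relative to control
  r_tin <- firing_rate(simulate(p$tinnitus_day7, pl$gap_free))
  expect_gt(r_tin, r_ctrl)
})

test_that("noisy simulations are reproducible given the seed", {
  cellp <- cell_params(noise_sd = 20, spike_on = FALSE)
  proto <- clamp_protocol("current_clamp",
                          data.frame(duration_ms = 500, from = 0, to = 0))
  a <- simulate(cellp, proto, seed = 7)
  b <- simulate(cellp, proto, seed = 7)
  expect_identical(a$signal, b$signal)
  c2 <- simulate(cellp, proto, seed = 8)
  expect_false(identical(a$signal, c2$signal))
})
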