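test_that("baseline RMS follows the root-mean-square definition", {
  expect_equal(rms_baseline(rep(0, 50)), 0)
  expect_equal(rms_baseline(rep(-3, 10)), 3)
  expect_equal(rms_baseline(c(3, 4)), sqrt((9 + 16) / 2))
})

metrics_fixture <- function(rms, pair_of = rep(seq_len(length(rms) / 2), each = 2)) {
  data.frame(
    mouse_id = "M1", phase = "pre", round_index = 1,
    pair_id = paste0("p", pair_of),
    frequency_khz = 16,
    measure = "gap",
    trial_type = rep(c("no_gap", "gap"), length(rms) / 2),
    p2p = 100, max_abs_amp = 50, rms_base = rms,
    stringsAsFactors = FALSE
  )
}

test_that("baseline filter eliminates outliers with their paired trials", {
  # identical baselines: SD = 0, nothing outside the band
  m0 <- filter_trials_by_baseline(metrics_fixture(rep(0.5, 40)))
  expect_true(all(m0$keep))

  # 19 clean pairs plus one pair whose gap trial has 10x baseline RMS
  set.seed(7)
  rms <- rnorm(40, 0.5, 0.02)
  rms[10] <- 5                       # gap trial of pair 5
  m <- filter_trials_by_baseline(metrics_fixture(rms))
  # brute-force recomputation of the band
  expect_identical(which(abs(rms - mean(rms)) > 2.5 * sd(rms)), 10L)
  expect_equal(which(!m$keep), c(9L, 10L))          # paired removal
  expect_equal(sum(!m$keep) %% 2, 0)                # eliminations come in pairs

  # already-filtered data lie inside the original band: nothing further
  orig_m <- mean(rms)
  orig_s <- sd(rms)
  expect_true(all(abs(m$rms_base[m$keep] - orig_m) <= 2.5 * orig_s))

  expect_error(filter_trials_by_baseline(metrics_fixture(c(0.5, 0.5))[1, , drop = FALSE]),
               "at least 2")
})

test_that("pair ratios divide probe by reference peak-to-peak amplitude", {
  m <- metrics_fixture(rep(0.5, 6))
  m$p2p <- c(100, 100, 100, 70, 100, 0)
  m$keep <- TRUE
  r <- compute_pair_ratios(m)
  expect_equal(sort(r$ratio), c(0, 0.7, 1))      # identical pair -> 1, 70/100, flat probe -> 0
})

test_that("zero-amplitude reference trials invalidate their pair", {
  m <- metrics_fixture(rep(0.5, 4))
  m$p2p <- c(0, 70, 100, 70)        # pair1 reference is flat
  m$keep <- TRUE
  r <- compute_pair_ratios(m)
  expect_equal(nrow(r), 1)
  expect_equal(r$ratio, 0.7)
})

test_that("sorted-jump filter truncates at the first >0.5 gap and drops overlong tails", {
  f <- filter_sorted_ratios(c(0.5, 0.6, 0.7, 1.3, 1.4))
  expect_equal(f$retained, c(0.5, 0.6, 0.7))
  expect_equal(f$n_excluded, 2L)
  expect_false(f$dropped)

  mono <- seq(0.2, 1.2, by = 0.1)      # all gaps 0.1
  expect_equal(filter_sorted_ratios(mono)$retained, mono)

  twelve <- c(seq(0.1, 0.6, by = 0.1), seq(1.3, 1.8, by = 0.1))  # 6 after jump
  f12 <- filter_sorted_ratios(twelve)
  expect_equal(f12$n_excluded, 6L)
  expect_true(f12$dropped)

  expect_true(filter_sorted_ratios(numeric(0))$dropped)
})

test_that("sorted-jump filter matches the brute-force linear oracle on random lists", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    r <- round(runif(n, 0, 2), 2)
    expect_identical(filter_sorted_ratios(r), oracle_jump_filter(r))
  }
})

test_that("final ratios average rounds then apply the exclusion limits", {
  base <- expand.grid(round_index = 1:3, frequency_khz = startle_frequencies,
                      measure = c("gap", "ppi"), phase = c("pre", "post"),
                      stringsAsFactors = FALSE)
  base$mouse_id <- "M1"
  base$ratio <- 0.6
  base$n_pairs_used <- 10
  base$n_excluded <- 0
  sel <- function(ph, f, me) base$phase == ph & base$frequency_khz == f &
    base$measure == me
  base$ratio[sel("pre", 16, "gap")] <- c(0.6, 0.7, 0.8)   # mean 0.7
  base$ratio[sel("pre", 20, "gap")] <- 0.95               # > 0.9 pre
  base$ratio[sel("post", 24, "ppi")] <- 1.05              # > 1 either phase
  fin <- finalize_ratios(base)
  pick <- function(ph, f, me) fin[fin$phase == ph & fin$frequency_khz == f &
                                    fin$measure == me, ]
  expect_equal(pick("pre", 16, "gap")$ratio, 0.7)
  expect_true(is.na(pick("pre", 20, "gap")$ratio))
  expect_equal(pick("pre", 20, "gap")$drop_reason, "ratio_limit")
  expect_true(is.na(pick("post", 24, "ppi")$ratio))
  expect_equal(pick("post", 10, "gap")$ratio, 0.6)
})

test_that("noise-free pipeline regenerates the configured latent ratio exactly", {
  prof <- fixed_profile(gap_pre = 0.67, gap_post = 0.67, trial_noise_sd = 0,
                        artifact_rate = 0)
  s <- generate_session(prof, "pre", seed = 1)
  rr <- session_round_ratios(s)
  got <- rr$ratio[rr$frequency_khz == 16 & rr$measure == "gap"]
  expect_equal(got, rep(0.67, 3), tolerance = 1e-12)
})

test_that("ratios are invariant to a common amplitude scale", {
  prof <- fixed_profile(trial_noise_sd = 0.1)
  s <- generate_session(prof, "pre", seed = 8)
  s2 <- s
  s2$waveforms <- s$waveforms * 3.7
  expect_equal(session_round_ratios(s2)$ratio, session_round_ratios(s)$ratio,
               tolerance = 1e-12)
})
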