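test_that("degenerate RR process is exactly periodic", {
  rr <- simulate_rr(sim_config(duration_s = 60, rr_cv = 0, base_rate_bpm = 30,
                               seed = 1))
  expect_true(all(rr == 2.0))
  expect_lte(sum(rr), 60)
})

test_that("truncation keeps ordinary intervals below the pause cut-off", {
  rr <- simulate_rr(sim_config(duration_s = 600, rr_cv = 0.2, seed = 2))
  # mean 2 s, truncated at +-20%: nothing can reach 3 s without a pause
  expect_true(all(rr > 1.6 & rr < 2.4))
  expect_identical(sum(rr > 3), 0L)
})

test_that("RR dispersion follows the configured coefficient of variation", {
  cfg <- sim_config(duration_s = 11000, rr_cv = 0.05, seed = 3)
  rr <- simulate_rr(cfg)
  expect_gt(length(rr), 5000)
  # SD of the difference of two i.i.d. normals is sqrt(2) * sigma
  expect_equal(sd(diff(rr)), sqrt(2) * 2 * 0.05, tolerance = 0.05)
})

test_that("mean RR converges to the configured rate", {
  cfg <- sim_config(duration_s = 4300, base_rate_bpm = 30,
                    chronotropy_factor = 1.2, seed = 4)
  rr <- simulate_rr(cfg)
  expect_gt(length(rr), 2000)
  mu <- 60 / (30 * 1.2)
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - mu), 3 * se)
})

test_that("pause injection is conserved in the ground truth", {
  cfg <- sim_config(duration_s = 600, pause_prob = 0.08, seed = 5)
  sim <- simulate_trace(cfg)
  expect_identical(sim$truth$n_pauses, sum(sim$truth$rr_s > 3.0))
  expect_gt(sim$truth$n_pauses, 0)
  expect_length(sim$truth$rr_s, length(sim$truth$event_times_s) - 1L)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- quick_config(noise_sd_nN = 2, drift_nN_per_s = 0.05, seed = 6)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$f, b$trace$f)
  expect_identical(a$truth, b$truth)
})

test_that("noise-free rendering reproduces the configured amplitude per beat", {
  cfg <- sim_config(duration_s = 25, noise_sd_nN = 0, seed = 7)
  sim <- simulate_trace(cfg)
  ev_t <- sim$truth$event_times_s
  expect_gte(length(ev_t), 10)
  for (i in seq_along(ev_t)) {
    win <- sim$trace$t >= ev_t[i] - 0.4 & sim$trace$t <= ev_t[i] + 1.2
    p2p <- max(sim$trace$f[win]) - min(sim$trace$f[win])
    expect_lt(abs(p2p - 100), 0.5)
  }
})

test_that("drift adds exactly the configured linear ramp", {
  base <- quick_config(noise_sd_nN = 0, seed = 8)
  drifted <- base
  drifted$drift_nN_per_s <- 0.1
  rr <- simulate_rr(base)
  a <- render_trace(rr, base)
  b <- render_trace(rr, drifted)
  expect_equal(b$trace$f - a$trace$f, 0.1 * a$trace$t, tolerance = 1e-12)
})

test_that("zero-amplitude configuration yields a beat-free trace", {
  sim <- simulate_trace(sim_config(duration_s = 30, amplitude_nN = 0,
                                   seed = 9))
  ev <- detect_events(detrend_trace(sim$trace))
  expect_identical(nrow(ev), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(base_rate_bpm = 0), "positive")
  expect_error(sim_config(pause_prob = 1), "pause_prob")
  expect_error(sim_config(pause_range_s = c(2, 5)), "cut-off")
  expect_error(render_trace(c(1, 1), sim_config(duration_s = 1)),
               "too short")
})

test_that("experiment design produces paired phases and exact bookkeeping", {
  des <- list(control = quick_config(noise_sd_nN = 2),
              treated = quick_config(noise_sd_nN = 2, pause_prob = 0.05,
                                     duration_s = 120))
  ex <- simulate_experiment(des, n_per_group = 4, seed = 11)
  expect_identical(nrow(ex$manifest), 16L)  # 8 recordings x 2 phases
  expect_false(anyDuplicated(paste(ex$manifest$recording_id,
                                   ex$manifest$phase)) > 0)
  # injected long-RR bookkeeping matches the manifest totals exactly
  for (rid in names(ex$recordings)) {
    tru <- ex$recordings[[rid]]$treatment$truth
    expect_identical(tru$n_pauses, sum(tru$rr_s > 3.0))
    # baselines are drug-free: no injected pauses
    expect_identical(ex$recordings[[rid]]$baseline$truth$n_pauses, 0L)
  }
})

test_that("control-only experiment has unit amplitude ratio in ground truth", {
  des <- list(control = quick_config(noise_sd_nN = 1))
  ex <- simulate_experiment(des, n_per_group = 5, seed = 12)
  ratios <- vapply(ex$recordings, function(r) {
    mean(r$treatment$truth$amplitudes_nN) /
      mean(r$baseline$truth$amplitudes_nN)
  }, numeric(1))
  expect_equal(unname(ratios), rep(1, 5), tolerance = 1e-12)
})

test_that("configured inotropy factor is recovered from ground truth", {
  des <- list(drug = quick_config(noise_sd_nN = 1, inotropy_factor = 1.4))
  ex <- simulate_experiment(des, n_per_group = 10, seed = 13)
  ratios <- vapply(ex$recordings, function(r) {
    mean(r$treatment$truth$amplitudes_nN) /
      mean(r$baseline$truth$amplitudes_nN)
  }, numeric(1))
  expect_equal(mean(ratios), 1.4, tolerance = 0.05 * 1.4)
})

test_that("duplicate group labels are rejected", {
  des <- list(a = quick_config(), a = quick_config())
  names(des) <- c("a", "a")
  expect_error(simulate_experiment(des, 2, seed = 1), "named")
})
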