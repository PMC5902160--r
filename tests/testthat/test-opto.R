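test_that("step PSTHs report rates against a pre-stimulus baseline", {
  sp <- regular_spikes(100, 0, 20)
  st <- stimulus_trials(1:3, "step", c(3, 8, 13), 1.7)
  ps <- step_psth(sp, st)
  expect_length(ps$rate, 20)
  expect_equal(ps$rate, rep(100, 20), tolerance = 0.01 * 100)
  expect_equal(ps$baseline, 100, tolerance = 1)
  # PSTH average equals the mean stimulus rate (consistency)
  rc <- mean(vapply(1:3, function(i)
    stim_rate_change(sp, st[i, ])$stim_rate, numeric(1)))
  expect_equal(mean(ps$rate), rc, tolerance = 1e-9)
  # silence during the stimulus -> all bins zero
  gap <- spike_train(c(seq(0, 2.99, by = 0.01), seq(4.1, 6, by = 0.01)),
                     span = c(0, 6))
  ps0 <- step_psth(gap, stimulus_trials(1, "step", 3, 1.7))
  expect_equal(ps0$rate, rep(0, 20))
})

test_that("step responses reproduce the suppression-then-recovery shape", {
  ses <- noiseless_session(seed = 4, n_strides = 150)
  om <- opto_model("step", rate_effect_hz = -70, transient_frac = 0.4,
                   tau_ms = 100)
  trials <- list(list(onset_s = 6, opto = om), list(onset_s = 14, opto = om),
                 list(onset_s = 22, opto = om))
  sp <- suppressWarnings(
    gen_spike_train(gen_tuning("I", 100, 0.2), ses$truth, 90, trials,
                    cell_type = "CbN", seed = 8))
  st <- stimulus_trials(1:3, "step", c(6, 14, 22), 1.7)
  ps <- step_psth(sp, st)
  expect_lt(mean(ps$rate[1:2]), mean(ps$rate[11:20]))   # deepest at onset
  expect_lt(mean(ps$rate[11:20]), ps$baseline)          # plateau below base
  # mean rate change over trials near the configured effect
  deltas <- vapply(1:3, function(i) stim_rate_change(sp, st[i, ])$delta,
                   numeric(1))
  expect_lt(abs(mean(deltas) + 70 * 1.04), 3 * sqrt(100 / 3) + 10)
})

test_that("train PSTHs lock to pulses and conserve spike counts", {
  ses <- noiseless_session(seed = 5, n_strides = 100)
  om <- opto_model("train", freq_hz = 100, lock_prob = 1,
                   lock_latency_ms = 2.5, deterministic = TRUE)
  sp <- gen_spike_train(gen_tuning("I", 100, 0.3), ses$truth, 90,
                        list(list(onset_s = 5, opto = om)), seed = 6)
  st <- stimulus_trials(1, "train", 5, 1.7, 100)
  ps <- train_psth(sp, st)
  expect_equal(ps$prob[3], 1)                 # all mass in the 2-3 ms bin
  expect_equal(sum(ps$prob[-3]), 0)
  expect_equal(ps$groups$early, ps$groups$middle)
  expect_equal(ps$groups$early, ps$groups$late)
  # count conservation: sum(prob) * freq = mean stimulus rate
  expect_equal(sum(ps$prob) * 100, stim_rate_change(sp, st[1, ])$stim_rate)
  # pulse-group split generalizes as thirds with remainder late
  om2 <- opto_model("train", freq_hz = 50, lock_prob = 0.5)
  sp2 <- gen_spike_train(gen_tuning("I", 100, 0.3), ses$truth, 90,
                         list(list(onset_s = 5, opto = om2)), seed = 7)
  st2 <- stimulus_trials(1, "train", 5, 1.7, 50)
  ps2 <- train_psth(sp2, st2)
  expect_equal(sum(ps2$prob) * 50, stim_rate_change(sp2, st2[1, ])$stim_rate,
               tolerance = 1e-9)
})

test_that("unlocked trains give a flat pulse PSTH at baseline", {
  ses <- noiseless_session(seed = 6, n_strides = 100)
  om <- opto_model("train", freq_hz = 100, lock_prob = 0)
  sp <- gen_spike_train(function(p) 100, ses$truth, 100,
                        list(list(onset_s = 5, opto = om)), seed = 9)
  ps <- train_psth(sp, stimulus_trials(1, "train", 5, 1.7, 100))
  expect_lt(max(abs(ps$prob - ps$baseline)), 0.1)    # binomial noise only
  expect_lt(abs(mean(ps$prob) - 0.1), 0.03)          # 100 Hz -> 0.1/ms
})

test_that("CbN-style locking suppresses spikes 2-6 ms after each pulse", {
  ses <- noiseless_session(seed = 7, n_strides = 150)
  om <- opto_model("train", freq_hz = 100, lock_prob = 1,
                   lock_latency_ms = 2, lock_window_ms = 4)
  trials <- lapply(c(5, 13, 21), function(on) list(onset_s = on, opto = om))
  sp <- gen_spike_train(function(p) 100, ses$truth, 100, trials,
                        cell_type = "CbN", seed = 10)
  st <- stimulus_trials(1:3, "train", c(5, 13, 21), 1.7, 100)
  ps <- train_psth(sp, st)
  expect_lt(sum(ps$prob[3:6]), 0.005)        # 2-6 ms window empty
  expect_gt(sum(ps$prob[c(1, 2, 8:10)]), 0.2)
})

test_that("Rayleigh statistics detect pulse locking", {
  expect_equal(rayleigh_test(rep(1.2, 50))$R, 1)
  grid <- 2 * pi * (1:100 - 0.5) / 100
  rg <- rayleigh_test(grid)
  expect_lt(rg$R, 1e-10)
  expect_gt(rg$p, 0.99)
  expect_true(is.na(rayleigh_test(rep(1, 5))$p))
  # partial locking is significant in nearly all seeds
  ses <- noiseless_session(seed = 8, n_strides = 60)
  om <- opto_model("train", freq_hz = 100, lock_prob = 0.5)
  n_sig <- 0
  for (s in 1:20) {
    sp <- gen_spike_train(function(p) 90, ses$truth, 90,
                          list(list(onset_s = 5, opto = om)),
                          seed = 500 + s)
    rl <- rayleigh_locking(sp, 5 + (0:99) / 100, 100)
    if (rl$p < 0.001) n_sig <- n_sig + 1
  }
  expect_gte(n_sig, 19)
})

test_that("Rayleigh p-values agree with the uniform-phase null", {
  for (n in c(10, 50, 200)) {
    null_R <- rayleigh_null(n)
    set.seed(n + 1)
    for (i in 1:5) {
      th <- 2 * pi * ((stats::rnorm(n, 0, 0.6)) %% 1)
      rt <- rayleigh_test(th)
      emp <- mean(null_R >= rt$R)
      mc_err <- 3 * sqrt(emp * (1 - emp) / 10000) + 0.01
      if (emp > 0.002 && emp < 0.998)
        expect_lt(abs(rt$p - emp), mc_err + 0.25 * emp)
    }
  }
})

test_that("rate changes and rebound are measured by direct counting", {
  sp <- spike_train(c(seq(0.01, 1, by = 1 / 90), seq(1.05, 2, by = 0.19)),
                    span = c(0, 4))
  tr <- stimulus_trials(1, "step", 1, 1.7)
  rc <- stim_rate_change(sp, tr[1, ])
  expect_equal(rc$pre_rate, 90)
  expect_equal(rc$stim_rate, 5)
  expect_equal(rc$delta, -85)
  # identical windows -> delta 0
  sp2 <- regular_spikes(80, 0, 6)
  expect_equal(stim_rate_change(sp2, tr[1, ])$delta, 0)
  # rebound: +20 spikes/s for 200 ms after offset, recovered
  ses <- noiseless_session(seed = 9, n_strides = 100)
  om <- opto_model("step", rate_effect_hz = 0, rebound_hz = 60)
  trials <- lapply(c(4, 10, 16), function(on) list(onset_s = on, opto = om))
  sp3 <- gen_spike_train(function(p) 90, ses$truth, 90, trials, seed = 12)
  st3 <- stimulus_trials(1:3, "step", c(4, 10, 16), 1.7)
  rb <- vapply(1:3, function(i) {
    r <- rebound_rate(sp3, st3[i, ])
    r$post_off - r$pre_off
  }, numeric(1))
  expect_lt(abs(mean(rb) - 60), 3 * sqrt(2 * 90 / 0.2 / 3))
  tiny <- spike_train(c(1, 2), span = c(0, 3))
  expect_error(rebound_rate(tiny, stimulus_trials(1, "step", 2.5, 1.7)),
               "span")
})

test_that("ISI CV uses the population SD and handles edge cases", {
  sp <- spike_train(c(0, 0.010, 0.030, 0.060), span = c(0, 0.1))
  expect_equal(isi_cv(sp, c(0, 0.1)), sqrt(200 / 3) / 20, tolerance = 1e-9)
  expect_equal(round(isi_cv(sp, c(0, 0.1)), 3), 0.408)
  # perfectly regular firing
  expect_equal(isi_cv(regular_spikes(100, 0, 1), c(0, 1)), 0)
  # Poisson firing approaches CV = 1
  set.seed(3)
  t <- cumsum(rexp(5000, 100))
  expect_equal(isi_cv(spike_train(t, span = c(0, max(t))), c(0, max(t))),
               1, tolerance = 0.06)
  # fewer than 2 ISIs is undefined
  expect_true(is.na(isi_cv(sp, c(0, 0.015))))
})
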