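test_that("instantaneous rate is the held reciprocal ISI", {
  sp <- spike_train(c(0, 0.01, 0.02), span = c(0, 0.05))
  ifr <- instantaneous_rate(sp)
  expect_equal(ifr_at(ifr, c(0.001, 0.015)), c(100, 100))
  expect_true(is.na(ifr_at(ifr, 0.03)))
  sp2 <- spike_train(c(0, 0.005, 0.025), span = c(0, 0.05))
  ifr2 <- instantaneous_rate(sp2)
  expect_equal(ifr_at(ifr2, c(0.002, 0.01)), c(200, 50))
  expect_equal(ifr_mean(ifr2, 0, 0.025), 80)  # time-weighted average
  # < 2 spikes -> empty rate function
  empty <- instantaneous_rate(spike_train(0.1, span = c(0, 1)))
  expect_true(is.na(ifr_at(empty, 0.1)))
  # long-run average converges to the Poisson rate
  set.seed(4)
  t <- cumsum(rexp(10000, 100))
  ifr3 <- instantaneous_rate(spike_train(t, span = c(0, max(t))))
  expect_lt(abs(ifr_mean(ifr3, 0, max(t)) - 100), 3 * 100 / sqrt(10000))
})

test_that("binned tuning is flat for regular firing and recovers the generator", {
  ses <- noiseless_session(seed = 1, n_strides = 120)
  t_end <- max(ses$truth$strides$next_plant_s) + 0.2
  sp <- regular_spikes(100, 0, t_end)
  bt <- binned_tuning(sp, ses$strides)
  expect_equal(bt$rate, rep(100, 10), tolerance = 1e-6)
  # class I, MI 0.4: bin curve matches the tuning function at bin centers
  tun <- gen_tuning("I", 110, 0.4)
  sp2 <- gen_spike_train(tun, ses$truth, 93, seed = 21)
  bt2 <- binned_tuning(sp2, ses$strides, trace = ses$trace)
  centers <- stridemod:::bin_center_phase(bt2$n_stance,
                                          10 - bt2$n_stance,
                                          ses$truth$stance_fraction)
  expect_equal(bt2$rate, tun(centers), tolerance = 0.08 * 110)
  # equal-width re-binning does not change the class assignment
  bt_eq <- binned_tuning(sp2, ses$strides, equal_bins = TRUE,
                         trace = ses$trace)
  expect_equal(classify_modulation(bt_eq), classify_modulation(bt2))
  # too few strides is an error
  expect_error(binned_tuning(sp, ses$strides[1:10, ]), "at least 30")
})

test_that("modulation index follows its definition and invariances", {
  mk <- function(r, ns = 6) structure(list(rate = r, n_stance = ns),
                                      class = "stride_tuning")
  expect_equal(unname(modulation_index(mk(c(150, rep(100, 8), 50)))["MI"]),
               0.5)
  expect_equal(unname(modulation_index(mk(rep(80, 10)))["MI"]), 0)
  expect_equal(unname(modulation_index(mk(c(0, rep(5, 9))))["MI"]), 1)
  # stance/swing restrictions
  r <- c(10, 20, 30, 40, 30, 20, 5, 10, 15, 5)
  mi <- modulation_index(mk(r, 6))
  expect_equal(unname(mi["St_MI"]), (40 - 10) / (40 + 10))
  expect_equal(unname(mi["Sw_MI"]), (15 - 5) / (15 + 5))
  # scale invariance: MI(c * rates) = MI(rates)
  set.seed(2)
  for (i in 1:20) {
    r <- runif(10, 1, 200)
    cst <- runif(1, 0.1, 50)
    expect_equal(modulation_index(mk(r)), modulation_index(mk(cst * r)),
                 tolerance = 1e-12)
  }
})

test_that("rest and run rates are recovered from generated sessions", {
  # homogeneous firing: rest and run means agree
  cfg <- session_config(seed = 13, n_strides = 60,
                        rest_epochs = list(c(5, 4)), noise_sd_au = 0,
                        artifact_rate_hz = 0)
  pw <- gen_paw_trace(cfg)
  st <- detect_strides(pw$trace)
  re <- detect_rest(pw$trace, st)
  t_end <- max(pw$truth$strides$next_plant_s) + 0.2
  rr <- rest_run_rates(regular_spikes(90, 0, t_end), re, st)
  expect_equal(rr$rest_mean, 90, tolerance = 0.02 * 90)
  expect_equal(rr$run_mean, 90, tolerance = 0.02 * 90)
  # Purkinje defaults: rest 93, run 93 + 26, recovered within sampling error
  tun <- gen_tuning("I", 93 + 26, 0.4)
  sp <- gen_spike_train(tun, pw$truth, 93, seed = 5)
  rr2 <- rest_run_rates(sp, re, st)
  expect_lt(abs(rr2$rest_mean - 93), 3 * sqrt(93 * 4) / 4)
  run_dur <- sum(st$next_plant_s - st$plant_s)
  expect_lt(abs(rr2$run_mean - 119), 3 * sqrt(119 * run_dur) / run_dur)
  # min/max of the bin curve reflect the MI 0.4 tuning (~167/71 spikes/s)
  expect_equal(rr2$run_max, 119 * 1.4, tolerance = 0.1 * 119 * 1.4)
  expect_equal(rr2$run_min, 119 * 0.6, tolerance = 0.12 * 119 * 0.6)
  expect_gt(length(rr2$ifr_hist$run), 10)
  # insufficient rest leaves the rest rate missing
  rr3 <- rest_run_rates(sp, re[0, ], st)
  expect_true(is.na(rr3$rest_mean))
})

test_that("Kuiper test separates concentrated from uniform phases", {
  k1 <- kuiper_test(rep(0.3, 100))
  expect_equal(k1$V, 1, tolerance = 0.01)
  expect_lt(k1$p, 1e-6)
  k2 <- kuiper_test((1:100 - 0.5) / 100)
  expect_gt(k2$p, 0.99)
  expect_true(is.na(kuiper_test(runif(5))$p))    # n below minimum
  # von Mises concentration is detected
  set.seed(31)
  th <- atan2(sin(stats::rnorm(200, 0, 1)), cos(stats::rnorm(200, 0, 1)))
  ph <- (th / (2 * pi)) %% 1
  expect_lt(kuiper_test(ph)$p, 0.001)
})

test_that("Kuiper p-values agree with the uniform sampling null", {
  # formula p vs the empirical placement of V in a 10,000-draw null
  for (n in c(10, 50, 200)) {
    null_V <- kuiper_null(n)
    set.seed(n)
    for (i in 1:5) {
      ph <- (stats::rnorm(n, 0.5, 0.35)) %% 1   # mildly non-uniform
      kt <- kuiper_test(ph)
      emp <- mean(null_V >= kt$V)
      mc_err <- 3 * sqrt(emp * (1 - emp) / 10000) + 0.01
      if (emp > 0.002 && emp < 0.998)
        expect_lt(abs(kt$p - emp), mc_err + 0.25 * emp)
    }
  }
})

test_that("modulation classes round-trip through spike generation", {
  ses <- noiseless_session(seed = 1, n_strides = 150)
  for (cl in c("I", "II", "III", "IV", "V", "VI")) {
    tun <- gen_tuning(cl, 119, 0.4)
    sp <- gen_spike_train(tun, ses$truth, 93, seed = 77)
    bt <- binned_tuning(sp, ses$strides, trace = ses$trace)
    expect_equal(classify_modulation(bt), cl)
  }
  # class assignment ignores constant rate offsets
  tun <- gen_tuning("III", 119, 0.4)
  sp <- gen_spike_train(tun, ses$truth, 93, seed = 78)
  bt <- binned_tuning(sp, ses$strides, trace = ses$trace)
  bt_off <- bt
  bt_off$rate <- bt$rate + 55
  expect_equal(classify_modulation(bt), classify_modulation(bt_off))
  # flat or non-modulated curves fall into class VII
  flat <- bt
  flat$rate <- rep(100, 10) + c(0.1, -0.1)
  expect_equal(classify_modulation(flat), "VII")
  expect_equal(classify_modulation(bt, kuiper_p = 0.2), "VII")
})

test_that("population averages cancel antiphase pairs and keep phase leads", {
  ses <- noiseless_session(seed = 2, n_strides = 120)
  mk <- function(tun, seed) binned_tuning(
    gen_spike_train(tun, ses$truth, 93, seed = seed), ses$strides)
  t1 <- mk(gen_tuning("I", 110, 0.4), 1)
  expect_equal(population_average(list(t1, t1)), t1$rate)
  # class I + class II with equal MI: near-flat average
  t2 <- mk(gen_tuning("II", 110, 0.4), 2)
  avg <- population_average(list(t1, t2), normalize = TRUE)
  expect_lt(diff(range(avg)), 0.35)
  expect_gt(diff(range((t1$rate - min(t1$rate)) / diff(range(t1$rate)))),
            0.99)
  # one population peaking two bins before the other
  r <- ses$truth$stance_fraction
  width2 <- 2 * r / t1$n_stance          # two stance bins in true phase
  tun_cbn <- gen_tuning("I", 110, 0.4)
  tun_pkj <- function(p) tun_cbn((p + width2) %% 1)
  pkj <- lapply(1:4, function(s) mk(tun_pkj, 10 + s))
  cbn <- lapply(1:4, function(s) mk(tun_cbn, 20 + s))
  lag <- which.max(population_average(pkj, TRUE)) -
    which.max(population_average(cbn, TRUE))
  expect_equal(lag, -2)
})

test_that("rate-velocity regression recovers a linear dependence", {
  ses <- noiseless_session(seed = 3, n_strides = 100)
  # rate tied to |velocity| via the tuning: build rate = a + b * velocity
  sm <- smooth_trace(ses$trace, 50)
  tt <- trace_times(sm)
  vel <- c(0, diff(sm$x)) * sm$sample_rate
  a <- 80; b <- 6
  rate <- pmax(a + b * vel, 0.1)
  set.seed(9)
  # thinning on the velocity-derived rate
  rmax <- max(rate)
  cand <- cumsum(rexp(20000, rmax))
  cand <- cand[cand < max(tt)]
  keep <- runif(length(cand)) < approx(tt, rate, cand)$y / rmax
  sp <- spike_train(cand[keep], span = c(0, max(tt)))
  fit <- rate_velocity_regression(sp, ses$trace)
  expect_gt(fit$r, 0.3)
  expect_lt(fit$p, 1e-6)
  expect_equal(fit$slope, b, tolerance = 0.35 * b)
  # null: no velocity dependence -> significant in roughly alpha of seeds
  n_sig <- 0
  for (s in 1:20) {
    spn <- gen_spike_train(function(p) 100, ses$truth, 100,
                           seed = 400 + s)
    if (rate_velocity_regression(spn, ses$trace)$p < 0.05)
      n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 4)
})
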