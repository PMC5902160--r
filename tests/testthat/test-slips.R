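# strides built by hand for rule-level tests
mk_strides <- function(plant, dur_ms, stance_frac = 0.65, amp = 1) {
  dur <- dur_ms / 1000
  df <- data.frame(plant_s = plant, lift_s = plant + stance_frac * dur,
                   next_plant_s = plant + dur, duration_ms = dur_ms,
                   stance_slope = amp / (stance_frac * dur),
                   swing_slope = amp / ((1 - stance_frac) * dur),
                   stance_fraction = stance_frac)
  class(df) <- c("stride_set", "data.frame")
  df
}
trial_row <- function(onset, kind = "step") {
  stimulus_trials(1L, kind, onset, 1.7,
                  if (kind == "train") 100 else NA_real_)[1, ]
}

test_that("trial screening applies the stated discard rules", {
  # regular running throughout -> accepted
  st <- mk_strides(seq(0, 4.75, by = 0.25), 250)
  tr <- trial_row(3.05)
  expect_equal(screen_trial(tr, st, rest = NULL), "accepted")
  # running stops during the stimulus without resuming
  rest <- data.frame(start_s = 3.3, end_s = 6)
  expect_equal(screen_trial(tr, st[st$next_plant_s <= 3.3, ], rest),
               "discarded_stop")
  # rest inside the stimulus but running resumes before trial end
  st2 <- mk_strides(c(seq(0, 3, by = 0.25), 4.4, 4.65), 250)
  rest2 <- data.frame(start_s = 3.35, end_s = 4.35)
  expect_equal(screen_trial(tr, st2, rest2), "accepted")
  # last pre-stimulus stride twice the prior median
  st3 <- mk_strides(c(0, 0.25, 0.5, 0.75, 1.0), c(250, 250, 250, 250, 500))
  expect_equal(screen_trial(trial_row(1.55), st3, NULL),
               "discarded_prestim_change")
  # no pre-stimulus stride at all
  expect_equal(screen_trial(trial_row(0.1), st, NULL), "unresolved")
})

test_that("the reference stride is the last one ending by stimulus onset", {
  st <- mk_strides(c(1.0, 1.25, 1.64), c(250, 250, 250))
  # strides ending 120 and 10 ms before onset = 1.9: the later one wins
  ref <- reference_stride(trial_row(1.9), st[1:2, ])
  expect_equal(ref$plant_s, 1.25)
  # a stride straddling onset by 50 ms is not eligible under the 30 ms grace
  ref2 <- reference_stride(trial_row(1.84), st)
  expect_equal(ref2$plant_s, 1.25)
  expect_null(reference_stride(trial_row(1.2), st))
  # noiseless generated trials: the chosen stride matches ground truth
  ses <- simulate_session(quiet_cfg(seed = 21), slip_plan(NA))
  ss <- detect_strides(ses$trace)
  ref3 <- reference_stride(ses$trials[1, ], ss)
  q <- ses$truth$trial_truth$slip_stride[1]
  expect_equal(ref3$plant_s, ses$truth$strides$plant_s[q - 2],
               tolerance = 0.005)
})

test_that("slip criteria fire at the 20% boundaries, inclusively", {
  ref <- mk_strides(2.0, 250)
  tr <- trial_row(2.3)
  # prolonged in the reported regime: 250 -> 522 ms (ratio 2.09)
  out <- classify_trial(tr, rbind(ref, mk_strides(2.5, 522)), ref)
  expect_equal(out$label, "slip")
  expect_true(out$prolonged)
  expect_false(out$incomplete)
  # arrested stance slope 5.5 -> 2.7 AU/s (0.49x)
  slow <- mk_strides(2.5, 250, amp = 2.7 / 5.5)
  out2 <- classify_trial(tr, rbind(ref, slow), ref)
  expect_true(out2$arrested)
  expect_true(out2$altered)    # both stance and swing slopes reduced
  # identical strides -> non-slip, with the most deviant stride reported
  same <- mk_strides(c(2.5, 2.75, 3.0), c(250, 251, 250))
  out3 <- classify_trial(tr, rbind(ref, same), ref)
  expect_equal(out3$label, "non_slip")
  expect_equal(out3$worst_duration_ms, 251)
  # exact 1.20 ratio is prolonged (inclusive boundary)
  out4 <- classify_trial(tr, rbind(ref, mk_strides(2.5, 300)), ref)
  expect_true(out4$prolonged)
  out5 <- classify_trial(tr, rbind(ref, mk_strides(2.5, 299)), ref)
  expect_equal(out5$label, "non_slip")
  # no evaluable stimulus stride: unresolved, or slip under the option
  out6 <- classify_trial(tr, ref, ref)
  expect_equal(out6$screen, "unresolved")
  out7 <- classify_trial(tr, ref, ref, unresolved_as_slip = TRUE)
  expect_equal(out7$label, "slip")
})

test_that("injected slips are recovered with their categories and latencies", {
  cats <- c("prolonged", "incomplete", "arrested")
  n_lat <- 0; n_lat_ok <- 0
  for (s in 1:10) {
    plan <- rbind(slip_plan(cats[(s %% 3) + 1]), slip_plan(NA),
                  slip_plan(cats[((s + 1) %% 3) + 1], kind = "train"),
                  slip_plan(NA, kind = "train"))
    cfg <- session_config(seed = 600 + s, noise_sd_au = 0.01,
                          cell_type = "CbN")
    res <- run_pipeline(cfg, plan)
    o <- res$outcomes
    tt <- res$truth$trial_truth
    for (i in seq_len(nrow(o))) {
      if (is.na(o$label[i])) next
      expect_equal(o$label[i] == "slip", tt$slip[i])
      if (tt$slip[i] && o$label[i] == "slip") {
        expect_true(o[[tt$category[i]]][i])
        if (!is.na(o$latency_ms[i])) {
          n_lat <- n_lat + 1
          n_lat_ok <- n_lat_ok + (abs(o$latency_ms[i] - 120) <= 25)
        }
      }
    }
  }
  expect_gte(n_lat, 15)
  expect_gte(n_lat_ok / n_lat, 0.9)
})

test_that("slip probabilities are exact count ratios with the right tests", {
  mk_out <- function(n_slip, n_tot, cond) data.frame(
    label = rep(c("slip", "non_slip"), c(n_slip, n_tot - n_slip)),
    kind = cond)
  out <- rbind(mk_out(1, 77, "control"), mk_out(31, 33, "chr2"))
  spb <- slip_probability(out)
  tab <- spb$table[order(spb$table$condition), ]
  expect_equal(tab$p_slip, c(31 / 33, 1 / 77))
  expect_equal(round(100 * tab$p_slip, 1), c(93.9, 1.3))
  expect_lt(spb$fisher_p, 0.001)
  expect_lt(spb$chisq$p, 0.001)
  # zero slips
  spb0 <- slip_probability(rbind(mk_out(0, 20, "a"), mk_out(5, 20, "b")))
  expect_equal(spb0$table$p_slip[spb0$table$condition == "a"], 0)
})

test_that("rate matching pairs trials within 10 spikes/s above the floor", {
  steps <- data.frame(cell = "c1", trial_id = 1:3, rate = c(71, 71, 8),
                      slip = c(TRUE, FALSE, TRUE))
  trains <- data.frame(cell = "c1", trial_id = 11:13, rate = c(75, 85, 9),
                       slip = c(FALSE, FALSE, TRUE))
  pr <- rate_match_pairs(steps, trains)
  # 71-75 pairs (twice, two step trials); 71-85 and the sub-floor 8/9 do not
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$train_id == 11))
  expect_true(all(abs(pr$step_rate - pr$train_rate) <= 10))
  expect_true(all(pr$step_rate >= 10 & pr$train_rate >= 10))
  # cells are never mixed
  trains2 <- trains; trains2$cell <- "c2"
  expect_equal(nrow(rate_match_pairs(steps, trains2)), 0)
})

test_that("McNemar uses the uncorrected chi-square or the exact binomial", {
  m <- mcnemar_slip_test(b = 127, c = 31)
  expect_equal(m$statistic, 96^2 / 158, tolerance = 1e-12)
  expect_lt(m$p, 0.001)
  expect_equal(m$method, "chi-square (uncorrected)")
  # b = c -> p = 1 in the asymptotic regime
  expect_equal(mcnemar_slip_test(b = 15, c = 15)$p, 1)
  # exact: b = 10, c = 0 -> 2 * 0.5^10
  m2 <- mcnemar_slip_test(b = 10, c = 0)
  expect_equal(m2$p, 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(m2$method, "exact binomial")
  # degenerate case
  expect_equal(mcnemar_slip_test(b = 0, c = 0)$p, 1)
  # exact p equals the two-tailed binomial for every b + c <= 20
  for (n in 1:20) for (b in 0:n) {
    got <- mcnemar_slip_test(b = b, c = n - b)$p
    if (n < 25) {
      oracle <- min(1, 2 * pbinom(min(b, n - b), n, 0.5))
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  }
  # pair-level interface reports arm probabilities and fractions
  pairs <- data.frame(step_slip = rep(c(TRUE, TRUE, FALSE), c(6, 3, 1)),
                      train_slip = rep(c(TRUE, FALSE, FALSE), c(6, 3, 1)))
  mp <- mcnemar_slip_test(pairs)
  expect_equal(mp$b, 3)
  expect_equal(mp$c, 0)
  expect_equal(mp$p_step, 0.9)
  expect_equal(mp$p_train, 0.6)
  expect_equal(mp$frac_step_only, 0.3)
})
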