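# Shared builders for synthetic fixtures. Everything is generated in code;
# sizes are kept small enough for the default test run.

quiet_cfg <- function(seed = 1L, n_strides = 120L, ...) {
  session_config(seed = seed, n_strides = n_strides, noise_sd_au = 0,
                 artifact_rate_hz = 0, ...)
}

# a noiseless session plus its detected strides (computed once per call)
noiseless_session <- function(seed = 1L, n_strides = 120L, ...) {
  pw <- gen_paw_trace(quiet_cfg(seed, n_strides, ...))
  list(trace = pw$trace, truth = pw$truth,
       strides = detect_strides(pw$trace))
}

# spikes at a constant rate (regular intervals -> exactly flat IFR)
regular_spikes <- function(rate_hz, t0, t1) {
  spike_train(seq(t0, t1, by = 1 / rate_hz), span = c(t0, t1))
}

# default slip trial plan: one trial per row
slip_plan <- function(category, magnitude = 0.5, kind = "step",
                      rate_effect_hz = -30, lock_prob = 0.3,
                      latency_ms = 120) {
  data.frame(kind = kind, intensity_mw = 1.7,
             freq_hz = ifelse(kind == "train", 100, NA_real_),
             rate_effect_hz = rate_effect_hz, lock_prob = lock_prob,
             slip_category = category, slip_magnitude = magnitude,
             slip_latency_ms = latency_ms)
}

# empirical V distribution of the Kuiper statistic under uniformity
kuiper_null <- function(n, n_draws = 10000, seed = 42) {
  set.seed(seed)
  i <- seq_len(n)
  replicate(n_draws, {
    u <- sort(stats::runif(n))
    max(i / n - u) + max(u - (i - 1) / n)
  })
}

# empirical resultant-length distribution under circular uniformity
rayleigh_null <- function(n, n_draws = 10000, seed = 42) {
  set.seed(seed)
  replicate(n_draws, Mod(mean(exp(2i * pi * stats::runif(n)))))
}
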