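#' Synthetic session configuration
#'
#' Parameters of the synthetic locomotion/recording sessions used to validate
#' the pipeline by parameter recovery. Defaults emulate the recorded data:
#' stride durations 140-419 ms (mean 222, SD 71), stance occupying ~65% of
#' the stride, paw tracking at 240 samples/s, Purkinje-like rest rates near
#' 93 spikes/s with a ~26 spikes/s increase during running, and a stride
#' modulation index of 0.4.
#'
#' @param seed integer seed; all generation downstream of the config is
#'   reproducible given the seed.
#' @param n_strides number of strides to generate.
#' @param stride_mean_ms,stride_sd_ms mean and SD of stride duration (ms).
#' @param stride_min_ms,stride_max_ms admissible duration range (ms); the
#'   duration distribution is a truncated normal (out-of-range draws are
#'   redrawn, preserving the mean).
#' @param stance_fraction fraction of each stride occupied by the stance
#'   (rising) phase, in (0,1).
#' @param rest_epochs list of `c(start_s, duration_s)` quiescent epochs to
#'   insert between strides.
#' @param cell_type `"Purkinje"` or `"CbN"`; sets rate defaults and the sign
#'   of optogenetic rate effects.
#' @param base_rest_rate_hz firing rate at rest (spikes/s). Default 93 for
#'   Purkinje, 85 for CbN.
#' @param run_rate_offset_hz rate increase during running (default 26
#'   Purkinje, 16 CbN).
#' @param tuning_class modulation class "I".."VI" (see [gen_tuning()]).
#' @param target_mi target modulation index in (0,1).
#' @param paw_sample_hz video sampling rate (Hz).
#' @param noise_sd_au SD of additive position noise (AU).
#' @param artifact_rate_hz rate of square-pulse tracking-loss artifacts
#'   (events/s; 1-3 samples wide, full-scale).
#' @return a `session_config` list.
#' @export
session_config <- function(seed = 1L, n_strides = 200L,
                           stride_mean_ms = 222, stride_sd_ms = 71,
                           stride_min_ms = 140, stride_max_ms = 419,
                           stance_fraction = 0.65, rest_epochs = list(),
                           cell_type = c("Purkinje", "CbN"),
                           base_rest_rate_hz = NULL, run_rate_offset_hz = NULL,
                           tuning_class = "I", target_mi = 0.4,
                           paw_sample_hz = 240, noise_sd_au = 0.01,
                           artifact_rate_hz = 0.1) {
  cell_type <- match.arg(cell_type)
  if (is.null(base_rest_rate_hz))
    base_rest_rate_hz <- if (cell_type == "Purkinje") 93 else 85
  if (is.null(run_rate_offset_hz))
    run_rate_offset_hz <- if (cell_type == "Purkinje") 26 else 16
  stopifnot(stride_min_ms <= stride_mean_ms, stride_mean_ms <= stride_max_ms,
            target_mi > 0, target_mi < 1,
            stance_fraction > 0, stance_fraction < 1,
            n_strides >= 1, base_rest_rate_hz > 0)
  structure(list(seed = as.integer(seed), n_strides = as.integer(n_strides),
                 stride_mean_ms = stride_mean_ms, stride_sd_ms = stride_sd_ms,
                 stride_min_ms = stride_min_ms, stride_max_ms = stride_max_ms,
                 stance_fraction = stance_fraction, rest_epochs = rest_epochs,
                 cell_type = cell_type,
                 base_rest_rate_hz = base_rest_rate_hz,
                 run_rate_offset_hz = run_rate_offset_hz,
                 tuning_class = tuning_class, target_mi = target_mi,
                 paw_sample_hz = paw_sample_hz, noise_sd_au = noise_sd_au,
                 artifact_rate_hz = artifact_rate_hz),
            class = "session_config")
}

#' Optogenetic stimulus model
#'
#' Describes how one 1 s light stimulus perturbs the generated spike train.
#' Steps apply a signed rate offset (positive for Purkinje, negative for CbN)
#' with an onset transient decaying with time constant `tau_ms`; trains add
#' (Purkinje) or remove (CbN) spikes in a short window after each 1 ms pulse.
#'
#' @param kind `"step"` or `"train"`.
#' @param intensity_mw light power; one of 0.56, 0.65, 0.9 (0.87), 1.7, 2.6.
#' @param freq_hz train pulse rate (50/100/150/200 Hz); trains only.
#' @param rate_effect_hz signed rate offset during the stimulus (spikes/s).
#' @param lock_prob probability that a pulse evokes (Purkinje) or suppresses
#'   (CbN) a spike in its locking window.
#' @param lock_latency_ms latency from pulse onset to the locked event (ms).
#' @param lock_window_ms width of the locking window (ms).
#' @param transient_frac relative amplitude of the onset transient on top of
#'   the plateau offset.
#' @param tau_ms onset-transient decay time constant (ms).
#' @param rebound_hz rate offset for 200 ms after stimulus offset.
#' @param abolish_modulation if `TRUE`, stride-phase modulation is replaced
#'   by a flat rate during the stimulus (used to emulate disrupted
#'   modulation on slip trials).
#' @param deterministic if `TRUE` (trains), the stimulus epoch contains
#'   exactly one spike per pulse at the lock latency.
#' @param slip optional slip specification `list(category, magnitude,
#'   latency_ms)` attached to the trial.
#' @return an `opto_model` list.
#' @export
opto_model <- function(kind = c("step", "train"), intensity_mw = 1.7,
                       freq_hz = NA_real_, rate_effect_hz = 0,
                       lock_prob = 0, lock_latency_ms = 2.5,
                       lock_window_ms = 1, transient_frac = 0.5,
                       tau_ms = 100, rebound_hz = 0,
                       abolish_modulation = FALSE, deterministic = FALSE,
                       slip = NULL) {
  kind <- match.arg(kind)
  if (kind == "step" && is.finite(freq_hz))
    stop("step stimuli have no pulse frequency")
  if (kind == "train") {
    stopifnot(is.finite(freq_hz), freq_hz > 0)
    if (1000 / freq_hz <= 1) stop("pulse period must exceed the 1 ms pulse")
  }
  stopifnot(lock_prob >= 0, lock_prob <= 1)
  structure(list(kind = kind, intensity_mw = intensity_mw, freq_hz = freq_hz,
                 pulse_ms = 1, rate_effect_hz = rate_effect_hz,
                 lock_prob = lock_prob, lock_latency_ms = lock_latency_ms,
                 lock_window_ms = lock_window_ms,
                 transient_frac = transient_frac, tau_ms = tau_ms,
                 rebound_hz = rebound_hz,
                 abolish_modulation = abolish_modulation,
                 deterministic = deterministic, slip = slip),
            class = "opto_model")
}

# Truncated-normal stride durations (s), redrawn rather than clipped.
# Asymmetric bounds shift the truncated mean above the parent mean, so the
# parent mean is solved so that the truncated distribution's mean equals the
# configured stride_mean_ms exactly.
draw_stride_durations <- function(cfg, n) {
  lo <- cfg$stride_min_ms / 1000
  hi <- cfg$stride_max_ms / 1000
  target <- cfg$stride_mean_ms / 1000
  sd <- cfg$stride_sd_ms / 1000
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- if (sd <= 1e-9) target else
    stats::uniroot(function(m) trunc_mean(m) - target,
                   c(lo - 4 * sd, hi), tol = 1e-10)$root
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(2 * (n - length(out)) + 10, mu, sd)
    out <- c(out, d[d >= lo & d <= hi])
  }
  out[seq_len(n)]
}

#' Generate a sawtooth paw trace with ground truth
#'
#' Renders one piecewise-linear sawtooth per stride: a rising segment
#' (stance) occupying `stance_fraction` of the stride and a falling segment
#' (swing) for the remainder, spanning 1 AU, with additive Gaussian noise and
#' optional square-pulse tracking-loss artifacts. Stride durations are drawn
#' from a truncated normal. Injected slips edit a single stride each:
#' `prolonged` sets its duration to (1+m) times its predecessor's,
#' `incomplete` to (1-m) times, and `arrested` keeps the predecessor's
#' duration but scales both slopes by (1-m). Rest epochs are rendered as
#' position jitter under 10% of the stride amplitude.
#'
#' @param cfg a [session_config()].
#' @param slips list of `list(stride = k, category, magnitude)` specs;
#'   magnitudes must exceed 0.2 (smaller edits would sit below the slip
#'   criterion by construction) and strides must be distinct and >= 2.
#' @param stable list of `list(from, to, mean_ms)` stride-index windows of
#'   steady running: durations inside a window are `mean_ms` with 2%
#'   stride-to-stride jitter, emulating the locally stable gait of trials
#'   that survive screening (across the whole session durations still span
#'   the configured range).
#' @return `list(trace, truth)` where `truth` holds the stride table (plant,
#'   lift, next plant, slopes, slip labels), rendered rest epochs, artifact
#'   sample indices, and the generating parameters.
#' @export
gen_paw_trace <- function(cfg, slips = list(), stable = list()) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(cfg$seed)
  n <- cfg$n_strides
  dur <- draw_stride_durations(cfg, n)
  for (w in stable) {
    idx <- max(1, w$from):min(n, w$to)
    dur[idx] <- w$mean_ms / 1000 *
      (1 + stats::rnorm(length(idx), 0, 0.02))
  }
  amp <- rep(1, n)
  slip_cat <- rep(NA_character_, n)
  slip_mag <- rep(NA_real_, n)
  if (length(slips)) {
    ks <- vapply(slips, function(s) as.integer(s$stride), integer(1))
    if (anyDuplicated(ks)) stop("overlapping slip specs (same stride)")
    for (s in slips) {
      k <- as.integer(s$stride)
      m <- s$magnitude
      if (k < 2 || k > n) stop("slip stride index out of range")
      if (m <= 0.2)
        stop("slip magnitude must exceed 0.2 (sub-threshold by construction)")
      cat_ <- match.arg(s$category, c("prolonged", "incomplete", "arrested"))
      if (cat_ == "prolonged") dur[k] <- (1 + m) * dur[k - 1]
      else if (cat_ == "incomplete") dur[k] <- (1 - m) * dur[k - 1]
      else { dur[k] <- dur[k - 1]; amp[k] <- 1 - m }
      slip_cat[k] <- cat_
      slip_mag[k] <- m
    }
  }

  # place strides sequentially; insert configured rest epochs between strides
  rest <- cfg$rest_epochs
  rest_used <- rep(FALSE, length(rest))
  plant <- numeric(n)
  rest_out <- list()
  t_cur <- 0.4                       # lead-in so the first plant is interior
  for (i in seq_len(n)) {
    if (length(rest)) {
      for (j in seq_along(rest)) {
        if (!rest_used[j] && rest[[j]][1] <= t_cur) {
          rest_out[[length(rest_out) + 1]] <- c(t_cur, t_cur + rest[[j]][2])
          t_cur <- t_cur + rest[[j]][2]
          rest_used[j] <- TRUE
        }
      }
    }
    plant[i] <- t_cur
    t_cur <- t_cur + dur[i]
  }
  t_end <- t_cur + 0.5
  lift <- plant + cfg$stance_fraction * dur
  next_plant <- plant + dur

  fs <- cfg$paw_sample_hz
  tt <- seq(0, t_end, by = 1 / fs)
  x <- rep(0.5, length(tt))                      # mid-range when not striding
  # swing into the first plant and out of the last, so both are troughs
  lead <- tt >= plant[1] - 0.1 & tt < plant[1]
  x[lead] <- 0.5 * (plant[1] - tt[lead]) / 0.1
  tail_ <- tt >= next_plant[n] & tt < next_plant[n] + 0.1
  x[tail_] <- 0.5 * (tt[tail_] - next_plant[n]) / 0.1
  for (i in seq_len(n)) {
    sel <- tt >= plant[i] & tt < next_plant[i]
    ts <- tt[sel]
    up <- ts < lift[i]
    xi <- numeric(length(ts))
    xi[up] <- amp[i] * (ts[up] - plant[i]) / (lift[i] - plant[i])
    xi[!up] <- amp[i] * (next_plant[i] - ts[!up]) / (next_plant[i] - lift[i])
    x[sel] <- xi
  }
  if (length(rest_out)) {
    for (re in rest_out) {
      sel <- tt >= re[1] & tt < re[2]
      x[sel] <- 0.5 + stats::runif(sum(sel), -0.03, 0.03)
    }
  }
  if (cfg$noise_sd_au > 0)
    x <- x + stats::rnorm(length(x), 0, cfg$noise_sd_au)

  art_idx <- integer(0)
  if (cfg$artifact_rate_hz > 0) {
    n_art <- stats::rpois(1, cfg$artifact_rate_hz * t_end)
    if (n_art > 0) {
      starts <- sort(sample.int(length(tt) - 4, n_art))
      for (s0 in starts) {
        w <- sample(1:3, 1)
        idx <- s0:(s0 + w - 1)
        x[idx] <- x[idx] + 1          # full-scale square pulse
        art_idx <- c(art_idx, idx)
      }
      art_idx <- sort(unique(art_idx))
    }
  }

  truth <- list(
    strides = data.frame(
      plant_s = plant, lift_s = lift, next_plant_s = next_plant,
      duration_ms = dur * 1000,
      stance_slope = amp / (lift - plant),
      swing_slope = amp / (next_plant - lift),
      amplitude = amp, slip_category = slip_cat, slip_magnitude = slip_mag),
    rest = if (length(rest_out))
      data.frame(start_s = vapply(rest_out, `[`, 0, 1),
                 end_s = vapply(rest_out, `[`, 0, 2))
      else data.frame(start_s = numeric(0), end_s = numeric(0)),
    artifact_idx = art_idx,
    stance_fraction = cfg$stance_fraction,
    tuning_class = cfg$tuning_class, target_mi = cfg$target_mi)
  list(trace = paw_trace(x, sample_rate = fs), truth = truth)
}

#' Stride-phase tuning functions for the six modulation classes
#'
#' Builds a nonnegative periodic rate function over normalized stride phase
#' in `[0,1)` (phase 0 = plant, phase `stance_fraction` = lift). Classes I/II
#' are a single sinusoidal cycle peaking at the lift (in phase with paw
#' position) or half a cycle away (anti-phase); III/IV lead/lag by a quarter
#' cycle; V/VI carry two peaks/troughs at +/- a quarter stride from the lift.
#' The sinusoid amplitude is set analytically so that
#' (max-min)/(max+min) equals `target_mi` exactly.
#'
#' @param class_id one of `"I".."VI"`.
#' @param base_rate mean rate (spikes/s), > 0.
#' @param target_mi modulation index in (0,1).
#' @param stance_fraction phase of the lift.
#' @return a function `phase -> rate` (vectorized).
#' @export
gen_tuning <- function(class_id, base_rate, target_mi,
                       stance_fraction = 0.65) {
  class_id <- match.arg(class_id, c("I", "II", "III", "IV", "V", "VI"))
  stopifnot(base_rate > 0)
  if (target_mi >= 1 || target_mi <= 0)
    stop("target_mi must be in (0,1)")
  m <- target_mi
  r <- stance_fraction
  f <- switch(class_id,
    I   = function(p) base_rate * (1 + m * cos(2 * pi * (p - r))),
    II  = function(p) base_rate * (1 + m * cos(2 * pi * (p - r - 0.5))),
    III = function(p) base_rate * (1 + m * cos(2 * pi * (p - r + 0.25))),
    IV  = function(p) base_rate * (1 + m * cos(2 * pi * (p - r - 0.25))),
    V   = function(p) base_rate * (1 + m * cos(4 * pi * (p - r - 0.25))),
    VI  = function(p) base_rate * (1 - m * cos(4 * pi * (p - r - 0.25))))
  f
}

# Normalized stride phase at arbitrary times, from ground-truth boundaries.
# NA outside strides.
truth_phase <- function(truth, t) {
  st <- truth$strides
  r <- truth$stance_fraction
  i <- findInterval(t, st$plant_s)
  ph <- rep(NA_real_, length(t))
  ok <- i >= 1 & i <= nrow(st)
  ok[ok] <- t[ok] < st$next_plant_s[i[ok]]
  ii <- i[ok]; ti <- t[ok]
  up <- ti < st$lift_s[ii]
  p <- numeric(length(ti))
  p[up] <- r * (ti[up] - st$plant_s[ii[up]]) /
    (st$lift_s[ii[up]] - st$plant_s[ii[up]])
  p[!up] <- r + (1 - r) * (ti[!up] - st$lift_s[ii[!up]]) /
    (st$next_plant_s[ii[!up]] - st$lift_s[ii[!up]])
  ph[ok] <- p
  ph
}

# Session rate function on a fine grid: tuning(phase) during strides,
# rest_rate elsewhere, plus per-trial step offsets/flat epochs.
session_rate_grid <- function(truth, tuning, rest_rate, trials = list(),
                              t_end, dt = 5e-4) {
  tg <- seq(0, t_end, by = dt)
  ph <- truth_phase(truth, tg)
  rate <- ifelse(is.na(ph), rest_rate, tuning(ifelse(is.na(ph), 0, ph)))
  for (tr in trials) {
    om <- tr$opto
    on <- tg >= tr$onset_s & tg < tr$onset_s + 1
    if (om$abolish_modulation)
      rate[on] <- mean(rate[on])
    if (om$kind == "step" && om$rate_effect_hz != 0) {
      tloc <- tg[on] - tr$onset_s
      rate[on] <- rate[on] + om$rate_effect_hz *
        (1 + om$transient_frac * exp(-tloc / (om$tau_ms / 1000)))
    }
    if (om$rebound_hz != 0) {
      post <- tg >= tr$onset_s + 1 & tg < tr$onset_s + 1.2
      rate[post] <- rate[post] + om$rebound_hz
    }
  }
  neg <- rate < 0
  if (any(neg)) {
    warning("negative instantaneous rate clipped at 0")
    rate[neg] <- 0
  }
  list(t = tg, rate = rate)
}

# Inhomogeneous point process by time rescaling: unit-mean exponential
# (Poisson) or gamma(shape) intervals in integrated-rate time.
rescaled_spikes <- function(grid, process = c("poisson", "gamma"),
                            shape = 4) {
  process <- match.arg(process)
  dt <- grid$t[2] - grid$t[1]
  Lam <- cumsum(grid$rate) * dt
  total <- Lam[length(Lam)]
  if (total <= 0) return(numeric(0))
  n_guess <- ceiling(total + 6 * sqrt(total)) + 10
  isis <- if (process == "poisson") stats::rexp(n_guess)
          else stats::rgamma(n_guess, shape = shape, rate = shape)
  s <- cumsum(isis)
  while (s[length(s)] < total) {
    more <- if (process == "poisson") stats::rexp(n_guess)
            else stats::rgamma(n_guess, shape = shape, rate = shape)
    s <- c(s, s[length(s)] + cumsum(more))
  }
  s <- s[s <= total]
  stats::approx(c(0, Lam), c(grid$t[1], grid$t), xout = s,
                ties = "ordered")$y
}

#' Generate a spike train over a synthetic session
#'
#' Realizes spikes from an inhomogeneous renewal process (Poisson by default,
#' or gamma with `shape` > 1 for sub-Poisson regularity) whose rate follows
#' the stride-phase tuning during strides and the rest rate elsewhere.
#' Step stimuli add their rate offset with an onset transient; train stimuli
#' additionally evoke (Purkinje) or delete (CbN) pulse-locked spikes.
#'
#' @param tuning a rate function over phase, from [gen_tuning()].
#' @param truth generator ground truth from [gen_paw_trace()].
#' @param rest_rate firing rate outside strides (spikes/s).
#' @param trials list of `list(onset_s, opto)` with [opto_model()] entries;
#'   may be empty.
#' @param cell_type `"Purkinje"` (pulses add spikes) or `"CbN"` (pulses
#'   delete spikes).
#' @param seed integer seed.
#' @param process `"poisson"` or `"gamma"` interval statistics.
#' @param shape gamma shape (regularity) parameter; CV of intervals is
#'   approximately `1/sqrt(shape)`.
#' @param t_end recording end time (s); defaults to just past the last
#'   stride or trial.
#' @return a [spike_train()].
#' @export
gen_spike_train <- function(tuning, truth, rest_rate, trials = list(),
                            cell_type = c("Purkinje", "CbN"), seed = 1L,
                            process = c("poisson", "gamma"), shape = 4,
                            t_end = NULL) {
  cell_type <- match.arg(cell_type)
  process <- match.arg(process)
  set.seed(seed)
  if (is.null(t_end)) {
    t_end <- max(truth$strides$next_plant_s) + 0.5
    if (length(trials))
      t_end <- max(t_end, max(vapply(trials, `[[`, 0, "onset_s")) + 3)
  }
  grid <- session_rate_grid(truth, tuning, rest_rate, trials, t_end)
  sp <- rescaled_spikes(grid, process, shape)

  for (tr in trials) {
    om <- tr$opto
    if (om$kind != "train") next
    pulses <- tr$onset_s + (seq_len(round(om$freq_hz)) - 1) / om$freq_hz
    lat <- om$lock_latency_ms / 1000
    win <- om$lock_window_ms / 1000
    if (om$deterministic) {
      sp <- sp[sp < tr$onset_s | sp >= tr$onset_s + 1]
      sp <- sort(c(sp, pulses + lat))
    } else if (cell_type == "Purkinje" && om$lock_prob > 0) {
      hit <- stats::runif(length(pulses)) < om$lock_prob
      add <- pulses[hit] + lat +
        stats::runif(sum(hit), -win / 2, win / 2)
      sp <- sort(c(sp, add))
    } else if (cell_type == "CbN" && om$lock_prob > 0) {
      for (p in pulses) {
        in_win <- sp >= p + lat & sp < p + lat + win
        if (any(in_win)) {
          kill <- in_win & stats::runif(length(sp)) < om$lock_prob
          sp <- sp[!kill]
        }
      }
    }
  }
  sp <- sp[sp >= 0 & sp <= t_end]
  sp <- sp[!duplicated(sp)]
  spike_train(sp, span = c(0, t_end))
}

#' Generate local field potential sweeps
#'
#' Each of the `n_sweeps` sweeps is the superposition of a damped-oscillation
#' kernel at every pulse time, white noise, and a 60 Hz mains contaminant,
#' sampled at 10 kHz (matching the acquisition rate).
#'
#' @param pulse_times pulse (or step-onset) times in s.
#' @param duration_s sweep length (s).
#' @param kernel_freq_hz,kernel_tau_ms oscillation frequency and decay time
#'   constant of the kernel (defaults: 300 Hz, 10 ms, i.e. a ~50 ms event).
#' @param kernel_amp kernel amplitude (uV).
#' @param noise_sd white-noise SD (uV).
#' @param hum_amp amplitude of the 60 Hz contaminant (uV).
#' @param n_sweeps number of repetitions (10 by convention).
#' @param sample_rate_hz sampling rate.
#' @param seed integer seed.
#' @return numeric matrix (samples x sweeps) with attributes `sample_rate`
#'   and `time_s`.
#' @export
gen_lfp <- function(pulse_times, duration_s = 1, kernel_freq_hz = 300,
                    kernel_tau_ms = 10, kernel_amp = 20, noise_sd = 2,
                    hum_amp = 1, n_sweeps = 10, sample_rate_hz = 10000,
                    seed = 1L) {
  set.seed(seed)
  fs <- sample_rate_hz
  nt <- round(duration_s * fs)
  tt <- (seq_len(nt) - 1) / fs
  klen <- round(5 * kernel_tau_ms / 1000 * fs)
  kt <- (seq_len(klen) - 1) / fs
  kernel <- kernel_amp * exp(-kt / (kernel_tau_ms / 1000)) *
    sin(2 * pi * kernel_freq_hz * kt)
  if (length(pulse_times) > 1) {
    per <- min(diff(sort(pulse_times)))
    if (klen / fs >= per)
      warning("kernel duration exceeds the pulse period; responses overlap")
  }
  base <- numeric(nt)
  for (p in pulse_times) {
    i0 <- round(p * fs) + 1
    idx <- i0:min(nt, i0 + klen - 1)
    if (i0 > nt || i0 < 1) next
    base[idx] <- base[idx] + kernel[seq_along(idx)]
  }
  hum <- hum_amp * sin(2 * pi * 60 * tt)
  sweeps <- vapply(seq_len(n_sweeps), function(i)
    base + hum + stats::rnorm(nt, 0, noise_sd), numeric(nt))
  attr(sweeps, "sample_rate") <- fs
  attr(sweeps, "time_s") <- tt
  sweeps
}

#' Simulate a full recording session
#'
#' Builds a continuous paw trace, a labeled trial table, and a spike train
#' for one cell. Trials are spaced along the stride sequence with at least
#' 2 s of running context on each side; each slip trial injects its slip
#' into the stride that begins `slip_latency_ms` after stimulus onset, so
#' the ground-truth slip latency is known. On slip trials stride-phase
#' modulation is abolished during the stimulus; on non-slip trials the
#' tuning is preserved under the rate offset.
#'
#' @param cfg a [session_config()].
#' @param trial_plan data.frame with columns `kind`, `intensity_mw`,
#'   `freq_hz`, `rate_effect_hz`, `lock_prob`, `slip_category` (NA for
#'   non-slip), `slip_magnitude`, `slip_latency_ms`. May have zero rows.
#' @param process,shape interval statistics passed to [gen_spike_train()].
#' @return list with `trace`, `spikes`, `trials` ([stimulus_trials()]),
#'   `truth` (stride/rest/artifact ground truth plus a `trial_truth` table),
#'   and the tuning function.
#' @export
simulate_session <- function(cfg, trial_plan = NULL,
                             process = "poisson", shape = 4) {
  stopifnot(inherits(cfg, "session_config"))
  n_trials <- if (is.null(trial_plan)) 0L else nrow(trial_plan)
  mean_s <- cfg$stride_mean_ms / 1000
  per_trial <- ceiling(8 / mean_s)          # ~2s pre + 1s stim + 2s post + gap
  slips <- list()
  stable <- list()
  slip_stride <- integer(0)
  if (n_trials > 0) {
    first <- ceiling(2.5 / mean_s) + 4
    slip_stride <- first + (seq_len(n_trials) - 1) * per_trial
    need <- slip_stride[n_trials] + ceiling(2.5 / mean_s) + 4
    if (cfg$n_strides < need)
      cfg$n_strides <- as.integer(need)
    # steady-running window around each trial: local gait speed drawn from
    # the session distribution but bounded so edited strides stay in the
    # detectable 100-500 ms range
    set.seed(cfg$seed + 1000L)
    local_mean <- 210 + 110 * stats::runif(n_trials)
    for (j in seq_len(n_trials)) {
      stable[[j]] <- list(from = slip_stride[j] - 14,
                          to = slip_stride[j] + 16,
                          mean_ms = local_mean[j])
      if (!is.na(trial_plan$slip_category[j]))
        slips[[length(slips) + 1]] <- list(
          stride = slip_stride[j],
          category = trial_plan$slip_category[j],
          magnitude = trial_plan$slip_magnitude[j])
    }
  }
  pw <- gen_paw_trace(cfg, slips, stable)
  truth <- pw$truth

  run_rate <- cfg$base_rest_rate_hz + cfg$run_rate_offset_hz
  tuning <- gen_tuning(cfg$tuning_class, run_rate, cfg$target_mi,
                       cfg$stance_fraction)

  trials_list <- list()
  trial_truth <- NULL
  stim_tbl <- NULL
  if (n_trials > 0) {
    lat <- trial_plan$slip_latency_ms
    lat[is.na(lat)] <- 120
    onset <- truth$strides$plant_s[slip_stride] - lat / 1000
    oms <- lapply(seq_len(n_trials), function(j) {
      is_slip <- !is.na(trial_plan$slip_category[j])
      opto_model(kind = trial_plan$kind[j],
                 intensity_mw = trial_plan$intensity_mw[j],
                 freq_hz = if (trial_plan$kind[j] == "train")
                   trial_plan$freq_hz[j] else NA_real_,
                 rate_effect_hz = trial_plan$rate_effect_hz[j],
                 lock_prob = if (is.na(trial_plan$lock_prob[j])) 0
                   else trial_plan$lock_prob[j],
                 abolish_modulation = is_slip)
    })
    trials_list <- lapply(seq_len(n_trials), function(j)
      list(onset_s = onset[j], opto = oms[[j]]))
    stim_tbl <- stimulus_trials(seq_len(n_trials), trial_plan$kind, onset,
                                trial_plan$intensity_mw,
                                ifelse(trial_plan$kind == "train",
                                       trial_plan$freq_hz, NA_real_))
    trial_truth <- data.frame(
      trial_id = seq_len(n_trials), kind = trial_plan$kind,
      onset_s = onset, slip = !is.na(trial_plan$slip_category),
      category = trial_plan$slip_category,
      magnitude = trial_plan$slip_magnitude,
      latency_ms = ifelse(!is.na(trial_plan$slip_category), lat, NA_real_),
      slip_stride = slip_stride)
  }
  truth$trial_truth <- trial_truth

  spikes <- gen_spike_train(tuning, truth, cfg$base_rest_rate_hz,
                            trials_list, cell_type = cfg$cell_type,
                            seed = cfg$seed + 1L, process = process,
                            shape = shape)
  list(trace = pw$trace, spikes = spikes, trials = stim_tbl, truth = truth,
       tuning = tuning)
}

#' Write a simulated session bundle to disk
#'
#' Writes the paw trace, spikes and stimuli as CSV and the ground truth as
#' JSON under `dir`.
#'
#' @param session output of [simulate_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_paw_csv(session$trace, file.path(dir, "paw.csv"))
  write_spikes_csv(session$spikes, file.path(dir, "spikes.csv"))
  if (!is.null(session$trials))
    write_stimuli_csv(session$trials, file.path(dir, "stimuli.csv"))
  jsonlite::write_json(
    list(strides = session$truth$strides, rest = session$truth$rest,
         artifact_idx = session$truth$artifact_idx,
         stance_fraction = session$truth$stance_fraction,
         tuning_class = session$truth$tuning_class,
         target_mi = session$truth$target_mi,
         trial_truth = session$truth$trial_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
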