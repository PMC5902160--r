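#' Peri-stimulus time histogram for light steps
#'
#' Spike counts in `bin_ms` bins over the 1 s stimulus window, averaged
#' across trials and converted to spikes/s. The baseline is the mean rate
#' over the 1 s immediately preceding each stimulus, reported both per trial
#' and pooled across trials.
#'
#' @param spikes a [spike_train()].
#' @param trials a [stimulus_trials()] table of step trials.
#' @param bin_ms bin width in ms (default 50).
#' @return list of class `psth` with `edges_s` (relative to onset), `rate`
#'   (spikes/s per bin), `baseline` (pooled pre-stimulus rate),
#'   `trial_baseline` (per trial), `n_trials`, `kind = "step"`.
#' @export
step_psth <- function(spikes, trials, bin_ms = 50) {
  trials <- trials[trials$kind == "step", , drop = FALSE]
  stopifnot(nrow(trials) >= 1)
  w <- bin_ms / 1000
  edges <- seq(0, 1, by = w)
  counts <- matrix(0, nrow(trials), length(edges) - 1)
  base <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_s[i]
    rel <- spikes$times[spikes$times >= on & spikes$times < on + 1] - on
    counts[i, ] <- graphics::hist(rel, breaks = edges, plot = FALSE)$counts
    base[i] <- sum(spikes$times >= on - 1 & spikes$times < on)
  }
  structure(list(edges_s = edges, rate = colMeans(counts) / w,
                 baseline = mean(base), trial_baseline = base,
                 n_trials = nrow(trials), kind = "step"), class = "psth")
}

#' Pulse-locked PSTH for light trains
#'
#' Every spike during the stimulus is assigned to the most recent pulse
#' onset and its latency binned at 1 ms over one inter-pulse interval;
#' spike probability is spikes per pulse per bin. The pulse sequence is also
#' split into early/middle/late thirds (1-33, 34-67, 68-100 for 100 pulses;
#' the remainder goes to the late group for other counts). The baseline is
#' the mean spike probability per 1 ms over the 1 s pre-stimulus window.
#'
#' @param spikes a [spike_train()].
#' @param trials a [stimulus_trials()] table of train trials (all the same
#'   frequency).
#' @param bin_ms bin width (default 1 ms).
#' @return list of class `psth` with `edges_s` (latency bins), `prob` (whole
#'   train), `groups` (early/middle/late probabilities), `baseline`,
#'   `n_pulses`, `kind = "train"`.
#' @export
train_psth <- function(spikes, trials, bin_ms = 1) {
  trials <- trials[trials$kind == "train", , drop = FALSE]
  stopifnot(nrow(trials) >= 1)
  freq <- unique(trials$freq_hz)
  if (length(freq) != 1) stop("mix of train frequencies; analyze separately")
  ipi <- 1 / freq
  edges <- seq(0, ipi, by = bin_ms / 1000)
  if (edges[length(edges)] < ipi) edges <- c(edges, ipi)
  nb <- length(edges) - 1
  acc <- function() numeric(nb)
  whole <- acc(); early <- acc(); middle <- acc(); late <- acc()
  n_pulse_tot <- 0; n_e <- 0; n_m <- 0; n_l <- 0
  base <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    pulses <- pulse_onsets(tr)
    np <- length(pulses)
    i_e <- seq_len(ceiling(np / 3))
    i_m <- seq(max(i_e) + 1, max(i_e) + ceiling(np / 3))
    i_m <- i_m[i_m <= np]
    i_l <- setdiff(seq_len(np), c(i_e, i_m))
    sp <- spikes$times[spikes$times >= pulses[1] &
                         spikes$times < tr$onset_s + tr$duration_s]
    pi_ <- findInterval(sp, pulses)
    lat <- sp - pulses[pi_]
    bins <- findInterval(lat, edges, rightmost.closed = TRUE)
    bins[bins > nb] <- nb
    for (k in seq_along(sp)) {
      whole[bins[k]] <- whole[bins[k]] + 1
      if (pi_[k] %in% i_e) early[bins[k]] <- early[bins[k]] + 1
      else if (pi_[k] %in% i_m) middle[bins[k]] <- middle[bins[k]] + 1
      else late[bins[k]] <- late[bins[k]] + 1
    }
    n_pulse_tot <- n_pulse_tot + np
    n_e <- n_e + length(i_e); n_m <- n_m + length(i_m)
    n_l <- n_l + length(i_l)
    base[i] <- sum(spikes$times >= tr$onset_s - 1 &
                     spikes$times < tr$onset_s) / 1000
  }
  structure(list(edges_s = edges, prob = whole / n_pulse_tot,
                 groups = list(early = early / n_e, middle = middle / n_m,
                               late = late / n_l),
                 baseline = mean(base), n_pulses = n_pulse_tot,
                 freq_hz = freq, kind = "train"), class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  if (x$kind == "step")
    cat(sprintf("Step PSTH: %d trials, %d bins of %.0f ms, baseline %.1f spikes/s\n",
                x$n_trials, length(x$rate), diff(x$edges_s[1:2]) * 1000,
                x$baseline))
  else
    cat(sprintf("Train PSTH: %d pulses at %g Hz, peak probability %.3f (baseline %.4f per ms)\n",
                x$n_pulses, x$freq_hz, max(x$prob), x$baseline))
  invisible(x)
}

#' Rayleigh test of pulse locking
#'
#' Spike latencies from the most recent pulse are mapped to cycle phase
#' theta = 2 pi latency freq, and the Rayleigh statistic R (mean resultant
#' length) is tested against circular uniformity with the standard
#' approximation p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n)), where
#' Rn = n R.
#'
#' @param spikes a [spike_train()].
#' @param pulses pulse onset times (s).
#' @param freq_hz pulse rate (defines the cycle).
#' @param min_n minimum spikes during the stimulus (default 8).
#' @return list with `R`, `p`, `n`.
#' @export
rayleigh_locking <- function(spikes, pulses, freq_hz, min_n = 8) {
  sp <- spikes$times[spikes$times >= pulses[1] &
                       spikes$times < pulses[length(pulses)] + 1 / freq_hz]
  lat <- sp - pulses[findInterval(sp, pulses)]
  rayleigh_test(2 * pi * lat * freq_hz, min_n = min_n)
}

#' @rdname rayleigh_locking
#' @param theta angles in radians.
#' @export
rayleigh_test <- function(theta, min_n = 8) {
  n <- length(theta)
  if (n < 1) return(list(R = NA_real_, p = NA_real_, n = 0L))
  R <- Mod(mean(exp(1i * theta)))
  p <- NA_real_
  if (n >= min_n) {
    Rn <- n * R
    p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
    p <- min(max(p, 0), 1)
  }
  list(R = R, p = p, n = n)
}

#' Firing-rate change during a stimulus
#'
#' Spike counts over the 1 s pre-stimulus and 1 s stimulus windows, and
#' their difference.
#'
#' @param spikes a [spike_train()].
#' @param trial one row of a [stimulus_trials()] table.
#' @return list `pre_rate`, `stim_rate`, `delta` (spikes/s).
#' @export
stim_rate_change <- function(spikes, trial) {
  on <- trial$onset_s
  d <- trial$duration_s
  pre <- sum(spikes$times >= on - d & spikes$times < on) / d
  stim <- sum(spikes$times >= on & spikes$times < on + d) / d
  list(pre_rate = pre, stim_rate = stim, delta = stim - pre)
}

#' Post-stimulus rebound rate
#'
#' Rates over the 200 ms immediately before and after stimulus offset
#' (CbN cells typically rebound above the within-stimulus rate after light
#' steps end).
#'
#' @param spikes a [spike_train()].
#' @param trial one stimulus trial row.
#' @param window_ms comparison window (default 200).
#' @return list `pre_off`, `post_off` (spikes/s).
#' @export
rebound_rate <- function(spikes, trial, window_ms = 200) {
  off <- trial$onset_s + trial$duration_s
  w <- window_ms / 1000
  if (off - w < spikes$span[1] || off + w > spikes$span[2])
    stop("windows extend beyond the recorded span")
  list(pre_off = sum(spikes$times >= off - w & spikes$times < off) / w,
       post_off = sum(spikes$times >= off & spikes$times < off + w) / w)
}

#' Coefficient of variation of interspike intervals
#'
#' CV = SD(ISI)/mean(ISI) over intervals lying fully inside the window,
#' using the population (1/n) standard deviation. Undefined (NA) with fewer
#' than 2 intervals; such trials are excluded from CV statistics.
#'
#' @param spikes a [spike_train()].
#' @param window length-2 numeric `(t0, t1)`.
#' @return the CV, or NA.
#' @export
isi_cv <- function(spikes, window) {
  s <- spikes$times[spikes$times >= window[1] & spikes$times <= window[2]]
  if (length(s) < 3) return(NA_real_)
  isi <- diff(s)
  sd_pop <- sqrt(mean((isi - mean(isi))^2))
  sd_pop / mean(isi)
}
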