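#' Paw position trace
#'
#' Container for a uniformly sampled hind-paw x-position record. Position is
#' expressed in arbitrary units (AU) where 1 AU spans the full
#' forward-to-backward range of the paw, so a normal stride has amplitude
#' close to 1 AU. The nominal video rate is ~240 frames/s.
#'
#' @param x numeric vector of paw x-positions (AU).
#' @param sample_rate sampling rate in Hz (default 240).
#' @param tracked logical vector, one flag per sample; `FALSE` marks samples
#'   known to be tracking failures. Defaults to all `TRUE`.
#' @param t0 time (s) of the first sample.
#' @return an object of class `paw_trace`.
#' @export
paw_trace <- function(x, sample_rate = 240, tracked = NULL, t0 = 0) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 2, is.finite(sample_rate), sample_rate > 0)
  if (is.null(tracked)) tracked <- rep(TRUE, length(x))
  stopifnot(length(tracked) == length(x))
  structure(list(x = x, sample_rate = as.numeric(sample_rate),
                 tracked = as.logical(tracked), t0 = as.numeric(t0)),
            class = "paw_trace")
}

#' Sample times of a paw trace
#' @param trace a [paw_trace()].
#' @return numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "paw_trace"))
  trace$t0 + (seq_along(trace$x) - 1) / trace$sample_rate
}

#' @export
print.paw_trace <- function(x, ...) {
  dur <- length(x$x) / x$sample_rate
  cat(sprintf("Paw trace: %d samples at %g Hz (%.2f s), %d untracked\n",
              length(x$x), x$sample_rate, dur, sum(!x$tracked)))
  invisible(x)
}

#' Spike train
#'
#' Strictly increasing spike times over a recording span. Spike detection is
#' assumed to have been done upstream (times, not voltages, are the input).
#'
#' @param times numeric vector of spike times (s).
#' @param span length-2 numeric, recording span `(t0, t1)`; defaults to the
#'   range of `times`.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, span = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (is.null(span)) span <- range(times)
  span <- as.numeric(span)
  stopifnot(length(span) == 2, span[1] <= span[2])
  if (length(times) && (times[1] < span[1] || times[length(times)] > span[2]))
    stop("all spikes must lie within the span")
  structure(list(times = times, span = span), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- diff(x$span)
  cat(sprintf("Spike train: %d spikes over %.2f s (mean rate %.1f spikes/s)\n",
              length(x$times), dur,
              if (dur > 0) length(x$times) / dur else NA_real_))
  invisible(x)
}

#' Stimulus trial table
#'
#' One row per 1 s optogenetic stimulus epoch (light step or pulse train),
#' each with 2 s of pre- and post-stimulus context. For trains, 1 ms pulses
#' are delivered at `freq_hz` for the whole second, so the pulse count equals
#' the frequency.
#'
#' @param trial_id integer identifiers.
#' @param kind `"step"` or `"train"` per trial.
#' @param onset_s stimulus onset times (s).
#' @param intensity_mw light intensity (mW).
#' @param freq_hz pulse rate (Hz) for trains, `NA` for steps.
#' @param duration_s stimulus duration (s), 1 by convention.
#' @return a `data.frame` of class `stimulus_trials`.
#' @export
stimulus_trials <- function(trial_id, kind, onset_s, intensity_mw = NA_real_,
                            freq_hz = NA_real_, duration_s = 1) {
  kind <- match.arg(kind, c("step", "train"), several.ok = TRUE)
  n <- length(onset_s)
  df <- data.frame(trial_id = as.integer(trial_id),
                   kind = rep_len(kind, n),
                   onset_s = as.numeric(onset_s),
                   duration_s = rep_len(as.numeric(duration_s), n),
                   intensity_mw = rep_len(as.numeric(intensity_mw), n),
                   freq_hz = rep_len(as.numeric(freq_hz), n))
  bad <- df$kind == "train" & (!is.finite(df$freq_hz) | df$freq_hz <= 0)
  if (any(bad)) stop("train trials require a positive freq_hz")
  if (any(df$kind == "step" & is.finite(df$freq_hz)))
    stop("step trials must not carry a frequency")
  class(df) <- c("stimulus_trials", "data.frame")
  df
}

#' Pulse onset times of one train trial
#' @param trial one row of a [stimulus_trials()] table.
#' @return numeric vector of pulse onset times (s); empty for steps.
#' @export
pulse_onsets <- function(trial) {
  if (trial$kind != "train") return(numeric(0))
  n <- round(trial$freq_hz * trial$duration_s)
  trial$onset_s + (seq_len(n) - 1) / trial$freq_hz
}

# ---- plain-text IO -----------------------------------------------------

#' Read/write session files
#'
#' Flat CSV formats used by the pipeline: paw traces (`time_s, x_au,
#' tracked_flag`), spike times (`spike_time_s`), stimuli (`trial_id, kind,
#' onset_s, duration_s, intensity_mw, freq_hz`), and detected strides.
#'
#' @param path file path.
#' @name session_io
NULL

#' @rdname session_io
#' @param trace a [paw_trace()].
#' @export
write_paw_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace_times(trace), x_au = trace$x,
                              tracked_flag = as.integer(trace$tracked)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_paw_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- diff(df$time_s)
  paw_trace(df$x_au, sample_rate = 1 / stats::median(dt),
            tracked = df$tracked_flag != 0, t0 = df$time_s[1])
}

#' @rdname session_io
#' @param spikes a [spike_train()].
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(data.frame(spike_time_s = spikes$times), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @param span optional recording span for the spike train.
#' @export
read_spikes_csv <- function(path, span = NULL) {
  spike_train(utils::read.csv(path)$spike_time_s, span = span)
}

#' @rdname session_io
#' @param trials a [stimulus_trials()] table.
#' @export
write_stimuli_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_stimuli_csv <- function(path) {
  df <- utils::read.csv(path)
  stimulus_trials(df$trial_id, df$kind, df$onset_s, df$intensity_mw,
                  df$freq_hz, df$duration_s)
}
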