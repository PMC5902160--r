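#' Average and band-pass filter LFP sweeps
#'
#' Pointwise mean of the (usually 10) sweeps of one stimulation condition,
#' band-pass filtered 50 Hz - 1 kHz with a 4th-order Butterworth applied
#' forward and backward (zero phase).
#'
#' @param sweeps numeric matrix, samples x sweeps (as from [gen_lfp()]), or
#'   a single sweep vector.
#' @param sample_rate sampling rate (Hz); taken from the matrix attribute
#'   when present.
#' @param band band edges in Hz (default `c(50, 1000)`).
#' @param order filter order (default 4).
#' @return filtered mean trace (numeric vector) with attribute
#'   `sample_rate`.
#' @export
lfp_average_filter <- function(sweeps, sample_rate = NULL,
                               band = c(50, 1000), order = 4) {
  if (is.null(sample_rate)) sample_rate <- attr(sweeps, "sample_rate")
  stopifnot(!is.null(sample_rate))
  if (is.matrix(sweeps)) {
    if (ncol(sweeps) < 2) stop("need at least 2 sweeps")
    avg <- rowMeans(sweeps)
  } else avg <- as.numeric(sweeps)
  bf <- signal::butter(order, band / (sample_rate / 2), type = "pass")
  out <- signal::filtfilt(bf, avg)
  attr(out, "sample_rate") <- sample_rate
  out
}

#' Periodogram with 60 Hz blanking
#'
#' Single-window periodogram over the first 1 s of the trace (1 Hz
#' frequency resolution), one-sided, scaled so that the total power (before
#' blanking) equals the variance of the analyzed segment. Bins within
#' 60 +/- `blank_hz` Hz are replaced by linear interpolation between their
#' neighbors to blank residual mains noise.
#'
#' @param trace numeric vector (with a `sample_rate` attribute) or a vector
#'   plus explicit `sample_rate`.
#' @param sample_rate sampling rate (Hz).
#' @param blank blank the 60 Hz region? (default TRUE)
#' @param blank_hz half-width of the blanked region (default 2).
#' @return data.frame `freq_hz`, `power`, with attribute `power_raw`
#'   (pre-blanking).
#' @export
lfp_psd <- function(trace, sample_rate = NULL, blank = TRUE, blank_hz = 2) {
  if (is.null(sample_rate)) sample_rate <- attr(trace, "sample_rate")
  stopifnot(!is.null(sample_rate))
  n <- round(sample_rate)             # 1 s -> 1 Hz resolution
  if (length(trace) < n) stop("trace must cover at least 1 s")
  x <- as.numeric(trace[seq_len(n)])
  x <- x - mean(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  freq <- seq_len(half)               # 1..Nyquist Hz
  p <- Mod(X[freq + 1])^2 / n^2
  two_sided <- freq < n / 2           # double all but Nyquist (n even)
  p[two_sided] <- 2 * p[two_sided]
  raw <- p
  if (blank) {
    bl <- which(abs(freq - 60) <= blank_hz)
    if (length(bl)) {
      lo <- min(bl) - 1
      hi <- max(bl) + 1
      if (lo >= 1 && hi <= length(p))
        p[bl] <- stats::approx(c(freq[lo], freq[hi]), c(p[lo], p[hi]),
                               xout = freq[bl])$y
    }
  }
  out <- data.frame(freq_hz = freq, power = p)
  attr(out, "power_raw") <- raw
  out
}

#' Harmonic peaks of a stimulus-entrained LFP spectrum
#'
#' For every harmonic k * stim_freq up to 1 kHz, reports the maximal power
#' within +/- `tol_hz` of the harmonic and its prominence relative to the
#' median power in a +/- `surround_hz` surround (the +/- `tol_hz` core
#' excluded). Harmonics with prominence above `flag_at` are flagged as
#' entrainment peaks.
#'
#' @param psd data.frame from [lfp_psd()].
#' @param stim_freq stimulation frequency (Hz), inside the analysis band.
#' @param max_freq highest frequency considered (default 1000).
#' @param tol_hz peak search half-width (default 2).
#' @param surround_hz background half-width (default 10).
#' @param flag_at prominence threshold (default 3). A flagged harmonic must
#'   also rise at least an order of magnitude above the spectrum's global
#'   median, so local noise fluctuations in an otherwise empty band are not
#'   reported as entrainment.
#' @return data.frame `harmonic`, `freq_hz`, `power`, `prominence`,
#'   `flagged`.
#' @export
harmonic_peaks <- function(psd, stim_freq, max_freq = 1000, tol_hz = 2,
                           surround_hz = 10, flag_at = 3) {
  stopifnot(stim_freq >= min(psd$freq_hz), stim_freq <= max(psd$freq_hz))
  floor_power <- 10 * stats::median(psd$power)
  ks <- seq_len(floor(max_freq / stim_freq))
  rows <- lapply(ks, function(k) {
    f0 <- k * stim_freq
    core <- psd$freq_hz >= f0 - tol_hz & psd$freq_hz <= f0 + tol_hz
    ring <- psd$freq_hz >= f0 - surround_hz & psd$freq_hz <= f0 + surround_hz &
      !core
    if (!any(core) || !any(ring)) return(NULL)
    pk <- max(psd$power[core])
    bg <- stats::median(psd$power[ring])
    prom <- if (bg > 0) pk / bg else Inf
    data.frame(harmonic = k, freq_hz = f0, power = pk, prominence = prom,
               flagged = prom > flag_at && pk > floor_power)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
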