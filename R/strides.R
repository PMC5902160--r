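#' Remove square-pulse tracking artifacts from a paw trace
#'
#' Paw tracking occasionally loses the paw for a few frames, producing
#' instantaneous full-scale square transients in the record. Samples
#' belonging to such transients (rise and fall within at most `max_width`
#' samples, amplitude above `min_amp` AU relative to the surrounding trace)
#' are replaced by linear interpolation and their tracked flag is cleared.
#'
#' @param trace a [paw_trace()].
#' @param max_width maximum transient width in samples (default 5).
#' @param min_amp minimum transient amplitude in AU (default 0.5).
#' @return a cleaned [paw_trace()].
#' @export
clean_trace <- function(trace, max_width = 5, min_amp = 0.5) {
  stopifnot(inherits(trace, "paw_trace"))
  x <- trace$x
  n <- length(x)
  d <- diff(x)
  bad <- rep(FALSE, n)
  # a transient: a jump up (|step| > min_amp) followed within max_width
  # samples by a jump of comparable size in the opposite direction
  jumps <- which(abs(d) > min_amp)
  for (j in jumps) {
    if (bad[j + 1]) next
    lookahead <- jumps[jumps > j & jumps <= j + max_width]
    k <- lookahead[sign(d[lookahead]) == -sign(d[j])]
    if (length(k)) {
      k <- k[1]
      bad[(j + 1):k] <- TRUE
    }
  }
  if (any(bad)) {
    if (mean(bad) > 0.2)
      stop("more than 20% of samples flagged as artifacts; trace unusable")
    good <- which(!bad)
    x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
    trace$tracked[bad] <- FALSE
  }
  trace$x <- x
  trace
}

#' Smooth a paw trace with a centered sliding average
#'
#' The window is rounded to the nearest odd sample count (50 ms at 240 Hz
#' gives 13 samples). Edges use shrinking windows rather than zero padding,
#' which avoids manufacturing troughs at the ends of the record.
#'
#' @param trace a [paw_trace()].
#' @param window_ms filter duration in ms (default 50).
#' @return a smoothed [paw_trace()].
#' @export
smooth_trace <- function(trace, window_ms = 50) {
  stopifnot(inherits(trace, "paw_trace"))
  w <- window_ms / 1000 * trace$sample_rate
  if (w < 2) stop("window must cover at least 2 sample periods")
  w <- 2 * floor(w / 2) + 1               # nearest odd count (round half up)
  h <- (w - 1) / 2
  x <- trace$x
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  trace$x <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  trace
}

# Local maxima of x with at least the given topographic prominence and
# mutual separation (indices). Prominence of a peak: its height above the
# higher of the two minima separating it from the nearest higher terrain
# (or the trace end) on each side.
find_extrema <- function(x, prominence, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  mid <- 2:(n - 1)
  cand <- mid[x[mid] > x[mid - 1] & x[mid] >= x[mid + 1]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]
    j <- i - 1
    while (j >= 1 && x[j] < x[i]) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- x[i]
    j <- i + 1
    while (j <= n && x[j] < x[i]) { rmin <- min(rmin, x[j]); j <- j + 1 }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (length(keep) <= 1) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  sort(sel)
}

#' Detect strides as trough-to-trough sawtooth cycles
#'
#' The trace is smoothed internally (50 ms sliding average) and local
#' troughs and peaks are located with a prominence threshold and a minimum
#' trough separation; each extremum is then refined to the nearest vertex of
#' the unsmoothed input within half a smoothing window (the boxcar shifts
#' the vertices of an asymmetric sawtooth by a couple of samples). Every
#' trough-peak-trough triple with exactly one interior peak and a
#' plant-to-plant duration inside `duration_range_ms` becomes a stride;
#' stance slope is (peak - trough)/(lift - plant) and swing slope the
#' magnitude of the descending slope.
#'
#' @param trace a cleaned [paw_trace()] (see [clean_trace()]).
#' @param prominence minimum peak/trough prominence in AU (default 0.2).
#' @param min_sep_ms minimum separation between troughs in ms (default 100).
#' @param duration_range_ms accepted stride duration range (default
#'   `c(100, 500)`).
#' @param min_strides sessions with fewer accepted strides than this are
#'   flagged (attribute `sufficient` set to `FALSE`); trial-level operations
#'   remain possible.
#' @param smooth_window_ms smoothing window used for extrema finding.
#' @return a `stride_set`: data.frame with columns `plant_s`, `lift_s`,
#'   `next_plant_s`, `duration_ms`, `stance_slope`, `swing_slope`,
#'   `stance_fraction`, plus attributes `sufficient` and `sample_rate`.
#' @export
detect_strides <- function(trace, prominence = 0.2, min_sep_ms = 100,
                           duration_range_ms = c(100, 500),
                           min_strides = 30, smooth_window_ms = 50) {
  stopifnot(inherits(trace, "paw_trace"))
  sm <- smooth_trace(trace, smooth_window_ms)
  x <- trace$x
  fs <- trace$sample_rate
  tt <- trace_times(trace)
  min_sep <- max(1, round(min_sep_ms / 1000 * fs))
  h <- max(1, floor(smooth_window_ms / 1000 * fs / 2))
  refine <- function(idx, sign_) vapply(idx, function(i) {
    w <- max(1, i - h):min(length(x), i + h)
    w[which.max(sign_ * x[w])]
  }, integer(1))
  peaks <- find_extrema(sm$x, prominence, min_sep)
  troughs <- find_extrema(-sm$x, prominence, min_sep)
  empty <- data.frame(plant_s = numeric(0), lift_s = numeric(0),
                      next_plant_s = numeric(0), duration_ms = numeric(0),
                      stance_slope = numeric(0), swing_slope = numeric(0),
                      stance_fraction = numeric(0))
  if (length(peaks) < 1 || length(troughs) < 2) {
    out <- empty
  } else {
    peaks <- sort(unique(refine(peaks, 1)))
    troughs <- sort(unique(refine(troughs, -1)))
    rows <- list()
    for (i in seq_len(length(troughs) - 1)) {
      a <- troughs[i]; b <- troughs[i + 1]
      inner <- peaks[peaks > a & peaks < b]
      if (length(inner) != 1) next
      dur_ms <- (tt[b] - tt[a]) * 1000
      if (dur_ms < duration_range_ms[1] || dur_ms > duration_range_ms[2])
        next
      p <- inner
      st_sl <- (x[p] - x[a]) / (tt[p] - tt[a])
      sw_sl <- (x[p] - x[b]) / (tt[b] - tt[p])
      if (!is.finite(st_sl) || !is.finite(sw_sl) || st_sl <= 0) next
      rows[[length(rows) + 1]] <- data.frame(
        plant_s = tt[a], lift_s = tt[p], next_plant_s = tt[b],
        duration_ms = dur_ms, stance_slope = st_sl, swing_slope = abs(sw_sl),
        stance_fraction = (tt[p] - tt[a]) / (tt[b] - tt[a]))
    }
    out <- if (length(rows)) do.call(rbind, rows) else empty
  }
  attr(out, "sufficient") <- nrow(out) >= min_strides
  attr(out, "sample_rate") <- fs
  class(out) <- c("stride_set", "data.frame")
  out
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("Stride set: %d strides%s\n", nrow(x),
              if (isTRUE(attr(x, "sufficient"))) ""
              else " (insufficient for session-level statistics)"))
  if (nrow(x))
    cat(sprintf("  duration %.0f-%.0f ms (mean %.0f), median stance fraction %.2f\n",
                min(x$duration_ms), max(x$duration_ms), mean(x$duration_ms),
                stats::median(x$stance_fraction)))
  invisible(x)
}

#' Allocate stance and swing bins for a session
#'
#' The session's 10 normalized-stride bins are split between stance and
#' swing according to the median stance fraction: e.g. a 70% stance gives 7
#' bins before the lift and 3 after. Rounding is half-up, clamped so each
#' phase keeps at least one bin.
#'
#' @param strides a `stride_set` (or data.frame with `stance_fraction`).
#' @param n_bins total bin count (10 by convention).
#' @return integer vector `c(n_stance, n_swing)`.
#' @export
allocate_bins <- function(strides, n_bins = 10) {
  stopifnot(nrow(strides) >= 1)
  r <- stats::median(strides$stance_fraction)
  n_st <- floor(n_bins * r + 0.5)                 # half-up
  n_st <- min(max(n_st, 1L), n_bins - 1L)
  c(n_stance = as.integer(n_st), n_swing = as.integer(n_bins - n_st))
}

#' Bin edges of one normalized stride
#'
#' Divides the stance interval (plant to lift) into `n_stance` equal
#' sub-intervals and the swing (lift to next plant) into `n_swing`, so edge
#' `n_stance + 1` is exactly the lift. The edges tile the stride with no
#' gaps or overlaps.
#'
#' @param stride one stride row (`plant_s`, `lift_s`, `next_plant_s`).
#' @param n_stance,n_swing bin allocation from [allocate_bins()].
#' @return numeric vector of `n_stance + n_swing + 1` strictly increasing
#'   time edges.
#' @export
bin_edges <- function(stride, n_stance, n_swing) {
  c(seq(stride$plant_s, stride$lift_s, length.out = n_stance + 1),
    seq(stride$lift_s, stride$next_plant_s,
        length.out = n_swing + 1)[-1])
}

#' Detect rest epochs
#'
#' Rest is operationalized as maximal intervals of at least `min_dur_s`
#' where the rolling peak-to-peak amplitude of the paw trace (over
#' `window_ms`) stays below 10% of the median stride amplitude. Session-level
#' rest statistics require the total rest time to exceed 2 s.
#'
#' @param trace a [paw_trace()].
#' @param strides a `stride_set` used to define the stride amplitude.
#' @param frac amplitude criterion relative to stride amplitude (default
#'   0.1).
#' @param window_ms rolling window for peak-to-peak amplitude (default 200).
#' @param min_dur_s minimum epoch duration (default 0.5).
#' @return data.frame `start_s`, `end_s` (possibly empty) with attribute
#'   `total_s` and `sufficient` (total >= 2 s).
#' @export
detect_rest <- function(trace, strides, frac = 0.1, window_ms = 200,
                        min_dur_s = 0.5) {
  stopifnot(inherits(trace, "paw_trace"), nrow(strides) >= 1)
  x <- trace$x
  fs <- trace$sample_rate
  tt <- trace_times(trace)
  # stride amplitude: median of per-stride stance rise
  amp <- stats::median(strides$stance_slope *
                         (strides$lift_s - strides$plant_s))
  w <- max(2, round(window_ms / 1000 * fs))
  n <- length(x)
  # rolling peak-to-peak via running max/min
  ptp <- vapply(seq_len(n - w + 1), function(i) {
    xi <- x[i:(i + w - 1)]
    max(xi) - min(xi)
  }, numeric(1))
  quiet <- ptp < frac * amp           # quiet window starting at i
  # a sample is restful if some quiet window covers it
  cover <- rep(FALSE, n)
  runs <- rle(quiet)
  idx <- cumsum(c(1, runs$lengths))
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- idx[k]
    i1 <- idx[k + 1] - 1 + w - 1
    cover[i0:min(i1, n)] <- TRUE
  }
  runs2 <- rle(cover)
  idx2 <- cumsum(c(1, runs2$lengths))
  out <- list()
  for (k in seq_along(runs2$values)) {
    if (!runs2$values[k]) next
    i0 <- idx2[k]; i1 <- idx2[k + 1] - 1
    if ((i1 - i0 + 1) / fs >= min_dur_s)
      out[[length(out) + 1]] <- c(tt[i0], tt[i1])
  }
  df <- if (length(out))
    data.frame(start_s = vapply(out, `[`, 0, 1),
               end_s = vapply(out, `[`, 0, 2))
  else data.frame(start_s = numeric(0), end_s = numeric(0))
  total <- sum(df$end_s - df$start_s)
  attr(df, "total_s") <- total
  attr(df, "sufficient") <- total >= 2
  df
}

#' @rdname session_io
#' @param strides a `stride_set`.
#' @export
write_strides_csv <- function(strides, path) {
  utils::write.csv(as.data.frame(strides)[, c("plant_s", "lift_s",
                                              "next_plant_s", "duration_ms",
                                              "stance_slope", "swing_slope")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_strides_csv <- function(path) {
  df <- utils::read.csv(path)
  df$stance_fraction <- (df$lift_s - df$plant_s) /
    (df$next_plant_s - df$plant_s)
  attr(df, "sufficient") <- nrow(df) >= 30
  class(df) <- c("stride_set", "data.frame")
  df
}
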