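#' Instantaneous firing rate
#'
#' The IFR is the reciprocal of the interspike interval, held constant over
#' that interval: IFR(t) = 1/(s[i+1]-s[i]) for t in [s[i], s[i+1]). It is
#' undefined before the first and after the last spike.
#'
#' @param spikes a [spike_train()] with at least 2 spikes (fewer returns an
#'   empty rate function which downstream operations treat as missing).
#' @return an object of class `ifr`: a step function queryable with
#'   [ifr_at()] and integrable with [ifr_mean()].
#' @export
instantaneous_rate <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  s <- spikes$times
  if (length(s) < 2)
    return(structure(list(knots = numeric(0), rate = numeric(0)),
                     class = "ifr"))
  structure(list(knots = s, rate = 1 / diff(s)), class = "ifr")
}

#' @rdname instantaneous_rate
#' @param ifr an `ifr` object.
#' @param t times (s) at which to evaluate.
#' @return `ifr_at`: rates at `t` (NA outside the defined range).
#' @export
ifr_at <- function(ifr, t) {
  if (!length(ifr$knots)) return(rep(NA_real_, length(t)))
  i <- findInterval(t, ifr$knots)
  out <- rep(NA_real_, length(t))
  ok <- i >= 1 & i <= length(ifr$rate)
  out[ok] <- ifr$rate[i[ok]]
  out
}

#' @rdname instantaneous_rate
#' @param a,b interval bounds (s).
#' @return `ifr_mean`: the time-weighted mean IFR over `[a, b)`, i.e. the
#'   integral of the step function over its defined part of the interval
#'   divided by that part's duration; NA if the IFR is undefined throughout.
#' @export
ifr_mean <- function(ifr, a, b) {
  k <- ifr$knots
  if (!length(k) || b <= k[1] || a >= k[length(k)]) return(NA_real_)
  i0 <- max(1L, findInterval(a, k))
  i1 <- min(length(k) - 1L, findInterval(b, k, left.open = TRUE) + 1L)
  idx <- i0:i1
  lo <- pmax(k[idx], a)
  hi <- pmin(k[idx + 1L], b)
  w <- pmax(hi - lo, 0)
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  sum(w * ifr$rate[idx]) / sw
}

#' Stride-normalized binned tuning curve
#'
#' For every accepted stride, the mean IFR is computed inside each of the 10
#' stance/swing bins (time-weighted average of the piecewise-constant IFR),
#' then averaged across strides; the paw position receives the same binning
#' when a trace is supplied.
#'
#' @param spikes a [spike_train()].
#' @param strides a `stride_set` from [detect_strides()].
#' @param allocation optional `c(n_stance, n_swing)`; defaults to
#'   [allocate_bins()] of the stride set.
#' @param trace optional [paw_trace()] for per-bin mean paw position.
#' @param min_strides minimum strides required (30 by convention; relax for
#'   trial-level curves).
#' @param equal_bins if `TRUE`, ignore the stance/swing split and use 10
#'   equal-width bins per stride (reanalysis option).
#' @return an object of class `stride_tuning`: list with `rate` (10 mean
#'   rates), `paw` (10 mean positions or NULL), `n_strides`, `n_stance`,
#'   `stance_fraction`.
#' @export
binned_tuning <- function(spikes, strides, allocation = NULL, trace = NULL,
                          min_strides = 30, equal_bins = FALSE) {
  stopifnot(nrow(strides) >= 1)
  if (nrow(strides) < min_strides)
    stop(sprintf("need at least %d strides (got %d)", min_strides,
                 nrow(strides)))
  if (is.null(allocation)) allocation <- allocate_bins(strides)
  if (equal_bins) allocation <- c(5L, 5L)   # any split; edges overridden
  n_bins <- sum(allocation)
  ifr <- instantaneous_rate(spikes)
  tt <- if (!is.null(trace)) trace_times(trace)
  rate_mat <- matrix(NA_real_, nrow(strides), n_bins)
  paw_mat <- if (!is.null(trace)) matrix(NA_real_, nrow(strides), n_bins)
  for (i in seq_len(nrow(strides))) {
    st <- strides[i, ]
    e <- if (equal_bins)
      seq(st$plant_s, st$next_plant_s, length.out = n_bins + 1)
    else bin_edges(st, allocation[1], allocation[2])
    for (k in seq_len(n_bins)) {
      rate_mat[i, k] <- ifr_mean(ifr, e[k], e[k + 1])
      if (!is.null(trace)) {
        sel <- tt >= e[k] & tt < e[k + 1]
        if (any(sel)) paw_mat[i, k] <- mean(trace$x[sel])
      }
    }
  }
  rate <- colMeans(rate_mat, na.rm = TRUE)
  if (any(!is.finite(rate)))
    stop("some bins have no defined IFR in any stride")
  structure(list(rate = rate,
                 paw = if (!is.null(trace)) colMeans(paw_mat, na.rm = TRUE),
                 n_strides = nrow(strides),
                 n_stance = as.integer(allocation[1]),
                 stance_fraction = stats::median(strides$stance_fraction)),
            class = "stride_tuning")
}

#' @export
print.stride_tuning <- function(x, ...) {
  mi <- modulation_index(x)
  cat(sprintf(
    "Stride tuning: %d strides, %d stance + %d swing bins\n",
    x$n_strides, x$n_stance, length(x$rate) - x$n_stance))
  cat(sprintf("  rates %.1f-%.1f spikes/s, MI = %.3f\n",
              min(x$rate), max(x$rate), mi["MI"]))
  invisible(x)
}

#' @export
plot.stride_tuning <- function(x, ...) {
  centers <- (seq_along(x$rate) - 0.5) / length(x$rate)
  graphics::plot(centers, x$rate, type = "b", col = "red",
                 xlab = "normalized stride time", ylab = "rate (spikes/s)",
                 ...)
  graphics::abline(v = x$n_stance / length(x$rate), lty = 2)
  if (!is.null(x$paw)) {
    pr <- range(x$paw)
    scl <- (x$paw - pr[1]) / diff(pr) * diff(range(x$rate)) +
      min(x$rate)
    graphics::lines(centers, scl, col = "blue")
  }
  invisible(x)
}

#' Modulation index of a tuning curve
#'
#' MI = (FR_max - FR_min)/(FR_max + FR_min) over the 10-bin curve; St_MI and
#' Sw_MI apply the same formula to the stance and swing bins alone.
#'
#' @param tuning a `stride_tuning` (or a bare numeric vector of bin rates,
#'   in which case only `MI` is returned meaningfully and all bins are
#'   treated as stance).
#' @return named numeric `c(MI, St_MI, Sw_MI)`.
#' @export
modulation_index <- function(tuning) {
  if (is.numeric(tuning))
    tuning <- list(rate = tuning, n_stance = length(tuning))
  r <- tuning$rate
  mi1 <- function(v) {
    if (max(v) + min(v) <= 0) return(NA_real_)
    (max(v) - min(v)) / (max(v) + min(v))
  }
  st <- seq_len(tuning$n_stance)
  c(MI = mi1(r),
    St_MI = mi1(r[st]),
    Sw_MI = if (tuning$n_stance < length(r)) mi1(r[-st]) else NA_real_)
}

#' Rest and run firing-rate statistics
#'
#' Rest rate is the spike count divided by total rest time (requires > 2 s
#' of rest); run mean is computed over detected strides; run min/max are the
#' extrema of the 10-bin tuning curve. 20 ms-binned IFR samples are returned
#' for histogramming in both states.
#'
#' @param spikes a [spike_train()].
#' @param rest data.frame of rest epochs from [detect_rest()].
#' @param strides a `stride_set`.
#' @param tuning optional precomputed `stride_tuning` (computed if missing
#'   and enough strides exist).
#' @return list with `rest_mean`, `run_mean`, `run_min`, `run_max` (NA where
#'   preconditions fail) and `ifr_hist` (list of 20 ms-grid IFR samples for
#'   rest and run).
#' @export
rest_run_rates <- function(spikes, rest, strides, tuning = NULL) {
  ifr <- instantaneous_rate(spikes)
  total_rest <- sum(rest$end_s - rest$start_s)
  rest_mean <- NA_real_
  rest_ifr <- numeric(0)
  if (nrow(rest) && total_rest >= 2) {
    cnt <- sum(vapply(seq_len(nrow(rest)), function(i)
      sum(spikes$times >= rest$start_s[i] & spikes$times < rest$end_s[i]),
      numeric(1)))
    rest_mean <- cnt / total_rest
    rest_ifr <- unlist(lapply(seq_len(nrow(rest)), function(i)
      ifr_at(ifr, seq(rest$start_s[i], rest$end_s[i], by = 0.02))))
    rest_ifr <- rest_ifr[is.finite(rest_ifr)]
  }
  run_mean <- run_min <- run_max <- NA_real_
  run_ifr <- numeric(0)
  if (nrow(strides) >= 30) {
    dur <- sum(strides$next_plant_s - strides$plant_s)
    cnt <- sum(vapply(seq_len(nrow(strides)), function(i)
      sum(spikes$times >= strides$plant_s[i] &
            spikes$times < strides$next_plant_s[i]), numeric(1)))
    run_mean <- cnt / dur
    if (is.null(tuning)) tuning <- binned_tuning(spikes, strides)
    run_min <- min(tuning$rate)
    run_max <- max(tuning$rate)
    run_ifr <- unlist(lapply(seq_len(nrow(strides)), function(i)
      ifr_at(ifr, seq(strides$plant_s[i], strides$next_plant_s[i],
                      by = 0.02))))
    run_ifr <- run_ifr[is.finite(run_ifr)]
  }
  list(rest_mean = rest_mean, run_mean = run_mean, run_min = run_min,
       run_max = run_max,
       ifr_hist = list(rest = rest_ifr, run = run_ifr))
}

#' Stride phases of spikes
#'
#' Maps each spike falling inside a stride to its normalized stride phase in
#' `[0,1)`, with the lift at `n_stance/10` (bin-normalized time, so each of
#' the 10 bins has width 0.1).
#'
#' @param spikes a [spike_train()].
#' @param strides a `stride_set`.
#' @param allocation `c(n_stance, n_swing)`; defaults to [allocate_bins()].
#' @return numeric vector of phases.
#' @export
spike_phases <- function(spikes, strides, allocation = NULL) {
  if (is.null(allocation)) allocation <- allocate_bins(strides)
  r <- allocation[1] / sum(allocation)
  s <- spikes$times
  i <- findInterval(s, strides$plant_s)
  ok <- i >= 1 & i <= nrow(strides)
  ok[ok] <- s[ok] < strides$next_plant_s[i[ok]]
  ii <- i[ok]; ti <- s[ok]
  up <- ti < strides$lift_s[ii]
  ph <- numeric(length(ti))
  ph[up] <- r * (ti[up] - strides$plant_s[ii[up]]) /
    (strides$lift_s[ii[up]] - strides$plant_s[ii[up]])
  ph[!up] <- r + (1 - r) * (ti[!up] - strides$lift_s[ii[!up]]) /
    (strides$next_plant_s[ii[!up]] - strides$lift_s[ii[!up]])
  ph
}

#' Kuiper test of circular uniformity
#'
#' The Kuiper statistic V = D+ + D- against the uniform CDF on the circle;
#' unlike Kolmogorov-Smirnov it is invariant to the choice of phase origin.
#' The p-value uses the standard asymptotic series with the finite-n
#' correction factor (sqrt(n) + 0.155 + 0.24/sqrt(n)).
#'
#' @param phases values in `[0,1)` (fractions of the circle).
#' @param min_n minimum sample size for a defined p (default 8).
#' @return list with `V`, `p`, `n`.
#' @export
kuiper_test <- function(phases, min_n = 8) {
  n <- length(phases)
  u <- sort(phases %% 1)
  if (n < 2) return(list(V = NA_real_, p = NA_real_, n = n))
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  V <- dplus + dminus
  p <- NA_real_
  if (n >= min_n) {
    lam <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
    if (lam < 0.4) {
      p <- 1          # the asymptotic series is unusable here; true p ~ 1
    } else {
      j <- 1:120
      p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
      p <- min(max(p, 0), 1)
    }
  }
  list(V = V, p = p, n = n)
}

# true-phase centers of the 10 bins given the stance fraction
bin_center_phase <- function(n_stance, n_swing, stance_fraction) {
  r <- stance_fraction
  c(r * (seq_len(n_stance) - 0.5) / n_stance,
    r + (1 - r) * (seq_len(n_swing) - 0.5) / n_swing)
}

#' Classify the stride-modulation pattern of a tuning curve
#'
#' Quantitative operationalization of the six modulation classes: the first
#' two circular Fourier harmonics of the mean-subtracted 10-bin rate curve
#' are computed against stride phase. When the fundamental dominates (power
#' at least `dominance` times the second harmonic), the phase of the rate
#' fundamental relative to the paw-position fundamental assigns class I (in
#' phase, |dphi| < 45 deg), II (anti-phase), III (leading by a quarter
#' cycle) or IV (lagging). When the second harmonic dominates, the bins a
#' quarter stride before and after the lift are examined: class V if both
#' are local maxima, VI if both are local minima. Curves failing the Kuiper
#' test (p >= 0.05), with MI < `min_mi`, or matching no rule are class VII
#' (unclassified).
#'
#' @param tuning a `stride_tuning` with a paw curve, or with
#'   `stance_fraction` set (an ideal sawtooth is then used for the paw
#'   reference).
#' @param kuiper_p optional Kuiper p-value for the cell's spike phases.
#' @param dominance fundamental/second-harmonic power ratio required to
#'   treat the curve as single-peaked (default 2).
#' @param min_mi minimum MI for classification (default 0.05).
#' @return class label, one of `"I".."VII"`.
#' @export
classify_modulation <- function(tuning, kuiper_p = NULL, dominance = 2,
                                min_mi = 0.05) {
  stopifnot(inherits(tuning, "stride_tuning"))
  mi <- modulation_index(tuning)["MI"]
  if (!is.null(kuiper_p) && is.finite(kuiper_p) && kuiper_p >= 0.05)
    return("VII")
  if (!is.finite(mi) || mi < min_mi) return("VII")
  y <- tuning$rate - mean(tuning$rate)
  n_bins <- length(y)
  n_st <- tuning$n_stance
  n_sw <- n_bins - n_st
  r <- tuning$stance_fraction
  ph <- bin_center_phase(n_st, n_sw, r)
  harm <- function(v, k) sum(v * exp(-2i * pi * k * ph))
  c1 <- harm(y, 1)
  c2 <- harm(y, 2)
  paw <- tuning$paw
  if (is.null(paw)) {
    paw <- ifelse(ph < r, ph / r, (1 - ph) / (1 - r))  # ideal sawtooth
  }
  p1 <- harm(paw - mean(paw), 1)
  if (Mod(c1)^2 >= dominance * Mod(c2)^2) {
    # peak phase of a harmonic a*cos(2pi(phi - phi0)) is Arg of conj coeff
    dphi <- Arg(c1 / p1) * 180 / pi     # rate peak minus paw peak, degrees
    dphi <- ((-dphi) %% 360)            # positive = rate peak later (lag)
    dphi <- ifelse(dphi > 180, dphi - 360, dphi)
    if (abs(dphi) < 45) return("I")
    if (abs(abs(dphi) - 180) <= 45) return("II")
    if (dphi <= -45 && dphi >= -135) return("III")
    if (dphi >= 45 && dphi <= 135) return("IV")
    return("VII")
  }
  # two-peaked: compare the bins a quarter stride from the lift against the
  # bins at the lift and the plant. Quarter-phase bins higher -> two peaks
  # at +/- 90 deg from lift (V); lower -> two troughs (VI).
  nearest <- function(tp) which.min(abs(ph - tp))
  quarter <- vapply(c((r - 0.25) %% 1, (r + 0.25) %% 1), nearest,
                    integer(1))
  node <- vapply(c(0 + 0.02, r), nearest, integer(1))
  dq <- mean(tuning$rate[quarter]) - mean(tuning$rate[node])
  if (dq > 0) return("V")
  if (dq < 0) return("VI")
  "VII"
}

#' Population-average tuning curve
#'
#' Per-bin mean across cells; with `normalize = TRUE` each cell's curve is
#' first rescaled to `[0,1]` by its own min/max so strongly firing cells do
#' not dominate.
#'
#' @param tunings list of `stride_tuning` objects (>= 2).
#' @param normalize rescale each cell first?
#' @return numeric vector of 10 bin values.
#' @export
population_average <- function(tunings, normalize = FALSE) {
  stopifnot(length(tunings) >= 2)
  mat <- t(vapply(tunings, function(tn) {
    v <- tn$rate
    if (normalize) {
      rng <- range(v)
      if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
    }
    v
  }, numeric(length(tunings[[1]]$rate))))
  colMeans(mat)
}

#' Firing rate versus paw velocity regression
#'
#' Paw velocity is the first difference of the smoothed paw trace; IFR and
#' velocity are paired on a regular grid over the portion of the recording
#' where the IFR is defined, and related by ordinary least squares.
#'
#' @param spikes a [spike_train()].
#' @param trace a [paw_trace()] (smoothed internally, 50 ms window).
#' @param grid_s sampling grid spacing (s) for the paired samples.
#' @return list with `slope` (spikes/s per AU/s), Pearson `r`, and
#'   two-sided `p`.
#' @export
rate_velocity_regression <- function(spikes, trace, grid_s = 0.02) {
  sm <- smooth_trace(trace, 50)
  tt <- trace_times(sm)
  vel <- c(NA, diff(sm$x)) * sm$sample_rate
  ifr <- instantaneous_rate(spikes)
  if (!length(ifr$knots)) stop("need at least 2 spikes")
  tg <- seq(ifr$knots[1], ifr$knots[length(ifr$knots)], by = grid_s)
  ri <- ifr_at(ifr, tg)
  vi <- stats::approx(tt, vel, xout = tg)$y
  ok <- is.finite(ri) & is.finite(vi)
  if (sum(ok) < 10) stop("fewer than 10 paired samples")
  fit <- stats::lm(ri[ok] ~ vi[ok])
  ct <- stats::cor.test(vi[ok], ri[ok])
  list(slope = unname(stats::coef(fit)[2]), r = unname(ct$estimate),
       p = ct$p.value)
}
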