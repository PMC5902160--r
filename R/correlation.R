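#' Light-on versus no-light tuning correlation (non-slip trials)
#'
#' Bins firing rates over strides recorded without stimulation and over
#' strides during non-slip stimulation (same session bin allocation), and
#' returns the Pearson correlation of the two 10-bin curves. A high r means
#' the stride-phase modulation pattern survived the stimulus even if the
#' overall rate changed (r is invariant to positive affine transforms).
#'
#' @param spikes a [spike_train()].
#' @param strides_no_light,strides_light_on `stride_set`s (at least 5
#'   light-on strides).
#' @param allocation session bin allocation; defaults to
#'   [allocate_bins()] of the no-light strides.
#' @return Pearson r, or NA if either curve is constant.
#' @export
nonslip_tuning_correlation <- function(spikes, strides_no_light,
                                       strides_light_on,
                                       allocation = NULL) {
  if (nrow(strides_light_on) < 5)
    stop("need at least 5 light-on strides")
  if (is.null(allocation)) allocation <- allocate_bins(strides_no_light)
  a <- binned_tuning(spikes, strides_no_light, allocation)$rate
  b <- binned_tuning(spikes, strides_light_on, allocation,
                     min_strides = 5)$rate
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Template-stride correlation during a slip epoch
#'
#' The reference (template) stride's absolute bin durations are tiled
#' forward across the slip epoch, phase-anchored at the template stride's
#' own end (so a cell that keeps firing with its pre-stimulus phase
#' modulation through regular strides scores near 1, not at an arbitrary
#' phase offset); the firing rate in each tiled bin is averaged over
#' tilings and correlated (Pearson) against the template stride's own
#' 10-bin rates. Modulation loss drives r toward 0.
#'
#' @param spikes a [spike_train()].
#' @param trial one stimulus trial row.
#' @param reference the reference stride (from [reference_stride()]); also
#'   the tiling phase anchor.
#' @param allocation `c(n_stance, n_swing)` bin allocation.
#' @param from start of the slip epoch: `"onset"` (stimulus onset, default)
#'   or a numeric time in s (e.g. the slip onset when known).
#' @param single_tiling use only the first tiling of the template.
#' @return Pearson r, or NA when undefined.
#' @export
slip_template_correlation <- function(spikes, trial, reference, allocation,
                                      from = "onset",
                                      single_tiling = FALSE) {
  t0 <- if (identical(from, "onset")) trial$onset_s else as.numeric(from)
  t1 <- trial$onset_s + trial$duration_s
  e_ref <- bin_edges(reference, allocation[1], allocation[2])
  bin_dur <- diff(e_ref)
  d_ref <- sum(bin_dur)
  ifr <- instantaneous_rate(spikes)
  template <- vapply(seq_along(bin_dur), function(k)
    ifr_mean(ifr, e_ref[k], e_ref[k + 1]), numeric(1))
  anchor <- reference$next_plant_s
  ks <- 0:ceiling((t1 - anchor) / d_ref)
  starts <- anchor + ks * d_ref
  overlap <- pmin(starts + d_ref, t1) - pmax(starts, t0)
  keep <- starts[overlap >= 0.5 * d_ref]
  if (!length(keep)) keep <- starts[which.max(overlap)]
  if (single_tiling) keep <- keep[1]
  mat <- matrix(NA_real_, length(keep), length(bin_dur))
  for (j in seq_along(keep)) {
    edges <- keep[j] + cumsum(c(0, bin_dur))
    mat[j, ] <- vapply(seq_along(bin_dur), function(k)
      ifr_mean(ifr, edges[k], edges[k + 1]), numeric(1))
  }
  slip_rates <- colMeans(mat, na.rm = TRUE)
  ok <- is.finite(slip_rates) & is.finite(template)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(template[ok]) == 0 || stats::sd(slip_rates[ok]) == 0)
    return(NA_real_)
  stats::cor(template[ok], slip_rates[ok])
}

#' Polar alignment of a prolonged stride's tuning peak
#'
#' The prolonged stride is itself divided into 10 lift-aligned stance/swing
#' bins (same allocation as the session) and the angle of its peak firing
#' bin relative to the control tuning's peak bin is reported in 36-degree
#' increments, wrapped to (-180, 180]. Argmax ties take the lowest bin.
#'
#' @param spikes a [spike_train()].
#' @param prolonged_stride the prolonged stride row.
#' @param control_tuning the session's `stride_tuning` without light.
#' @param allocation bin allocation.
#' @return angle theta in degrees.
#' @export
prolonged_polar <- function(spikes, prolonged_stride, control_tuning,
                            allocation) {
  e <- bin_edges(prolonged_stride, allocation[1], allocation[2])
  ifr <- instantaneous_rate(spikes)
  rates <- vapply(seq_len(length(e) - 1), function(k)
    ifr_mean(ifr, e[k], e[k + 1]), numeric(1))
  if (all(!is.finite(rates))) return(NA_real_)
  # argmax with a tolerance so exact ties go to the lowest bin
  argmax1 <- function(v) which(v >= max(v, na.rm = TRUE) - 1e-9)[1]
  k_light <- argmax1(replace(rates, !is.finite(rates), -Inf))
  k_ctrl <- argmax1(control_tuning$rate)
  n <- length(control_tuning$rate)
  theta <- 360 / n * (k_light - k_ctrl)
  theta <- ((theta + 180) %% 360) - 180
  if (theta == -180) theta <- 180
  theta
}

#' Summarize a set of polar alignment angles
#'
#' Mean resultant vector and Rayleigh test over per-trial peak-alignment
#' angles, plus the fraction concentrated in the right half of the polar
#' plot (|theta| < 90 degrees, i.e. peak preserved within a quarter
#' stride).
#'
#' @param theta_deg angles in degrees.
#' @return list with `n`, `mean_deg`, `resultant`, `rayleigh_p`,
#'   `frac_right_half`.
#' @export
polar_summary <- function(theta_deg) {
  theta_deg <- theta_deg[is.finite(theta_deg)]
  th <- theta_deg * pi / 180
  z <- mean(exp(1i * th))
  rt <- rayleigh_test(th)
  list(n = length(th), mean_deg = Arg(z) * 180 / pi, resultant = Mod(z),
       rayleigh_p = rt$p, frac_right_half = mean(abs(theta_deg) < 90))
}

#' Fraction of correlations at or above a threshold
#'
#' @param r_values correlation coefficients (NAs are dropped as undefined).
#' @param threshold descriptive criterion (default 0.4).
#' @return list with `fraction`, `n_above`, `n`.
#' @export
threshold_summary <- function(r_values, threshold = 0.4) {
  r <- r_values[is.finite(r_values)]
  if (!length(r)) return(list(fraction = NA_real_, n_above = 0L, n = 0L))
  list(fraction = mean(r >= threshold), n_above = sum(r >= threshold),
       n = length(r))
}
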