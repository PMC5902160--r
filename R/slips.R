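#' Screen a stimulation trial
#'
#' Automated replacement for the manual pre-screening of trials: a trial is
#' `discarded_stop` when a rest epoch overlaps the 1 s stimulus window and
#' running does not resume before the end of the 2 s post-stimulus context;
#' `discarded_prestim_change` when the last pre-stimulus stride duration
#' deviates more than `prestim_change` (default 50%) from the median of the
#' three preceding strides; `unresolved` when no pre-stimulus stride exists;
#' otherwise `accepted`.
#'
#' @param trial one row of a [stimulus_trials()] table.
#' @param strides a `stride_set`.
#' @param rest rest epochs from [detect_rest()] (may be empty).
#' @param prestim_change relative deviation threshold (default 0.5).
#' @return one of `"accepted"`, `"discarded_stop"`,
#'   `"discarded_prestim_change"`, `"unresolved"`.
#' @export
screen_trial <- function(trial, strides, rest = NULL,
                         prestim_change = 0.5) {
  on <- trial$onset_s
  stim_end <- on + trial$duration_s
  trial_end <- stim_end + 2
  pre <- strides[strides$next_plant_s <= on + 0.03, , drop = FALSE]
  if (!nrow(pre)) return("unresolved")
  if (!is.null(rest) && nrow(rest)) {
    ov <- rest$start_s < stim_end & rest$end_s > on
    for (k in which(ov)) {
      resumed <- any(strides$plant_s > rest$end_s[k] &
                       strides$plant_s <= trial_end)
      if (!resumed) return("discarded_stop")
    }
  }
  if (nrow(pre) >= 4) {
    last_dur <- pre$duration_ms[nrow(pre)]
    med3 <- stats::median(pre$duration_ms[(nrow(pre) - 3):(nrow(pre) - 1)])
    if (abs(last_dur - med3) / med3 > prestim_change)
      return("discarded_prestim_change")
  }
  "accepted"
}

#' Reference (control) stride of a trial
#'
#' The last complete stride ending at or before stimulus onset, with a
#' configurable grace allowing an overlap of up to `grace_ms` into the
#' stimulus. Trials with no such stride are unresolved.
#'
#' @param trial one stimulus trial row.
#' @param strides a `stride_set`.
#' @param grace_ms tolerated overlap into the stimulus (default 30 ms).
#' @return the reference stride row, or `NULL` (unresolved).
#' @export
reference_stride <- function(trial, strides, grace_ms = 30) {
  cand <- strides[strides$next_plant_s <= trial$onset_s + grace_ms / 1000, ,
                  drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand[nrow(cand), , drop = FALSE]
}

#' Classify a trial as slip or non-slip
#'
#' Every detected stride overlapping the 1 s stimulus window is compared to
#' the reference stride. A duration at least 20% longer marks a `prolonged`
#' stride, at least 20% shorter an `incomplete` stride, and a stance or
#' swing slope at least 20% lower an `arrested` stride (boundaries
#' inclusive). Any hit classifies the trial as a slip; two or more distinct
#' hits (counting stance- and swing-slope reductions separately) mark it
#' `altered`. Non-slip trials also report the stimulus stride differing
#' most from the reference (maximal relative deviation across duration and
#' both slopes).
#'
#' @param trial one stimulus trial row.
#' @param strides a `stride_set`.
#' @param reference reference stride from [reference_stride()].
#' @param threshold relative-change criterion (default 0.2, the ">= 20%"
#'   rule).
#' @param unresolved_as_slip count trials with no evaluable stimulus stride
#'   as slips (the manual analysis did, accepting <= 7% error); default
#'   `FALSE` flags them unresolved.
#' @return a one-row data.frame (`trial_outcome`): `trial_id`, `screen`,
#'   `label`, logical `prolonged`/`incomplete`/`arrested`/`altered`,
#'   `offending_plant_s` (the first criterion-hitting stride, or the most
#'   deviant stride for non-slips), reference and worst-stride metrics.
#' @export
classify_trial <- function(trial, strides, reference, threshold = 0.2,
                           unresolved_as_slip = FALSE) {
  on <- trial$onset_s
  stim_end <- on + trial$duration_s
  out <- data.frame(trial_id = trial$trial_id, screen = "accepted",
                    label = NA_character_, prolonged = FALSE,
                    incomplete = FALSE, arrested = FALSE, altered = FALSE,
                    offending_plant_s = NA_real_, latency_ms = NA_real_,
                    ref_duration_ms = NA_real_, ref_stance_slope = NA_real_,
                    ref_swing_slope = NA_real_, worst_duration_ms = NA_real_,
                    worst_stance_slope = NA_real_,
                    worst_swing_slope = NA_real_)
  if (is.null(reference)) {
    out$screen <- "unresolved"
    if (unresolved_as_slip) out$label <- "slip"
    return(out)
  }
  out$ref_duration_ms <- reference$duration_ms
  out$ref_stance_slope <- reference$stance_slope
  out$ref_swing_slope <- reference$swing_slope
  stim <- strides[strides$plant_s < stim_end & strides$next_plant_s > on &
                    strides$plant_s >= reference$next_plant_s - 1e-9, ,
                  drop = FALSE]
  if (!nrow(stim)) {
    out$screen <- "unresolved"
    if (unresolved_as_slip) out$label <- "slip"
    return(out)
  }
  dur_ratio <- stim$duration_ms / reference$duration_ms
  st_ratio <- stim$stance_slope / reference$stance_slope
  sw_ratio <- stim$swing_slope / reference$swing_slope
  prolonged <- dur_ratio >= 1 + threshold
  incomplete <- dur_ratio <= 1 - threshold
  st_hit <- st_ratio <= 1 - threshold
  sw_hit <- sw_ratio <= 1 - threshold
  arrested <- st_hit | sw_hit
  hits_per_stride <- prolonged + incomplete + st_hit + sw_hit
  any_hit <- prolonged | incomplete | arrested
  out$prolonged <- any(prolonged)
  out$incomplete <- any(incomplete)
  out$arrested <- any(arrested)
  n_criteria <- sum(out$prolonged, out$incomplete, any(st_hit), any(sw_hit))
  out$altered <- n_criteria >= 2 || any(hits_per_stride >= 2)
  if (any(any_hit)) {
    out$label <- "slip"
    k <- which(any_hit)[1]
    out$offending_plant_s <- stim$plant_s[k]
    out$worst_duration_ms <- stim$duration_ms[k]
    out$worst_stance_slope <- stim$stance_slope[k]
    out$worst_swing_slope <- stim$swing_slope[k]
  } else {
    out$label <- "non_slip"
    dev <- pmax(abs(dur_ratio - 1), abs(st_ratio - 1), abs(sw_ratio - 1))
    k <- which.max(dev)
    out$offending_plant_s <- stim$plant_s[k]
    out$worst_duration_ms <- stim$duration_ms[k]
    out$worst_stance_slope <- stim$stance_slope[k]
    out$worst_swing_slope <- stim$swing_slope[k]
  }
  out
}

# reference sawtooth position at times t, anchored at `anchor` (a plant)
ref_template_pos <- function(t, anchor, reference) {
  d <- reference$duration_ms / 1000
  r <- (reference$lift_s - reference$plant_s) / d
  amp <- reference$stance_slope * (reference$lift_s - reference$plant_s)
  ph <- ((t - anchor) / d) %% 1
  ifelse(ph < r, amp * ph / r, amp * (1 - ph) / (1 - r))
}

#' Latency from stimulus onset to slip onset
#'
#' The offending stride's trajectory is compared to the reference-stride
#' sawtooth template anchored at the offending stride's plant. The slip
#' onset is the point where the trajectory last matched the template (within
#' 5% of stride amplitude) before its first excursion exceeding 20% of the
#' amplitude sustained for at least `sustain_ms`. Trials whose excursion
#' never reaches threshold have no unambiguous onset and return NA.
#'
#' @param trace the (cleaned, smoothed) [paw_trace()].
#' @param trial one stimulus trial row.
#' @param outcome the trial's `trial_outcome` row from [classify_trial()].
#' @param reference the reference stride.
#' @param threshold divergence criterion as a fraction of stride amplitude
#'   (default 0.2).
#' @param sustain_ms required duration of the excursion (default 25).
#' @return latency in ms from stimulus onset, or NA.
#' @export
slip_latency <- function(trace, trial, outcome, reference, threshold = 0.2,
                         sustain_ms = 25) {
  if (is.na(outcome$label) || outcome$label != "slip") return(NA_real_)
  if (is.na(outcome$offending_plant_s)) return(NA_real_)
  anchor <- outcome$offending_plant_s
  trace <- smooth_trace(trace, 25)      # keep noise from fragmenting runs
  tt <- trace_times(trace)
  stim_end <- trial$onset_s + trial$duration_s
  sel <- tt >= anchor & tt <= min(stim_end + 0.5, max(tt))
  if (!any(sel)) return(NA_real_)
  t_sel <- tt[sel]
  amp <- reference$stance_slope * (reference$lift_s - reference$plant_s)
  div <- abs(trace$x[sel] - ref_template_pos(t_sel, anchor, reference))
  over <- div > threshold * amp
  need <- max(1, round(sustain_ms / 1000 * trace$sample_rate))
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= need)
  if (!length(hit)) return(NA_real_)
  i_cross <- starts[hit[1]]
  # divergence onset: extrapolate the rising divergence ramp back to zero
  # through its half- and full-threshold crossings
  low <- which(div[seq_len(i_cross)] < 0.5 * threshold * amp)
  i_half <- if (length(low)) low[length(low)] else 1
  t_half <- t_sel[i_half]
  t_cross <- t_sel[i_cross]
  t_on <- max(t_half - (t_cross - t_half), t_sel[1])
  (t_on - trial$onset_s) * 1000
}

#' Slip probabilities by stimulus condition
#'
#' Counts and proportions of slip trials per condition, with a chi-square
#' test of independence across conditions and, for two conditions, Fisher's
#' exact test.
#'
#' @param outcomes data.frame of trial outcomes (needs `label`) merged with
#'   condition columns, e.g. from [run_pipeline()].
#' @param group_by name(s) of the condition column(s) (default `"kind"`).
#' @return list with `table` (`condition`, `n_slip`, `n_total`, `p_slip`),
#'   `chisq` (`statistic`, `df`, `p`) and `fisher_p` (2x2 only).
#' @export
slip_probability <- function(outcomes, group_by = "kind") {
  ok <- !is.na(outcomes$label)
  outcomes <- outcomes[ok, , drop = FALSE]
  key <- interaction(outcomes[group_by], drop = TRUE)
  if (any(table(key) == 0)) warning("empty condition omitted")
  n_slip <- tapply(outcomes$label == "slip", key, sum)
  n_tot <- tapply(outcomes$label == "slip", key, length)
  tab <- data.frame(condition = names(n_slip),
                    n_slip = as.integer(n_slip),
                    n_total = as.integer(n_tot),
                    p_slip = as.numeric(n_slip) / as.numeric(n_tot))
  chisq <- fisher_p <- NULL
  if (nrow(tab) >= 2 && all(tab$n_total > 0)) {
    m <- cbind(tab$n_slip, tab$n_total - tab$n_slip)
    ct <- suppressWarnings(stats::chisq.test(m))
    chisq <- list(statistic = unname(ct$statistic),
                  df = unname(ct$parameter), p = ct$p.value)
    if (nrow(tab) == 2)
      fisher_p <- stats::fisher.test(m)$p.value
  }
  list(table = tab, chisq = chisq, fisher_p = fisher_p)
}

#' Rate-matched step/train trial pairs
#'
#' All (step, train) trial pairs from the same cell whose mean
#' stimulus-window firing rates differ by at most `match_hz` and are both at
#' least `floor_hz` (pairs below the floor always produce slips and are
#' excluded). A trial may appear in multiple pairs.
#'
#' @param step_trials,train_trials data.frames with columns `cell`,
#'   `trial_id`, `rate` (stimulus-window spikes/s) and `slip` (logical).
#' @param match_hz rate-matching tolerance (default 10 spikes/s).
#' @param floor_hz minimum rate (default 10 spikes/s).
#' @return data.frame of pairs: `cell`, `step_id`, `train_id`, `step_rate`,
#'   `train_rate`, `step_slip`, `train_slip`.
#' @export
rate_match_pairs <- function(step_trials, train_trials, match_hz = 10,
                             floor_hz = 10) {
  out <- list()
  for (cell in intersect(unique(step_trials$cell),
                         unique(train_trials$cell))) {
    s <- step_trials[step_trials$cell == cell, , drop = FALSE]
    tr <- train_trials[train_trials$cell == cell, , drop = FALSE]
    for (i in seq_len(nrow(s))) for (j in seq_len(nrow(tr))) {
      if (s$rate[i] < floor_hz || tr$rate[j] < floor_hz) next
      if (abs(s$rate[i] - tr$rate[j]) > match_hz) next
      out[[length(out) + 1]] <- data.frame(
        cell = cell, step_id = s$trial_id[i], train_id = tr$trial_id[j],
        step_rate = s$rate[i], train_rate = tr$rate[j],
        step_slip = s$slip[i], train_slip = tr$slip[j])
    }
  }
  if (!length(out))
    return(data.frame(cell = character(0), step_id = integer(0),
                      train_id = integer(0), step_rate = numeric(0),
                      train_rate = numeric(0), step_slip = logical(0),
                      train_slip = logical(0)))
  do.call(rbind, out)
}

#' McNemar test for paired slip outcomes
#'
#' Compares slip probability between paired step and train trials from the
#' discordant pairs: b = step-only slips, c = train-only slips. Uses the
#' continuity-uncorrected chi-square (b-c)^2/(b+c) with its asymptotic
#' p-value when b + c >= 25, and the exact two-tailed binomial probability
#' otherwise. With no discordant pairs, p = 1 by convention.
#'
#' @param pairs data.frame from [rate_match_pairs()], or NULL if `b`/`c`
#'   are given directly.
#' @param b,c discordant-pair counts (step-only and train-only slips).
#' @return list with `b`, `c`, `statistic` (chi-square, NA in the exact
#'   regime), `p`, `method`, per-arm slip probabilities `p_step`/`p_train`,
#'   and discordant fractions `frac_step_only`/`frac_train_only`.
#' @export
mcnemar_slip_test <- function(pairs = NULL, b = NULL, c = NULL) {
  n_pairs <- NA_integer_
  p_step <- p_train <- NA_real_
  if (!is.null(pairs)) {
    b <- sum(pairs$step_slip & !pairs$train_slip)
    c <- sum(!pairs$step_slip & pairs$train_slip)
    n_pairs <- nrow(pairs)
    p_step <- mean(pairs$step_slip)
    p_train <- mean(pairs$train_slip)
  }
  stopifnot(!is.null(b), !is.null(c))
  if (b + c == 0)
    return(list(b = b, c = c, statistic = NA_real_, p = 1,
                method = "degenerate", n_pairs = n_pairs,
                p_step = p_step, p_train = p_train,
                frac_step_only = 0, frac_train_only = 0))
  if (b + c >= 25) {
    stat <- (b - c)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square (uncorrected)"
  } else {
    stat <- NA_real_
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
    method <- "exact binomial"
  }
  list(b = b, c = c, statistic = stat, p = p, method = method,
       n_pairs = n_pairs, p_step = p_step, p_train = p_train,
       frac_step_only = if (is.na(n_pairs)) NA_real_ else b / n_pairs,
       frac_train_only = if (is.na(n_pairs)) NA_real_ else c / n_pairs)
}
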