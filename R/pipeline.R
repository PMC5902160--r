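#' Run the full analysis pipeline on one session
#'
#' Executes every stage in order on a single cell's session: trace cleaning
#' and smoothing, stride detection and bin allocation, rest detection,
#' stride-phase tuning with modulation index, Kuiper test and class
#' assignment, per-trial optogenetic responses (rate changes, screening,
#' slip classification and latency), tuning-preservation correlations, and
#' the per-kind slip-probability comparison. Intermediate tables and a
#' summary JSON are written when `out_dir` is given; the run is
#' deterministic given the seed.
#'
#' @param cfg a [session_config()] (simulated input), or a list with
#'   elements `paw`, `spikes`, `stimuli` naming CSV files.
#' @param trial_plan trial plan for [simulate_session()] (simulated input
#'   only).
#' @param out_dir optional output directory.
#' @param seed optional integer; overrides `cfg$seed` for simulated input.
#' @return a list with elements `strides`, `allocation`, `rest`, `tuning`,
#'   `mi`, `kuiper`, `class_id`, `rates`, `outcomes`, `slip_prob`,
#'   `correlations`, and (simulated input) `truth`.
#' @export
run_pipeline <- function(cfg, trial_plan = NULL, out_dir = NULL,
                         seed = NULL) {
  simulated <- inherits(cfg, "session_config")
  if (simulated) {
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    ses <- simulate_session(cfg, trial_plan)
    trace <- ses$trace
    spikes <- ses$spikes
    trials <- ses$trials
    truth <- ses$truth
  } else {
    trace <- read_paw_csv(cfg$paw)
    spikes <- read_spikes_csv(cfg$spikes)
    trials <- if (!is.null(cfg$stimuli)) read_stimuli_csv(cfg$stimuli)
    truth <- NULL
  }

  trace <- clean_trace(trace)
  strides <- detect_strides(trace)
  if (!nrow(strides)) stop("no strides detected")
  allocation <- allocate_bins(strides)
  rest <- detect_rest(trace, strides)

  stim_overlap <- function(st) {
    if (is.null(trials) || !nrow(trials)) return(rep(FALSE, nrow(st)))
    hit <- rep(FALSE, nrow(st))
    for (i in seq_len(nrow(trials)))
      hit <- hit | (st$plant_s < trials$onset_s[i] + trials$duration_s[i] &
                      st$next_plant_s > trials$onset_s[i])
    hit
  }
  no_light <- strides[!stim_overlap(strides), , drop = FALSE]
  class(no_light) <- class(strides)

  tuning <- binned_tuning(spikes, no_light, allocation, trace = trace)
  mi <- modulation_index(tuning)
  ku <- kuiper_test(spike_phases(spikes, no_light, allocation))
  class_id <- classify_modulation(tuning, kuiper_p = ku$p)
  rates <- rest_run_rates(spikes, rest, no_light, tuning = tuning)

  outcomes <- NULL
  slip_prob <- NULL
  correlations <- NULL
  if (!is.null(trials) && nrow(trials)) {
    rows <- list()
    r_nonslip <- c()
    r_slip <- c()
    theta <- c()
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      scr <- screen_trial(tr, strides, rest)
      ref <- reference_stride(tr, strides)
      out <- classify_trial(tr, strides, ref)
      out$screen <- scr
      if (scr != "accepted") out$label <- NA_character_
      rc <- stim_rate_change(spikes, tr)
      out$pre_rate <- rc$pre_rate
      out$stim_rate <- rc$stim_rate
      out$delta <- rc$delta
      out$cv <- isi_cv(spikes, c(tr$onset_s, tr$onset_s + tr$duration_s))
      if (!is.na(out$label) && out$label == "slip" && !is.null(ref)) {
        out$latency_ms <- slip_latency(trace, tr, out, ref)
        r_slip <- c(r_slip,
                    slip_template_correlation(spikes, tr, ref, allocation))
        if (out$prolonged) {
          ps <- strides[strides$plant_s == out$offending_plant_s, ,
                        drop = FALSE]
          if (nrow(ps) == 1)
            theta <- c(theta,
                       prolonged_polar(spikes, ps[1, ], tuning, allocation))
        }
      }
      rows[[i]] <- out
    }
    outcomes <- do.call(rbind, rows)
    # cell-level light-on vs no-light tuning, pooling strides lying fully
    # inside the stimulus window of accepted non-slip trials
    ns_idx <- which(!is.na(outcomes$label) & outcomes$label == "non_slip")
    if (length(ns_idx)) {
      on_str <- do.call(rbind, lapply(ns_idx, function(i)
        strides[strides$plant_s >= trials$onset_s[i] &
                  strides$next_plant_s <=
                    trials$onset_s[i] + trials$duration_s[i], ,
                drop = FALSE]))
      class(on_str) <- class(strides)
      if (nrow(on_str) >= 5)
        r_nonslip <- nonslip_tuning_correlation(spikes, no_light, on_str,
                                                allocation)
    }
    outcomes <- cbind(outcomes,
                      kind = trials$kind,
                      intensity_mw = trials$intensity_mw,
                      freq_hz = trials$freq_hz)
    if (any(!is.na(outcomes$label)))
      slip_prob <- slip_probability(outcomes, group_by = "kind")
    correlations <- list(
      nonslip_r = r_nonslip, slip_r = r_slip,
      nonslip_frac04 = threshold_summary(r_nonslip)$fraction,
      slip_frac04 = threshold_summary(r_slip)$fraction,
      polar = if (length(theta)) polar_summary(theta))
  }

  res <- list(strides = strides, allocation = allocation, rest = rest,
              tuning = tuning, mi = mi, kuiper = ku, class_id = class_id,
              rates = rates, outcomes = outcomes, slip_prob = slip_prob,
              correlations = correlations, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_strides_csv(strides, file.path(out_dir, "strides.csv"))
    utils::write.csv(
      data.frame(bin = seq_along(tuning$rate), mean_rate_hz = tuning$rate,
                 mean_paw_au = if (is.null(tuning$paw)) NA else tuning$paw),
      file.path(out_dir, "tuning.csv"), row.names = FALSE)
    if (!is.null(outcomes))
      utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                       row.names = FALSE)
    summary_json <- list(
      n_strides = nrow(strides),
      allocation = as.list(allocation),
      mi = as.list(mi), kuiper_p = ku$p, class = class_id,
      rest_mean = rates$rest_mean, run_mean = rates$run_mean,
      run_min = rates$run_min, run_max = rates$run_max,
      slip_prob = if (!is.null(slip_prob)) slip_prob$table,
      nonslip_frac04 = correlations$nonslip_frac04,
      slip_frac04 = correlations$slip_frac04)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}
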