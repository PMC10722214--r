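# Experiment protocols: substrate assembly, tissue pre-pacing, SR-load
# reset, focal-excitation trials and P(TA) estimation, rapid-pacing
# re-entry induction, sinus-rhythm interruption, activation maps and
# conduction-velocity measurement.

#' Assemble a tissue substrate
#'
#' Bundles an orientation field, an optional patchy-fibrosis map and the
#' resulting connection map (with fibrosis-specific connection removal
#' applied) into one object consumed by the protocol drivers.  Uses R's RNG
#' for the random field types and the connection removal; seed the generator
#' for reproducible substrates.
#'
#' @param nx,ny grid dimensions.
#' @param orientation orientation field type (see [make_orientation()]) or a
#'   ready-made `orientation_field`.
#' @param fibrosis `NULL` for none, a `fibrosis_map`, or a list with
#'   elements `patch_seed` and `area_fraction` passed to [make_fibrosis()].
#' @param g_a,anisotropy_ratio,dx coupling parameters (see
#'   [build_connection_map()]).
#' @param p_transverse,p_longitudinal removal fractions inside patches.
#' @return a `substrate` list with `orient`, `fib`, `cmap`, and geometry.
#' @export
make_substrate <- function(nx, ny, orientation = "OY", fibrosis = NULL,
                           g_a = 1.28, anisotropy_ratio = 7, dx = 0.3125,
                           p_transverse = 0.8, p_longitudinal = 0.2) {
  orient <- if (inherits(orientation, "orientation_field")) orientation
            else make_orientation(orientation, nx, ny)
  cmap <- build_connection_map(orient, g_a, anisotropy_ratio, dx)
  fib <- NULL
  if (!is.null(fibrosis)) {
    fib <- if (inherits(fibrosis, "fibrosis_map")) fibrosis
           else make_fibrosis(nx, ny, fibrosis$patch_seed, fibrosis$area_fraction)
    cmap <- apply_fibrosis_removal(cmap, fib, p_transverse, p_longitudinal)
  }
  structure(list(orient = orient, fib = fib, cmap = cmap, nx = nx, ny = ny,
                 dx = dx),
            class = "substrate")
}

#' Pre-pace a tissue model
#'
#' Paces the tissue for a number of beats at a fixed cycle length, starting
#' from the supplied state (typically a single-cell steady state broadcast
#' over the grid), and returns the end-diastolic tissue state.  Issues a
#' warning naming the beat index if fewer than 90% of nodes activate on any
#' beat (conduction failure).
#'
#' @param state a `tissue_state`.
#' @param substrate a [make_substrate()] object.
#' @param params a [cell_params()] object.
#' @param cycle_length pacing cycle length (ms).
#' @param n_beats number of beats (0 returns the input unchanged).
#' @param stimulus_region,radius stimulus site passed to [apply_stimulus()].
#' @param dt time step (ms).
#' @param checkpoint optional file path; the returned state is serialised
#'   there with [saveRDS()].
#' @return the post-pacing `tissue_state`.
#' @export
pre_pace_tissue <- function(state, substrate, params, cycle_length = 400,
                            n_beats = 5, stimulus_region = "centre",
                            radius = 5, dt = 0.01, checkpoint = NULL) {
  stopifnot(inherits(state, "tissue_state"), inherits(substrate, "substrate"))
  if (n_beats == 0) return(state)
  n <- state$nx * state$ny
  for (b in seq_len(n_beats)) {
    stim <- apply_stimulus(stimulus_region, state$nx, state$ny,
                           times = state$t, radius = radius)
    res <- run_tissue(state, substrate$cmap, params, duration = cycle_length,
                      dt = dt, stimulus = stim, trace_dt = 0)
    if (length(unique(res$events$node)) < 0.9 * n)
      warning("conduction failure on pre-pacing beat ", b, ": ",
              length(unique(res$events$node)), " of ", n, " nodes activated")
    state <- res$state
  }
  if (!is.null(checkpoint)) saveRDS(state, checkpoint)
  state
}

#' Reset the SR calcium load everywhere
#'
#' Sets every node's SR calcium to an exact value, leaving all other state
#' variables untouched.  Used to control for the load before spontaneous
#' release is enabled, so that outcomes can be attributed to the release
#' waveform parameters rather than to load heterogeneity.
#'
#' @param state a `tissue_state`.
#' @param value SR calcium load (mM, positive).
#' @return the modified `tissue_state`.
#' @export
reset_sr_load <- function(state, value = 1.0) {
  stopifnot(inherits(state, "tissue_state"))
  if (!is.finite(value) || value <= 0) stop("SR load value must be positive")
  state$matrix[, "CaSR"] <- value
  state
}

#' Run one focal-excitation trial
#'
#' The trial protocol: sample per-node SRF waveforms (timing relative to the
#' stimulus), apply one stimulus, integrate until the SR has refilled from
#' the paced beat (detected as the post-repolarisation maximum of the mean
#' SR load, monitored in 10 ms chunks, with a deadline just before the
#' earliest sampled initiation time), set the SR load to exactly
#' `reset_value`, then let the model evolve with the release waveforms
#' enabled and classify the outcome with [detect_focal_excitation()].
#'
#' @param substrate a [make_substrate()] object.
#' @param params a [cell_params()] object.
#' @param state the pre-paced end-diastolic `tissue_state`.
#' @param distribution an [srf_distribution()].
#' @param seed integer seed for the trial's sampling.
#' @param duration total trial length from the stimulus (ms).
#' @param reset_value SR load applied at the reset (mM).
#' @param stimulus_region,radius stimulus site.
#' @param dt time step (ms).
#' @param detect detector settings (see [detect_focal_excitation()]).
#' @return a `trial_outcome` list: `focal_excitation`, focus `x`, `y`,
#'   `time` (NA when none), `fraction_activated`, `t_reset`, `seed`, and the
#'   `srf` assignment table.
#' @export
run_focal_trial <- function(substrate, params, state, distribution, seed,
                            duration = 1000, reset_value = 1.0,
                            stimulus_region = "centre", radius = 5,
                            dt = 0.01, baseline = NULL,
                            detect = list(fraction = 0.1, exclusion = 50,
                                          window = 200)) {
  stopifnot(inherits(substrate, "substrate"), inherits(state, "tissue_state"))
  set.seed(seed)
  n <- state$nx * state$ny
  t0 <- state$t
  srf <- assign_srf_to_tissue(n, distribution, t_offset = t0)
  stim <- apply_stimulus(stimulus_region, state$nx, state$ny, times = t0,
                         radius = radius)
  earliest <- suppressWarnings(min(srf$table$t_i, na.rm = TRUE))
  deadline <- max(t0 + 60, min(earliest - 5, t0 + 390))
  # stage 1: paced beat + refill, release disabled
  events <- list()
  casr_prev <- -Inf
  repeat {
    chunk <- min(10, deadline - state$t)
    if (chunk < dt / 2) break  # below one integration step: done
    res <- run_tissue(state, substrate$cmap, params, duration = chunk,
                      dt = dt, stimulus = stim, trace_dt = chunk)
    events[[length(events) + 1]] <- res$events
    if (res$state$t <= state$t) break  # no forward progress possible
    state <- res$state
    vm <- utils::tail(res$trace$V_mean, 1)
    casr <- utils::tail(res$trace$CaSR_mean, 1)
    if (length(vm) == 1 && length(casr) == 1 && is.finite(vm) &&
        state$t - t0 > 120 && vm < -60 && casr < casr_prev) break
    if (length(casr) == 1) casr_prev <- casr
  }
  t_reset <- state$t
  state <- reset_sr_load(state, reset_value)
  # stage 2: evolve with the release waveforms enabled
  remain <- t0 + duration - state$t
  if (remain > 0) {
    res <- run_tissue(state, substrate$cmap, params, duration = remain,
                      dt = dt, srf = srf, srf_gate = t_reset, trace_dt = 0)
    events[[length(events) + 1]] <- res$events
    state <- res$state
  }
  events <- do.call(rbind, events)
  det <- detect_focal_excitation(events, stim, state$nx, state$ny,
                                 sim_end = state$t,
                                 fib = substrate$fib,
                                 baseline = baseline,
                                 fraction = detect$fraction,
                                 exclusion = detect$exclusion,
                                 window = detect$window)
  structure(list(focal_excitation = det$focal, x = det$x, y = det$y,
                 time = det$time, fraction_activated = det$fraction_activated,
                 t_reset = t_reset, seed = seed, srf = srf$table,
                 events = events, state = state),
            class = "trial_outcome")
}

#' Detect a spontaneous focal excitation in an upstroke-event record
#'
#' A focal excitation is declared when at least `fraction` of the
#' non-fibrotic nodes have an *unexplained* upstroke inside some
#' `window`-ms interval.  Two exclusion mechanisms remove activity
#' attributable to the paced beat: a fixed dead time (`exclusion` ms after
#' the last stimulus offset), and -- more robustly on fibrotic substrates,
#' where the paced wavefront can zigzag for well over 100 ms -- an optional
#' per-node `baseline` of paced activation times from a release-free
#' reference run: a crossing is unexplained only if it occurs more than
#' `baseline_tol` ms after the node's baseline activation (or the node
#' never activated in the baseline).  The focus is the earliest unexplained
#' crossing of the detected wave over *all* nodes, fibrotic ones included
#' (spontaneous waves originate inside patches; the fraction denominator
#' still counts only non-fibrotic tissue).
#'
#' @param events a data frame with columns `node`, `time` (and optionally
#'   `x`, `y`) of threshold upstroke crossings, as returned by
#'   [run_tissue()].
#' @param stimulus the [apply_stimulus()] schedule used in the run.
#' @param nx,ny grid dimensions.
#' @param sim_end end time of the record (ms); the record must extend at
#'   least `exclusion + window` past the last stimulus offset.
#' @param fib optional `fibrosis_map`; fibrotic nodes are excluded from the
#'   fraction denominator.
#' @param baseline optional matrix (or vector) of per-node paced activation
#'   times from a reference run without spontaneous release (NA = never
#'   activated), e.g. from [paced_baseline()].
#' @param baseline_tol slack added to baseline times (ms).
#' @param fraction,exclusion,window detector thresholds (defaults: 10% of
#'   non-fibrotic nodes, 50 ms exclusion, 200 ms window).
#' @return a list: `focal` (logical), focus `node`, `x`, `y`, `time`,
#'   and `fraction_activated` (largest windowed fraction observed).
#' @export
detect_focal_excitation <- function(events, stimulus, nx, ny, sim_end,
                                    fib = NULL, baseline = NULL,
                                    baseline_tol = 30, fraction = 0.1,
                                    exclusion = 50, window = 200) {
  last_off <- max(stimulus$times) + stimulus$duration
  t_min <- last_off + exclusion
  if (sim_end < t_min + window)
    stop("event record too short: needs to extend ", window,
         " ms beyond the post-stimulus exclusion window")
  nonfib <- rep(TRUE, nx * ny)
  if (!is.null(fib)) nonfib[as.vector(fib$mask)] <- FALSE
  n_elig <- sum(nonfib)
  ev <- events[events$time > t_min, , drop = FALSE]
  if (!is.null(baseline)) {
    bl <- as.vector(baseline)[ev$node]
    ev <- ev[is.na(bl) | ev$time > bl + baseline_tol, , drop = FALSE]
  }
  none <- list(focal = FALSE, node = NA_integer_, x = NA_integer_,
               y = NA_integer_, time = NA_real_, fraction_activated = 0)
  if (nrow(ev) == 0) return(none)
  first <- ev[!duplicated(ev$node), , drop = FALSE]  # events are time-ordered
  first <- first[order(first$time), , drop = FALSE]
  fc <- first[nonfib[first$node], , drop = FALSE]    # fraction over healthy
  if (nrow(fc) == 0) return(none)
  times <- fc$time
  # largest number of unexplained first-crossings in any window interval
  upper <- findInterval(times + window, times)
  counts <- upper - seq_along(times) + 1
  best <- which.max(counts)
  frac <- counts[best] / n_elig
  if (frac < fraction)
    return(modifyList(none, list(fraction_activated = frac)))
  # focus: earliest unexplained crossing (any node) shortly before or
  # within the detected wave window -- spontaneous waves start in patches
  t_w <- times[best]
  cand <- first[first$time >= t_w - 150 & first$time <= t_w + window, ,
                drop = FALSE]
  hit <- cand[which.min(cand$time), ]
  list(focal = TRUE, node = hit$node,
       x = (hit$node - 1) %% nx + 1, y = (hit$node - 1) %/% nx + 1,
       time = hit$time, fraction_activated = frac)
}

#' Paced-beat activation baseline for focal detection
#'
#' Runs the trial protocol without any spontaneous release and returns the
#' per-node first-activation times of the paced beat.  Passed to
#' [detect_focal_excitation()] (via [run_focal_trial()] /
#' [estimate_pta()]), it lets the detector exclude slow fibrotic paced
#' conduction instead of relying on a fixed dead time.
#'
#' @inheritParams run_focal_trial
#' @return matrix of activation times (ms, absolute clock; NA = never).
#' @export
paced_baseline <- function(substrate, params, state, duration = 1000,
                           stimulus_region = "centre", radius = 5,
                           dt = 0.01) {
  stim <- apply_stimulus(stimulus_region, state$nx, state$ny,
                         times = state$t, radius = radius)
  res <- run_tissue(state, substrate$cmap, params, duration = duration,
                    dt = dt, stimulus = stim, trace_dt = 0)
  amap <- compute_activation_map(res$events, state$nx, state$ny,
                                 reference = state$t)
  amap$times + state$t
}

#' Estimate the probability of triggered activity P(TA)
#'
#' Runs `n` independent focal-excitation trials (seeds derived from the
#' master seed) and reports the fraction that exhibited a spontaneous focal
#' beat, along with the full per-trial table.  A release-free paced
#' baseline ([paced_baseline()]) is computed once for the condition and
#' shared by all trials, so slow fibrotic paced conduction is never counted
#' as spontaneous.  Trials that abort are recorded, excluded, and the
#' denominator adjusted with a warning.
#'
#' @inheritParams run_focal_trial
#' @param n number of trials (the study protocol uses 30).
#' @param master_seed integer master seed; per-trial seeds are drawn from it.
#' @param ... further arguments passed to [run_focal_trial()].
#' @return a `pta_result`: list with `p_ta`, `n`, `k_focal`, the paced
#'   `baseline`, and the `outcomes` data frame (trial, seed, focal, x, y,
#'   time).
#' @export
estimate_pta <- function(substrate, params, state, distribution, n = 30,
                         master_seed = 1, ...) {
  stopifnot(n >= 1)
  dots <- list(...)
  baseline <- paced_baseline(
    substrate, params, state,
    duration = if (is.null(dots$duration)) 1000 else dots$duration,
    stimulus_region = if (is.null(dots$stimulus_region)) "centre"
                      else dots$stimulus_region,
    radius = if (is.null(dots$radius)) 5 else dots$radius,
    dt = if (is.null(dots$dt)) 0.01 else dots$dt)
  set.seed(master_seed)
  seeds <- sample.int(2^31 - 2, n)
  rows <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    out <- tryCatch(
      run_focal_trial(substrate, params, state, distribution, seeds[i],
                      baseline = baseline, ...),
      error = function(e) e)
    if (inherits(out, "error")) {
      warning("trial ", i, " aborted and was excluded: ",
              conditionMessage(out))
      failed <- failed + 1L
      rows[[i]] <- data.frame(trial = i, seed = seeds[i], focal = NA,
                              x = NA, y = NA, time = NA)
    } else {
      rows[[i]] <- data.frame(trial = i, seed = seeds[i],
                              focal = out$focal_excitation,
                              x = out$x, y = out$y, time = out$time)
    }
  }
  outcomes <- do.call(rbind, rows)
  n_eff <- n - failed
  k <- sum(outcomes$focal, na.rm = TRUE)
  structure(list(p_ta = if (n_eff > 0) k / n_eff else NA_real_,
                 n = n_eff, k_focal = k, outcomes = outcomes,
                 baseline = baseline, master_seed = master_seed),
            class = "pta_result")
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf("<pta_result> P(TA) = %.3f (%d focal of %d trials)\n",
              x$p_ta, x$k_focal, x$n))
  invisible(x)
}

#' Rapid pacing and re-entry outcome classification
#'
#' Paces the inferior edge rapidly (five beats at a short cycle length, as
#' used to probe the arrhythmia substrate under AF remodelling), follows the
#' activity for `follow_up` ms, and classifies the outcome from the
#' post-pacing activity: `"no re-entry"` when activity outlasts the final
#' paced beat by less than `none_cutoff` ms, `"transient re-entry"` when
#' self-sustained activity terminates before the end of the follow-up
#' window, and sustained re-entry otherwise -- split into
#' `"sustained stable"` versus `"sustained evolving"` by the standard
#' deviation of per-node cycle lengths in the late window (below/above
#' `stable_sd` ms).
#'
#' @param substrate a [make_substrate()] object.
#' @param params a [cell_params()] object (AF remodelling is recommended; a
#'   warning is issued otherwise).
#' @param state the pre-paced `tissue_state`.
#' @param cycle_length pacing cycle length (ms; 150, 200 or 250 in the
#'   substrate protocol).
#' @param n_beats number of paced beats.
#' @param follow_up post-pacing observation window (ms, >= 2000
#'   recommended).
#' @param edge_width width of the stimulated inferior-edge strip (nodes).
#' @param none_cutoff,quiescent_gap,stable_sd classification thresholds
#'   (ms).
#' @param dt time step (ms).
#' @return a `pacing_outcome` list: `outcome` (one of the four classes),
#'   `last_activity` (ms), `late_cl_sd` (ms or NA), and the event record.
#' @export
run_rapid_pacing <- function(substrate, params, state, cycle_length = 150,
                             n_beats = 5, follow_up = 2000, edge_width = 3,
                             none_cutoff = 200, quiescent_gap = 100,
                             stable_sd = 10, dt = 0.01) {
  stopifnot(inherits(substrate, "substrate"), inherits(state, "tissue_state"))
  if (!isTRUE(attr(params, "af")))
    warning("rapid-pacing substrate protocol is intended for AF-remodelled ",
            "parameters")
  t0 <- state$t
  stim_times <- t0 + cycle_length * (seq_len(n_beats) - 1)
  stim <- apply_stimulus("edge", state$nx, state$ny, times = stim_times,
                         radius = edge_width)
  dur <- cycle_length * n_beats + follow_up
  res <- run_tissue(state, substrate$cmap, params, duration = dur, dt = dt,
                    stimulus = stim, trace_dt = 1)
  classify_reentry(res$events, last_stim = max(stim_times),
                   cycle_length = cycle_length, t_end = t0 + dur,
                   none_cutoff = none_cutoff, quiescent_gap = quiescent_gap,
                   stable_sd = stable_sd)
}

#' Classify post-pacing activity into re-entry outcome classes
#'
#' The classifier behind [run_rapid_pacing()], exposed so that constructed
#' event records can be classified directly.
#'
#' @param events upstroke-event data frame (`node`, `time`).
#' @param last_stim onset of the final paced beat (ms).
#' @param cycle_length pacing cycle length (ms).
#' @param t_end end of the record (ms).
#' @param none_cutoff,quiescent_gap,stable_sd thresholds (ms): activity
#'   ending within `none_cutoff` of the final beat is "no re-entry";
#'   activity that stops more than `quiescent_gap` before `t_end` is
#'   "transient re-entry"; otherwise sustained, stable when the late-window
#'   per-node cycle-length SD is below `stable_sd`.
#' @return a `pacing_outcome` list.
#' @export
classify_reentry <- function(events, last_stim, cycle_length, t_end,
                             none_cutoff = 200, quiescent_gap = 100,
                             stable_sd = 10) {
  post <- events[events$time > last_stim + cycle_length, , drop = FALSE]
  last_act <- if (nrow(post)) max(post$time) else
    (if (nrow(events)) max(events$time) else -Inf)
  late_sd <- NA_real_
  if (!nrow(post) || last_act < last_stim + cycle_length + none_cutoff) {
    outcome <- "no re-entry"
  } else if (last_act < t_end - quiescent_gap) {
    outcome <- "transient re-entry"
  } else {
    late <- post[post$time > t_end - 4 * cycle_length, , drop = FALSE]
    cls <- unlist(tapply(late$time, late$node,
                         function(t) if (length(t) > 1) diff(sort(t)) else NULL))
    late_sd <- if (length(cls) > 1) sd(cls) else NA_real_
    outcome <- if (!is.na(late_sd) && late_sd < stable_sd)
      "sustained stable" else "sustained evolving"
  }
  structure(list(outcome = outcome, last_activity = last_act,
                 late_cl_sd = late_sd, events = events),
            class = "pacing_outcome")
}

#' Sinus-rhythm interruption by spontaneous focal excitations
#'
#' Paces at a sinus-like cycle length with the spontaneous-release model
#' active between beats: each cycle receives a fresh per-node SRF assignment
#' (timing relative to that cycle's stimulus).  Returns the sequence of
#' global activation onsets -- upward crossings of the mean membrane
#' potential above `onset_threshold` -- labelled by origin (`"stimulus"`
#' when the onset falls within `latency` ms of a stimulus, `"focal"`
#' otherwise) and the resulting activation-interval series.
#'
#' @param substrate a [make_substrate()] object.
#' @param params a [cell_params()] object.
#' @param state the pre-paced `tissue_state`.
#' @param distribution an [srf_distribution()], or `NULL` to run without
#'   spontaneous release (the rhythm is then exactly periodic).
#' @param cycle_length pacing cycle length (ms; 1000 for sinus rhythm).
#' @param n_beats number of paced cycles.
#' @param seed integer seed for the per-cycle waveform sampling.
#' @param stimulus_region,radius stimulus site.
#' @param onset_threshold mean-voltage threshold defining a global
#'   activation (mV).
#' @param latency maximum onset delay attributed to a stimulus (ms).
#' @param dt time step (ms).
#' @return a `rhythm_result`: data frame `activations` (onset, origin),
#'   `intervals` (ms), and the mean-voltage trace.
#' @export
run_sinus_interruption <- function(substrate, params, state, distribution,
                                   cycle_length = 1000, n_beats = 5, seed = 1,
                                   stimulus_region = "centre", radius = 5,
                                   onset_threshold = -40, latency = 60,
                                   dt = 0.01) {
  stopifnot(inherits(substrate, "substrate"), inherits(state, "tissue_state"))
  set.seed(seed)
  n <- state$nx * state$ny
  traces <- list()
  stim_times <- numeric(0)
  for (b in seq_len(n_beats)) {
    t_b <- state$t
    stim_times <- c(stim_times, t_b)
    stim <- apply_stimulus(stimulus_region, state$nx, state$ny, times = t_b,
                           radius = radius)
    srf <- if (is.null(distribution)) NULL
           else assign_srf_to_tissue(n, distribution, t_offset = t_b)
    res <- run_tissue(state, substrate$cmap, params, duration = cycle_length,
                      dt = dt, stimulus = stim, srf = srf,
                      srf_gate = t_b + 100, trace_dt = 1)
    traces[[b]] <- res$trace
    state <- res$state
  }
  trace <- do.call(rbind, traces)
  vm <- trace$V_mean
  onsets <- trace$t[which(vm[-1] >= onset_threshold &
                          vm[-length(vm)] < onset_threshold) + 1]
  origin <- vapply(onsets, function(t) {
    d <- t - stim_times
    if (any(d >= 0 & d <= latency)) "stimulus" else "focal"
  }, character(1))
  structure(list(activations = data.frame(onset = onsets, origin = origin),
                 intervals = diff(onsets), trace = trace,
                 stim_times = stim_times, state = state),
            class = "rhythm_result")
}

#' Compute an activation map from an upstroke-event record
#'
#' First upstroke crossing per node at or after the reference time; nodes
#' that never cross carry the sentinel `NA` (conduction failed to reach
#' them).
#'
#' @param events upstroke-event data frame from [run_tissue()].
#' @param nx,ny grid dimensions.
#' @param reference reference time (ms); activation times are reported
#'   relative to it.
#' @param threshold the detection threshold the events were recorded at
#'   (metadata).
#' @return an `activation_map`: list with the `times` matrix (ms, NA =
#'   never activated), `reference` and `threshold`.
#' @export
compute_activation_map <- function(events, nx, ny, reference = 0,
                                   threshold = -20) {
  ev <- events[events$time >= reference, , drop = FALSE]
  tm <- matrix(NA_real_, nx, ny)
  if (nrow(ev)) {
    first <- tapply(ev$time, ev$node, min)
    tm[as.integer(names(first))] <- first - reference
  }
  structure(list(times = tm, reference = reference, threshold = threshold,
                 nx = nx, ny = ny),
            class = "activation_map")
}

#' Total activation time of an activation map
#'
#' Time from the first to the last node activation (max minus min over
#' activated nodes).
#'
#' @param amap an [compute_activation_map()] result.
#' @return total activation time (ms).
#' @export
total_activation_time <- function(amap) {
  stopifnot(inherits(amap, "activation_map"))
  tt <- amap$times[!is.na(amap$times)]
  if (!length(tt)) return(NA_real_)
  max(tt) - min(tt)
}

#' Measure planar-wave conduction velocity
#'
#' Builds an idealised fibre-aligned (OY) strip, paces one end with the
#' default stimulus, and measures CV between two interior probes placed
#' along the propagation direction: `CV = separation * dx / (t2 - t1)`.
#' `direction = "longitudinal"` propagates along the fibre direction at the
#' axial coupling strength; `"transverse"` across it at the transverse
#' strength.
#'
#' @param params a [cell_params()] object.
#' @param direction `"longitudinal"` or `"transverse"`.
#' @param g_a,anisotropy_ratio,dx coupling parameters.
#' @param n_long,n_wide strip length and width (nodes).
#' @param probes probe positions along the strip (nodes, >= 20 apart).
#' @param cycle_length single-cell pre-pacing cycle length (ms).
#' @param dt time step (ms).
#' @param state optional pre-paced single-cell state (computed if omitted).
#' @return CV in mm/ms.
#' @export
measure_cv <- function(params, direction = c("longitudinal", "transverse"),
                       g_a = 1.28, anisotropy_ratio = 7, dx = 0.3125,
                       n_long = 200, n_wide = 12, probes = c(60, 140),
                       cycle_length = 400, dt = 0.01, state = NULL) {
  direction <- match.arg(direction)
  stopifnot(diff(probes) >= 20, max(probes) <= n_long - 20)
  if (is.null(state)) state <- pre_pace_cell(params, cycle_length,
                                             max_beats = 60)
  if (direction == "longitudinal") { nx <- n_wide; ny <- n_long }
  else { nx <- n_long; ny <- n_wide }
  orient <- make_orientation("OY", nx, ny)
  cmap <- build_connection_map(orient, g_a, anisotropy_ratio, dx)
  ts <- make_tissue_state(state, nx, ny, dx)
  mask <- matrix(FALSE, nx, ny)
  if (direction == "longitudinal") mask[, 1:3] <- TRUE else mask[1:3, ] <- TRUE
  dur <- 1.2 * max(probes) * dx / (if (direction == "longitudinal") 0.8 else 0.2)
  res <- run_tissue(ts, cmap, params, duration = dur, dt = dt,
                    stimulus = apply_stimulus(mask, times = 0), trace_dt = 0)
  ev <- res$events
  mid <- ceiling(n_wide / 2)
  probe_t <- function(pos) {
    tt <- if (direction == "longitudinal")
      ev$time[ev$x == mid & ev$y == pos]
    else ev$time[ev$x == pos & ev$y == mid]
    if (length(tt)) min(tt) else NA_real_
  }
  t1 <- probe_t(probes[1])
  t2 <- probe_t(probes[2])
  if (is.na(t1) || is.na(t2) || t2 <= t1)
    stop("conduction velocity measurement failed: no propagation between ",
         "probes (t1 = ", t1, ", t2 = ", t2, ")")
  diff(probes) * dx / (t2 - t1)
}
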