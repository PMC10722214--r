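# Single-cell operations: state construction, stepping, simulation and
# pre-pacing of the minimal atrial model.

.state_names <- c("V", "m", "h", "j", "d", "f", "x", "a", "r", "Cai", "CaSR")

#' Initial resting state of a cell
#'
#' Builds a cell state vector at a given membrane potential with all gates at
#' their steady state for that voltage and default calcium concentrations.
#'
#' @param params a [cell_params()] object.
#' @param V resting potential to initialise at (mV).
#' @param Cai,CaSR initial cytosolic and SR calcium (mM).
#' @return a named numeric vector of class `cell_state` with entries
#'   `V, m, h, j, d, f, x, a, r, Cai, CaSR`.
#' @export
cell_state_init <- function(params, V = -81, Cai = 1e-4, CaSR = 0.8) {
  g <- .gate_inf_cpp(V, .param_vec(params))
  s <- c(V = V, g[["m"]], g[["h"]], g[["j"]], g[["d"]], g[["f"]], g[["x"]],
         g[["a"]], g[["r"]], Cai = Cai, CaSR = CaSR)
  names(s) <- .state_names
  class(s) <- "cell_state"
  s
}

.validate_cell_state <- function(state) {
  if (length(state) != length(.state_names))
    stop("cell state must have ", length(.state_names), " entries")
  if (any(!is.finite(state))) stop("cell state contains non-finite values")
  gates <- state[2:9]
  if (any(gates < 0 | gates > 1)) stop("gating variables must lie in [0, 1]")
  if (state[["CaSR"]] <= 0) stop("CaSR must be positive")
  invisible(state)
}

#' Advance a single cell by one or more time steps
#'
#' Integrates the minimal cell model forward with a constant stimulus current
#' and a constant imposed RyR open fraction.  The SR release flux is
#' proportional to the total open fraction times the SR-cytosol calcium
#' gradient, so an imposed spontaneous release produces a calcium transient
#' whose NCX current depolarises the membrane (a DAD).
#'
#' @param state a `cell_state` vector (see [cell_state_init()]).
#' @param params a [cell_params()] object.
#' @param I_stim stimulus current (pA/pF; negative = depolarising).
#' @param N_ryr imposed RyR open fraction in `[0, 1]`.
#' @param dt time step (ms).
#' @param n_steps number of steps to take.
#' @return the advanced `cell_state`.
#' @export
ionic_step <- function(state, params, I_stim = 0, N_ryr = 0, dt = 0.01,
                       n_steps = 1) {
  stopifnot(dt > 0, n_steps >= 1)
  .validate_cell_state(state)
  if (N_ryr < 0 || N_ryr > 1) stop("N_ryr must lie in [0, 1]")
  out <- .ionic_step_cpp(unclass(state), .param_vec(params), I_stim, N_ryr,
                         dt, as.integer(n_steps), .gfb_eff(params))
  class(out) <- "cell_state"
  out
}

#' Simulate a single cell with a stimulus train and an optional SRF waveform
#'
#' @param state starting `cell_state`.
#' @param params a [cell_params()] object.
#' @param duration simulation length (ms).
#' @param dt time step (ms).
#' @param stim_times onsets of stimulus pulses (ms).
#' @param stim_amplitude,stim_duration stimulus current (pA/pF) and pulse
#'   width (ms).
#' @param srf an optional [srf_waveform()] imposed on the RyR open fraction.
#' @param N_ryr_const an optional constant imposed open fraction.
#' @param trace_dt sampling interval of the returned traces (ms).
#' @param t0 clock time of the start of the run (ms); waveform times are
#'   absolute.
#' @return a list with the final `state` and trace vectors `t`, `V`, `Cai`,
#'   `CaSR`, `Nryr`.
#' @export
cell_simulate <- function(state, params, duration, dt = 0.01,
                          stim_times = numeric(), stim_amplitude = -12.5,
                          stim_duration = 5, srf = NULL, N_ryr_const = 0,
                          trace_dt = 0.1, t0 = 0) {
  stopifnot(duration > 0, dt > 0)
  .validate_cell_state(state)
  stim <- .stim_matrix(stim_times, stim_duration, stim_amplitude)
  srf_row <- if (is.null(srf)) numeric(0) else .srf_row(srf)
  res <- .cell_run_cpp(unclass(state), .param_vec(params), srf_row,
                       N_ryr_const, stim, t0, duration, dt, trace_dt,
                       .gfb_eff(params))
  names(res$state) <- .state_names
  class(res$state) <- "cell_state"
  res
}

.stim_matrix <- function(times, duration, amplitude) {
  if (length(times) == 0) return(matrix(numeric(0), 0, 3))
  cbind(times, duration, amplitude)
}

#' Pre-pace a single cell to steady state
#'
#' Paces the cell at a fixed cycle length until the beat-to-beat change in
#' end-diastolic membrane potential and SR calcium load falls below a
#' tolerance, and returns the saved end-diastolic state (taken just before a
#' stimulus).  Faster pacing loads the SR more heavily, which is what makes
#' spontaneous release consequential.
#'
#' @param params a [cell_params()] object.
#' @param cycle_length pacing cycle length (ms).  The protocols of this
#'   package use 150, 200, 250, 400 or 1000 ms; other values are accepted
#'   with a warning.
#' @param max_beats maximum number of beats before giving up (with a
#'   warning).  `max_beats = 0` returns the initial conditions with a
#'   warning.
#' @param tol_V,tol_CaSR beat-to-beat convergence tolerances (mV, mM).
#' @param dt time step (ms).
#' @return the end-diastolic `cell_state`, with attributes `beats` (number of
#'   beats run) and `converged`.
#' @export
pre_pace_cell <- function(params, cycle_length, max_beats = 200,
                          tol_V = 0.01, tol_CaSR = 1e-5, dt = 0.01) {
  stopifnot(cycle_length > 5)
  if (!cycle_length %in% c(150, 200, 250, 400, 1000))
    warning("cycle length ", cycle_length,
            " ms is outside the standard protocol set")
  state <- cell_state_init(params)
  if (max_beats == 0) {
    warning("max_beats = 0: returning initial conditions")
    attr(state, "beats") <- 0L
    attr(state, "converged") <- FALSE
    return(state)
  }
  prev <- c(state[["V"]], state[["CaSR"]])
  pvec <- .param_vec(params)
  gfb <- .gfb_eff(params)
  stim <- .stim_matrix(0, 5, -12.5)
  converged <- FALSE
  beats <- 0L
  fired <- FALSE
  for (b in seq_len(max_beats)) {
    res <- .cell_run_cpp(unclass(state), pvec, numeric(0), 0, stim, 0,
                         cycle_length, dt, 1, gfb)
    state[] <- res$state
    beats <- b
    if (max(res$V) > 0) fired <- TRUE
    cur <- c(state[["V"]], state[["CaSR"]])
    if (b > 1 && abs(cur[1] - prev[1]) < tol_V &&
        abs(cur[2] - prev[2]) < tol_CaSR) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!fired)
    stop("pacing failure: no action potential elicited at cycle length ",
         cycle_length, " ms")
  if (!converged)
    warning("pre-pacing did not converge within ", max_beats, " beats")
  attr(state, "beats") <- beats
  attr(state, "converged") <- converged
  state
}

#' Action potential duration from a voltage trace
#'
#' Measures APD at a given repolarisation level from a sampled trace: the
#' time from the upstroke crossing of the threshold to the downstroke
#' crossing of `V_rest + (1 - level) * amplitude`.
#'
#' @param t,V trace time (ms) and voltage (mV) vectors.
#' @param level repolarisation fraction (0.9 gives APD90).
#' @param V_thresh upstroke detection threshold (mV).
#' @return APD in ms (NA if no complete action potential is found).
#' @export
apd_measure <- function(t, V, level = 0.9, V_thresh = -20) {
  up <- which(V[-1] >= V_thresh & V[-length(V)] < V_thresh)
  if (length(up) == 0) return(NA_real_)
  i0 <- up[1] + 1
  vrest <- min(V[seq_len(i0)])
  vmax <- max(V[i0:length(V)])
  vrep <- vmax - level * (vmax - vrest)
  after <- seq(i0, length(V) - 1)
  dn <- after[V[after] > vrep & V[after + 1] <= vrep]
  dn <- dn[dn > which.max(V)]
  if (length(dn) == 0) return(NA_real_)
  t[dn[1] + 1] - t[i0]
}
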