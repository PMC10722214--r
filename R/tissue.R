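# Tissue state, stimulus delivery and the coupled-lattice integrator wrapper.

#' Build a tissue state by replicating a single-cell state
#'
#' @param cell_state a `cell_state` (typically from [pre_pace_cell()]).
#' @param nx,ny grid dimensions.
#' @param dx inter-nodal spacing (mm).
#' @param t0 initial simulation clock (ms).
#' @return a `tissue_state`: list with the n x 11 state `matrix` (rows in
#'   column-major node order), grid geometry and the clock.
#' @export
make_tissue_state <- function(cell_state, nx, ny, dx = 0.3125, t0 = 0) {
  .validate_cell_state(cell_state)
  m <- matrix(rep(unclass(cell_state), each = nx * ny), nx * ny,
              length(.state_names))
  colnames(m) <- .state_names
  structure(list(matrix = m, nx = nx, ny = ny, dx = dx, t = t0),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat("<tissue_state>", x$nx, "x", x$ny, "nodes, dx =", x$dx,
      "mm, t =", x$t, "ms\n")
  cat(sprintf("  V: [%.1f, %.1f] mV, mean CaSR = %.3f mM\n",
              min(x$matrix[, "V"]), max(x$matrix[, "V"]),
              mean(x$matrix[, "CaSR"])))
  invisible(x)
}

#' Define a stimulus schedule
#'
#' @param region stimulated region: `"centre"` (disc of `radius` nodes
#'   around the grid centre), `"edge"` (strip of `radius` rows along the
#'   inferior edge, y = 1), a logical nx by ny mask, or a vector of node
#'   indices.
#' @param nx,ny grid dimensions (needed for the named regions).
#' @param times stimulus onset times (ms).
#' @param amplitude stimulus current (pA/pF; negative = depolarising).
#' @param duration pulse width (ms).
#' @param radius disc radius or strip width (nodes).
#' @return a `stimulus_spec` consumed by [run_tissue()].
#' @export
apply_stimulus <- function(region = "centre", nx = NULL, ny = NULL,
                           times = 0, amplitude = -12.5, duration = 5,
                           radius = 5) {
  if (is.character(region)) {
    region <- match.arg(region, c("centre", "edge"))
    stopifnot(!is.null(nx), !is.null(ny))
    if (region == "centre") {
      cx <- (nx + 1) / 2
      cy <- (ny + 1) / 2
      xs <- matrix(seq_len(nx), nx, ny)
      ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
      nodes <- which((xs - cx)^2 + (ys - cy)^2 <= radius^2)
    } else {
      nodes <- which(matrix(rep(seq_len(ny), each = nx), nx, ny) <= radius)
    }
  } else if (is.logical(region) && is.matrix(region)) {
    nodes <- which(region)
  } else if (is.numeric(region)) {
    nodes <- as.integer(region)
  } else {
    stop("unknown stimulus region specification")
  }
  if (length(nodes) == 0) stop("stimulus region is empty")
  structure(list(nodes = nodes, times = times, amplitude = amplitude,
                 duration = duration),
            class = "stimulus_spec")
}

#' Advance a tissue simulation
#'
#' Runs the coupled-lattice model: every node advances by the minimal cell
#' model with its stimulus current, its SRF-imposed RyR open fraction at the
#' current clock, and the network coupling current added to dV/dt.  Gates
#' use the Rush-Larsen update and V/concentrations forward Euler at `dt`
#' (default 0.01 ms).  Upstroke crossings of `v_thresh` are recorded as
#' events.  Aborts with a diagnostic naming the node and time if any state
#' becomes non-finite or |V| exceeds 100 mV.
#'
#' @param state a `tissue_state`.
#' @param cmap a `connection_map` of matching dimensions.
#' @param params a [cell_params()] object.
#' @param duration simulation length (ms).
#' @param dt time step (ms).
#' @param stimulus optional [apply_stimulus()] schedule (absolute times).
#' @param srf optional [assign_srf_to_tissue()] assignment (absolute
#'   waveform times).
#' @param srf_gate clock time before which the SRF drive is not evaluated
#'   (used to hold release until after the SR-load reset).
#' @param fibroblast_nodes optional logical mask or node index vector:
#'   nodes receiving the fibroblast coupling current (requires the
#'   `fibroblast_coupling` flag on `params` to be meaningful at the
#'   single-cell level; at tissue level the mask alone activates it in the
#'   selected region).
#' @param trace_dt sampling interval for mean-field traces (ms; 0 disables).
#' @param snap_dt interval for full voltage snapshots (ms; 0 disables).
#' @param v_thresh event-detection threshold (mV).
#' @return a `tissue_result`: list with the advanced `state`, an `events`
#'   data frame (node, x, y, time of upstroke crossings), `trace` (t,
#'   V_mean, CaSR_mean), and optional `snapshots`.
#' @export
run_tissue <- function(state, cmap, params, duration, dt = 0.01,
                       stimulus = NULL, srf = NULL, srf_gate = -Inf,
                       fibroblast_nodes = NULL, trace_dt = 1, snap_dt = 0,
                       v_thresh = -20) {
  stopifnot(inherits(state, "tissue_state"), inherits(cmap, "connection_map"),
            duration > 0, dt > 0)
  if (state$nx != cmap$nx || state$ny != cmap$ny)
    stop("tissue and connection map dimensions differ")
  n <- state$nx * state$ny
  stim <- if (is.null(stimulus)) {
    list(mat = matrix(numeric(0), 0, 3), nodes = integer(0))
  } else {
    list(mat = cbind(stimulus$times, stimulus$duration, stimulus$amplitude),
         nodes = as.integer(stimulus$nodes) - 1L)
  }
  srf_m <- if (is.null(srf)) matrix(numeric(0), 0, 10) else srf$matrix
  if (!is.null(srf) && nrow(srf_m) != n)
    stop("SRF assignment size does not match the tissue")
  gfb <- numeric(0)
  if (!is.null(fibroblast_nodes)) {
    gfb <- numeric(n)
    idx <- if (is.logical(fibroblast_nodes)) which(fibroblast_nodes) else as.integer(fibroblast_nodes)
    gfb[idx] <- params$g_fb
  } else if (isTRUE(attr(params, "fibroblast_coupling"))) {
    gfb <- rep(params$g_fb, n)
  }
  res <- .tissue_run_cpp(state$matrix, cmap$w, c(state$nx, state$ny),
                         .param_vec(params), gfb, srf_m,
                         if (is.finite(srf_gate)) srf_gate else -1e18,
                         stim$mat, stim$nodes, state$t, duration, dt,
                         v_thresh, trace_dt, snap_dt, 5L)
  out_state <- state
  out_state$matrix[] <- res$state
  out_state$t <- res$t_end
  ev <- data.frame(node = res$event_node, time = res$event_time)
  ev$x <- (ev$node - 1) %% state$nx + 1
  ev$y <- (ev$node - 1) %/% state$nx + 1
  out <- list(state = out_state,
              events = ev,
              trace = data.frame(t = res$trace_t, V_mean = res$trace_vmean,
                                 CaSR_mean = res$trace_casr_mean),
              v_thresh = v_thresh)
  if (!is.null(res$snap_v)) {
    out$snapshots <- res$snap_v
    out$snapshot_times <- res$snap_t
  }
  class(out) <- "tissue_result"
  out
}

#' @export
print.tissue_result <- function(x, ...) {
  cat("<tissue_result> t =", x$state$t, "ms,", nrow(x$events),
      "upstroke events\n")
  invisible(x)
}
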