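# Reduced stochastic model of spontaneous calcium release (SCRE):
# analytic RyR open-fraction waveforms, skewed two-branch sigmoidal
# sampling distributions for the initiation time t_i and duration lambda,
# and the static (sigma) and SR-load-dependent (dynamic) control mappings.

#' Construct a spontaneous release function (SRF) waveform
#'
#' Derives the full waveform parameterisation from the two free parameters:
#' initiation time `t_i` and duration `lambda`.  The end time is
#' `t_f = t_i + lambda`, the peak time defaults to the waveform midpoint
#' `t_i + 0.5 * lambda`, and the amplitudes are a monotone decreasing
#' saturating function of the duration (long, desynchronised release is
#' weak; short synchronised release is strong):
#' `N_peak = 0.02 + 0.55 / (1 + (lambda/120)^1.6)`, with the plateau
#' amplitude a fixed fraction `beta = 0.5` of the peak.  Durations longer
#' than 300 ms give the plateau morphology, shorter ones the spike
#' morphology.
#'
#' @param t_i initiation time (ms).
#' @param lambda duration (ms); must be positive (values below 10 ms are
#'   raised to that floor).
#' @param t_p peak time (ms); defaults to the midpoint.
#' @param n_peak,n_plateau optional amplitude overrides in `[0, 1]`.
#' @param beta plateau-to-peak amplitude ratio used when `n_plateau` is not
#'   given.
#' @return an `srf_waveform` list with fields `t_i`, `t_f`, `lambda`, `t_p`,
#'   `n_peak`, `n_plateau`, `t1`, `t2`, `k1`, `k2`, `morphology`.
#' @export
#' @examples
#' w <- srf_waveform(t_i = 300, lambda = 100)
#' w$morphology  # "spike"
srf_waveform <- function(t_i, lambda, t_p = NULL, n_peak = NULL,
                         n_plateau = NULL, beta = 0.5) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  lambda <- max(lambda, 10)
  t_f <- t_i + lambda
  if (is.null(t_p)) t_p <- t_i + 0.5 * lambda
  if (t_p <= t_i || t_p >= t_f) stop("t_p must lie strictly inside (t_i, t_f)")
  if (is.null(n_peak)) n_peak <- 0.02 + 0.55 / (1 + (lambda / 120)^1.6)
  if (is.null(n_plateau)) n_plateau <- beta * n_peak
  if (n_peak < 0 || n_peak > 1 || n_plateau < 0 || n_plateau > n_peak)
    stop("amplitudes must satisfy 0 <= n_plateau <= n_peak <= 1")
  w <- list(
    t_i = t_i, t_f = t_f, lambda = lambda, t_p = t_p,
    n_peak = n_peak, n_plateau = n_plateau,
    t1 = t_i + 0.5 * (t_p - t_i),
    t2 = t_p + 0.5 * (t_f - t_p),
    k1 = 0.1689 * (t_p - t_i) + 0.00255,
    k2 = 0.1689 * (t_f - t_p) + 0.00255,
    morphology = if (lambda > 300) "plateau" else "spike"
  )
  class(w) <- "srf_waveform"
  w
}

#' @export
print.srf_waveform <- function(x, ...) {
  cat("<srf_waveform>", x$morphology, "\n")
  cat(sprintf("  t_i = %.1f ms, lambda = %.1f ms, t_p = %.1f ms\n",
              x$t_i, x$lambda, x$t_p))
  cat(sprintf("  N_peak = %.3f, N_plateau = %.3f\n", x$n_peak, x$n_plateau))
  invisible(x)
}

# "no release" placeholder waveform
.srf_none <- function() {
  structure(list(t_i = NA_real_, t_f = NA_real_, lambda = NA_real_,
                 t_p = NA_real_, n_peak = 0, n_plateau = 0, t1 = NA_real_,
                 t2 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                 morphology = "none"),
            class = "srf_waveform")
}

# row consumed by the C++ core: morph, ti, tf, tp, npeak, nplat, t1, t2, k1, k2
.srf_row <- function(w) {
  stopifnot(inherits(w, "srf_waveform"))
  morph <- match(w$morphology, c("none", "spike", "plateau")) - 1
  if (morph == 0) return(c(0, rep(0, 9)))
  c(morph, w$t_i, w$t_f, w$t_p, w$n_peak, w$n_plateau, w$t1, w$t2, w$k1, w$k2)
}

#' Evaluate the spike-morphology SRF waveform
#'
#' The spike waveform is a product of a rising and a falling sigmoid,
#' `N_peak / ((1 + exp(-(t - t1)/k1)) (1 + exp((t - t2)/k2)))`, with
#' `t1 = t_i + 0.5 (t_p - t_i)`, `t2 = t_p + 0.5 (t_f - t_p)`,
#' `k1 = 0.1689 (t_p - t_i) + 0.00255` and `k2 = 0.1689 (t_f - t_p) +
#' 0.00255`.
#'
#' @param t time (ms); vectorised.
#' @param w an `srf_waveform` with spike morphology.
#' @return RyR open fraction in `[0, n_peak]`.
#' @export
srf_eval_spike <- function(t, w) {
  stopifnot(inherits(w, "srf_waveform"))
  if (w$morphology != "spike") stop("waveform does not have spike morphology")
  if (any(!is.finite(t))) stop("t must be finite")
  w$n_peak / ((1 + exp(-(t - w$t1) / w$k1)) * (1 + exp((t - w$t2) / w$k2)))
}

#' Evaluate the plateau-morphology SRF waveform
#'
#' Used for durations longer than 300 ms: a plateau term at level
#' `n_plateau` (sigmoid rise centred at `t_i + 17.5` ms, fall at
#' `t_f - 17.5` ms, slope 5.946 ms) plus a peak term of height
#' `n_peak - n_plateau` centred on the peak time (rise at `t_p - 25` ms,
#' fall at `t_p + 17.5` ms, same slope).
#'
#' @inheritParams srf_eval_spike
#' @export
srf_eval_plateau <- function(t, w) {
  stopifnot(inherits(w, "srf_waveform"))
  if (w$morphology != "plateau") stop("waveform does not have plateau morphology")
  if (any(!is.finite(t))) stop("t must be finite")
  k <- 5.946
  p1 <- w$n_plateau / ((1 + exp(-(t - (w$t_i + 17.5)) / k)) *
                       (1 + exp((t - (w$t_f - 17.5)) / k)))
  p2 <- (w$n_peak - w$n_plateau) /
    ((1 + exp(-(t - (w$t_p - 25)) / k)) * (1 + exp((t - (w$t_p + 17.5)) / k)))
  p1 + p2
}

#' Evaluate an SRF waveform at given times
#'
#' Dispatches on the waveform morphology ("none" evaluates to 0).
#'
#' @inheritParams srf_eval_spike
#' @param w an `srf_waveform`.
#' @export
srf_eval <- function(t, w) {
  stopifnot(inherits(w, "srf_waveform"))
  switch(w$morphology,
         none = rep(0, length(t)),
         spike = srf_eval_spike(t, w),
         plateau = srf_eval_plateau(t, w))
}

#' Construct an SRF sampling distribution
#'
#' The initiation time and duration are each sampled from a skewed
#' distribution whose cumulative frequency is a two-branch sigmoid: below
#' the separation point the CDF is `2 CF_sep / (1 + exp(-(x - x_sep)/kF1))`,
#' above it `2 (1 - CF_sep) / (1 + exp(-(x - x_sep)/kF2)) - 1 + 2 CF_sep`.
#' The two slope parameters make the two tails independently controllable.
#'
#' @param ti_sep,cf_ti,k_f1_ti,k_f2_ti separation point (ms), cumulative
#'   frequency at separation, and branch slopes (ms) for the initiation
#'   time.
#' @param la_sep,cf_la,k_f1_la,k_f2_la the analogous parameters for the
#'   duration.
#' @param p_scre probability that a node undergoes SCRE at all.
#' @return an `srf_distribution` object.
#' @export
srf_distribution <- function(ti_sep, cf_ti, k_f1_ti, k_f2_ti,
                             la_sep, cf_la, k_f1_la, k_f2_la,
                             p_scre = 1.0) {
  if (cf_ti <= 0 || cf_ti >= 1 || cf_la <= 0 || cf_la >= 1)
    stop("CF_sep values must lie strictly in (0, 1)")
  if (k_f1_ti <= 0 || k_f2_ti <= 0 || k_f1_la <= 0 || k_f2_la <= 0)
    stop("branch slopes must be positive")
  if (p_scre < 0 || p_scre > 1) stop("p_scre must lie in [0, 1]")
  structure(list(ti_sep = ti_sep, cf_ti = cf_ti, k_f1_ti = k_f1_ti,
                 k_f2_ti = k_f2_ti, la_sep = la_sep, cf_la = cf_la,
                 k_f1_la = k_f1_la, k_f2_la = k_f2_la, p_scre = p_scre),
            class = "srf_distribution")
}

.two_branch_cdf <- function(x, sep, cf, k1, k2) {
  lo <- 2 * cf / (1 + exp(-(x - sep) / k1))
  hi <- 2 * (1 - cf) / (1 + exp(-(x - sep) / k2)) - 1 + 2 * cf
  ifelse(x < sep, lo, hi)
}

.two_branch_inv <- function(r, sep, cf, k1, k2) {
  if (any(r <= 0 | r >= 1)) stop("random input must lie strictly in (0, 1)")
  out <- numeric(length(r))
  lo <- r < cf
  out[lo] <- -k1 * log(2 * cf / r[lo] - 1) + sep
  out[!lo] <- -k2 * log(2 * (1 - cf) / (r[!lo] + 1 - 2 * cf) - 1) + sep
  out
}

#' Cumulative distribution of the SCRE initiation time
#'
#' @param t_i initiation time (ms); vectorised.
#' @param d an [srf_distribution()].
#' @return cumulative frequency in (0, 1).
#' @export
srf_cdf_ti <- function(t_i, d) {
  stopifnot(inherits(d, "srf_distribution"))
  .two_branch_cdf(t_i, d$ti_sep, d$cf_ti, d$k_f1_ti, d$k_f2_ti)
}

#' Cumulative distribution of the SCRE duration
#' @param lambda duration (ms); vectorised.
#' @inheritParams srf_cdf_ti
#' @export
srf_cdf_lambda <- function(lambda, d) {
  stopifnot(inherits(d, "srf_distribution"))
  .two_branch_cdf(lambda, d$la_sep, d$cf_la, d$k_f1_la, d$k_f2_la)
}

#' Sample an SCRE initiation time by inverse-CDF transform
#'
#' Exact inverse of [srf_cdf_ti()]: uniform random inputs in (0, 1) map to
#' initiation times with the distribution's probabilities.
#'
#' @param rand uniform random numbers strictly in (0, 1); vectorised.
#' @param d an [srf_distribution()].
#' @return initiation times (ms).
#' @export
srf_sample_ti <- function(rand, d) {
  stopifnot(inherits(d, "srf_distribution"))
  .two_branch_inv(rand, d$ti_sep, d$cf_ti, d$k_f1_ti, d$k_f2_ti)
}

#' Sample an SCRE duration by inverse-CDF transform
#'
#' As [srf_sample_ti()] with the duration branch parameters; results are
#' clipped below at the 10 ms support floor.
#'
#' @inheritParams srf_sample_ti
#' @export
srf_sample_lambda <- function(rand, d) {
  stopifnot(inherits(d, "srf_distribution"))
  pmax(.two_branch_inv(rand, d$la_sep, d$cf_la, d$k_f1_la, d$k_f2_la), 10)
}

# endpoint parameter sets for the sigma control mapping.  sigma = 0 gives the
# widest distributions (timing spread of hundreds of ms, long median
# duration); sigma = 1 the tightest (spread of tens of ms, short median
# duration).  All parameters interpolate linearly in sigma.
.sigma_endpoints <- list(
  ti0 = c(sep = 500, cf = 0.4, k1 = 120, k2 = 200),
  ti1 = c(sep = 300, cf = 0.4, k1 = 10, k2 = 15),
  la0 = c(sep = 450, cf = 0.4, k1 = 100, k2 = 150),
  la1 = c(sep = 50, cf = 0.4, k1 = 8, k2 = 12)
)

#' Map the static control parameters to an SRF distribution
#'
#' The two control variables `sigma_ti` and `sigma_lambda` each vary from 0
#' (widest distribution, longest median duration) to 1 (tightest
#' distribution, shortest median duration).  Every distribution parameter is
#' a linear interpolation between the stored endpoint sets, and the SCRE
#' probability is 1 in this mode.
#'
#' @param sigma_ti,sigma_lambda control variables in `[0, 1]`.
#' @return an [srf_distribution()].
#' @export
srf_map_sigma <- function(sigma_ti, sigma_lambda) {
  if (!is.finite(sigma_ti) || sigma_ti < 0 || sigma_ti > 1 ||
      !is.finite(sigma_lambda) || sigma_lambda < 0 || sigma_lambda > 1)
    stop("sigma controls must lie in [0, 1]")
  ep <- .sigma_endpoints
  ti <- ep$ti0 + sigma_ti * (ep$ti1 - ep$ti0)
  la <- ep$la0 + sigma_lambda * (ep$la1 - ep$la0)
  srf_distribution(ti[["sep"]], ti[["cf"]], ti[["k1"]], ti[["k2"]],
                   la[["sep"]], la[["cf"]], la[["k1"]], la[["k2"]],
                   p_scre = 1.0)
}

#' Map the SR calcium load to an SRF distribution and SCRE probability
#'
#' In the dynamic mode the SCRE probability is a sigmoid of the SR load,
#' crossing 0.5 at `threshold` with slope `slope`, and the distribution
#' parameters respond monotonically to the load: a fuller SR gives earlier
#' and more tightly synchronised initiation times and shorter (hence
#' larger-amplitude) release durations.  This is implemented by driving the
#' static control mapping with an effective sigma that increases linearly
#' with the load over `ca_lo` to `ca_hi`.  The magnitude of the calcium
#' release flux additionally scales with the SR-cytosol gradient inside the
#' cell model, so release amplitude also grows with load for a fixed
#' waveform.
#'
#' @param ca_sr SR calcium load (mM).
#' @param threshold load at which the SCRE probability is 0.5 (mM).
#' @param slope sigmoid slope (mM).
#' @param ca_lo,ca_hi loads mapped to effective sigma 0 and 1.
#' @return a list with elements `distribution` (an [srf_distribution()] with
#'   `p_scre` set) and `p_scre`.
#' @export
srf_map_casr <- function(ca_sr, threshold = 0.9, slope = 0.025,
                         ca_lo = 0.7, ca_hi = 1.3) {
  if (!is.finite(ca_sr) || ca_sr <= 0) stop("ca_sr must be positive")
  p <- 1 / (1 + exp(-(ca_sr - threshold) / slope))
  sig <- min(1, max(0, (ca_sr - ca_lo) / (ca_hi - ca_lo)))
  d <- srf_map_sigma(sig, sig)
  d$p_scre <- p
  list(distribution = d, p_scre = p)
}

#' Assign SRF waveforms to tissue nodes
#'
#' Each node independently undergoes SCRE with probability `p_scre`; nodes
#' that do draw an initiation time and duration from the distribution and
#' receive the derived waveform.  The distributions are homogeneous across
#' the tissue; only the sampled parameters differ between nodes.  Sampling
#' uses R's RNG, so results are reproducible under [set.seed()].
#'
#' @param n_nodes number of nodes.
#' @param distribution an [srf_distribution()], e.g. from [srf_map_sigma()]
#'   or [srf_map_casr()].
#' @param t_offset added to sampled initiation times (ms); use it to place
#'   waveform times on the simulation clock.
#' @return an `srf_assignment`: a list with `matrix` (the n x 10 per-node
#'   waveform parameter matrix consumed by the tissue integrator) and
#'   `table` (a data frame with node, occurrence, t_i, lambda, morphology).
#' @export
assign_srf_to_tissue <- function(n_nodes, distribution, t_offset = 0) {
  stopifnot(inherits(distribution, "srf_distribution"), n_nodes >= 1)
  occ <- runif(n_nodes) < distribution$p_scre
  m <- matrix(0, n_nodes, 10)
  ti <- rep(NA_real_, n_nodes)
  la <- rep(NA_real_, n_nodes)
  idx <- which(occ)
  if (length(idx)) {
    r1 <- runif(length(idx))
    r2 <- runif(length(idx))
    # guard against exact 0/1 from the generator
    r1 <- pmin(pmax(r1, 1e-12), 1 - 1e-12)
    r2 <- pmin(pmax(r2, 1e-12), 1 - 1e-12)
    ti[idx] <- srf_sample_ti(r1, distribution) + t_offset
    la[idx] <- srf_sample_lambda(r2, distribution)
    for (k in seq_along(idx)) {
      m[idx[k], ] <- .srf_row(srf_waveform(ti[idx[k]], la[idx[k]]))
    }
  }
  tab <- data.frame(node = seq_len(n_nodes), scre = occ, t_i = ti,
                    lambda = la,
                    morphology = c("none", "spike", "plateau")[m[, 1] + 1])
  structure(list(matrix = m, table = tab, distribution = distribution,
                 t_offset = t_offset),
            class = "srf_assignment")
}

#' Write an SRF assignment to a CSV audit table
#'
#' @param assignment an [assign_srf_to_tissue()] result.
#' @param path output file path.
#' @export
write_srf_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "srf_assignment"))
  write.csv(assignment$table, path, row.names = FALSE)
  invisible(path)
}
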