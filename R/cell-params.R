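# Parameters of the minimal atrial cell model and the condition modifiers.

# order must match the enum in src/core.cpp
.param_names <- c(
  "g_Na", "E_Na", "g_CaL", "E_CaL", "g_K", "E_K", "g_K1", "k_NCX",
  "g_up", "K_up", "g_leak", "g_rel", "gate_scale", "E_fb",
  "tau_m_scale", "tau_h_scale", "tau_j_scale", "tau_f_scale", "tau_x_scale",
  "buf", "c_conv", "v_ratio", "casr_floor", "g_fb", "m_shift", "E_K1"
)

#' Parameters of the minimal atrial cell model
#'
#' Builds a validated parameter set for the minimal atrial action-potential
#' model.  The model comprises a fast sodium current (m^3 h j gating), an
#' L-type calcium current, a lumped repolarising potassium current, an
#' inward-rectifier current, an electrogenic sodium-calcium exchanger (NCX),
#' SERCA uptake, an SR leak, and an RyR release flux whose open fraction is
#' the sum of a voltage-triggered (calcium-induced calcium release) gate and
#' an externally imposed spontaneous-release drive.  Conductances are
#' per-capacitance (nS/pF for ohmic terms, pA/pF scales otherwise).
#'
#' The default values are calibrated so that, at the default tissue coupling
#' (axial 1.28 nS/pF, 7:1 anisotropy, 0.3125 mm node spacing), planar-wave
#' conduction velocities are 1.27 mm/ms along and 0.4 mm/ms across the fibre
#' direction, the resting potential is close to -81 mV, and the action
#' potential is atrial-like at a cycle length of 1000 ms.
#'
#' @param ... named overrides of individual parameters (see
#'   `fibronet:::.param_names` for the full list).
#' @param af logical; apply atrial-fibrillation electrical remodelling
#'   (reduced L-type calcium current and lumped repolariser, increased
#'   inward rectifier), shortening the action potential and lowering the
#'   steady-state SR load.
#' @param iso logical; apply sympathetic stimulation (increased L-type
#'   calcium current and SERCA uptake), raising the steady-state SR load.
#' @param fibroblast_coupling logical; add a constant ohmic
#'   myocyte-fibroblast current `g_fb * (V - E_fb)` that raises the resting
#'   potential.
#' @param model_variant `"minimal"` or `"mCRN"`.  The mCRN variant is a
#'   reduced-fidelity overlay of Courtemanche-like membrane-current balance
#'   on the same calcium subsystem: it carries a larger opposing
#'   resting-potential current load, so larger spontaneous release is needed
#'   to trigger activity and large subthreshold DADs (which can inactivate
#'   the sodium current and block conduction) become possible.
#' @return an object of class `cell_params`: a named list of parameters with
#'   the condition flags stored as attributes.
#' @export
#' @examples
#' p <- cell_params()
#' p_af <- cell_params(af = TRUE)
cell_params <- function(..., af = FALSE, iso = FALSE,
                        fibroblast_coupling = FALSE,
                        model_variant = c("minimal", "mCRN")) {
  model_variant <- match.arg(model_variant)
  p <- list(
    g_Na = 48.0, E_Na = 65, g_CaL = 0.15, E_CaL = 60, g_K = 0.12, E_K = -85,
    g_K1 = 0.65, k_NCX = 2200, g_up = 4e-4, K_up = 6e-4, g_leak = 6e-6,
    g_rel = 4.5e-3, gate_scale = 0.55, E_fb = -40, tau_m_scale = 1,
    tau_h_scale = 1, tau_j_scale = 1, tau_f_scale = 1, tau_x_scale = 1,
    buf = 0.05, c_conv = 5.2e-5, v_ratio = 15, casr_floor = 0.05,
    g_fb = 0.02, m_shift = 0, E_K1 = -81.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "cell_params",
                 af = FALSE, iso = FALSE, fibroblast_coupling = FALSE,
                 model_variant = "minimal")
  .validate_cell_params(p)
  apply_condition(p, af = af, iso = iso,
                  fibroblast_coupling = fibroblast_coupling,
                  model_variant = model_variant)
}

.validate_cell_params <- function(p) {
  conduct <- c("g_Na", "g_CaL", "g_K", "g_K1", "k_NCX", "g_up", "g_leak",
               "g_rel", "g_fb")
  for (nm in conduct) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop("cell parameter ", nm, " must be a single non-negative number")
  }
  if (p$E_fb <= -60 || p$E_fb >= -20)
    stop("E_fb must lie in (-60, -20) mV")
  invisible(p)
}

#' Apply condition modifiers to a cell parameter set
#'
#' Applies any combination of AF remodelling, sympathetic stimulation (ISO),
#' myocyte-fibroblast coupling, and the mCRN model-variant overlay to a base
#' parameter set.  Flags compose independently; applying no flags returns
#' the parameters unchanged.  A flag already set on `params` is not applied
#' twice.
#'
#' AF remodelling scales `g_CaL` by 0.6, `g_K1` by 1.3 and `g_K` by 0.85,
#' shortening the action potential by roughly 30% and lowering the
#' steady-state SR calcium load.  ISO scales `g_CaL` by 1.4 and `g_up` by
#' 1.15, raising the SR load.
#' Fibroblast coupling switches on the ohmic current `g_fb * (V - E_fb)`
#' (the conductance `g_fb` itself is a parameter).  The mCRN overlay scales
#' `g_K1` by 1.6 and `g_K` by 1.2.
#'
#' @param params a `cell_params` object.
#' @param af,iso,fibroblast_coupling logical flags.
#' @param model_variant `"minimal"` or `"mCRN"`.
#' @return the modified `cell_params` object.
#' @export
apply_condition <- function(params, af = FALSE, iso = FALSE,
                            fibroblast_coupling = FALSE,
                            model_variant = NULL) {
  stopifnot(inherits(params, "cell_params"))
  if (!is.logical(af) || !is.logical(iso) || !is.logical(fibroblast_coupling))
    stop("condition flags must be logical")
  if (isTRUE(af) && !isTRUE(attr(params, "af"))) {
    params$g_CaL <- params$g_CaL * 0.6
    params$g_K1 <- params$g_K1 * 1.3
    params$g_K <- params$g_K * 0.85
    attr(params, "af") <- TRUE
  }
  if (isTRUE(iso) && !isTRUE(attr(params, "iso"))) {
    params$g_CaL <- params$g_CaL * 1.4
    params$g_up <- params$g_up * 1.15
    attr(params, "iso") <- TRUE
  }
  if (isTRUE(fibroblast_coupling)) attr(params, "fibroblast_coupling") <- TRUE
  if (!is.null(model_variant)) {
    model_variant <- match.arg(model_variant, c("minimal", "mCRN"))
    if (model_variant == "mCRN" && attr(params, "model_variant") != "mCRN") {
      params$g_K1 <- params$g_K1 * 1.6
      params$g_K <- params$g_K * 1.2
      attr(params, "model_variant") <- "mCRN"
    }
  }
  params
}

# flat numeric vector consumed by the C++ core
.param_vec <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  v <- unlist(params[.param_names], use.names = FALSE)
  stopifnot(length(v) == length(.param_names))
  v
}

# effective fibroblast conductance: 0 unless the flag is on
.gfb_eff <- function(params) {
  if (isTRUE(attr(params, "fibroblast_coupling"))) params$g_fb else 0
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> minimal atrial model",
      if (attr(x, "model_variant") == "mCRN") "(mCRN variant)" else "", "\n")
  flags <- c(AF = attr(x, "af"), ISO = attr(x, "iso"),
             fibroblast = attr(x, "fibroblast_coupling"))
  cat("  conditions:", if (any(unlist(flags))) {
    paste(names(flags)[unlist(flags)], collapse = ", ")
  } else "control", "\n")
  cat("  g_Na =", x$g_Na, " g_CaL =", signif(x$g_CaL, 4),
      " g_K1 =", signif(x$g_K1, 4), " k_NCX =", x$k_NCX, "\n")
  invisible(x)
}
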