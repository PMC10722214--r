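# Minimal atrial cell model: resting stability, action potentials,
# condition modifiers, DAD/TA behaviour, pre-pacing.

test_that("the settled resting state is a fixed point and gates stay in [0,1]", {
  p <- cell_params()
  s <- settled_cell(p)
  res <- cell_simulate(s, p, duration = 1000, dt = 0.01, trace_dt = 1)
  expect_lt(max(res$V) - min(res$V), 0.01)
  expect_lt(abs(res$state[["Cai"]] - s[["Cai"]]), 1e-6)
  gates <- res$state[2:9]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_within(s[["V"]], -81, 2)
})

test_that("gates remain in [0,1] through stimulated activity and imposed release", {
  p <- cell_params()
  s <- paced_cell(400, p)
  w <- srf_waveform(t_i = 150, lambda = 60)
  res <- cell_simulate(s, p, duration = 600, stim_times = 0, srf = w,
                       trace_dt = 0.5)
  expect_true(all(res$state[2:9] >= 0 & res$state[2:9] <= 1))
  expect_true(all(is.finite(res$V)))
})

test_that("a large imposed release spike triggers a full action potential (TA)", {
  p <- cell_params()
  s <- paced_cell(400, p)
  s[["CaSR"]] <- 1.0
  w <- srf_waveform(t_i = 100, lambda = 80, n_peak = 0.8)
  res <- cell_simulate(s, p, duration = 500, srf = w, trace_dt = 0.5)
  expect_gt(max(res$V), -20)  # crossed the sodium activation threshold
})

test_that("DAD amplitude grows monotonically with release amplitude up to the TA threshold", {
  p <- cell_params()
  s0 <- paced_cell(400, p)
  s0[["CaSR"]] <- 1.0
  amps <- c(0.02, 0.05, 0.08, 0.11, 0.14)
  dv <- vapply(amps, function(a) {
    w <- srf_waveform(t_i = 100, lambda = 80, n_peak = a)
    res <- cell_simulate(s0, p, duration = 500, srf = w, trace_dt = 0.5)
    max(res$V) - res$V[1]
  }, numeric(1))
  expect_true(all(diff(dv) > 0))
  expect_lt(dv[1], 5)  # smallest release: subthreshold deflection
})

test_that("APD90 agrees with an independent trace-analysis oracle", {
  p <- cell_params()
  s <- paced_cell(1000, p)
  res <- cell_simulate(s, p, duration = 600, stim_times = 0, trace_dt = 0.1)
  apd <- apd_measure(res$t, res$V, 0.9)
  # oracle: direct scan of the stored trace, written independently
  vmax <- max(res$V)
  i_up <- which(res$V > -20)[1]
  vrest <- res$V[1]
  v90 <- vmax - 0.9 * (vmax - vrest)
  i_dn <- which(seq_along(res$V) > which.max(res$V) & res$V <= v90)[1]
  oracle <- res$t[i_dn] - res$t[i_up]
  expect_within(apd, oracle, 1)
  expect_true(apd > 60 && apd < 200)  # atrial-like at CL 1000 ms
})

test_that("condition flags compose and have the documented direction of effect", {
  p <- cell_params()
  expect_identical(unclass(apply_condition(p)), unclass(p))  # no flags
  expect_error(apply_condition(p, af = "yes"), "logical")
  expect_error(cell_params(not_a_param = 1), "unknown")

  apd_of <- function(params) {
    s <- paced_cell(1000, params)
    res <- cell_simulate(s, params, duration = 600, stim_times = 0,
                         trace_dt = 0.5)
    apd_measure(res$t, res$V, 0.9)
  }
  p_af <- cell_params(af = TRUE)
  expect_lt(apd_of(p_af), apd_of(p))
  # AF lowers, ISO raises, the steady-state SR load
  expect_lt(paced_cell(1000, p_af)[["CaSR"]], paced_cell(1000, p)[["CaSR"]])
  expect_gt(paced_cell(1000, cell_params(iso = TRUE))[["CaSR"]],
            paced_cell(1000, p)[["CaSR"]])
  # flags are idempotent: applying AF twice scales once
  expect_identical(apply_condition(p_af, af = TRUE)$g_CaL, p_af$g_CaL)
})

test_that("fibroblast coupling raises the resting potential monotonically in g_fb", {
  rest_of <- function(gfb) {
    p <- cell_params(fibroblast_coupling = gfb > 0, g_fb = max(gfb, 1e-9))
    s <- cell_state_init(p)
    cell_simulate(s, p, duration = 4000, dt = 0.02, trace_dt = 0)$state[["V"]]
  }
  rests <- vapply(c(0, 0.005, 0.01, 0.02), rest_of, numeric(1))
  expect_true(all(diff(rests) > 0))
  expect_error(cell_params(E_fb = -10), "E_fb")
})

test_that("pre-pacing converges, loads the SR rate-dependently, and handles edge cases", {
  p <- cell_params()
  s400 <- paced_cell(400, p)
  s1000 <- paced_cell(1000, p)
  expect_true(attr(s400, "converged"))
  expect_gt(s400[["CaSR"]], s1000[["CaSR"]])  # faster pacing loads the SR

  # the saved state reproduces the same AP when re-stimulated
  r1 <- cell_simulate(s1000, p, duration = 1000, stim_times = 0, trace_dt = 1)
  r2 <- cell_simulate(r1$state, p, duration = 1000, stim_times = 0,
                      trace_dt = 1)
  expect_lt(max(abs(r1$V - r2$V)), 0.5)

  expect_warning(s_init <- pre_pace_cell(p, 400, max_beats = 0), "max_beats")
  expect_identical(attr(s_init, "beats"), 0L)
  expect_warning(expect_warning(pre_pace_cell(p, 320, max_beats = 3),
                                "outside the standard"),
                 "did not converge")
  expect_error(suppressWarnings(pre_pace_cell(cell_params(g_Na = 0), 400,
                                              max_beats = 3)),
               "pacing failure")
})

test_that("integration failure is reported with the offending quantity", {
  p <- cell_params()
  s <- cell_state_init(p)
  expect_error(ionic_step(s, p, I_stim = -1e8, dt = 0.5, n_steps = 10),
               "V|voltage")
  expect_error(ionic_step(s, p, N_ryr = 2), "N_ryr")
})

test_that("mCRN variant carries a larger opposing current load than the minimal model", {
  p_m <- cell_params()
  p_c <- cell_params(model_variant = "mCRN")
  expect_gt(p_c$g_K1, p_m$g_K1)
  # the same release produces a smaller depolarisation in the mCRN variant
  dad_of <- function(p) {
    s <- paced_cell(400, p)
    s[["CaSR"]] <- 1.0
    w <- srf_waveform(t_i = 100, lambda = 200)
    res <- cell_simulate(s, p, duration = 600, srf = w, trace_dt = 0.5)
    max(res$V) - res$V[1]
  }
  expect_lt(dad_of(p_c), dad_of(p_m))
})
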