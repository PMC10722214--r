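# Protocol drivers: activation maps, focal-excitation detection, SR reset,
# outcome classification, sinus rhythm, CV measurement.

test_that("activation map of a constructed planar wave is a linear ramp", {
  # wave at speed c = 0.5 nodes/ms along y
  nx <- 8; ny <- 40
  ev <- expand.grid(x = 1:nx, y = 1:ny)
  ev$node <- ev$x + nx * (ev$y - 1)
  ev$time <- 100 + ev$y / 0.5
  amap <- compute_activation_map(ev, nx, ny, reference = 100)
  expect_true(all(!is.na(amap$times)))
  ramp <- amap$times[1, ]
  expect_equal(unique(diff(ramp)), 2, tolerance = 1e-12)  # 1/c
  expect_equal(total_activation_time(amap), (ny - 1) * 2, tolerance = 1e-12)
  # nodes never activated carry the sentinel
  amap2 <- compute_activation_map(ev[ev$y <= 20, ], nx, ny, reference = 100)
  expect_true(all(is.na(amap2$times[, 21:ny])))
})

test_that("focal detection: quiescence, paced-beat exclusion, injected wave", {
  nx <- ny <- 30
  stim <- apply_stimulus("centre", nx, ny, times = 0)
  none <- data.frame(node = integer(0), time = numeric(0))
  det <- detect_focal_excitation(none, stim, nx, ny, sim_end = 1000)
  expect_false(det$focal)

  # the paced beat alone (all nodes activate within 40 ms) is not focal
  paced <- data.frame(node = 1:(nx * ny),
                      time = runif(nx * ny, 2, 40))
  det <- detect_focal_excitation(paced, stim, nx, ny, sim_end = 1000)
  expect_false(det$focal)

  # a travelling wave injected at node (5, 5) at t = 500 is focal with the
  # locus at the injection site
  wave <- expand.grid(x = 1:nx, y = 1:ny)
  wave$node <- wave$x + nx * (wave$y - 1)
  wave$time <- 500 + sqrt((wave$x - 5)^2 + (wave$y - 5)^2) * 2
  wave <- wave[order(wave$time), ]
  both <- rbind(paced, wave[, c("node", "time")])
  both <- both[order(both$time), ]
  det <- detect_focal_excitation(both, stim, nx, ny, sim_end = 1500)
  expect_true(det$focal)
  expect_equal(c(det$x, det$y), c(5, 5))
  expect_equal(det$time, 500)
  expect_error(detect_focal_excitation(none, stim, nx, ny, sim_end = 100),
               "too short")
})

test_that("SR-load reset touches only the SR compartment", {
  p <- cell_params()
  ts <- make_tissue_state(paced_cell(400, p), 10, 10)
  before <- ts$matrix
  ts2 <- reset_sr_load(ts, 1.0)
  expect_true(all(ts2$matrix[, "CaSR"] == 1.0))
  other <- setdiff(colnames(before), "CaSR")
  expect_identical(ts2$matrix[, other], before[, other])
  ts3 <- reset_sr_load(ts2, 1.0)  # resetting to the current value: identity
  expect_identical(ts3$matrix, ts2$matrix)
  expect_error(reset_sr_load(ts, -1), "positive")
})

test_that("re-entry classification distinguishes the four outcome classes", {
  nx <- ny <- 20
  n <- nx * ny
  last_stim <- 600; cl <- 150; t_end <- 3350
  beat <- function(t0) data.frame(node = 1:n, time = t0 + runif(n, 0, 30))
  paced <- do.call(rbind, lapply(seq(0, last_stim, by = cl), beat))

  quiet <- classify_reentry(paced, last_stim, cl, t_end)
  expect_identical(quiet$outcome, "no re-entry")

  trans <- rbind(paced, do.call(rbind, lapply(seq(900, 1500, 120), beat)))
  expect_identical(classify_reentry(trans, last_stim, cl, t_end)$outcome,
                   "transient re-entry")

  # a perfectly periodic spiral: sustained and stable
  set.seed(2)
  spiral <- rbind(paced, do.call(rbind, lapply(seq(900, t_end, 120), function(t0)
    data.frame(node = 1:n, time = t0 + rep(seq(0, 119, length.out = n))))))
  expect_identical(classify_reentry(spiral, last_stim, cl, t_end)$outcome,
                   "sustained stable")

  # irregular sustained activity: evolving
  evolving <- rbind(paced, data.frame(
    node = sample(1:n, 6000, replace = TRUE),
    time = sort(runif(6000, 900, t_end))))
  expect_identical(classify_reentry(evolving, last_stim, cl, t_end)$outcome,
                   "sustained evolving")
})

test_that("without spontaneous release the paced rhythm is exactly periodic", {
  p <- cell_params()
  set.seed(21)
  sub <- make_substrate(30, 30)
  ts <- make_tissue_state(paced_cell(400, p), 30, 30)
  r <- run_sinus_interruption(sub, p, ts, distribution = NULL,
                              cycle_length = 500, n_beats = 3, seed = 4)
  expect_identical(nrow(r$activations), 3L)
  expect_true(all(r$activations$origin == "stimulus"))
  expect_equal(unique(r$intervals), 500, tolerance = 1e-9)
})

test_that("pre-pacing a tissue is periodic and the degenerate case is the identity", {
  p <- cell_params()
  set.seed(31)
  sub <- make_substrate(40, 40)
  ts <- make_tissue_state(paced_cell(400, p), 40, 40)
  expect_identical(pre_pace_tissue(ts, sub, p, 400, n_beats = 0), ts)
  s4 <- pre_pace_tissue(ts, sub, p, 400, n_beats = 4)
  amap_of <- function(state) {
    stim <- apply_stimulus("centre", 40, 40, times = state$t)
    res <- run_tissue(state, sub$cmap, p, duration = 60, stimulus = stim,
                      trace_dt = 0)
    list(map = compute_activation_map(res$events, 40, 40,
                                      reference = state$t)$times,
         state = res$state)
  }
  a5 <- amap_of(s4)                      # beat 5
  s5 <- run_tissue(a5$state, sub$cmap, p, duration = 340, trace_dt = 0)$state
  a6 <- amap_of(s5)                      # beat 6
  expect_lt(max(abs(a5$map - a6$map), na.rm = TRUE), 1)
})

test_that("conduction velocity measurement fails loudly without propagation", {
  p0 <- cell_params()
  rest <- settled_cell(p0)
  p_dead <- cell_params(g_Na = 0)
  expect_error(measure_cv(p_dead, "longitudinal", n_long = 80,
                          probes = c(30, 60), state = rest),
               "measurement failed|propagation")
})

test_that("early, synchronised release interposes focal beats in sinus rhythm", {
  p <- cell_params()
  s0 <- paced_cell(1000, p)
  set.seed(61)
  subf <- make_substrate(40, 40, fibrosis = list(patch_seed = 10,
                                                 area_fraction = 0.5))
  ts <- make_tissue_state(s0, 40, 40)
  r <- run_sinus_interruption(subf, p, ts, srf_map_sigma(1, 1),
                              cycle_length = 1000, n_beats = 2, seed = 9)
  expect_true(any(r$activations$origin == "focal"))
  expect_true(any(r$intervals < 1000))
})

test_that("the rapid-pacing driver runs and yields a valid outcome class", {
  paf <- cell_params(af = TRUE)
  s <- paced_cell(150, paf)
  set.seed(100)
  sub <- make_substrate(60, 60, fibrosis = list(patch_seed = 50,
                                                area_fraction = 0.25))
  ts <- make_tissue_state(s, 60, 60)
  out <- run_rapid_pacing(sub, paf, ts, cycle_length = 150, n_beats = 3,
                          follow_up = 600)
  expect_true(out$outcome %in% c("no re-entry", "transient re-entry",
                                 "sustained evolving", "sustained stable"))
  expect_gt(nrow(out$events), 0)
  # slow pacing of an unremodelled, unfibrotic substrate: never re-entry
  p <- cell_params()
  set.seed(101)
  sub0 <- make_substrate(40, 40)
  ts0 <- make_tissue_state(paced_cell(400, p), 40, 40)
  out0 <- NULL
  expect_warning(
    out0 <- run_rapid_pacing(sub0, p, ts0, cycle_length = 400, n_beats = 2,
                             follow_up = 500),
    "AF-remodelled")
  expect_identical(out0$outcome, "no re-entry")
})
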