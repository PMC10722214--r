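# Reduced spontaneous-release model: waveforms, sampling distributions,
# control mappings and tissue assignment.

test_that("waveform derivation fills the slope/midpoint parameters correctly", {
  w <- srf_waveform(t_i = 200, lambda = 200)  # t_p - t_i = 100 ms
  expect_equal(w$k1, 0.1689 * 100 + 0.00255, tolerance = 1e-12)
  expect_equal(w$k2, 0.1689 * 100 + 0.00255, tolerance = 1e-12)
  expect_equal(w$t1, 200 + 50)
  expect_equal(w$t2, 300 + 50)
  expect_identical(w$t_f - w$t_i, w$lambda)
  expect_identical(w$morphology, "spike")
  expect_identical(srf_waveform(0, 400)$morphology, "plateau")
  expect_error(srf_waveform(0, -5), "positive")
})

test_that("waveform amplitudes are a monotone non-increasing function of duration", {
  lambdas <- c(20, 50, 100, 200, 400, 800, 1500)
  peaks <- vapply(lambdas, function(l) srf_waveform(0, l)$n_peak, numeric(1))
  expect_true(all(diff(peaks) <= 0))
  expect_true(all(peaks >= 0 & peaks <= 1))
})

test_that("spike waveform: zero amplitude, bounds, and argmax versus a numeric oracle", {
  w0 <- srf_waveform(100, 150, n_peak = 0)
  tt <- seq(0, 400, by = 0.5)
  expect_true(all(srf_eval_spike(tt, w0) == 0))

  w <- srf_waveform(t_i = 100, lambda = 150)
  v <- srf_eval_spike(tt, w)
  expect_true(all(v >= 0 & v <= w$n_peak + 1e-12))
  # independent oracle: continuous maximiser of the two-sigmoid product
  f <- function(t) -srf_eval_spike(t, w)
  opt <- optimize(f, c(w$t_i - 50, w$t_f + 50))
  grid_max <- tt[which.max(v)]
  expect_lt(abs(grid_max - opt$minimum), 1)
  expect_error(srf_eval_spike(NaN, w), "finite")
})

test_that("plateau waveform matches its closed form at reference points", {
  w <- srf_waveform(t_i = 100, lambda = 1000)
  expect_identical(w$morphology, "plateau")
  # far from all four sigmoid centres the value is the plateau level
  expect_lt(abs(srf_eval_plateau(350, w) - w$n_plateau), 1e-3)
  # equal amplitudes collapse the peak term
  w2 <- srf_waveform(100, 1000, n_peak = 0.4, n_plateau = 0.4)
  tt <- seq(0, 1300, by = 1)
  w2_peakless <- w2
  w2_peakless$n_peak <- w2_peakless$n_plateau
  expect_equal(srf_eval_plateau(tt, w2), srf_eval_plateau(tt, w2_peakless))
  # near the centre of the peak term the waveform approaches n_peak
  w3 <- srf_waveform(0, 600)
  expect_gt(max(srf_eval_plateau(seq(250, 350, 0.5), w3)), 0.9 * w3$n_peak)
})

test_that("morphology switch at 300 ms changes the waveform by a bounded amount", {
  # the two functional forms are different analytic families; the switch is
  # documented to change pointwise values by less than 0.35 * n_peak
  w_lo <- srf_waveform(0, 300 - 1e-6)
  w_hi <- srf_waveform(0, 300 + 1e-6)
  tt <- seq(-50, 400, by = 0.5)
  d <- max(abs(srf_eval(tt, w_lo) - srf_eval(tt, w_hi)))
  expect_lt(d, 0.35 * w_lo$n_peak)
})

test_that("two-branch CDF passes through its separation point and is monotone", {
  d <- srf_map_sigma(0.5, 0.5)
  expect_equal(srf_cdf_ti(d$ti_sep, d), d$cf_ti, tolerance = 1e-12)
  expect_equal(srf_cdf_lambda(d$la_sep, d), d$cf_la, tolerance = 1e-12)
  tt <- seq(d$ti_sep - 500, d$ti_sep + 800, length.out = 1000)
  expect_true(all(diff(srf_cdf_ti(tt, d)) >= 0))
  # asymptotes
  expect_lt(srf_cdf_ti(d$ti_sep - 50 * d$k_f1_ti, d), 1e-3)
  expect_gt(srf_cdf_ti(d$ti_sep + 50 * d$k_f2_ti, d), 1 - 1e-3)
})

test_that("inverse sampling is the exact inverse of the CDF on both branches", {
  for (sig in list(c(0, 0), c(0.3, 0.7), c(1, 1))) {
    d <- srf_map_sigma(sig[1], sig[2])
    expect_equal(srf_sample_ti(d$cf_ti, d), d$ti_sep, tolerance = 1e-10)
    r <- seq(0.05, 0.95, by = 0.05)
    expect_equal(srf_cdf_ti(srf_sample_ti(r, d), d), r, tolerance = 1e-10)
    expect_equal(srf_cdf_lambda(srf_sample_lambda(r, d), d), r,
                 tolerance = 1e-10)
  }
  d <- srf_map_sigma(0.5, 0.5)
  expect_error(srf_sample_ti(0, d), "strictly")
  expect_error(srf_sample_ti(1.2, d), "strictly")
})

test_that("sampled distributions match the analytic CDF (Kolmogorov-Smirnov)", {
  d <- srf_map_sigma(0.4, 0.6)
  set.seed(101)
  x <- srf_sample_ti(runif(1e5, min = 1e-12, max = 1 - 1e-12), d)
  emp <- ecdf(x)
  grid <- quantile(x, seq(0.001, 0.999, length.out = 400))
  ks <- max(abs(emp(grid) - srf_cdf_ti(grid, d)))
  expect_lt(ks, 0.01)
  # durations are clipped at the positive support floor
  la <- srf_sample_lambda(runif(1e5, 1e-12, 1 - 1e-12), d)
  expect_true(all(la >= 10))
})

test_that("sigma controls tighten the distributions monotonically", {
  set.seed(7)
  iqr_ti <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    d <- srf_map_sigma(s, 0.5)
    IQR(srf_sample_ti(runif(1e4, 1e-9, 1 - 1e-9), d))
  }, numeric(1))
  expect_true(all(diff(iqr_ti) < 0))
  med_la <- vapply(c(0, 0.5, 1), function(s) {
    d <- srf_map_sigma(0.5, s)
    median(srf_sample_lambda(runif(1e4, 1e-9, 1 - 1e-9), d))
  }, numeric(1))
  expect_true(all(diff(med_la) < 0))
  # endpoints reproduce the stored parameter sets exactly
  d0 <- srf_map_sigma(0, 0)
  ep <- fibronet:::.sigma_endpoints
  expect_identical(c(d0$ti_sep, d0$cf_ti, d0$k_f1_ti, d0$k_f2_ti),
                   unname(ep$ti0))
  d1 <- srf_map_sigma(1, 1)
  expect_identical(c(d1$la_sep, d1$cf_la, d1$k_f1_la, d1$k_f2_la),
                   unname(ep$la1))
  expect_error(srf_map_sigma(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("SR-load mapping: probability sigmoid asymptotes and earlier timing at high load", {
  expect_lt(srf_map_casr(0.5)$p_scre, 1e-3)
  expect_gt(srf_map_casr(1.4)$p_scre, 1 - 1e-3)
  expect_equal(srf_map_casr(0.9)$p_scre, 0.5, tolerance = 1e-12)
  set.seed(11)
  d_hi <- srf_map_casr(1.1)$distribution
  d_lo <- srf_map_casr(0.9)$distribution
  m_hi <- median(srf_sample_ti(runif(1e4, 1e-9, 1 - 1e-9), d_hi))
  m_lo <- median(srf_sample_ti(runif(1e4, 1e-9, 1 - 1e-9), d_lo))
  expect_lt(m_hi, m_lo)
  expect_error(srf_map_casr(-1), "positive")
})

test_that("tissue assignment: occurrence probability, determinism, audit export", {
  d <- srf_map_sigma(0.5, 0.5)
  d$p_scre <- 0
  set.seed(1)
  a0 <- assign_srf_to_tissue(500, d)
  expect_true(all(!a0$table$scre))
  expect_true(all(a0$matrix == 0))

  d$p_scre <- 0.5
  set.seed(2)
  a <- assign_srf_to_tissue(1e4, d)
  expect_within(mean(a$table$scre), 0.5, 0.02)

  set.seed(99); b1 <- assign_srf_to_tissue(200, d)
  set.seed(99); b2 <- assign_srf_to_tissue(200, d)
  expect_identical(b1$matrix, b2$matrix)

  path <- tempfile(fileext = ".csv")
  write_srf_assignment(b1, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 200)
  expect_equal(tab$t_i, b1$table$t_i)
})
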