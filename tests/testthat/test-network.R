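# Orientation-weighted connection maps, fibrosis removal, coupling current.

test_that("fibre-aligned fields engage exactly two directions with g_a / g_t", {
  o <- make_orientation("OY", 20, 20)
  cm <- build_connection_map(o, g_a = 1.28, anisotropy_ratio = 7)
  expect_equal(cm$g_t, 1.28 / 7, tolerance = 1e-15)
  w <- cm$w
  interior <- which(matrix(TRUE, 20, 20)[] &
                    (seq_len(400) - 1) %% 20 + 1 < 20 &
                    (seq_len(400) - 1) %/% 20 + 1 < 20)
  expect_true(all(w[interior, 1] == cm$g_t))  # +x carries transverse
  expect_true(all(w[interior, 2] == 1.28))    # +y carries axial
  expect_true(all(w[, 3] == 0))               # diagonals exactly zero
  expect_true(all(w[, 4] == 0))

  # fibre along the +x+y diagonal: only the diagonals are non-zero
  o45 <- o
  o45$theta <- matrix(pi / 4, 20, 20)
  o45$fx <- cos(o45$theta); o45$fy <- sin(o45$theta)
  cm45 <- build_connection_map(o45, 1.28, 7)
  expect_true(all(cm45$w[, 1] == 0))
  expect_true(all(cm45$w[, 2] == 0))
  interior3 <- cm45$w[, 3][cm45$w[, 3] != 0]
  interior4 <- cm45$w[, 4][cm45$w[, 4] != 0]
  expect_equal(unique(interior3), 1.28 / sqrt(2), tolerance = 1e-12)
  expect_equal(unique(interior4), cm45$g_t / sqrt(2), tolerance = 1e-12)
})

test_that("total coupling is equivariant under a 90-degree rotation of the fibre field", {
  # OX field is the OY field rotated by 90 degrees: the x and y bond maps swap
  o <- make_orientation("OY", 15, 15)
  ox <- o
  ox$theta <- matrix(0, 15, 15)
  ox$fx <- matrix(1, 15, 15); ox$fy <- matrix(0, 15, 15)
  cy <- build_connection_map(o, 1.28, 7)
  cx <- build_connection_map(ox, 1.28, 7)
  expect_equal(connection_grid(cy, "y")[, 1:14],
               t(connection_grid(cx, "x")[1:14, ]), tolerance = 1e-12)
})

test_that("generic orientations engage all four directions with symmetric bond weights", {
  o <- make_orientation("OY", 12, 12)
  o$theta <- matrix(pi / 2 + 0.4, 12, 12) + outer(1:12, 1:12, function(a, b) 0.01 * a)
  o$fx <- cos(o$theta); o$fy <- sin(o$theta)
  cm <- build_connection_map(o, 1.28, 7)
  inner <- matrix(cm$w[, 1], 12, 12)[2:10, 2:10]
  expect_true(all(inner > 0))
  for (k in 3:4) expect_true(any(cm$w[, k] > 0))
  # stored bond weight equals the mean of the two endpoint evaluations
  node_w <- (1.28 * cos(o$theta)^2 + cm$g_t * sin(o$theta)^2) *
    cos(2 * o$theta)^2
  bond_x <- (node_w[1:11, ] + node_w[2:12, ]) / 2
  expect_equal(matrix(cm$w[, 1], 12, 12)[1:11, ], bond_x, tolerance = 1e-12)
})

test_that("fibrosis removal: identity at zero, exact fractions, subset contract", {
  set.seed(8)
  o <- make_orientation("OY", 40, 40)
  cm <- build_connection_map(o, 1.28, 7)
  allfib <- threshold_to_area(matrix(1, 40, 40) + 0 * ramp_field(40, 40), 1)

  cm0 <- apply_fibrosis_removal(cm, allfib, 0, 0)
  expect_identical(cm0$w, cm$w)

  cmr <- apply_fibrosis_removal(cm, allfib, 0.8, 0.2)
  rm <- attr(cmr, "removed")
  expect_identical(rm[["transverse"]], as.integer(round(0.8 * rm[["n_transverse"]])))
  expect_identical(rm[["longitudinal"]], as.integer(round(0.2 * rm[["n_longitudinal"]])))
  expect_equal(rm[["transverse"]] / rm[["n_transverse"]], 0.8, tolerance = 1e-12)
  # removal only zeroes weights; survivors are bitwise unchanged
  changed <- cmr$w != cm$w
  expect_true(all(cmr$w[changed] == 0))
  expect_identical(cmr$w[!changed], cm$w[!changed])
  expect_error(apply_fibrosis_removal(cm, allfib, 1.2, 0), "\\[0, 1\\]")
})

test_that("coupling current: equilibrium, two-node value, conservation", {
  o <- make_orientation("OY", 10, 10)
  cm <- build_connection_map(o, 1.28, 7)
  V <- matrix(-80, 10, 10)
  expect_true(all(coupling_current(V, cm) == 0))

  # two-node hand calculation: w = 1 nS/pF, dV = 10 mV -> +-10 pA/pF
  o2 <- make_orientation("OY", 2, 2)
  cm2 <- build_connection_map(o2, 1, 1)  # isotropic unit bonds
  expect_equal(cm2$w[1, 1], 1)
  I <- coupling_current(matrix(c(0, 10, 0, 10), 2, 2), cm2)
  expect_equal(as.vector(I), c(10, -10, 10, -10))

  set.seed(3)
  for (i in 1:5) {
    V <- matrix(rnorm(100, -60, 30), 10, 10)
    I <- coupling_current(V, cm)
    expect_lt(abs(sum(I)), 1e-9 * sqrt(sum(V^2)))
  }
  expect_error(coupling_current(matrix(c(1, NA), 2, 1), cm2), "finite")
})

test_that("removal classification splits bonds by fibre alignment", {
  set.seed(4)
  o <- make_orientation("OY", 30, 30)
  cm <- build_connection_map(o, 1.28, 7)
  allfib <- threshold_to_area(ramp_field(30, 30), 1)
  cmr <- apply_fibrosis_removal(cm, allfib, 1, 0)  # remove all transverse
  # all x-bonds (transverse to the y-fibres) are gone; y-bonds survive
  expect_true(all(cmr$w[, 1] == 0))
  expect_identical(cmr$w[, 2], cm$w[, 2])
})
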