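# Monte Carlo moves, Metropolis correctness, trajectory mechanics.

test_that("crankshaft rotation preserves both adjacent bond lengths exactly", {
  x <- stretched_coil(30, seed = 4)
  for (ang in c(0, 0.05, -0.26, 1.2)) {
    y <- crankshaft_move(x, 15, ang)
    expect_equal(y[-15, ], x[-15, ], tolerance = 0)  # only the bead moves
    for (nb in c(14, 16))
      expect_equal(sqrt(sum((y[15, ] - y[nb, ])^2)),
                   sqrt(sum((x[15, ] - x[nb, ])^2)), tolerance = 1e-10)
  }
  expect_equal(crankshaft_move(x, 15, 0), x, tolerance = 1e-12)
})

test_that("crankshaft displacement is bounded by the chord 2 b sin(amplitude/2)", {
  x <- stretched_coil(30, seed = 4)
  amp <- 15 * pi / 180
  b <- max(sqrt(rowSums(diff(x)^2)))
  bound <- 2 * b * sin(amp / 2)
  for (k in 1:50) {
    y <- crankshaft_move(x, 2 + (k %% 27), ((k / 50) * 2 - 1) * amp)
    expect_lte(max(sqrt(rowSums((y - x)^2))), bound + 1e-9)
  }
})

test_that("endpoint move rotates exactly the terminal segment rigidly about its pivot", {
  x <- stretched_coil(30, seed = 8)
  y <- endpoint_move(x, "C", axis = c(0.3, -1, 0.5), angle = 0.7)
  expect_equal(y[1:21, ], x[1:21, ], tolerance = 0)  # pivot bead 21 immobile
  moved <- 22:30
  expect_false(isTRUE(all.equal(y[moved, ], x[moved, ])))
  d_before <- as.matrix(dist(x[21:30, ]))
  d_after <- as.matrix(dist(y[21:30, ]))
  expect_equal(d_after, d_before, tolerance = 1e-10)
})

test_that("cartesian proposals stay in the 0.15 A ball with the uniform-ball mean", {
  x <- stretched_coil(20, seed = 2)
  dr <- knotfold:::.draw_moves_cpp(x, 2e5, 0.15, seed = 31, "cartesian")
  expect_lte(max(dr$disp), 0.15 + 1e-12)
  expect_equal(mean(dr$disp), 3 * 0.15 / 4, tolerance = 0.002)
  expect_gte(min(dr$which), 1)
  expect_lte(max(dr$which), 20)
})

test_that("termini and pivot sides are chosen with frequency 1/2", {
  x <- stretched_coil(30, seed = 2)
  ep <- knotfold:::.draw_moves_cpp(x, 1e4, 0.15, seed = 5, "endpoint")
  expect_lt(abs(mean(ep$which) - 0.5), 0.02)
  pv <- knotfold:::.draw_moves_cpp(x, 1e4, 0.15, seed = 6, "pivot")
  expect_lt(abs(mean(pv$which) - 0.5), 0.02)
})

test_that("pivot move rotates one arm rigidly, pivot residue immobile", {
  x <- stretched_coil(30, seed = 3)
  y <- pivot_move(x, 12, "suffix", axis = c(1, 1, 0), angle = 1.1)
  expect_equal(y[1:12, ], x[1:12, ], tolerance = 0)
  expect_equal(as.matrix(dist(y[13:30, ])), as.matrix(dist(x[13:30, ])),
               tolerance = 1e-10)
  y2 <- pivot_move(x, 1, "suffix", axis = c(0, 0, 1), angle = 0.9)
  expect_equal(y2[1, ], x[1, ], tolerance = 0)     # whole chain minus bead 1 rotates
  expect_false(isTRUE(all.equal(y2[2:30, ], x[2:30, ])))
})

test_that("Metropolis acceptance: downhill always, uphill at exp(-dE)", {
  expect_equal(metropolis_acceptance(-1, 1e4, seed = 1), 1)
  expect_equal(metropolis_acceptance(0, 1e4, seed = 2), 1)
  acc <- metropolis_acceptance(1, 1e5, seed = 3)
  expect_lt(abs(acc - exp(-1)), 0.01)
  # detailed-balance smoke test: acceptance ratio for +dE vs -dE proposals
  for (dE in c(0.5, 2)) {
    a_up <- metropolis_acceptance(dE, 2e5, seed = 11)
    expect_lt(abs(a_up - exp(-dE)), 3 * sqrt(exp(-dE) / 2e5) + 0.003)
  }
})

test_that("trajectories attempt exactly 100 moves per residue per MC time unit", {
  m <- toy_model_cached("knotted", "native_only")
  tr <- run_trajectory(m, quick_config(units = 3, seed = 21))
  expect_equal(sum(tr$attempts), 3 * 100 * 60)
})

test_that("identical seeds give bit-identical trajectories; seeds differ otherwise", {
  m <- toy_model_cached("knotted", "full")
  tr1 <- run_trajectory(m, quick_config(units = 5, seed = 77))
  tr2 <- run_trajectory(m, quick_config(units = 5, seed = 77))
  expect_identical(tr1$snapshots, tr2$snapshots)
  expect_identical(tr1$log, tr2$log)
  tr3 <- run_trajectory(m, quick_config(units = 5, seed = 78))
  expect_false(identical(tr1$final, tr3$final))
})

test_that("incremental energy bookkeeping does not drift over a long run", {
  m <- toy_model_cached("knotted", "full")
  tr <- run_trajectory(m, quick_config(units = 30, seed = 13))
  expect_lt(tr$energy_drift, 1e-4)
})

test_that("the phase switch engages and end moves replace pivots afterwards", {
  m <- toy_model_cached("knotted", "full")
  tr <- run_trajectory(m, quick_config(units = 20, seed = 5))  # forced at 10
  expect_equal(tr$phase_switch_time, 10, tolerance = 0.01)
  expect_gt(tr$attempts[["endpoint"]], 0)
  expect_gt(tr$attempts[["pivot"]], 0)
  # pivots stop at the switch: their share matches ~10% of phase-1 attempts
  expect_lt(tr$attempts[["pivot"]], 0.11 * 10 * 100 * 60)
})

test_that("chain-crossing detection flags a bead dragged through a segment", {
  # bead 2 sweeps through the distant segment between beads 5 and 6
  before <- rbind(c(0, 0, 0), c(1.9, 1, 1), c(3.8, 0, 0), c(20, 0, 0),
                  c(0, 2, 0), c(3.8, 2, 0))
  after <- before
  after[2, ] <- c(1.9, 3, -1)
  expect_true(detect_chain_crossing(before, after, moved = 2))
  # a tiny far-away displacement is clean
  after2 <- before
  after2[4, ] <- after2[4, ] + c(0.01, 0, 0)
  expect_false(detect_chain_crossing(before, after2, moved = 4))
})

test_that("sampled pseudo-angle distribution matches Boltzmann quadrature", {
  p <- forcefield_params()
  th <- sample_angle_distribution(p, n_samples = 5e4, thin = 150, seed = 42)
  breaks <- seq(0, pi, length.out = 26)
  probs <- angle_bin_probs(p, breaks)
  keep <- probs / sum(probs) > 1e-6
  counts <- as.numeric(table(cut(th, breaks)))
  suppressWarnings(ct <- chisq.test(counts[keep], p = probs[keep],
                                    rescale.p = TRUE))
  expect_gt(ct$p.value, 0.01)
})

test_that("ring evolution with the crossing auditor conserves the knot type", {
  ring <- make_closed_torus_knot(48, 2, 3)
  d0 <- alexander_determinants(ring)
  ev <- evolve_ring(ring, n_moves = 2e5, max_disp = 0.5, seed = 97)
  expect_gt(ev$accepted, 1e4)
  expect_identical(alexander_determinants(ev$coords), d0)
})
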