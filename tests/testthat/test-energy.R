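# Potential-energy terms, decomposition, incremental updates, calibration.

test_that("bonded terms: zero at equilibrium bonds, exact harmonic increments", {
  m <- toy_model_cached("knotted", "full")
  b0 <- m$params$bonded$b0
  k <- m$params$bonded$k_bond
  n <- 10
  straight <- cbind(b0 * (seq_len(n) - 1), 0, 0)
  seqv <- rep("A", n)
  cm <- data.frame(i = 1, j = 5, strength = 1, r0 = 4 * b0, class = "sidechain")
  ms <- folding_model(straight, seqv, cm, mode = "native_only", calibrate = FALSE)
  # a perfectly straight chain has undefined dihedrals: the documented
  # behaviour is a zero torsion term plus a warning
  expect_warning(be <- bonded_energy(ms, straight), "collinear")
  expect_equal(be[["bond"]], 0, tolerance = 1e-12)

  # stretch one bond by +0.1 A: the increase is the closed-form quadratic
  stretched <- straight
  stretched[n, 1] <- stretched[n, 1] + 0.1
  expect_warning(be2 <- bonded_energy(ms, stretched), "collinear")
  expect_equal(be2[["bond"]] - be[["bond"]], k * 0.1^2, tolerance = 1e-9)
})

test_that("pseudo-angle double well has minima at the helical and extended angles", {
  p <- forcefield_params()
  th <- seq(0.6, 3.1, by = 2e-3)
  v <- knotfold:::.angle_potential_cpp(th, p$bonded)
  # local minima of the curve
  i <- which(diff(sign(diff(v))) == 2) + 1
  expect_length(i, 2)
  # the soft-min coupling of the two basins shifts the effective minima a
  # little from the nominal equilibrium angles
  expect_lt(abs(th[i[1]] - p$bonded$ang_theta_alpha), 0.15)
  expect_lt(abs(th[i[2]] - p$bonded$ang_theta_beta), 0.15)
  # at each equilibrium angle the term is at its well's minimum level
  expect_lt(v[i[1]] - min(v[abs(th - p$bonded$ang_theta_alpha) < 0.2]), 1e-6)
})

test_that("native 12-10-6 well: minimum -eps at r_native, decay, excluded volume", {
  r0 <- 6; eps <- 2.5
  expect_equal(native_pair_energy(r0, r0, eps), -eps, tolerance = 1e-12)
  # r_native is the global minimum
  r <- seq(3, 30, by = 0.01)
  expect_gte(min(native_pair_energy(r, r0, eps)), -eps - 1e-9)
  expect_lt(abs(native_pair_energy(3 * r0, r0, eps)), 0.05 * eps)
  expect_gt(native_pair_energy(0.5 * r0, r0, eps), 10 * eps)
})

test_that("quasi-chemical pairs: GLU-GLN repulsive, ILE-LEU attractive, decay to zero", {
  p <- forcefield_params()
  sig <- unname((p$diameters["E"] + p$diameters["Q"]) / 2)
  r <- seq(0.7 * sig, 4 * sig, by = 0.05)
  v_eq <- nonnative_pair_energy(r, "GLU", "GLN", p)
  expect_true(all(v_eq >= -1e-12))

  sig_il <- unname((p$diameters["I"] + p$diameters["L"]) / 2)
  eps_il <- nonnative_eps_matrix(p)["I", "L"]
  expect_lt(eps_il, 0)
  v_il <- nonnative_pair_energy(sig_il, "ILE", "LEU", p)
  expect_equal(v_il, -abs(eps_il), tolerance = 1e-12)
  expect_lt(abs(nonnative_pair_energy(50, "ILE", "LEU", p)), 1e-4)
  expect_lt(abs(nonnative_pair_energy(50, "GLU", "GLN", p)), 1e-4)
})

test_that("screened electrostatics: sign rule, closed form at the Debye length", {
  p <- forcefield_params()
  expect_identical(electrostatic_pair_energy(5, 0, 1, p), 0)
  lD <- p$debye_length
  expect_equal(electrostatic_pair_energy(lD, 1, 1, p),
               p$dh_prefactor / lD * exp(-1), tolerance = 1e-12)
  r <- c(3, 8, 20)
  expect_true(all(electrostatic_pair_energy(r, 1, -1, p) < 0))
  expect_true(all(electrostatic_pair_energy(r, -1, -1, p) > 0))
})

test_that("total energy decomposes exactly and matches a brute-force pair-sum oracle", {
  m <- toy_model_cached("knotted", "full")
  set.seed(42)
  x <- toy_knotted()$coords + matrix(rnorm(180, sd = 0.2), ncol = 3)
  e <- total_energy(m, x)
  expect_equal(e[["total"]],
               e[["bonded"]] + e[["native"]] + e[["nonnative"]] + e[["electrostatic"]],
               tolerance = 1e-9)

  # independent R-level oracle for the non-bonded components
  p <- m$params
  emat <- nonnative_eps_matrix(p)
  cmk <- paste(m$contact_map$i, m$contact_map$j)
  en <- enn <- eel <- 0
  n <- nrow(x)
  chg <- unname(p$charges[m$sequence])
  for (i in seq_len(n - 3)) for (j in seq(i + 3, n)) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    key <- paste(i, j)
    if (key %in% cmk) {
      row <- m$contact_map[match(key, cmk), ]
      z <- row$r0 / r
      en <- en + row$strength * (13 * z^12 - 18 * z^10 + 4 * z^6)
    } else {
      sig <- unname((p$diameters[m$sequence[i]] + p$diameters[m$sequence[j]]) / 2)
      if (r < 3 * sig) {
        epsn <- emat[m$sequence[i], m$sequence[j]]
        z <- sig / r
        lj <- z^12 - 2 * z^6
        enn <- enn + if (epsn < 0) -epsn * lj
          else if (r < sig) epsn * lj + 2 * epsn else -epsn * lj
      }
    }
    if (chg[i] * chg[j] != 0 && r <= 4 * p$debye_length)
      eel <- eel + p$dh_prefactor * chg[i] * chg[j] * exp(-r / p$debye_length) / r
  }
  expect_equal(e[["native"]], en, tolerance = 1e-8)
  expect_equal(e[["nonnative"]], enn, tolerance = 1e-8)
  expect_equal(e[["electrostatic"]], eel, tolerance = 1e-8)
})

test_that("native-only mode zeroes electrostatics and non-native attraction", {
  mk <- toy_model_cached("knotted", "native_only")
  x <- toy_knotted()$coords
  e <- total_energy(mk, x)
  expect_identical(e[["electrostatic"]], 0)
  expect_gte(e[["nonnative"]], 0)  # pure excluded-volume repulsion
  # at the native structure all contacts sit at their minima
  expect_equal(e[["native"]], -sum(mk$contact_map$strength), tolerance = 1e-6)
})

test_that("local energy delta matches full recomputation for all move classes", {
  m <- toy_model_cached("knotted", "full")
  x <- stretched_coil(60, m$params, seed = 9)
  full_delta <- function(x2) total_energy(m, x2)[["total"]] - total_energy(m, x)[["total"]]

  # null move
  d0 <- local_energy_delta(m, x, x[17, , drop = FALSE], 17, 17)
  expect_equal(d0[["total"]], 0, tolerance = 1e-12)

  # single-bead displacement
  x1 <- x; x1[17, ] <- x1[17, ] + c(0.15, -0.05, 0.02)
  d1 <- local_energy_delta(m, x, x1[17, , drop = FALSE], 17, 17)
  expect_equal(d1[["total"]], full_delta(x1), tolerance = 1e-8)

  # crankshaft
  x2 <- crankshaft_move(x, 30, 0.3)
  d2 <- local_energy_delta(m, x, x2[30, , drop = FALSE], 30, 30)
  expect_equal(d2[["total"]], full_delta(x2), tolerance = 1e-8)

  # rigid pivot of a long suffix
  x3 <- pivot_move(x, 20, "suffix", c(0.2, 0.9, -0.4), 0.8)
  d3 <- local_energy_delta(m, x, x3[21:60, ], 21, 60)
  expect_equal(d3[["total"]], full_delta(x3), tolerance = 1e-8)

  # rigid endpoint rotation
  x4 <- endpoint_move(x, "C", c(1, 0.2, 0.1), 0.5)
  d4 <- local_energy_delta(m, x, x4[52:60, ], 52, 60)
  expect_equal(d4[["total"]], full_delta(x4), tolerance = 1e-8)
})

test_that("overlapping beads are rejected as unphysical", {
  m <- toy_model_cached("knotted", "full")
  x <- toy_knotted()$coords
  x[40, ] <- x[10, ] + c(0.05, 0, 0)
  expect_error(total_energy(m, x), "overlap")
})

test_that("non-native calibration: ratio exactly 0.1, linear in native strengths", {
  toy <- toy_knotted()
  p <- forcefield_params()
  pc <- calibrate_nonnative_scale(p, toy$contact_map, toy$sequence)

  ratio_of <- function(params, cm, seqv) {
    emat <- abs(nonnative_eps_matrix(params))
    n <- length(seqv)
    prs <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 3), arr.ind = TRUE)
    keep <- !(paste(prs[, 1], prs[, 2]) %in% paste(cm$i, cm$j))
    prs <- prs[keep, , drop = FALSE]
    mean(emat[cbind(seqv[prs[, 1]], seqv[prs[, 2]])]) / mean(cm$strength)
  }
  expect_equal(ratio_of(pc, toy$contact_map, toy$sequence), 0.1, tolerance = 1e-12)

  # doubling native strengths doubles the calibrated prefactor
  cm2 <- toy$contact_map; cm2$strength <- 2 * cm2$strength
  pc2 <- calibrate_nonnative_scale(p, cm2, toy$sequence)
  expect_equal(pc2$lambda, 2 * pc$lambda, tolerance = 1e-12)

  # degenerate single-residue-type homopolymer still calibrates exactly
  seq_homo <- rep("L", length(toy$sequence))
  pch <- calibrate_nonnative_scale(p, toy$contact_map, seq_homo)
  expect_equal(ratio_of(pch, toy$contact_map, seq_homo), 0.1, tolerance = 1e-12)
})

test_that("electrostatic segment energies are much smaller than quasi-chemical ones", {
  m <- toy_model_cached("knotted", "full")
  set.seed(7)
  vals <- replicate(10, {
    x <- toy_knotted()$coords + matrix(rnorm(180, sd = 0.3), ncol = 3)
    c(abs(segment_interaction_energy(m, x, 49:60, "electrostatic")),
      abs(segment_interaction_energy(m, x, 49:60, "nonnative")))
  })
  expect_lte(mean(vals[1, ]), 0.1 * mean(vals[2, ]))
})
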