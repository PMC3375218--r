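# Ensemble observables and their invariants.

test_that("gyration radius: closed forms and brute-force agreement", {
  expect_equal(gyration_radius(matrix(c(1, 2, 3), 1, 3)), 0)
  d <- 7.4
  expect_equal(gyration_radius(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  set.seed(5)
  x <- matrix(rnorm(300), 100, 3)
  ctr <- colMeans(x)
  oracle <- sqrt(mean(rowSums((x - matrix(ctr, 100, 3, byrow = TRUE))^2)))
  expect_equal(gyration_radius(x), oracle, tolerance = 1e-10)
})

test_that("fraction of native contacts uses a strict 7.5 A criterion", {
  cm <- data.frame(i = c(1, 1), j = c(4, 5), strength = 1)
  x <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.5, 3, 0), c(20, 0, 0))
  x[4, ] <- c(7.5, 0, 0)   # pair (1,4) at exactly the threshold
  expect_equal(fraction_native_contacts(x, cm), 0)   # 7.5 is not < 7.5
  x[4, ] <- c(7.499, 0, 0)
  expect_equal(fraction_native_contacts(x, cm), 0.5)
  # native toy: every contact formed by construction of the map
  toy <- toy_knotted()
  expect_gte(fraction_native_contacts(toy$coords, toy$contact_map), 0.95)
  # stretched chain: nothing formed
  m <- toy_model_cached("knotted", "full")
  expect_lt(fraction_native_contacts(stretched_coil(60, m$params, 1),
                                     toy$contact_map), 0.05)
})

test_that("class-restricted Q reports absent classes as NA, not 0/0", {
  toy <- toy_knotted()
  ss <- factor(rep("helix", 60), levels = c("helix", "strand", "coil"))
  f <- ss_contact_fractions(toy$coords, toy$contact_map, ss)
  expect_equal(unname(f["helix"]), 1)
  expect_true(is.na(f["sheet"]))
  ss2 <- factor(rep("coil", 60), levels = c("helix", "strand", "coil"))
  f2 <- ss_contact_fractions(toy$coords, toy$contact_map, ss2)
  expect_true(all(is.na(f2)))
})

test_that("segment interaction energy vanishes for the whole chain", {
  m <- toy_model_cached("knotted", "full")
  expect_identical(segment_interaction_energy(m, toy_knotted()$coords, 1:60,
                                              "nonnative"), 0)
  expect_identical(segment_interaction_energy(m, toy_knotted()$coords, 1:60,
                                              "electrostatic"), 0)
})

test_that("hydrophilic-substituted C-terminus shifts its non-native energy upward", {
  toy <- toy_knotted()
  mut <- make_mutant_sequence(toy, "hydrophilic_cterm", 12)
  m_wt <- toy_model_cached("knotted", "full")
  m_mut <- toy_model(mut, "full")
  set.seed(11)
  shift <- replicate(8, {
    x <- toy$coords + matrix(rnorm(180, sd = 0.4), ncol = 3)
    segment_interaction_energy(m_mut, x, 49:60, "nonnative") -
      segment_interaction_energy(m_wt, x, 49:60, "nonnative")
  })
  expect_gt(mean(shift), 0)  # less attractive / more repulsive than wild type
})

test_that("windowed knotting probability equals the pooled indicator mean", {
  mk_ass <- function(times, labels) data.frame(time = times, label = labels,
                                               consensus = 1, proper = TRUE,
                                               core_first = NA, core_last = NA,
                                               chirality = "n/a")
  a1 <- mk_ass(c(10, 30, 110, 130), c("unknot", "trefoil_3_1", "unknot", "unknot"))
  a2 <- mk_ass(c(20, 40, 120, 140), c("trefoil_3_1", "unknot", "trefoil_3_1", "unknot"))
  kp <- knotting_probability_series(list(a1, a2), window = 100)
  expect_equal(kp$mean, c(2 / 4, 1 / 4))
  expect_equal(kp$n, c(4, 4))
  # invariant to trajectory ordering
  kp2 <- knotting_probability_series(list(a2, a1), window = 100)
  expect_equal(kp$mean, kp2$mean)
  # all-unknot stream is identically zero
  kp3 <- knotting_probability_series(mk_ass(c(5, 15), c("unknot", "unknot")))
  expect_true(all(kp3$mean == 0))
  # alternating labels give 0.5 per window
  kp4 <- knotting_probability_series(
    mk_ass(seq(5, 95, by = 10), rep(c("trefoil_3_1", "unknot"), 5)), window = 100)
  expect_equal(kp4$mean, 0.5)
})

test_that("ensemble series have SEM = sd/sqrt(n) and honour the time grid", {
  m <- toy_model_cached("knotted", "native_only")
  trs <- lapply(1:3, function(s) run_trajectory(m, quick_config(units = 5, seed = s)))
  es <- ensemble_series(trs, "Rg")
  vals <- sapply(trs, function(tr) tr$log$Rg[3])
  expect_equal(es$mean[3], mean(vals))
  expect_equal(es$sem[3], sd(vals) / sqrt(3))
  expect_true(all(diff(es$time) > 0))
  # single trajectory: SEM reported absent
  es1 <- ensemble_series(trs[1], "Q")
  expect_true(all(is.na(es1$sem)))
})

test_that("snapshot streams round-trip through XYZ with logged observables intact", {
  m <- toy_model_cached("knotted", "full")
  tr <- run_trajectory(m, quick_config(units = 10, seed = 31))
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  back <- read_xyz(f)
  expect_equal(back$times, tr$snapshot_times)
  expect_equal(back$snapshots[[2]], tr$snapshots[[2]], tolerance = 1e-4)
  # Q and Rg recomputed from the stream match the online log at snap times
  for (k in seq_along(back$snapshots)) {
    t <- back$times[k]
    row <- which(abs(tr$log$time - t) < 1e-9)
    if (length(row)) {
      expect_equal(gyration_radius(back$snapshots[[k]]), tr$log$Rg[row],
                   tolerance = 1e-3)
      expect_equal(fraction_native_contacts(back$snapshots[[k]], m$contact_map),
                   tr$log$Q[row], tolerance = 1e-3)
    }
  }
})
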