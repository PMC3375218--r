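# Campaign orchestration, aggregation, reporting, and file round-trips.

test_that("campaigns are reproducible from the manifest seeds", {
  m <- toy_model_cached("knotted", "native_only")
  c1 <- run_campaign(m, quick_config(units = 4), n_trajectories = 2, base_seed = 55)
  c2 <- run_campaign(m, quick_config(units = 4), n_trajectories = 2, base_seed = 55)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$trajectories[[1]]$log, c2$trajectories[[1]]$log)
  expect_identical(c1$trajectories[[2]]$snapshots, c2$trajectories[[2]]$snapshots)
  expect_equal(c1$manifest$seed, c(56, 57))
  expect_true(all(c1$manifest$status == "completed"))
})

test_that("campaign outputs are written once and protected from overwriting", {
  m <- toy_model_cached("knotted", "native_only")
  dir <- file.path(tempdir(), "kf_campaign_test")
  on.exit(unlink(dir, recursive = TRUE))
  run_campaign(m, quick_config(units = 2), n_trajectories = 1, base_seed = 1,
               output_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "traj_001.tsv")))
  expect_true(file.exists(file.path(dir, "traj_001.xyz")))
  expect_error(run_campaign(m, quick_config(units = 2), n_trajectories = 1,
                            base_seed = 1, output_dir = dir), "overwrite")
  expect_silent_ish <- run_campaign(m, quick_config(units = 2), n_trajectories = 1,
                                    base_seed = 1, output_dir = dir,
                                    overwrite = TRUE)
  # report numbers recomputable from the raw TSV log
  logged <- read.delim(file.path(dir, "traj_001.tsv"))
  expect_equal(logged$Q, expect_silent_ish$trajectories[[1]]$log$Q,
               tolerance = 1e-9)
})

test_that("aggregation: absent SEM for one trajectory, zero for duplicated seeds", {
  m <- toy_model_cached("knotted", "native_only")
  tr <- run_trajectory(m, quick_config(units = 3, seed = 9))
  es <- ensemble_series(list(tr), "Rg")
  expect_true(all(is.na(es$sem)))
  es2 <- ensemble_series(list(tr, tr), "Rg")
  expect_true(all(es2$sem == 0))
})

test_that("subsampling half the trajectories stays within sampling error", {
  m <- toy_model_cached("knotted", "native_only")
  camp <- run_campaign(m, quick_config(units = 4), n_trajectories = 6, base_seed = 7)
  full <- aggregate_observables(camp, "Rg")$Rg
  half <- ensemble_series(camp$trajectories[c(1, 3, 5)], "Rg")
  n <- nrow(full)
  tol <- 2 * sqrt(full$sem[n]^2 + half$sem[n]^2) + 1e-9
  expect_lt(abs(full$mean[n] - half$mean[n]), max(tol, 2 * full$sem[n]))
})

test_that("the comparative report flags negligible vs elevated knotting", {
  mk <- toy_model_cached("knotted", "full")
  mn <- toy_model_cached("knotted", "native_only")
  ck <- run_campaign(mk, quick_config(units = 6), n_trajectories = 2, base_seed = 11,
                     label = "full")
  cn <- run_campaign(mn, quick_config(units = 6), n_trajectories = 2, base_seed = 11,
                     label = "native_only")
  rep <- compare_potentials_report(list(full = ck, native = cn), window = 3,
                                   n_closures = 20, seed = 5)
  expect_s3_class(rep, "potential_comparison")
  expect_named(rep$campaigns, c("full", "native"))
  expect_true(all(vapply(rep$campaigns, function(p)
    is.finite(p$max_window_probability), logical(1))))
  out <- capture.output(print(rep))
  expect_true(any(grepl("Comparative knotting-propensity report", out)))
})

test_that("model archives round-trip sequence, coordinates, contacts, residues", {
  m <- toy_model_cached("knotted", "full")
  f <- tempfile(fileext = ".txt")
  write_model_archive(m, f)
  back <- read_model_archive(f)
  expect_identical(back$sequence, m$sequence)
  expect_equal(back$coords, unclass(m$coords), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(back$contact_map$i, m$contact_map$i)
  expect_equal(back$contact_map$strength, m$contact_map$strength, tolerance = 1e-5)
  expect_equal(back$residues$charge,
               unname(m$params$charges[m$sequence]))
  # archive rebuilds into a working model
  m2 <- folding_model(back$coords, back$sequence, back$contact_map,
                      mode = "full")
  expect_equal(total_energy(m2, back$coords)[["native"]],
               total_energy(m, m$coords)[["native"]], tolerance = 0.1)
})
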