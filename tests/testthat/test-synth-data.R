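# Ground-truth generator: determinism, amount arithmetic, scenario rules.

test_that("the same seed reproduces a run exactly", {
  a <- challenge_amounts()
  r1 <- simulate_run(a, noise_cv = 0.05, seed = 99, run_id = "d")
  r2 <- simulate_run(a, noise_cv = 0.05, seed = 99, run_id = "d")
  expect_identical(r1$spectra, r2$spectra)
  expect_identical(attr(r1, "truth"), attr(r2, "truth"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tsv_run(r1, f1); write_tsv_run(r2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical on disk
  r3 <- simulate_run(a, noise_cv = 0.05, seed = 100, run_id = "d")
  expect_false(identical(r1$spectra, r3$spectra))
})

test_that("zero-amount species leave no centroids beyond background", {
  run <- simulate_run(c("32:6" = 1e-11, "34:6" = 0), noise_cv = 0,
                      background_per_scan = 0, seed = 1)
  allmz <- unlist(lapply(run$spectra, `[[`, "mz"))
  w <- ppm_window(mz_deprotonated("34:6"), 50)
  expect_false(any(allmz >= w[1] & allmz <= w[2]))
  # present species and the always-spiked IS do leave centroids
  w326 <- ppm_window(mz_deprotonated("32:6"), 50)
  expect_true(any(allmz >= w326[1] & allmz <= w326[2]))
  wIS <- ppm_window(mz_deprotonated("21:5"), 50)
  expect_true(any(allmz >= wIS[1] & allmz <= wIS[2]))
})

test_that("background centroids avoid every target window", {
  run <- simulate_run(c("32:6" = 1e-11), noise_cv = 0,
                      background_per_scan = 30, seed = 2)
  panel <- default_panel()
  allmz <- unlist(lapply(run$spectra, `[[`, "mz"))
  # anything inside a 5 ppm window must be a target species, not background
  for (tmz in unique(panel$mz)) {
    w <- ppm_window(tmz, 5)
    hits <- allmz[allmz >= w[1] & allmz <= w[2]]
    if (length(hits)) expect_lt(max(abs(hits / tmz - 1)) * 1e6, 2.001)
  }
})

test_that("nearly co-eluting isomers trigger the unresolvable warning", {
  expect_warning(
    simulate_run(c("22:5 (1)" = 1e-11, "22:5 (2)" = 1e-11), seed = 3,
                 background_per_scan = 0),
    "closer than 3 sigma")
})

test_that("scenario arithmetic follows the dose and knockdown rules", {
  cfg <- scenario_config("pos_challenge", pos_per_cell = c(0, 10, 20, 40))
  exp <- suppressWarnings(simulate_experiment(cfg, n_replicates = 1,
                                              seed = 21))
  tr <- exp$truth
  m <- tr[tr$species_label == "34:6", ]
  m <- m[order(as.numeric(sub("dose_", "", m$condition))), ]
  # dose 0 carries no marker; 10/20/40 sit in exact 1:2:4 ratio
  expect_false("dose_0" %in% m$condition)
  expect_equal(m$amount_mol / m$amount_mol[1], c(1, 2, 4))
  expect_equal(m$amount_mol[1],
               10 * cfg$n_cells * 2.01e-15 * cfg$uptake_fraction)

  kd <- scenario_config("knockdown", pos_per_cell = 10,
                        knockdown_effect = 0.82)
  ekd <- suppressWarnings(simulate_experiment(kd, n_replicates = 1,
                                              seed = 22))
  t2 <- ekd$truth
  for (mk in default_markers()) {
    ctrl <- t2$amount_mol[t2$condition == "control" & t2$species_label == mk]
    drop <- t2$amount_mol[t2$condition == "triple_kd" &
                            t2$species_label == mk]
    expect_equal(drop / ctrl, 0.18, tolerance = 1e-12)
  }

  expect_error(scenario_config("not_a_scenario"))
})

test_that("untreated RPE carries no species of 30 or more carbons", {
  cfg <- scenario_config("untreated_rpe")
  exp <- suppressWarnings(simulate_experiment(cfg, n_replicates = 2,
                                              seed = 23))
  carbons <- vapply(exp$truth$species_label,
                    function(l) parse_species(l)$carbons, integer(1))
  expect_true(all(carbons[exp$truth$species_label != "21:5 (IS)"] < 30))
})

test_that("calibration series converts nmol/L levels to moles", {
  cfg <- scenario_config("calibration_series",
                         calibration_levels = c(50, 1000))
  exp <- simulate_experiment(cfg, n_replicates = 1, seed = 24)
  tr <- exp$truth[exp$truth$species_label == "32:6", ]
  expect_equal(sort(tr$amount_mol), c(50, 1000) * 1e-9 * 1e-3)
})

test_that("experiments are reproducible and write a complete bundle", {
  cfg <- scenario_config("pos_challenge", pos_per_cell = c(0, 20),
                         noise_cv = 0.05)
  e1 <- suppressWarnings(simulate_experiment(cfg, n_replicates = 2, seed = 9))
  e2 <- suppressWarnings(simulate_experiment(cfg, n_replicates = 2, seed = 9))
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$runs[[1]]$spectra, e2$runs[[1]]$spectra)

  dir <- withr::local_tempdir()
  write_experiment(e1, dir)
  expect_equal(length(list.files(dir, pattern = "_rep[0-9]+\\.tsv$")), 4L)
  expect_true(file.exists(file.path(dir, "design.tsv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 9L)
  expect_equal(truth$scenario, "pos_challenge")
})
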