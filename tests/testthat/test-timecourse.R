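test_that("a single noiseless replicate reports the truth with zero SEM", {
  cfg <- scenario_config("control", seed = 1, n_replicates = 1,
                         noise = no_noise())
  sets <- generate_calibration_sets(cfg)
  calib <- estimate_calibration(sets$reduced, sets$oxidized)
  img <- generate_image_set(cfg, 0, 1)
  tc <- run_redox_timecourse(list(img), calib, cfg$constants)
  truth <- cfg$truth_oxd[cfg$truth_oxd$time_h == 0, ]
  for (comp in c("nucleus", "cytosol")) {
    expect_equal(grand_value(tc, comp),
                 100 * truth$oxd[truth$compartment == comp],
                 tolerance = 1e-9)
    expect_equal(grand_value(tc, comp, "oxd_sem_pct"), 0)
    expect_equal(grand_value(tc, comp, "e_mean_mV"),
                 truth$e_probe_mV[truth$compartment == comp],
                 tolerance = 1e-6)
  }
})

test_that("noiseless end-to-end recovery is exact across the time course", {
  cfg <- scenario_config("hc", seed = 2, n_replicates = 1,
                         timepoints_h = c(0, 2, 12, 24), noise = no_noise())
  sets <- generate_calibration_sets(cfg)
  calib <- estimate_calibration(sets$reduced, sets$oxidized)
  imgs <- lapply(cfg$timepoints_h, function(tp) generate_image_set(cfg, tp, 1))
  tc <- run_redox_timecourse(imgs, calib, cfg$constants)
  joined <- dplyr::inner_join(tc$measurements, cfg$truth_oxd,
                              by = c("compartment", "time_h"),
                              suffix = c("_est", "_truth"))
  expect_equal(joined$oxd_est, joined$oxd_truth, tolerance = 1e-9)
})

test_that("default-noise recovery over five replicates is within 1.5 points", {
  cfg <- scenario_config("hu", seed = 4, n_replicates = 5,
                         timepoints_h = c(8))
  sets <- generate_calibration_sets(cfg)
  calib <- estimate_calibration(sets$reduced, sets$oxidized)
  imgs <- lapply(1:5, function(r) generate_image_set(cfg, 8, r))
  tc <- run_redox_timecourse(imgs, calib, cfg$constants)
  truth <- cfg$truth_oxd[cfg$truth_oxd$time_h == 8, ]
  for (comp in c("nucleus", "cytosol")) {
    expect_lt(abs(grand_value(tc, comp) -
                    100 * truth$oxd[truth$compartment == comp]), 1.5)
  }
})

test_that("aggregation averages per-replicate potentials, not the reverse", {
  cfg <- scenario_config("control", seed = 6, n_replicates = 4,
                         timepoints_h = c(0))
  sets <- generate_calibration_sets(cfg)
  calib <- estimate_calibration(sets$reduced, sets$oxidized)
  imgs <- lapply(1:4, function(r) generate_image_set(cfg, 0, r))
  tc <- run_redox_timecourse(imgs, calib, cfg$constants)
  meas <- tc$measurements[tc$measurements$compartment == "nucleus", ]
  expect_equal(grand_value(tc, "nucleus", "e_mean_mV"),
               mean(meas$e_probe_mV))
  # not the potential of the mean oxidation (Jensen gap)
  e_of_mean <- compute_e_probe(mean(meas$oxd), cfg$constants)
  expect_false(isTRUE(all.equal(grand_value(tc, "nucleus", "e_mean_mV"),
                                e_of_mean, tolerance = 1e-9)))
})

test_that("the pipeline refuses to run without a calibration", {
  cfg <- scenario_config("control", seed = 1, n_replicates = 1)
  img <- generate_image_set(cfg, 0, 1)
  expect_error(run_redox_timecourse(list(img)), "calibration")
  expect_error(run_redox_timecourse(list(img), calib = "nope"), "calibration")
})

test_that("tidy, glance and autoplot expose the fitted time course", {
  res <- run_scenario_pipeline("control", seed = 1, n_replicates = 2,
                               timepoints_h = c(0, 12))
  tc <- res$timecourse
  expect_s3_class(tidy(tc), "tbl_df")
  expect_equal(nrow(tidy(tc)), 2 * 2 * 2) # compartment x timepoint x replicate
  gl <- glance(tc)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("oxd_mean_pct_nucleus", "oxd_mean_pct_cytosol") %in%
                    names(gl)))
  expect_s3_class(autoplot(tc), "ggplot")
})
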