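test_that("default scenario truths reproduce the study's reported values", {
  # Table-1 grand means (OxD fraction and potential), per compartment
  anchors <- list(
    control = list(nucleus = c(0.2290, -296.8), cytosol = c(0.2631, -294.1)),
    hc = list(nucleus = c(0.3122, -291.4), cytosol = c(0.3248, -289.6)),
    hu = list(nucleus = c(0.2135, -297.4), cytosol = c(0.2444, -295.2))
  )
  for (sc in names(anchors)) {
    cfg <- scenario_config(sc, seed = 1)
    for (comp in c("nucleus", "cytosol")) {
      tr <- cfg$truth_oxd[cfg$truth_oxd$compartment == comp, ]
      expect_equal(mean(tr$oxd), anchors[[sc]][[comp]][1], tolerance = 1e-6,
                   label = sprintf("%s %s mean OxD", sc, comp))
      expect_equal(mean(tr$e_probe_mV), anchors[[sc]][[comp]][2],
                   tolerance = 1e-6,
                   label = sprintf("%s %s mean E", sc, comp))
    }
  }
  # pinned 2 h cytosolic oxidation of the treated scenarios
  hc <- scenario_config("hc", seed = 1)$truth_oxd
  expect_equal(hc$oxd[hc$compartment == "cytosol" & hc$time_h == 2], 0.37)
  hu <- scenario_config("hu", seed = 1)$truth_oxd
  expect_equal(hu$oxd[hu$compartment == "cytosol" & hu$time_h == 2], 0.32)
})

test_that("truth trajectories are valid fractions and Nernst-consistent", {
  for (sc in c("control", "hc", "hu")) {
    cfg <- scenario_config(sc, seed = 1)
    tr <- cfg$truth_oxd
    expect_true(all(tr$oxd > 0 & tr$oxd < 1))
    # stored potential must equal the Nernst transform of the stored OxD
    expect_equal(tr$e_probe_mV,
                 compute_e_probe(tr$oxd, cfg$constants),
                 tolerance = 1e-9)
  }
})

test_that("phase-fraction truths are simplex-valued and match the study", {
  cfg <- scenario_config("control", seed = 1)
  ph <- cfg$truth_phases
  expect_equal(ph$g1 + ph$s + ph$g2, rep(1, nrow(ph)), tolerance = 1e-9)
  expect_equal(unlist(ph[ph$time_h == 0, c("g1", "s", "g2")]),
               c(g1 = 0.67, s = 0.08, g2 = 0.25))
  hc <- scenario_config("hc", seed = 1)$truth_phases
  expect_equal(hc$g1[hc$time_h == 24], 0.55)
  expect_equal(hc$g1 + hc$s + hc$g2, rep(1, nrow(hc)), tolerance = 1e-9)
})

test_that("growth truths carry the reported control and release rates", {
  ctrl <- scenario_config("control", seed = 1)$truth_growth
  expect_equal(ctrl$rate_mm_d, c(1.4, 1.7))
  hc <- scenario_config("hc", seed = 1)$truth_growth
  expect_equal(hc$rate_mm_d[1] / ctrl$rate_mm_d[1], 0.45)
  hu <- scenario_config("hu", seed = 1)$truth_growth
  expect_equal(hu$rate_mm_d[1] / ctrl$rate_mm_d[1], 0.72)
})

test_that("configuration validation rejects bad noise and calibration", {
  expect_error(sim_noise(background = -1), "non-negative")
  expect_error(sim_noise(debris_frac = 1.2), "< 1")
  expect_error(scenario_config("control", noise = list(a = 1)), "sim_noise")
  expect_error(
    scenario_config("control",
                    calibration_truth = list(r_red = 2, r_ox = 0.2, k = 0.5)),
    "calibration truth"
  )
})

test_that("scenario configs survive a YAML round trip", {
  cfg <- scenario_config("hc", seed = 7, n_replicates = 2,
                         timepoints_h = c(0, 2, 4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_equal(back$truth_oxd, cfg$truth_oxd)
  expect_equal(back$seed, cfg$seed)
  expect_equal(unclass(back$noise), unclass(cfg$noise))
  # a rebuilt config generates identical data
  expect_identical(generate_image_set(back, 2, 1),
                   generate_image_set(cfg, 2, 1))
})
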