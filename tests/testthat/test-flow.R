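ctrl_cfg <- scenario_config("control", seed = 1)

test_that("event counts per phase match the requested fractions exactly", {
  ev <- generate_flow_events(ctrl_cfg, 0, n_events = 10000)
  comp <- table(ev$.component)
  n_debris <- round(0.02 * 10000)
  n_nuc <- 10000 - n_debris
  expect_equal(unname(comp[["debris"]]), n_debris)
  # largest-remainder apportionment of 67/8/25
  expect_equal(unname(comp[["G1"]]), round(0.67 * n_nuc))
  expect_equal(unname(comp[["S"]]), round(0.08 * n_nuc))
  expect_equal(unname(comp[["G2"]]), round(0.25 * n_nuc))
  expect_true(all(ev$dna_fl > 0))
})

test_that("generation is deterministic and respects the scenario truth", {
  a <- generate_flow_events(ctrl_cfg, 5, n_events = 2000)
  b <- generate_flow_events(ctrl_cfg, 5, n_events = 2000)
  expect_identical(a, b)
  expect_error(generate_flow_events(ctrl_cfg, 3), "no phase fractions")
})

test_that("noiseless G2 events sit at exactly twice the G1 position", {
  cfg0 <- scenario_config("control", seed = 1, noise = no_noise())
  ev <- generate_flow_events(cfg0, 0, n_events = 5000)
  g1 <- ev$dna_fl[ev$.component == "G1"]
  g2 <- ev$dna_fl[ev$.component == "G2"]
  expect_equal(unique(g1), 200)
  expect_equal(unique(g2), 400)
})

test_that("degenerate single-population samples collapse to one peak", {
  cfg <- scenario_config("control", seed = 1,
                         noise = sim_noise(flow_cv = 1e-4, debris_frac = 0))
  cfg$truth_phases$g1 <- 1
  cfg$truth_phases$s <- 0
  cfg$truth_phases$g2 <- 0
  ev <- generate_flow_events(cfg, 0, n_events = 5000)
  expect_lt(max(abs(ev$dna_fl - 200)), 1)
  fit <- suppressWarnings(fit_phases(gate_debris(ev)))
  expect_gte(fit$g1, 0.99)
})

test_that("two equal peaks yield equal masses at mu and 2 mu", {
  cfg <- scenario_config("control", seed = 2,
                         noise = sim_noise(debris_frac = 0))
  cfg$truth_phases$g1 <- 0.5
  cfg$truth_phases$s <- 0
  cfg$truth_phases$g2 <- 0.5
  ev <- generate_flow_events(cfg, 0, n_events = 50000)
  # count events within 3 CV of each center: each should hold ~ half
  near_g1 <- mean(abs(ev$dna_fl - 200) <= 3 * 0.05 * 200)
  near_g2 <- mean(abs(ev$dna_fl - 400) <= 3 * 0.05 * 400)
  expect_equal(near_g1, 0.5, tolerance = 0.02)
  expect_equal(near_g2, 0.5, tolerance = 0.02)
  fit <- fit_phases(gate_debris(ev))
  expect_lt(abs(fit$g1 - 0.5), 0.02)
  expect_lt(abs(fit$g2 - 0.5), 0.02)
})

test_that("debris gating removes close to the true debris fraction", {
  ev <- generate_flow_events(ctrl_cfg, 0, n_events = 50000)
  gated <- gate_debris(ev)
  rejected_frac <- attr(gated, "n_rejected") / attr(gated, "n_input")
  expect_lt(abs(rejected_frac - 0.02), 0.01)
  # conservation: gated + rejected = input
  expect_equal(nrow(gated) + attr(gated, "n_rejected"), nrow(ev))
  expect_error(gate_debris(ev[0, ]), "empty")
})

test_that("noiseless debris-free samples are classified without error", {
  cfg0 <- scenario_config("control", seed = 1, noise = no_noise())
  ev <- generate_flow_events(cfg0, 0, n_events = 5000)
  gated <- gate_debris(ev)
  expect_equal(attr(gated, "n_rejected"), 0L)
  fit <- fit_phases(gated)
  truth <- table(ev$.component) / nrow(ev)
  # oracle equivalence: every event classified by its generating component
  expect_equal(fit$g1, unname(truth[["G1"]]))
  expect_equal(fit$s, unname(truth[["S"]]))
  expect_equal(fit$g2, unname(truth[["G2"]]))
})

test_that("phase fractions are scale-equivariant and sum to one", {
  ev <- generate_flow_events(ctrl_cfg, 0, n_events = 30000)
  fit1 <- fit_phases(gate_debris(ev))
  expect_equal(fit1$g1 + fit1$s + fit1$g2, 1, tolerance = 1e-9)
  for (c_mult in c(0.3, 7)) {
    ev2 <- ev
    ev2$dna_fl <- ev2$dna_fl * c_mult
    fit2 <- fit_phases(gate_debris(ev2))
    expect_equal(c(fit2$g1, fit2$s, fit2$g2), c(fit1$g1, fit1$s, fit1$g2),
                 tolerance = 1e-9)
  }
})

test_that("phase recovery error stays within two points across seeds", {
  errs <- sapply(1:20, function(seed) {
    cfg <- scenario_config("control", seed = seed)
    ev <- generate_flow_events(cfg, 0, n_events = 1e5)
    fit <- fit_phases(gate_debris(ev))
    abs(c(fit$g1, fit$s, fit$g2) - c(0.67, 0.08, 0.25))
  })
  expect_lte(mean(errs[1, ]), 0.02)
  expect_lte(mean(errs[2, ]), 0.02)
  expect_lte(mean(errs[3, ]), 0.02)
})

test_that("missing G2 population triggers the degraded mode with a flag", {
  cfg <- scenario_config("control", seed = 3,
                         noise = sim_noise(debris_frac = 0))
  cfg$truth_phases$g1 <- 0.97
  cfg$truth_phases$s <- 0.03
  cfg$truth_phases$g2 <- 0
  ev <- generate_flow_events(cfg, 0, n_events = 20000)
  fit <- suppressWarnings(fit_phases(gate_debris(ev)))
  # either a spurious tiny G2 mode is found or the degraded path is taken
  expect_gte(fit$g1, 0.9)
})

test_that("the phase time course aggregates replicates and compares groups", {
  cfg <- scenario_config("hc", seed = 1)
  tables <- list()
  for (tp in c(0, 24)) {
    for (rep in 1:3) {
      tables[[length(tables) + 1L]] <-
        generate_flow_events(cfg, tp, n_events = 20000, replicate = rep)
    }
  }
  pt <- phase_timecourse(tables)
  expect_equal(nrow(pt$fractions), 6)
  expect_equal(pt$summary$n, c(3, 3))
  # G1 fraction falls from 0.67 to ~0.55 between 0 and 24 h
  g1_drop <- pt$summary$g1_mean[pt$summary$time_h == 0] -
    pt$summary$g1_mean[pt$summary$time_h == 24]
  expect_gt(g1_drop, 0.08)
  expect_true(!is.null(pt$tukey$g1))
  expect_true(any(pt$tukey$g1$pairs$significant))
  expect_s3_class(autoplot(pt), "ggplot")
})
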