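# Shared fixtures: small hand-built image sets and pipeline shortcuts.

# a tiny image set with fully known pixel values (no RNG)
manual_image_set <- function(v405, v488, mask, cap = 65535) {
  redoxroot:::new_roimage_set(v405, v488, mask,
                              metadata = list(cap = cap))
}

# 6x6 frame: one cell (nucleus id 1, cytosol id 2), the rest background
tiny_mask <- function() {
  m <- matrix(0L, 6, 6)
  m[2:5, 2:5] <- 2L
  m[3:4, 3:4] <- 1L
  m
}

# run calibration + imaging + redox pipeline for one scenario
run_scenario_pipeline <- function(treatment, seed = 1, n_replicates = 5,
                                  timepoints_h = seq(0, 24, by = 2),
                                  noise = sim_noise()) {
  cfg <- scenario_config(treatment, seed = seed,
                         n_replicates = n_replicates,
                         timepoints_h = timepoints_h, noise = noise)
  cal_sets <- generate_calibration_sets(cfg)
  calib <- estimate_calibration(cal_sets$reduced, cal_sets$oxidized)
  imgs <- list()
  for (tp in cfg$timepoints_h) {
    for (rep in seq_len(cfg$n_replicates)) {
      imgs[[length(imgs) + 1L]] <- generate_image_set(cfg, tp, rep)
    }
  }
  list(config = cfg, calib = calib,
       timecourse = run_redox_timecourse(imgs, calib, cfg$constants))
}

grand_value <- function(tc, compartment, what = "oxd_mean_pct") {
  tc$grand[[what]][tc$grand$compartment == compartment]
}
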