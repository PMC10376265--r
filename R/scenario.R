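# Scenario configurations: the ground truth that drives every synthetic
# data stream (images, flow events, root lengths).

# Printed study values the default scenarios are anchored to.
# Grand means over the 24 h window, per compartment, plus the pinned 2 h
# cytosolic values of the treated scenarios.
scenario_anchors <- function() {
  list(
    control = list(
      nucleus = list(mean_e_mV = -296.8, mean_oxd = 0.2290),
      cytosol = list(mean_e_mV = -294.1, mean_oxd = 0.2631)
    ),
    hc = list(
      nucleus = list(mean_e_mV = -291.4, mean_oxd = 0.3122),
      cytosol = list(mean_e_mV = -289.6, mean_oxd = 0.3248,
                     pin_time_h = 2, pin_oxd = 0.37)
    ),
    hu = list(
      nucleus = list(mean_e_mV = -297.4, mean_oxd = 0.2135),
      cytosol = list(mean_e_mV = -295.2, mean_oxd = 0.2444,
                     pin_time_h = 2, pin_oxd = 0.32)
    )
  )
}

# Qualitative time-course shapes (arbitrary scale; the solver sets the
# amplitude).  control: mid-window excursion, reduced at the start and the
# final hours; hc: flat early phase then a saturating oxidation after ~12 h;
# hu: early oxidation burst around 4-8 h, then progressive reduction.
scenario_shape <- function(treatment, time_h) {
  switch(treatment,
    control = -cos(2 * pi * time_h / 24),
    hc = pmax(0, (time_h - 10) / 14)^0.35,
    hu = exp(-(time_h - 6)^2 / 18) - 0.9 * pmax(0, time_h - 12) / 12,
    stop("unknown treatment: ", treatment)
  )
}

# Solve a logit-linear trajectory oxd_t = inv_logit(a + b * shape_t) such
# that mean(oxd) and mean(E) both hit their anchors; optionally pin one
# timepoint to an exact oxd.  E is affine in the logit, so the mean-E
# constraint fixes the mean logit and one root-find in b does the rest.
solve_truth_trajectory <- function(time_h, shape, mean_e_mV, mean_oxd,
                                   e0_probe_mV, rt_zf_mV,
                                   pin_idx = NULL, pin_oxd = NULL) {
  n <- length(time_h)
  lbar <- (mean_e_mV - e0_probe_mV) / rt_zf_mV
  if (is.null(pin_idx)) {
    sh <- shape - mean(shape)
    f <- function(b) mean(inv_logit(lbar + b * sh)) - mean_oxd
  } else {
    pin_logit <- logit(pin_oxd)
    sh <- shape[-pin_idx]
    sh <- sh - mean(sh)
    a_rest <- (n * lbar - pin_logit) / (n - 1)
    f <- function(b) {
      (inv_logit(pin_logit) + sum(inv_logit(a_rest + b * sh))) / n - mean_oxd
    }
  }
  if (f(0) > 0) {
    stop("trajectory anchors unsolvable: mean OxD target below the ",
         "dispersion-free value implied by the mean potential", call. = FALSE)
  }
  b <- stats::uniroot(f, c(0, 20), tol = 1e-14)$root
  lg <- if (is.null(pin_idx)) {
    lbar + b * (shape - mean(shape))
  } else {
    out <- numeric(n)
    out[pin_idx] <- logit(pin_oxd)
    out[-pin_idx] <- (n * lbar - logit(pin_oxd)) / (n - 1) + b * sh
    out
  }
  tibble::tibble(
    time_h = time_h,
    oxd = inv_logit(lg),
    e_probe_mV = e0_probe_mV + rt_zf_mV * lg
  )
}

# Cell-cycle phase fractions (G1, S, G2). Control holds 67/8/25 throughout;
# HC loses G1 to G2 from 16 h, reaching 55/8/37 at 24 h; HU shows the early
# G1/S synchronisation typical of a replication inhibitor.
scenario_phase_truth <- function(treatment, flow_timepoints_h) {
  frac_at <- function(t) {
    switch(treatment,
      control = c(0.67, 0.08, 0.25),
      hc = {
        if (t < 16) c(0.67, 0.08, 0.25)
        else {
          g1 <- 0.67 - (0.67 - 0.55) * (t - 16) / 8
          c(g1, 0.08, 1 - g1 - 0.08)
        }
      },
      hu = {
        if (t <= 8) c(0.67 + 0.01 * t, 0.08 + 0.005 * t, 0.25 - 0.015 * t)
        else c(0.70 - 0.01 * (t - 8), 0.10 - 0.0025 * (t - 8),
               0.20 + 0.0125 * (t - 8))
      }
    )
  }
  m <- t(vapply(flow_timepoints_h, frac_at, numeric(3)))
  tibble::tibble(time_h = flow_timepoints_h,
                 g1 = m[, 1], s = m[, 2], g2 = m[, 3])
}

# Root growth: control rates of 1.4 then 1.7 mm/d over the two measured
# 24 h intervals; treated scenarios are post-release, at a fraction of the
# control rate (HC 45% then fully recovered; HU 72% then 65%).
scenario_growth_truth <- function(treatment) {
  rel <- switch(treatment,
    control = c(1, 1),
    hc = c(0.45, 1.00),
    hu = c(0.72, 0.65)
  )
  tibble::tibble(
    interval_start_h = c(0, 24),
    interval_end_h = c(24, 48),
    control_rate_mm_d = c(1.4, 1.7),
    relative_factor = rel,
    rate_mm_d = c(1.4, 1.7) * rel
  )
}

#' Noise model for the synthetic-data generator
#'
#' All stochastic imperfections of the emulated measurements in one place.
#' Setting every component to zero yields exactly deterministic, analytically
#' checkable outputs (the "noiseless limit" used by the round-trip tests).
#'
#' @param photon_gain Arbitrary-units-per-photon gain of the shot-noise
#'   model: pixel values are drawn as `gain * Poisson(AU / gain)`. Zero
#'   disables shot noise.
#' @param background Uniform background offset added to both channels (AU).
#' @param read_sd Additive Gaussian read noise SD (AU).
#' @param replicate_sd_logit SD of the biological replicate jitter applied
#'   to the true oxidation degree on the logit scale (keeps OxD in (0, 1)).
#' @param flow_cv Coefficient of variation of the G1 peak in DNA-content
#'   histograms; the G2 peak inherits it (same CV at twice the position).
#' @param debris_frac Fraction of flow events drawn from the low-channel
#'   debris population.
#' @param length_sd_mm Root length measurement SD (mm).
#' @param seedling_rate_cv Between-seedling CV of the growth rate.
#' @return A list of class `sim_noise`.
#' @export
sim_noise <- function(photon_gain = 4, background = 100, read_sd = 10,
                      replicate_sd_logit = 0.05, flow_cv = 0.05,
                      debris_frac = 0.02, length_sd_mm = 0.05,
                      seedling_rate_cv = 0.10) {
  vals <- list(photon_gain = photon_gain, background = background,
               read_sd = read_sd, replicate_sd_logit = replicate_sd_logit,
               flow_cv = flow_cv, debris_frac = debris_frac,
               length_sd_mm = length_sd_mm,
               seedling_rate_cv = seedling_rate_cv)
  bad <- vapply(vals, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("noise parameters must be single non-negative numbers: ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  if (debris_frac >= 1) stop("`debris_frac` must be < 1", call. = FALSE)
  structure(vals, class = "sim_noise")
}

#' Noise-free generator settings
#'
#' Convenience wrapper: every noise component of [sim_noise()] set to zero,
#' for exact analytical checks of the pipeline.
#' @return A `sim_noise` object.
#' @export
no_noise <- function() {
  sim_noise(photon_gain = 0, background = 0, read_sd = 0,
            replicate_sd_logit = 0, flow_cv = 0, debris_frac = 0,
            length_sd_mm = 0, seedling_rate_cv = 0)
}

#' Build a synthetic study scenario
#'
#' Defines the complete ground truth for one treatment arm of the emulated
#' study: per-compartment oxidation-degree time courses whose grand means
#' reproduce the study's reported mean oxidation degrees *and* mean redox
#' potentials (with the 2 h cytosolic oxidation of the treated scenarios
#' pinned exactly), cell-cycle phase fractions, root growth rates, probe
#' calibration truth, and the noise model.  Everything downstream
#' ([generate_image_set()], [generate_flow_events()],
#' [generate_root_lengths()], [generate_calibration_sets()]) is a
#' deterministic function of this object.
#'
#' @param treatment `"control"` (untreated), `"hc"` (1.5 mM hydrogen
#'   cyanamide) or `"hu"` (3 mM hydroxyurea).
#' @param seed Master integer seed; all generator randomness derives from it
#'   through a documented splitting scheme.
#' @param n_replicates Biological replicates per timepoint for imaging.
#' @param timepoints_h Imaging timepoints (hours; default every 2 h over
#'   24 h).
#' @param flow_timepoints_h Flow-cytometry sampling times (hours).
#' @param constants A [nernst_constants()]; also used to derive the truth
#'   trajectories, so generator and analysis share one midpoint potential.
#' @param calibration_truth List with the true `r_red`, `r_ox` and
#'   instrument factor `k` of the simulated instrument.
#' @param noise A [sim_noise()].
#' @param image Geometry of generated frames: `width`, `height` (pixels),
#'   `n_cells`, `cap` (saturation value), `i488_base` (mean cellular 488
#'   signal of the reduced probe, AU), `cell_sdlog` (between-cell lognormal
#'   intensity spread).
#' @param growth List with `baseline_mm` (length at the start of the
#'   measured window), `n_seedlings` per biological replicate and
#'   `n_bio_replicates`.
#'
#' @return An object of class `scenario_config` carrying, among other
#'   fields, `truth_oxd` (tibble: compartment, time_h, oxd, e_probe_mV),
#'   `truth_phases` (tibble: time_h, g1, s, g2) and `truth_growth`.
#' @examples
#' cfg <- scenario_config("control", seed = 1)
#' dplyr::summarise(dplyr::group_by(cfg$truth_oxd, compartment),
#'                  oxd = mean(oxd), e = mean(e_probe_mV))
#' @export
scenario_config <- function(treatment = c("control", "hc", "hu"),
                            seed = 1L,
                            n_replicates = 5L,
                            timepoints_h = seq(0, 24, by = 2),
                            flow_timepoints_h = c(0, 5, 12, 16, 24),
                            constants = nernst_constants(),
                            calibration_truth = list(r_red = 0.2, r_ox = 2.0,
                                                     k = 0.5),
                            noise = sim_noise(),
                            image = list(width = 128, height = 128,
                                         n_cells = 20, cap = 65535,
                                         i488_base = 3000, cell_sdlog = 0.25),
                            growth = list(baseline_mm = 2.0,
                                          n_seedlings = 10,
                                          n_bio_replicates = 3)) {
  treatment <- match.arg(treatment)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_replicates >= 1, all(timepoints_h >= 0))
  if (!inherits(noise, "sim_noise")) {
    stop("`noise` must be a sim_noise() object", call. = FALSE)
  }
  stopifnot(inherits(constants, "nernst_constants"))

  # Truth trajectories are defined on the canonical 2-hourly 24 h grid
  # (where the grand-mean anchors live) and sampled - logit-interpolated if
  # necessary - at the requested timepoints.
  canonical_tp <- seq(0, 24, by = 2)
  anchors <- scenario_anchors()[[treatment]]
  shape <- scenario_shape(treatment, canonical_tp)
  truth_oxd <- purrr::map_dfr(c("nucleus", "cytosol"), function(comp) {
    a <- anchors[[comp]]
    pin_idx <- NULL
    if (!is.null(a$pin_time_h)) pin_idx <- match(a$pin_time_h, canonical_tp)
    tr <- solve_truth_trajectory(
      canonical_tp, shape, a$mean_e_mV, a$mean_oxd,
      constants$e0_probe_mV, constants$rt_zf_mV,
      pin_idx = pin_idx, pin_oxd = a$pin_oxd
    )
    lg <- stats::approx(tr$time_h, logit(tr$oxd), xout = timepoints_h,
                        rule = 2)$y
    tibble::tibble(compartment = comp, time_h = timepoints_h,
                   oxd = inv_logit(lg),
                   e_probe_mV = constants$e0_probe_mV +
                     constants$rt_zf_mV * lg)
  })
  if (any(truth_oxd$oxd <= 0 | truth_oxd$oxd >= 1)) {
    stop("internal error: truth oxd left (0, 1)", call. = FALSE)
  }

  cfg <- structure(
    list(
      treatment = treatment,
      concentration_mM = switch(treatment, control = 0, hc = 1.5, hu = 3.0),
      seed = as.integer(seed),
      n_replicates = as.integer(n_replicates),
      timepoints_h = timepoints_h,
      flow_timepoints_h = flow_timepoints_h,
      constants = constants,
      calibration_truth = calibration_truth,
      noise = noise,
      image = image,
      growth = growth,
      truth_oxd = truth_oxd,
      truth_phases = scenario_phase_truth(treatment, flow_timepoints_h),
      truth_growth = scenario_growth_truth(treatment)
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  ph <- cfg$truth_phases
  if (any(abs(ph$g1 + ph$s + ph$g2 - 1) > 1e-9)) {
    stop("phase fractions must sum to 1", call. = FALSE)
  }
  if (any(c(ph$g1, ph$s, ph$g2) < 0 | c(ph$g1, ph$s, ph$g2) > 1)) {
    stop("phase fractions must lie in [0, 1]", call. = FALSE)
  }
  with(cfg$calibration_truth, {
    if (!(r_ox > r_red) || k <= 0) {
      stop("calibration truth invalid: need r_ox > r_red and k > 0",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

truth_oxd_at <- function(cfg, compartment, time_h) {
  row <- cfg$truth_oxd[cfg$truth_oxd$compartment == compartment &
                         cfg$truth_oxd$time_h == time_h, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no truth defined for %s at %g h", compartment, time_h),
         call. = FALSE)
  }
  row$oxd
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config: %s (%g mM), seed %d>\n",
              x$treatment, x$concentration_mM, x$seed))
  gm <- dplyr::summarise(dplyr::group_by(x$truth_oxd, .data$compartment),
                         oxd = mean(.data$oxd),
                         e_mV = mean(.data$e_probe_mV))
  for (i in seq_len(nrow(gm))) {
    cat(sprintf("  %-8s grand-mean OxD %.2f%%, E %.1f mV\n",
                gm$compartment[i], 100 * gm$oxd[i], gm$e_mV[i]))
  }
  cat(sprintf("  %d imaging timepoints x %d replicates; flow at %s h\n",
              length(x$timepoints_h), x$n_replicates,
              paste(x$flow_timepoints_h, collapse = ", ")))
  invisible(x)
}

#' Write or read a scenario configuration as YAML
#'
#' Serialises the *arguments* of [scenario_config()] (not the derived truth
#' tables) so that one small text file fully determines a run.
#'
#' @param cfg A `scenario_config`.
#' @param path File path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a rebuilt `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  args <- list(
    treatment = cfg$treatment,
    seed = cfg$seed,
    n_replicates = cfg$n_replicates,
    timepoints_h = cfg$timepoints_h,
    flow_timepoints_h = cfg$flow_timepoints_h,
    constants = list(e0_probe_mV = cfg$constants$e0_probe_mV,
                     e0_gsh_mV = cfg$constants$e0_gsh_mV,
                     gsh_total_M = cfg$constants$gsh_total_M,
                     temp_K = cfg$constants$temp_K),
    calibration_truth = cfg$calibration_truth,
    noise = unclass(cfg$noise),
    image = cfg$image,
    growth = cfg$growth
  )
  yaml::write_yaml(args, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  a <- yaml::read_yaml(path)
  scenario_config(
    treatment = a$treatment, seed = a$seed, n_replicates = a$n_replicates,
    timepoints_h = as.numeric(unlist(a$timepoints_h)),
    flow_timepoints_h = as.numeric(unlist(a$flow_timepoints_h)),
    constants = do.call(nernst_constants, a$constants),
    calibration_truth = a$calibration_truth,
    noise = do.call(sim_noise, a$noise),
    image = a$image, growth = a$growth
  )
}
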