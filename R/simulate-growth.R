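# Synthetic root-length time courses: per-seedling accumulation of the
# scenario's true growth rate plus measurement noise.

#' Generate a synthetic root-length table
#'
#' Each seedling starts near the configured baseline length and accumulates
#' `rate x elapsed days` over each measured interval, where the rate is the
#' scenario truth (control 1.4 then 1.7 mm/d; treated scenarios a relative
#' fraction of it) scaled by a per-seedling lognormal-like factor, with
#' Gaussian measurement error added to every length reading.  Default
#' design: 10 seedlings x 3 biological replicates, measured at 0, 24 and
#' 48 h.
#'
#' @param config A [scenario_config()].
#' @return A tibble with columns `treatment`, `concentration_mM`,
#'   `seedling_id`, `time_h`, `length_mm`.
#' @examples
#' tab <- generate_root_lengths(scenario_config("control", seed = 1))
#' head(tab)
#' @export
generate_root_lengths <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$growth
  tg <- config$truth_growth
  times <- sort(unique(c(tg$interval_start_h, tg$interval_end_h)))
  noise <- config$noise
  with_seed(split_seed(config$seed, STREAM_GROWTH, 0, 0L, config$treatment), {
    rows <- list()
    for (bio in seq_len(g$n_bio_replicates)) {
      for (sdl in seq_len(g$n_seedlings)) {
        id <- sprintf("%s_b%d_s%02d", config$treatment, bio, sdl)
        mult <- max(0.05, 1 + stats::rnorm(1, 0, noise$seedling_rate_cv))
        baseline <- g$baseline_mm + stats::rnorm(1, 0, 0.2 * g$baseline_mm)
        len <- baseline
        lengths <- numeric(length(times))
        lengths[1] <- len
        for (i in seq_len(nrow(tg))) {
          days <- (tg$interval_end_h[i] - tg$interval_start_h[i]) / 24
          len <- len + tg$rate_mm_d[i] * mult * days
          lengths[i + 1] <- len
        }
        meas <- lengths + stats::rnorm(length(lengths), 0, noise$length_sd_mm)
        rows[[id]] <- tibble::tibble(
          treatment = config$treatment,
          concentration_mM = config$concentration_mM,
          seedling_id = id,
          time_h = times,
          length_mm = pmax(meas, 0)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
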