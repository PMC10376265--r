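# Synthetic DNA-content flow cytometry: G1 and G2 Gaussian peaks at mu and
# 2*mu, an S-phase bridge between them, and a low-channel debris population
# separable on the scatter channels.

# integer phase counts matching the requested fractions exactly
# (largest-remainder apportionment)
apportion_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws DNA-fluorescence events from the scenario's true phase fractions at
#' a timepoint: G1 ~ Normal(mu, cv mu), G2 ~ Normal(2 mu, cv 2 mu), S from a
#' uniform bridge spanning the central 80% of (mu, 2 mu) convolved with the
#' G1 peak width, plus an exponential-tailed low-channel debris population
#' whose forward/side scatter separates it from intact nuclei.  Phase counts
#' match the requested fractions exactly before any classification; the
#' `.component` column records each event's generating population as ground
#' truth for validation (analysis functions never read it).
#'
#' @param config A [scenario_config()].
#' @param timepoint One of `config$flow_timepoints_h`.
#' @param n_events Number of events (default 100,000, the study's recording
#'   target).
#' @param replicate Replicate index (alters only the derived seed).
#' @param g1_peak_position Channel position of the G1 (2C) peak.
#' @return A tibble with columns `event_id`, `fsc`, `ssc`, `dna_fl`,
#'   `.component`, carrying a `metadata` attribute (treatment, time_h,
#'   n_events, g1_peak_position, replicate).
#' @examples
#' cfg <- scenario_config("control", seed = 1)
#' ev <- generate_flow_events(cfg, timepoint = 0, n_events = 1000)
#' table(ev$.component)
#' @export
generate_flow_events <- function(config, timepoint, n_events = 1e5,
                                 replicate = 1L, g1_peak_position = 200) {
  stopifnot(inherits(config, "scenario_config"), n_events > 0)
  ph <- config$truth_phases[config$truth_phases$time_h == timepoint, ]
  if (nrow(ph) != 1L) {
    stop("no phase fractions defined at this timepoint", call. = FALSE)
  }
  fr <- c(ph$g1, ph$s, ph$g2)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("phase fractions must sum to 1", call. = FALSE)
  }
  noise <- config$noise
  mu <- g1_peak_position
  with_seed(split_seed(config$seed, STREAM_FLOW, timepoint, replicate, config$treatment), {
    n <- as.integer(n_events)
    n_debris <- as.integer(round(noise$debris_frac * n))
    counts <- apportion_counts(n - n_debris, fr)
    cv <- noise$flow_cv
    g1 <- mu + (if (cv > 0) stats::rnorm(counts[1], 0, cv * mu) else
      numeric(counts[1]))
    g2 <- 2 * mu + (if (cv > 0) stats::rnorm(counts[3], 0, cv * 2 * mu) else
      numeric(counts[3]))
    s <- stats::runif(counts[2], 1.1 * mu, 1.9 * mu) +
      (if (cv > 0) stats::rnorm(counts[2], 0, cv * mu) else numeric(counts[2]))
    debris <- mu * 0.15 * stats::rexp(n_debris) + 1e-6
    dna <- c(g1, s, g2, debris)
    comp <- rep(c("G1", "S", "G2", "debris"),
                times = c(counts[1], counts[2], counts[3], n_debris))
    n_nuc <- n - n_debris
    fsc <- c(stats::rlnorm(n_nuc, log(500), 0.15),
             stats::rlnorm(n_debris, log(60), 0.35))
    ssc <- c(stats::rlnorm(n_nuc, log(400), 0.20),
             stats::rlnorm(n_debris, log(50), 0.35))
    ord <- sample.int(n)
    out <- tibble::tibble(
      event_id = seq_len(n),
      fsc = fsc[ord], ssc = ssc[ord],
      dna_fl = pmax(dna[ord], 1e-9),
      .component = comp[ord]
    )
    attr(out, "metadata") <- list(
      treatment = config$treatment, time_h = timepoint,
      n_events = n, g1_peak_position = mu, replicate = as.integer(replicate)
    )
    out
  })
}

#' Write / read flow event tables as CSV
#'
#' Plain-text interchange format with header `event_id,fsc,ssc,dna_fl`
#' (the ground-truth `.component` column is kept when present).
#' @param events Event tibble from [generate_flow_events()].
#' @param path CSV path.
#' @return The tibble (read) or `path`, invisibly (write).
#' @export
write_flow_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
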