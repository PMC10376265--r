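# Root growth rates, treatment-relative growth and recovery calls.

#' Per-treatment root growth rates over an interval
#'
#' Computes each seedling's growth rate `(length(t1) - length(t0)) /
#' elapsed days` and aggregates mean, SEM and n per treatment.  When a
#' `"control"` treatment is present, each treatment's rate is also expressed
#' as a percentage of the control rate, and - if `test_recovery` is set and
#' at least two treatments are available - a treatment is flagged
#' `recovered` when Tukey's HSD cannot distinguish its seedling rates from
#' the control's at `alpha`.
#'
#' @param table Root-length tibble with columns `treatment`, `seedling_id`,
#'   `time_h`, `length_mm` (multiple treatments may be row-bound).
#' @param interval Length-two numeric, the `(t0, t1)` measurement pair in
#'   hours.
#' @param test_recovery Run the Tukey recovery test against the control.
#' @param alpha Level for the recovery test.
#' @return A tibble with one row per treatment: `n`, `rate_mean_mm_d`,
#'   `rate_sem_mm_d`, `relative_to_control_pct`, `recovered`.  Per-seedling
#'   rates are attached as the `"rates"` attribute; the Tukey fit (if run)
#'   as `"tukey"`.
#' @examples
#' tab <- dplyr::bind_rows(
#'   generate_root_lengths(scenario_config("control", seed = 1)),
#'   generate_root_lengths(scenario_config("hc", seed = 1)))
#' growth_rate(tab, interval = c(0, 24))
#' @export
growth_rate <- function(table, interval = c(0, 24), test_recovery = TRUE,
                        alpha = 0.01) {
  stopifnot(is.data.frame(table), length(interval) == 2,
            interval[2] > interval[1])
  t0 <- interval[1]
  t1 <- interval[2]
  sub <- table[table$time_h %in% c(t0, t1), ]
  have <- dplyr::summarise(dplyr::group_by(sub, .data$seedling_id),
                           n_tp = dplyr::n_distinct(.data$time_h),
                           .groups = "drop")
  missing_ids <- have$seedling_id[have$n_tp < 2]
  all_ids <- unique(table$seedling_id)
  missing_ids <- union(missing_ids, setdiff(all_ids, have$seedling_id))
  if (length(missing_ids) > 0) {
    stop("missing timepoint rows for seedling(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  days <- (t1 - t0) / 24
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "treatment", "seedling_id", "time_h", "length_mm"),
    names_from = "time_h", values_from = "length_mm"
  )
  rates <- tibble::tibble(
    treatment = wide$treatment,
    seedling_id = wide$seedling_id,
    rate_mm_d = (wide[[as.character(t1)]] - wide[[as.character(t0)]]) / days
  )
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- dplyr::summarise(
    dplyr::group_by(rates, .data$treatment),
    n = dplyr::n(),
    rate_mean_mm_d = mean(.data$rate_mm_d),
    rate_sem_mm_d = sem(.data$rate_mm_d),
    .groups = "drop"
  )
  tk <- NULL
  if ("control" %in% out$treatment) {
    ctrl <- out$rate_mean_mm_d[out$treatment == "control"]
    out$relative_to_control_pct <- 100 * out$rate_mean_mm_d / ctrl
    out$recovered <- NA
    if (test_recovery && nrow(out) >= 2 && all(out$n >= 2)) {
      tk <- anova_tukey(rates, rate_mm_d, treatment, alpha = alpha)
      vs_ctrl <- tk$pairs[tk$pairs$group_a == "control" |
                            tk$pairs$group_b == "control", ]
      other <- ifelse(vs_ctrl$group_a == "control", vs_ctrl$group_b,
                      vs_ctrl$group_a)
      out$recovered[match(other, out$treatment)] <- !vs_ctrl$significant
      out$recovered[out$treatment == "control"] <- TRUE
    }
  } else {
    out$relative_to_control_pct <- NA_real_
    out$recovered <- NA
  }
  attr(out, "rates") <- rates
  attr(out, "tukey") <- tk
  attr(out, "interval_h") <- interval
  out
}
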