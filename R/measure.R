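# ROI measurement and probe calibration from labelled image sets.

compartment_pixels <- function(mask, compartment) {
  switch(compartment,
    nucleus = mask > 0L & mask %% 2L == 1L,
    cytosol = mask > 0L & mask %% 2L == 0L,
    roi = mask > 0L,
    stop("`compartment` must be \"nucleus\", \"cytosol\" or \"roi\"",
         call. = FALSE)
  )
}

#' Background-subtracted mean ROI intensities
#'
#' Mean intensity of the compartment's pixels in each channel minus the mean
#' of the background-labelled (0) pixels in the same channel, floored at a
#' small positive value.  Saturated pixels (at the metadata cap) are
#' excluded from the compartment mean and their count is reported.
#'
#' @param image_set A `roimage_set`.
#' @param compartment `"nucleus"`, `"cytosol"`, or `"roi"` (all labelled
#'   pixels pooled).
#' @param epsilon Floor applied to the background-subtracted means.
#' @return One-row tibble: `compartment`, `i405`, `i488`, `n_pixels`,
#'   `n_saturated`.
#' @examples
#' cfg <- scenario_config("control", seed = 1, noise = no_noise())
#' img <- generate_image_set(cfg, 0, 1)
#' measure_roi(img, "nucleus")
#' @export
measure_roi <- function(image_set, compartment = c("nucleus", "cytosol",
                                                   "roi"),
                        epsilon = 1e-6) {
  stopifnot(inherits(image_set, "roimage_set"))
  compartment <- match.arg(compartment)
  mask <- image_set$label_mask
  sel <- compartment_pixels(mask, compartment)
  if (!any(sel)) {
    stop(sprintf("mask contains no %s pixels", compartment), call. = FALSE)
  }
  bg <- mask == 0L
  if (!any(bg)) stop("mask contains no background pixels", call. = FALSE)
  cap <- image_set$metadata$cap %||% Inf
  channel_mean <- function(ch) {
    v <- ch[sel]
    sat <- v >= cap
    if (all(sat)) stop("all compartment pixels saturated", call. = FALSE)
    list(mean = mean(v[!sat]) - mean(ch[bg]), n_sat = sum(sat))
  }
  m405 <- channel_mean(image_set$channel_405)
  m488 <- channel_mean(image_set$channel_488)
  tibble::tibble(
    compartment = compartment,
    i405 = max(m405$mean, epsilon),
    i488 = max(m488$mean, epsilon),
    n_pixels = sum(sel),
    n_saturated = m405$n_sat + m488$n_sat
  )
}

# 405/488 ratio of a compartment; either ratio of mean intensities
# (default, mirroring ImageJ-style ROI means) or mean of per-pixel ratios
roi_ratio <- function(image_set, compartment, pixelwise = FALSE,
                      epsilon = 1e-6) {
  if (!pixelwise) {
    m <- measure_roi(image_set, compartment, epsilon)
    return(list(ratio = m$i405 / m$i488, i405 = m$i405, i488 = m$i488,
                n_saturated = m$n_saturated))
  }
  mask <- image_set$label_mask
  sel <- compartment_pixels(mask, compartment)
  if (!any(sel)) stop("mask contains no ", compartment, " pixels",
                      call. = FALSE)
  bg <- mask == 0L
  cap <- image_set$metadata$cap %||% Inf
  v405 <- image_set$channel_405[sel] - mean(image_set$channel_405[bg])
  v488 <- image_set$channel_488[sel] - mean(image_set$channel_488[bg])
  ok <- image_set$channel_405[sel] < cap & image_set$channel_488[sel] < cap &
    v488 > epsilon
  list(ratio = mean(pmax(v405[ok], epsilon) / v488[ok]),
       i405 = mean(pmax(v405[ok], epsilon)), i488 = mean(v488[ok]),
       n_saturated = sum(!ok))
}

#' Estimate the probe calibration from reference image sets
#'
#' Pools all labelled (nucleus + cytosol) pixels of each reference set:
#' `r_red` and the 488 intensity of the reduced probe from the fully reduced
#' (DTT) set, `r_ox` and the oxidised 488 intensity from the fully oxidised
#' (H2O2) set, background-subtracted per channel.  The instrument factor is
#' `k = i488_min / i488_max`, the oxidised over the reduced 488 signal.
#' If the estimated `r_ox` does not exceed `r_red` the inputs were swapped
#' or a reference treatment failed, and an error is raised.
#'
#' @param reduced,oxidized `roimage_set`s of the fully reduced / fully
#'   oxidised probe.
#' @return A [calibration_state()].
#' @examples
#' cfg <- scenario_config("control", seed = 1, noise = no_noise())
#' cal <- generate_calibration_sets(cfg)
#' estimate_calibration(cal$reduced, cal$oxidized)
#' @export
estimate_calibration <- function(reduced, oxidized) {
  m_red <- measure_roi(reduced, "roi")
  m_ox <- measure_roi(oxidized, "roi")
  r_red <- m_red$i405 / m_red$i488
  r_ox <- m_ox$i405 / m_ox$i488
  if (!(r_ox > r_red)) {
    stop("calibration inversion: oxidised ratio does not exceed reduced ",
         "ratio (inputs swapped or reference treatments failed)",
         call. = FALSE)
  }
  calibration_state(r_red = r_red, r_ox = r_ox,
                    i488_min = m_ox$i488, i488_max = m_red$i488)
}
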