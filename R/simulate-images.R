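# Synthetic two-channel roGFP2 image sets: ~20 elliptical cells per frame,
# nucleus nested in a cytosol ring, paired integer labels (2i-1 / 2i),
# Poisson shot noise + Gaussian read noise + uniform background.

new_roimage_set <- function(ch405, ch488, mask, metadata) {
  structure(list(channel_405 = ch405, channel_488 = ch488,
                 label_mask = mask, metadata = metadata),
            class = "roimage_set")
}

#' @export
print.roimage_set <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<roimage_set %dx%d: %s, t = %s h, replicate %s>\n",
              nrow(x$channel_488), ncol(x$channel_488),
              md$treatment %||% "?", format(md$time_h %||% NA),
              format(md$replicate %||% NA)))
  cat(sprintf("  %d cells, background %.1f%% of pixels\n",
              max(x$label_mask) %/% 2,
              100 * mean(x$label_mask == 0)))
  invisible(x)
}

# Paint the label mask: cells on a jittered grid, each a cytosol ellipse
# (even id) with a nested nucleus ellipse (odd id). Consumes RNG.
draw_cell_mask <- function(width, height, n_cells) {
  mask <- matrix(0L, nrow = height, ncol = width)
  ncol_g <- ceiling(sqrt(n_cells * width / height))
  nrow_g <- ceiling(n_cells / ncol_g)
  slot_w <- width / ncol_g
  slot_h <- height / nrow_g
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  placed <- 0L
  for (gy in seq_len(nrow_g)) {
    for (gx in seq_len(ncol_g)) {
      if (placed >= n_cells) break
      placed <- placed + 1L
      cx <- (gx - 0.5) * slot_w + stats::runif(1, -0.08, 0.08) * slot_w
      cy <- (gy - 0.5) * slot_h + stats::runif(1, -0.08, 0.08) * slot_h
      # cytosol ellipse fits its slot with margin; nucleus nested, offset
      ax <- 0.33 * slot_w * stats::runif(1, 0.85, 1.05)
      ay <- 0.33 * slot_h * stats::runif(1, 0.85, 1.05)
      nx <- 0.38 * ax * stats::runif(1, 0.85, 1.1)
      ny <- 0.38 * ay * stats::runif(1, 0.85, 1.1)
      ox <- stats::runif(1, -0.2, 0.2) * ax
      oy <- stats::runif(1, -0.2, 0.2) * ay
      in_cyt <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
      in_nuc <- ((xs - cx - ox) / nx)^2 + ((ys - cy - oy) / ny)^2 <= 1
      mask[in_cyt & mask == 0L] <- 2L * placed        # cytosol id (even)
      mask[in_nuc & in_cyt] <- 2L * placed - 1L       # nucleus id (odd)
    }
  }
  mask
}

# Shot + read noise on an expected-value image; exact in the noiseless case.
apply_pixel_noise <- function(expected, noise, cap) {
  img <- expected
  if (noise$photon_gain > 0) {
    img <- noise$photon_gain *
      matrix(stats::rpois(length(img), img / noise$photon_gain),
             nrow = nrow(img))
  }
  if (noise$read_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise$read_sd),
                        nrow = nrow(img))
  }
  pmin(pmax(img, 0), cap)
}

# Shared renderer for sample and calibration frames.  `oxd` is a named
# vector c(nucleus=, cytosol=).  `scene` (mask + per-cell base levels) may
# be passed in so that paired frames depict the same cells.
draw_scene <- function(cfg) {
  im <- cfg$image
  mask <- draw_cell_mask(im$width, im$height, im$n_cells)
  n_cells <- max(mask) %/% 2L
  list(mask = mask,
       cell_base = im$i488_base * exp(stats::rnorm(n_cells, 0,
                                                   im$cell_sdlog)))
}

render_image <- function(cfg, oxd, scene = NULL, metadata = list()) {
  im <- cfg$image
  noise <- cfg$noise
  truth_cal <- do.call(calibration_state, cfg$calibration_truth)
  scene <- scene %||% draw_scene(cfg)
  mask <- scene$mask
  cell_base <- scene$cell_base
  exp488 <- matrix(0, nrow = im$height, ncol = im$width)
  exp405 <- matrix(0, nrow = im$height, ncol = im$width)
  n_cells <- max(mask) %/% 2L
  for (cell in seq_len(n_cells)) {
    for (comp in c("nucleus", "cytosol")) {
      id <- if (comp == "nucleus") 2L * cell - 1L else 2L * cell
      px <- mask == id
      p <- oxd[[comp]]
      # 488 signal falls with oxidation (factor k at full oxidation);
      # 405 follows the calibrated ratio of the local oxidation degree
      i488 <- cell_base[cell] * ((1 - p) + truth_cal$k * p)
      exp488[px] <- i488
      exp405[px] <- invert_ratio(p, truth_cal) * i488
    }
  }
  exp488 <- exp488 + noise$background
  exp405 <- exp405 + noise$background
  ch488 <- apply_pixel_noise(exp488, noise, im$cap)
  ch405 <- apply_pixel_noise(exp405, noise, im$cap)
  metadata$cap <- im$cap
  metadata$true_oxd <- oxd
  new_roimage_set(ch405, ch488, mask, metadata)
}

#' Generate one synthetic two-channel image set
#'
#' Renders a frame of elliptical cells whose 405/488 pixel ratios encode the
#' scenario's true oxidation degree at the requested timepoint, perturbed by
#' a replicate-specific logit-scale jitter, shot noise, read noise and a
#' uniform background.  Deterministic given `(config$seed, timepoint,
#' replicate)`; the RNG state of the caller is left untouched.
#'
#' @param config A [scenario_config()].
#' @param timepoint One of `config$timepoints_h`.
#' @param replicate Positive replicate index.
#' @return A `roimage_set`: matrices `channel_405`, `channel_488`, integer
#'   `label_mask` (0 background, odd ids nuclei, even ids cytosol rings,
#'   paired per cell), and `metadata` including the jittered `true_oxd`.
#' @examples
#' cfg <- scenario_config("control", seed = 1, noise = no_noise())
#' img <- generate_image_set(cfg, timepoint = 0, replicate = 1)
#' table(img$label_mask == 0)
#' @export
generate_image_set <- function(config, timepoint, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  if (!timepoint %in% config$timepoints_h) {
    stop("`timepoint` is not one of the configured timepoints", call. = FALSE)
  }
  with_seed(split_seed(config$seed, STREAM_IMAGES, timepoint, replicate, config$treatment), {
    jit_sd <- config$noise$replicate_sd_logit
    oxd <- vapply(c(nucleus = "nucleus", cytosol = "cytosol"), function(comp) {
      p <- truth_oxd_at(config, comp, timepoint)
      inv_logit(logit(p) + stats::rnorm(1, 0, jit_sd))
    }, numeric(1))
    render_image(config, oxd,
                 metadata = list(treatment = config$treatment,
                                 time_h = timepoint,
                                 replicate = as.integer(replicate)))
  })
}

#' Generate a calibration image pair (fully reduced / fully oxidised)
#'
#' Emulates the DTT and H2O2 reference treatments applied to the same
#' roots: both frames share one cell layout and per-cell brightness field.
#' The reduced frame carries a true oxidation degree of 0 everywhere (ratio
#' `r_red`); the oxidised frame 1 (ratio `r_ox`) with its 488 intensity
#' scaled by the configured instrument factor `k` relative to the reduced
#' frame, so that [estimate_calibration()] recovers `k` (exactly in the
#' noiseless limit).  Pixel noise is drawn independently per frame.
#'
#' @inheritParams generate_image_set
#' @return A list with elements `reduced` and `oxidized`, both
#'   `roimage_set`s.
#' @export
generate_calibration_sets <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(split_seed(config$seed, STREAM_CALIB, 0, 1L, config$treatment), {
    scene <- draw_scene(config)
    reduced <- render_image(config, c(nucleus = 0, cytosol = 0),
                            scene = scene,
                            metadata = list(treatment = config$treatment,
                                            state = "reduced"))
    oxidized <- render_image(config, c(nucleus = 1, cytosol = 1),
                             scene = scene,
                             metadata = list(treatment = config$treatment,
                                             state = "oxidized"))
    list(reduced = reduced, oxidized = oxidized)
  })
}

#' Write / read an image set as TIFF files
#'
#' The two fluorescence channels go into one multi-page 16-bit TIFF (page 1
#' = 405 nm, page 2 = 488 nm); the label mask into a companion single-page
#' 16-bit TIFF.  Intensities are quantised to integers on write.
#'
#' @param x A `roimage_set`.
#' @param path Base path without extension; writes `<path>.tif` and
#'   `<path>_mask.tif`.
#' @param cap Saturation value used to scale 16-bit storage on read.
#' @return `write_image_set()` returns `path` invisibly; `read_image_set()`
#'   returns a `roimage_set` (metadata restricted to the cap).
#' @export
write_image_set <- function(x, path) {
  stopifnot(inherits(x, "roimage_set"))
  cap <- x$metadata$cap %||% 65535
  tiff::writeTIFF(list(round(x$channel_405) / cap, round(x$channel_488) / cap),
                  paste0(path, ".tif"), bits.per.sample = 16L)
  tiff::writeTIFF(x$label_mask / 65535, paste0(path, "_mask.tif"),
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(path, cap = 65535) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  if (length(pages) != 2L) stop("expected a two-page channel TIFF",
                                call. = FALSE)
  mask <- tiff::readTIFF(paste0(path, "_mask.tif"))
  new_roimage_set(round(pages[[1]] * cap), round(pages[[2]] * cap),
                  matrix(as.integer(round(mask * 65535)), nrow = nrow(mask)),
                  metadata = list(cap = cap))
}
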