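# Synthetic inputs for the localization statistics: two-compartment
# intensity images with a known partition ratio, and 1D junction line
# profiles with a known peak count.

#' Generate a partition image with a known in/out intensity ratio
#'
#' Mean intensity inside `mask` is `ratio_true` times the mean outside;
#' Gaussian noise is added on top. Used to validate compartment
#' statistics such as the sarcomeric:non-sarcomeric ubiquitin ratio.
#'
#' @param mask Logical (or 0/1) matrix defining the compartment.
#' @param pixel_size_um Micrometres per pixel.
#' @param ratio_true True inside/outside mean-intensity ratio (> 0).
#' @param base_intensity Outside mean intensity (default 100).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Optional RNG seed.
#' @return List with `signal` and `mask` ([image_frame()]s) and the
#'   ground-truth ratio.
#' @export
gen_partition_image <- function(mask, pixel_size_um, ratio_true,
                                base_intensity = 100, noise_sd = 0,
                                seed = NULL) {
  if (!is.matrix(mask)) stop_contract("`mask` must be a matrix")
  mask <- mask != 0
  if (!any(mask) || all(mask)) {
    stop_contract("`mask` must contain both compartment and complement pixels")
  }
  check_number(ratio_true, "ratio_true", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  with_seed_opt(seed, {
    img <- matrix(base_intensity, nrow(mask), ncol(mask))
    img[mask] <- base_intensity * ratio_true
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- pmax(img, 0)
    list(signal = image_frame(img, pixel_size_um, channel_label = "signal"),
         mask = image_frame(mask * 1, pixel_size_um, channel_label = "mask",
                            bit_depth = 8L),
         ratio_true = ratio_true)
  })
}

#' Generate a junction intensity line profile with known peak positions
#'
#' Gaussian peaks on a flat baseline at uniform-random positions;
#' position sets violating the minimum separation are redrawn so every
#' true junction is resolvable.
#'
#' @param length_mm Profile length in millimetres.
#' @param n_junctions Number of junction peaks (>= 0).
#' @param peak_amp Peak amplitude above baseline.
#' @param baseline Baseline intensity.
#' @param noise_sd Additive Gaussian noise SD.
#' @param peak_sigma_um Gaussian peak SD (um).
#' @param min_sep_um Minimum separation between junction centres (um).
#' @param step_um Sampling step along the line (um).
#' @param seed Optional RNG seed.
#' @return List with `profile` (tibble: `position_um`, `intensity`),
#'   `truth` (tibble of true junction positions), `length_mm`.
#' @export
gen_junction_profile <- function(length_mm, n_junctions, peak_amp = 100,
                                 baseline = 20, noise_sd = 2,
                                 peak_sigma_um = 1.5, min_sep_um = 20,
                                 step_um = 0.5, seed = NULL) {
  check_number(length_mm, "length_mm", min = 0, strict_min = TRUE)
  if (n_junctions < 0) stop_contract("n_junctions must be >= 0")
  check_number(noise_sd, "noise_sd", min = 0)
  len_um <- length_mm * 1000
  if (n_junctions * min_sep_um > 0.8 * len_um) {
    stop_contract("cannot place %d junctions with %g um separation on %g um",
                  n_junctions, min_sep_um, len_um)
  }
  with_seed_opt(seed, {
    margin <- 5 * peak_sigma_um
    pos <- numeric(0)
    if (n_junctions > 0) {
      repeat {
        pos <- sort(runif(n_junctions, margin, len_um - margin))
        if (n_junctions == 1L || min(diff(pos)) >= min_sep_um) break
      }
    }
    x <- seq(0, len_um, by = step_um)
    y <- rep(baseline, length(x))
    for (p0 in pos) y <- y + peak_amp * exp(-(x - p0)^2 / (2 * peak_sigma_um^2))
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    list(profile = tibble::tibble(position_um = x, intensity = pmax(y, 0)),
         truth = tibble::tibble(position_um = pos),
         length_mm = length_mm)
  })
}
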