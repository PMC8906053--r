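# Sarcomere architecture: scanning-window Fourier orientation mapping of
# alpha-actinin striations, axial organization statistics and rose
# histograms, and sarcomere content (I_sarc / Area).

#' Map local striation orientation by windowed 2D FFT
#'
#' The image is scanned with 50%-overlapping square windows. In each
#' window the 2D FFT magnitude is restricted to the annulus of spatial
#' frequencies corresponding to the expected Z-disc spacing band; if the
#' band holds at least `strength_min` of the total non-DC power the
#' window is striated, and its angle is the Z-disc line direction
#' (perpendicular to the band-limited peak wave vector), with the
#' spacing read off the peak frequency. The peak is refined by a
#' centroid over its 3x3 frequency neighbourhood.
#'
#' @param img An [image_frame()].
#' @param window_size_um Scanning window side (default 12.8 um).
#' @param spacing_band_um Z-disc spacing band (default 1.4-2.6 um).
#' @param strength_min Band-power fraction below which a window is
#'   non-striated (default 0.1).
#' @param overlap_frac Window overlap (default 0.5).
#' @return An `orientation_map` tibble: `x_um`, `y_um`, `angle_deg`,
#'   `strength`, `spacing_um`, `striated`.
#' @export
orientation_map <- function(img, window_size_um = 12.8,
                            spacing_band_um = c(1.4, 2.6),
                            strength_min = 0.1, overlap_frac = 0.5) {
  stopifnot(inherits(img, "image_frame"))
  px <- img$pixel_size_um
  w <- 2L * max(4L, round(window_size_um / px / 2))
  npx <- dim(img$pixels)
  if (any(npx < w)) stop_contract("image smaller than one %g um window",
                                  window_size_um)
  if (w * px < 3 * max(spacing_band_um)) {
    stop_contract("window must be >= 3x the largest spacing in the band")
  }
  step <- max(1L, round(w * (1 - overlap_frac)))
  xs <- seq(1L, npx[2] - w + 1L, by = step)
  ys <- seq(1L, npx[1] - w + 1L, by = step)
  # frequency coordinates (cycles/um) of the w x w FFT
  fidx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / (w * px)
  FX <- matrix(fidx, w, w, byrow = TRUE)
  FY <- matrix(fidx, w, w)
  FR <- sqrt(FX^2 + FY^2)
  band <- FR >= 1 / max(spacing_band_um) & FR <= 1 / min(spacing_band_um)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(w) - 1) / (w - 1)))
  win2d <- outer(hann, hann)
  wrap <- function(i) ((i - 1L) %% w) + 1L
  res <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      k <- k + 1L
      sub <- img$pixels[ys[iy]:(ys[iy] + w - 1L), xs[ix]:(xs[ix] + w - 1L)]
      sub <- (sub - mean(sub)) * win2d
      P <- Mod(fft(sub))^2
      P[1, 1] <- 0
      tot <- sum(P)
      strength <- if (tot > 0) sum(P[band]) / tot else 0
      angle <- spacing <- NA_real_
      striated <- FALSE
      if (tot > 0 && strength >= strength_min) {
        striated <- TRUE
        Pb <- P; Pb[!band] <- 0
        pk <- which(Pb == max(Pb), arr.ind = TRUE)[1, ]
        # centroid over the 3x3 neighbourhood in frequency space
        ri <- wrap(pk[1] + (-1:1)); ci <- wrap(pk[2] + (-1:1))
        nb <- P[ri, ci]
        fxn <- matrix(FX[cbind(rep(ri, 3), rep(ci, each = 3))], 3, 3)
        fyn <- matrix(FY[cbind(rep(ri, 3), rep(ci, each = 3))], 3, 3)
        # guard the wrap across the conjugate origin: use the raw peak if
        # the neighbourhood spans inconsistent signs at high |f|
        fx_pk <- FX[pk[1], pk[2]]; fy_pk <- FY[pk[1], pk[2]]
        consistent <- all(abs(fxn - fx_pk) <= 1.5 / (w * px)) &&
          all(abs(fyn - fy_pk) <= 1.5 / (w * px))
        if (consistent) {
          fx_hat <- sum(nb * fxn) / sum(nb)
          fy_hat <- sum(nb * fyn) / sum(nb)
        } else {
          fx_hat <- fx_pk; fy_hat <- fy_pk
        }
        spacing <- 1 / sqrt(fx_hat^2 + fy_hat^2)
        normal_deg <- (atan2(fy_hat, fx_hat) * 180 / pi) %% 180
        angle <- (normal_deg + 90) %% 180
      }
      res[[k]] <- tibble::tibble(
        x_um = (xs[ix] - 1 + w / 2) * px,
        y_um = (ys[iy] - 1 + w / 2) * px,
        angle_deg = angle, strength = strength, spacing_um = spacing,
        striated = striated)
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "window_size_um") <- w * px
  attr(out, "spacing_band_um") <- spacing_band_um
  class(out) <- c("orientation_map", class(tibble::tibble()))
  out
}

#' Axial organization statistics of an orientation map
#'
#' Angles are expressed relative to the groove axis (so 90 degrees means
#' Z-disc lines perpendicular to the grooves, i.e. myofibrils running
#' along them — perfect longitudinal alignment). The organization index
#' is the strength-weighted axial resultant length of the doubled
#' angles: 1 when all striated windows agree, ~0 for a uniform or
#' antipodally split distribution.
#'
#' @param m An [orientation_map()].
#' @param groove_axis_deg Groove axis direction (deg CCW from +x).
#' @param bin_deg Rose-histogram bin width (default 10 degrees).
#' @param min_windows Below this many striated windows the result is
#'   flagged low-confidence (default 10).
#' @return An `organization_result` list: `organization_index`,
#'   `circular_mean_deg`, `circular_sd_deg`, `n_windows_striated`,
#'   `low_confidence`, `rose` (tibble of bin mid-angles and counts).
#' @export
organization_index <- function(m, groove_axis_deg = 0, bin_deg = 10,
                               min_windows = 10L) {
  stopifnot(inherits(m, "orientation_map"))
  st <- m[m$striated & is.finite(m$angle_deg), ]
  n <- nrow(st)
  low <- n < min_windows
  if (low) cq_warn("only %d striated windows; organization index is low-confidence", n)
  if (n == 0L) {
    return(structure(list(organization_index = NA_real_,
                          circular_mean_deg = NA_real_,
                          circular_sd_deg = NA_real_,
                          n_windows_striated = 0L, low_confidence = TRUE,
                          rose = tibble::tibble(bin_mid_deg = numeric(0),
                                                count = integer(0))),
                     class = "organization_result"))
  }
  rel <- (st$angle_deg - groove_axis_deg) %% 180
  ax <- axial_stats(rel, weights = st$strength)
  edges <- seq(0, 180, by = bin_deg)
  cuts <- cut(rel, breaks = edges, include.lowest = TRUE, right = FALSE)
  rose <- tibble::tibble(bin_mid_deg = edges[-length(edges)] + bin_deg / 2,
                         count = as.integer(table(cuts)))
  structure(list(organization_index = ax$resultant,
                 circular_mean_deg = ax$mean_deg,
                 circular_sd_deg = ax$sd_deg,
                 n_windows_striated = n,
                 low_confidence = low,
                 rose = rose),
            class = "organization_result")
}

#' @export
print.organization_result <- function(x, ...) {
  cat(sprintf("<organization_result> index = %.3f; mean angle = %.1f deg; n = %d%s\n",
              x$organization_index, x$circular_mean_deg,
              x$n_windows_striated,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Tidy an organization result: the rose histogram
#' @param x An `organization_result`.
#' @param ... Unused.
#' @export
tidy.organization_result <- function(x, ...) x$rose

#' One-row summary of an organization result
#' @param x An `organization_result`.
#' @param ... Unused.
#' @export
glance.organization_result <- function(x, ...) {
  tibble::tibble(organization_index = x$organization_index,
                 circular_mean_deg = x$circular_mean_deg,
                 circular_sd_deg = x$circular_sd_deg,
                 n_windows_striated = x$n_windows_striated,
                 low_confidence = x$low_confidence)
}

#' Z-disc mask by Otsu thresholding within a cell mask
#'
#' @param actinin Alpha-actinin [image_frame()].
#' @param cell_mask Logical/0-1 matrix; `NULL` means the whole frame.
#' @return An [image_frame()] with 0/1 pixels (the Z-disc mask) and the
#'   threshold as attribute `threshold_value`.
#' @export
zdisc_mask <- function(actinin, cell_mask = NULL) {
  stopifnot(inherits(actinin, "image_frame"))
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(actinin$pixels),
                                              ncol(actinin$pixels))
  cell_mask <- cell_mask != 0
  if (!any(cell_mask)) stop_contract("empty cell mask")
  thr <- otsu_threshold(actinin$pixels[cell_mask])
  if (is.na(thr)) {
    stop_signal("degenerate (constant) image: no Otsu threshold")
  }
  mk <- (actinin$pixels > thr) & cell_mask
  out <- image_frame(mk * 1, actinin$pixel_size_um,
                     channel_label = "zdisc-mask", bit_depth = 8L)
  attr(out, "threshold_value") <- thr
  out
}

#' Sarcomere content: I_sarc / Area
#'
#' Global Otsu threshold within the cell mask separates Z-disc pixels
#' from non-sarcomeric pixels; the summed above-threshold alpha-actinin
#' intensity is divided by the cell area in um^2.
#'
#' @param actinin Alpha-actinin [image_frame()].
#' @param cell_mask Logical/0-1 matrix defining the cell (non-empty).
#' @return One-row tibble: `i_sarc_per_area` (intensity per um^2),
#'   `zdisc_area_frac`, `threshold_value`, `cell_area_um2`, `degenerate`.
#' @export
sarcomere_content <- function(actinin, cell_mask = NULL) {
  stopifnot(inherits(actinin, "image_frame"))
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(actinin$pixels),
                                              ncol(actinin$pixels))
  cell_mask <- cell_mask != 0
  if (!any(cell_mask)) stop_contract("empty cell mask")
  pxa <- actinin$pixel_size_um^2
  area <- sum(cell_mask) * pxa
  thr <- otsu_threshold(actinin$pixels[cell_mask])
  if (is.na(thr)) {
    cq_warn("degenerate (constant) image: sarcomere content undefined")
    return(tibble::tibble(i_sarc_per_area = NA_real_,
                          zdisc_area_frac = NA_real_,
                          threshold_value = NA_real_,
                          cell_area_um2 = area, degenerate = TRUE))
  }
  zd <- (actinin$pixels > thr) & cell_mask
  tibble::tibble(
    i_sarc_per_area = sum(actinin$pixels[zd]) / area,
    zdisc_area_frac = sum(zd) / sum(cell_mask),
    threshold_value = thr,
    cell_area_um2 = area,
    degenerate = FALSE)
}
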