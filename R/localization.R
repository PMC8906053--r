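# Immunofluorescence localization statistics: connexin-43 puncta per
# myocyte nucleus, channel area ratios, junction counting on
# groove-parallel line profiles, vinculin metrics and the
# sarcomeric:non-sarcomeric intensity partition.

as_mask <- function(x) {
  if (inherits(x, "image_frame")) x <- x$pixels
  if (!is.matrix(x)) stop_contract("mask must be a matrix or image_frame")
  x != 0
}

# Euclidean distance (in pixels) from every pixel to the nearest TRUE
# pixel of `mask`, via EBImage's distance transform of the complement.
dist_to_mask_px <- function(mask) {
  if (!any(mask)) stop_contract("mask has no foreground pixels")
  d <- EBImage::distmap(EBImage::Image(1 - mask * 1), metric = "euclidean")
  EBImage::imageData(d)
}

# Connected components above a threshold, with areas in um^2.
labelled_objects <- function(bin, pixel_size_um) {
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labv <- as.vector(EBImage::imageData(lab))
  n <- max(labv)
  if (n == 0) return(tibble::tibble(label = integer(0), area_um2 = numeric(0)))
  cnt <- tabulate(labv[labv > 0], nbins = n)
  tibble::tibble(label = seq_len(n), area_um2 = cnt * pixel_size_um^2)
}

#' Connexin-43 content per myocyte nucleus
#'
#' Cx43 puncta are Otsu-thresholded objects within a size range; nuclei
#' are Otsu-segmented, hole-filled and size-filtered; a nucleus counts as
#' a myocyte nucleus when the mean alpha-actinin intensity in a
#' perinuclear ring exceeds the alpha-actinin Otsu threshold (cultures
#' contain non-myocytes, which lack perinuclear sarcomeric actinin).
#'
#' @param cx43,actinin,nuclei Registered [image_frame()] channels.
#' @param puncta_range_um2 Punctum area range (default 0.1-10 um^2).
#' @param nucleus_min_um2 Minimum nucleus area (default 20 um^2).
#' @param ring_um Perinuclear ring width (default 2 um).
#' @return One-row tibble: `n_puncta`, `total_puncta_area_um2`,
#'   `n_nuclei`, `n_myocyte_nuclei`, `area_per_nucleus_um2`,
#'   `threshold_value`, `raw_thresholded_area_um2`.
#' @export
cx43_content <- function(cx43, actinin, nuclei,
                         puncta_range_um2 = c(0.1, 10),
                         nucleus_min_um2 = 20, ring_um = 2) {
  stopifnot(inherits(cx43, "image_frame"), inherits(actinin, "image_frame"),
            inherits(nuclei, "image_frame"))
  if (!identical(dim(cx43$pixels), dim(actinin$pixels)) ||
      !identical(dim(cx43$pixels), dim(nuclei$pixels))) {
    stop_contract("the three channels must share one shape")
  }
  px <- cx43$pixel_size_um
  thr_cx <- otsu_threshold(cx43$pixels)
  bin_cx <- if (is.na(thr_cx)) matrix(FALSE, nrow(cx43$pixels),
                                      ncol(cx43$pixels))
            else cx43$pixels > thr_cx
  objs <- labelled_objects(bin_cx, px)
  puncta <- objs[objs$area_um2 >= puncta_range_um2[1] &
                   objs$area_um2 <= puncta_range_um2[2], ]
  # nuclei: threshold, fill holes, size filter
  thr_nuc <- otsu_threshold(nuclei$pixels)
  bin_nuc <- EBImage::fillHull(EBImage::bwlabel(
    EBImage::Image((nuclei$pixels > thr_nuc) * 1)))
  labv <- EBImage::imageData(bin_nuc)
  nuc <- labelled_objects(labv > 0, px)
  # relabel after hole fill so labels and areas agree
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((labv > 0) * 1)))
  nuc_tab <- tabulate(lab[lab > 0])
  keep <- which(nuc_tab * px^2 >= nucleus_min_um2)
  thr_act <- otsu_threshold(actinin$pixels)
  if (is.na(thr_act)) thr_act <- Inf   # flat actinin: nothing is a myocyte
  ring_px <- ring_um / px
  is_myocyte <- vapply(keep, function(l) {
    m <- lab == l
    d <- dist_to_mask_px(m)
    ring <- d > 0 & d <= ring_px
    if (!any(ring)) return(FALSE)
    mean(actinin$pixels[ring]) > thr_act
  }, logical(1))
  n_myo <- sum(is_myocyte)
  total_area <- sum(puncta$area_um2)
  if (length(keep) == 0L) {
    cq_warn("no nuclei found; area per nucleus undefined")
  } else if (n_myo == 0L) {
    cq_warn("no myocyte (actinin-adjacent) nuclei; area per nucleus undefined")
  }
  tibble::tibble(
    n_puncta = nrow(puncta),
    total_puncta_area_um2 = total_area,
    n_nuclei = length(keep),
    n_myocyte_nuclei = n_myo,
    area_per_nucleus_um2 = if (n_myo > 0) total_area / n_myo else NA_real_,
    threshold_value = thr_cx,
    raw_thresholded_area_um2 = sum(bin_cx) * px^2)
}

#' Thresholded-area ratio of two channels
#'
#' Each channel is Otsu-thresholded; the ratio of above-threshold areas
#' is reported (e.g. N-cadherin area normalized to alpha-actinin area).
#'
#' @param numerator,denominator [image_frame()]s of equal shape.
#' @return One-row tibble: `numerator_area_um2`, `denominator_area_um2`,
#'   `ratio`.
#' @export
area_ratio <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "image_frame"),
            inherits(denominator, "image_frame"))
  area_of <- function(img) {
    thr <- otsu_threshold(img$pixels)
    if (is.na(thr)) stop_signal("degenerate (constant) channel")
    sum(img$pixels > thr) * img$pixel_size_um^2
  }
  num <- area_of(numerator)
  den <- area_of(denominator)
  if (den == 0) stop_contract("denominator channel has zero above-threshold area")
  tibble::tibble(numerator_area_um2 = num, denominator_area_um2 = den,
                 ratio = num / den)
}

# Peaks above a rolling-median baseline: excursions > baseline +
# beta * robust SD, with a minimum separation (greedy by height). The
# profile is pre-smoothed at the junction length scale (~1 um) so
# single-sample noise spikes cannot masquerade as junctions.
profile_peaks <- function(position_um, intensity, baseline_window_um = 20,
                          beta = 3, min_sep_um = 2, smooth_um = 1) {
  step <- stats::median(diff(position_um))
  raw <- intensity
  if (smooth_um > 0) {
    w <- 2L * floor(smooth_um / step / 2) + 1L
    if (w >= 3L) {
      half <- (w - 1L) %/% 2L
      xp <- c(rep(intensity[1], half), intensity,
              rep(intensity[length(intensity)], half))
      intensity <- as.numeric(stats::filter(xp, rep(1 / w, w),
                                            sides = 2))[(half + 1):(half + length(intensity))]
    }
  }
  k <- 2 * floor(baseline_window_um / step / 2) + 1
  if (k >= length(intensity)) return(NULL)  # line shorter than the window
  base <- stats::runmed(intensity, k, endrule = "median")
  resid <- intensity - base
  # threshold in units of the RAW profile's robust noise SD; candidate
  # maxima come from the smoothed residual so sub-junction-scale noise
  # spikes cannot split or fake a peak
  sigma <- stats::mad(raw - stats::runmed(raw, k, endrule = "median"))
  if (sigma == 0) sigma <- robust_noise_sd(raw)
  if (sigma == 0) sigma <- .Machine$double.eps
  cand <- local_maxima(resid)
  cand <- cand[resid[cand] > beta * sigma]
  if (length(cand) == 0L) {
    return(tibble::tibble(position_um = numeric(0), height = numeric(0)))
  }
  cand <- cand[order(resid[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(position_um[i] - position_um[keep]) >= min_sep_um)) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  tibble::tibble(position_um = position_um[keep], height = resid[keep])
}

#' Count junctions on groove-parallel intensity profiles
#'
#' Accepts either a single profile (tibble with `position_um`,
#' `intensity`), a list of profiles, or an [image_frame()] from which
#' lines parallel to the groove axis are sampled every `line_spacing_um`
#' (the groove/ridge pitch, so each myocyte lane is sampled once). Per
#' line the baseline is a rolling median and peaks are excursions above
#' `beta` robust SDs; counts are pooled and normalized to the total line
#' length in millimetres.
#'
#' @param x Profile tibble, list of such tibbles, or [image_frame()].
#' @param groove_axis_deg Groove axis direction (image input only).
#' @param line_spacing_um Distance between sampled lines (default 10 um).
#' @param baseline_window_um Rolling-median window (default 20 um).
#' @param beta Peak threshold in robust SDs (default 3).
#' @param min_sep_um Minimum peak separation (default 2 um).
#' @return One-row tibble: `n_lines`, `total_line_length_mm`,
#'   `n_junctions`, `junctions_per_mm`.
#' @export
count_junctions <- function(x, groove_axis_deg = 0, line_spacing_um = 10,
                            baseline_window_um = 20, beta = 3,
                            min_sep_um = 2) {
  profiles <-
    if (is.data.frame(x)) list(tibble::as_tibble(x))
    else if (inherits(x, "image_frame")) {
      extract_line_profiles(x, groove_axis_deg, line_spacing_um)
    } else if (is.list(x)) lapply(x, tibble::as_tibble)
    else stop_contract("`x` must be a profile, list of profiles, or image_frame")
  total_len_um <- 0
  n_junc <- 0L
  n_lines <- 0L
  for (pr in profiles) {
    if (!all(c("position_um", "intensity") %in% names(pr))) {
      stop_contract("profiles need columns position_um, intensity")
    }
    pk <- profile_peaks(pr$position_um, pr$intensity, baseline_window_um,
                        beta, min_sep_um)
    if (is.null(pk)) {
      cq_log("skipping line shorter than the baseline window")
      next
    }
    n_lines <- n_lines + 1L
    total_len_um <- total_len_um + diff(range(pr$position_um))
    n_junc <- n_junc + nrow(pk)
  }
  if (n_lines == 0L) stop_contract("no usable lines")
  tibble::tibble(n_lines = n_lines,
                 total_line_length_mm = total_len_um / 1000,
                 n_junctions = n_junc,
                 junctions_per_mm = n_junc / (total_len_um / 1000))
}

# Sample intensity profiles along lines parallel to the groove axis,
# spaced line_spacing_um apart, nearest-neighbour interpolation.
extract_line_profiles <- function(img, groove_axis_deg, line_spacing_um) {
  px <- img$pixel_size_um
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  th <- groove_axis_deg * pi / 180
  dir <- c(cos(th), sin(th))
  nrm <- c(-sin(th), cos(th))
  # project field corners on the normal to place the lines
  corners <- rbind(c(0, 0), c(nc * px, 0), c(0, nr * px), c(nc * px, nr * px))
  offs <- corners %*% nrm
  offsets <- seq(min(offs) + line_spacing_um / 2, max(offs), by = line_spacing_um)
  span <- sqrt((nc * px)^2 + (nr * px)^2)
  ss <- seq(-span, span, by = px)
  centre <- c(nc * px / 2, nr * px / 2)
  c0 <- sum(centre * nrm)
  lapply(offsets, function(o) {
    p0 <- centre + (o - c0) * nrm
    xs <- p0[1] + ss * dir[1]
    ys <- p0[2] + ss * dir[2]
    jj <- round(xs / px + 0.5); ii <- round(ys / px + 0.5)
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    if (sum(ok) < 2) return(NULL)
    tibble::tibble(position_um = ss[ok] - min(ss[ok]),
                   intensity = img$pixels[cbind(ii[ok], jj[ok])])
  }) |> Filter(f = Negate(is.null))
}

#' Vinculin intensity and focal-adhesion area
#'
#' Mean vinculin intensity within the cell mask, plus focal-adhesion
#' area: Otsu-within-mask above-threshold objects passing a minimum size,
#' normalized to the cell area.
#'
#' @param vinc Vinculin [image_frame()].
#' @param cell_mask Logical/0-1 matrix (non-empty).
#' @param fa_min_um2 Minimum adhesion size (default 0.2 um^2).
#' @return One-row tibble: `mean_intensity`, `fa_area_um2`,
#'   `cell_area_um2`, `fa_area_frac`, `degenerate`.
#' @export
vinculin_metrics <- function(vinc, cell_mask, fa_min_um2 = 0.2) {
  stopifnot(inherits(vinc, "image_frame"))
  cell_mask <- as_mask(cell_mask)
  if (!any(cell_mask)) stop_contract("empty cell mask")
  px <- vinc$pixel_size_um
  cell_area <- sum(cell_mask) * px^2
  mean_int <- mean(vinc$pixels[cell_mask])
  thr <- otsu_threshold(vinc$pixels[cell_mask])
  if (is.na(thr)) {
    cq_warn("degenerate (uniform) vinculin channel: adhesion area undefined")
    return(tibble::tibble(mean_intensity = mean_int, fa_area_um2 = NA_real_,
                          cell_area_um2 = cell_area, fa_area_frac = NA_real_,
                          degenerate = TRUE))
  }
  bin <- (vinc$pixels > thr) & cell_mask
  objs <- labelled_objects(bin, px)
  fa_area <- sum(objs$area_um2[objs$area_um2 >= fa_min_um2])
  tibble::tibble(mean_intensity = mean_int, fa_area_um2 = fa_area,
                 cell_area_um2 = cell_area,
                 fa_area_frac = fa_area / cell_area, degenerate = FALSE)
}

#' Sarcomeric vs non-sarcomeric intensity partition
#'
#' The sarcomeric compartment is every cell pixel within `annulus_um` of
#' a Z-disc pixel (Euclidean distance transform with a ceiling pixel
#' radius, so the stated distance errs inclusive); the statistic is the
#' mean per-pixel intensity inside the compartment divided by the mean
#' outside (within the cell mask) — e.g. Ub_sarc:Ub_non-sarc for
#' K48-linked ubiquitin.
#'
#' @param ub Signal [image_frame()] (e.g. oligo-K48 ubiquitin).
#' @param zdisc Z-disc mask ([image_frame()] or 0/1 matrix).
#' @param annulus_um Dilation distance (default 0.65 um); 0 uses the
#'   undilated Z-disc mask as the compartment.
#' @param cell_mask Optional logical/0-1 matrix; `NULL` = whole frame.
#' @return One-row tibble: `mean_intensity_in`, `mean_intensity_out`,
#'   `ratio_in_out`, `compartment_area_frac`, `radius_px`.
#' @export
ubiquitin_partition <- function(ub, zdisc, annulus_um = 0.65,
                                cell_mask = NULL) {
  stopifnot(inherits(ub, "image_frame"))
  zd <- as_mask(zdisc)
  if (!identical(dim(zd), dim(ub$pixels))) {
    stop_contract("Z-disc mask shape differs from signal image")
  }
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(zd), ncol(zd))
  cell_mask <- as_mask(cell_mask)
  if (any(zd & !cell_mask)) stop_contract("Z-disc mask extends outside the cell mask")
  if (annulus_um < 0) stop_contract("annulus_um must be >= 0")
  px <- ub$pixel_size_um
  radius_px <- as.integer(ceiling(annulus_um / px))
  compartment <- if (radius_px == 0L) zd else {
    dist_to_mask_px(zd) <= radius_px
  }
  compartment <- compartment & cell_mask
  outside <- cell_mask & !compartment
  if (!any(outside)) {
    stop_contract("compartment covers the whole cell: no outside pixels")
  }
  if (!any(compartment)) stop_contract("compartment is empty")
  m_in <- mean(ub$pixels[compartment])
  m_out <- mean(ub$pixels[outside])
  tibble::tibble(mean_intensity_in = m_in, mean_intensity_out = m_out,
                 ratio_in_out = m_in / m_out,
                 compartment_area_frac = sum(compartment) / sum(cell_mask),
                 radius_px = radius_px)
}
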