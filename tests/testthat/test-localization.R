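# Localization statistics: puncta per nucleus, area ratios, junction
# counting, vinculin metrics and the compartment partition.

px <- 0.25
mk <- function(m, label = "") image_frame(m, px, channel_label = label)

build_cx43_field <- function() {
  np <- 200
  cx <- matrix(10, np, np); act <- matrix(10, np, np); nuc <- matrix(5, np, np)
  # 12 puncta of 4x4 px = 1 um^2 at 0.25 um/px
  pos <- cbind(seq(10, 175, by = 15), rev(seq(10, 175, by = 15)))[1:12, ]
  for (i in 1:12) cx[pos[i, 1] + 0:3, pos[i, 2] + 0:3] <- 200
  yy <- row(nuc); xx <- col(nuc)
  centers <- rbind(c(40, 40), c(40, 150), c(150, 40), c(150, 150))
  for (i in 1:4) {
    d2 <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2
    nuc[d2 <= 12^2] <- 220
    act[d2 <= 20^2 & d2 > 12^2] <- 180
  }
  list(cx = mk(cx), act = mk(act), nuc = mk(nuc))
}

test_that("Cx43 content normalizes punctum area to myocyte nuclei", {
  f <- build_cx43_field()
  r <- cx43_content(f$cx, f$act, f$nuc)
  expect_equal(r$n_puncta, 12L)
  expect_equal(r$total_puncta_area_um2, 12)
  expect_equal(r$n_myocyte_nuclei, 4L)
  expect_equal(r$area_per_nucleus_um2, 3)
})

test_that("Cx43 edge cases: no puncta, and nuclei without perinuclear actinin", {
  f <- build_cx43_field()
  blank <- mk(matrix(10, 200, 200))
  r <- cx43_content(blank, f$act, f$nuc)
  expect_equal(r$total_puncta_area_um2, 0)
  expect_equal(r$n_puncta, 0L)
  # actinin flat -> no myocyte nuclei -> area per nucleus missing
  flat_act <- mk(matrix(10, 200, 200))
  expect_warning(r2 <- cx43_content(f$cx, flat_act, f$nuc), "myocyte")
  expect_true(is.na(r2$area_per_nucleus_um2))
  expect_equal(r2$n_puncta, 12L)
})

test_that("area ratio divides Otsu areas and guards the denominator", {
  a <- matrix(10, 100, 100); a[1:40, ] <- 200    # 4000 px
  b <- matrix(10, 100, 100); b[1:80, ] <- 200    # 8000 px
  r <- area_ratio(mk(a), mk(b))
  expect_equal(r$ratio, 0.5)
  expect_equal(r$numerator_area_um2, 4000 * px^2)
  expect_equal(area_ratio(mk(a), mk(a))$ratio, 1)
  expect_error(area_ratio(mk(a), mk(matrix(5, 100, 100))),
               class = "cq_signal_error")
})

test_that("generated partition pairs give the expected area-fraction quotient", {
  m1 <- matrix(FALSE, 80, 80); m1[1:20, ] <- TRUE    # fraction 0.25
  m2 <- matrix(FALSE, 80, 80); m2[1:40, ] <- TRUE    # fraction 0.50
  g1 <- gen_partition_image(m1, px, ratio_true = 8, noise_sd = 2, seed = 1)
  g2 <- gen_partition_image(m2, px, ratio_true = 8, noise_sd = 2, seed = 2)
  r <- area_ratio(g1$signal, g2$signal)
  expect_equal(r$ratio, 0.5, tolerance = 0.05)
})

test_that("junction counts recover generator truth and scale per millimetre", {
  g <- gen_junction_profile(0.5, 7, noise_sd = 2, seed = 1)
  r <- count_junctions(g$profile)
  expect_equal(r$n_junctions, 7L)
  expect_equal(r$junctions_per_mm, 14)
  expect_equal(r$total_line_length_mm, 0.5)

  flat <- tibble::tibble(position_um = seq(0, 500, 0.5), intensity = 20)
  expect_equal(count_junctions(flat)$n_junctions, 0L)

  # raising beta can only lower the count
  g2 <- gen_junction_profile(0.5, 7, noise_sd = 15, seed = 2)
  n3 <- count_junctions(g2$profile, beta = 3)$n_junctions
  n10 <- count_junctions(g2$profile, beta = 10)$n_junctions
  expect_lte(n10, n3)

  # lines shorter than the baseline window are skipped
  short <- tibble::tibble(position_um = seq(0, 10, 0.5), intensity = 20)
  expect_error(suppressMessages(count_junctions(short)),
               class = "cq_contract_error")
})

test_that("junction detection meets sensitivity and precision 0.95 at peak SNR 5", {
  tp <- fp <- fn <- 0L
  for (s in 1:20) {
    g <- gen_junction_profile(0.5, 7, peak_amp = 100, noise_sd = 20, seed = s)
    pk <- cardioquant:::profile_peaks(g$profile$position_um,
                                      g$profile$intensity)
    matched <- logical(nrow(pk))
    for (tpos in g$truth$position_um) {
      j <- which(!matched & abs(pk$position_um - tpos) < 5)
      if (length(j)) { matched[j[1]] <- TRUE; tp <- tp + 1L } else fn <- fn + 1L
    }
    fp <- fp + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("line profiles extracted from an image count banded junctions", {
  # vertical grooves (axis 90 deg): junction bands horizontal
  np <- 400
  img <- matrix(20, np, np)
  for (r0 in c(100, 200, 300)) img[r0 + (-2:2), ] <- 150
  r <- suppressMessages(count_junctions(mk(img), groove_axis_deg = 90,
                                        line_spacing_um = 10))
  expect_gt(r$n_lines, 5)
  expect_equal(r$n_junctions / r$n_lines, 3, tolerance = 0.1)
})

test_that("vinculin metrics report mean intensity and size-filtered adhesion area", {
  vm <- matrix(50, 100, 100)
  vm[10:29, 10:33] <- 250            # 480 px = 30 um^2
  cell <- matrix(TRUE, 100, 100)     # 625 um^2
  r <- vinculin_metrics(mk(vm), cell)
  expect_equal(r$mean_intensity, mean(vm))
  expect_equal(r$fa_area_um2, 30)
  expect_equal(r$fa_area_frac, 30 / 625)

  # doubling intensity doubles the mean, leaves the area fraction alone
  r2 <- vinculin_metrics(mk(vm * 2), cell)
  expect_equal(r2$mean_intensity, 2 * r$mean_intensity)
  expect_equal(r2$fa_area_frac, r$fa_area_frac, tolerance = 0.02)

  ru <- suppressWarnings(vinculin_metrics(mk(matrix(7, 50, 50)),
                                          matrix(TRUE, 50, 50)))
  expect_equal(ru$mean_intensity, 7)
  expect_true(ru$degenerate)
  expect_error(vinculin_metrics(mk(vm), matrix(FALSE, 100, 100)),
               class = "cq_contract_error")
})

test_that("the compartment partition is exact by construction and scale-invariant", {
  g <- gen_striated_image(striation_sim_params(
    pixel_size_um = px, image_size_um = 64, angle_kappa = Inf, noise_sd = 0,
    seed = 1))
  zd <- zdisc_mask(g$image)
  # paint the dilated compartment at exactly 2x the outside intensity
  d <- cardioquant:::dist_to_mask_px(zd$pixels != 0)
  comp <- d <= 3
  gi <- gen_partition_image(comp, px, ratio_true = 2, noise_sd = 0)
  r <- ubiquitin_partition(gi$signal, zd, annulus_um = 0.65)
  expect_equal(r$ratio_in_out, 2)
  expect_equal(r$radius_px, 3L)      # ceiling(0.65 / 0.25)

  # uniform image -> ratio 1
  ru <- ubiquitin_partition(mk(matrix(40, 256, 256)), zd)
  expect_equal(ru$ratio_in_out, 1)

  # annulus 0: exact match with the brute-force per-pixel oracle
  gi0 <- gen_partition_image(zd$pixels != 0, px, ratio_true = 1.7,
                             noise_sd = 5, seed = 2)
  r0 <- ubiquitin_partition(gi0$signal, zd, annulus_um = 0)
  zmask <- zd$pixels != 0
  expect_identical(r0$mean_intensity_in, mean(gi0$signal$pixels[zmask]))
  expect_identical(r0$mean_intensity_out, mean(gi0$signal$pixels[!zmask]))
  expect_identical(r0$ratio_in_out,
                   mean(gi0$signal$pixels[zmask]) /
                     mean(gi0$signal$pixels[!zmask]))

  # intensity-scale invariance
  sc <- gi0$signal; sc$pixels <- sc$pixels * 11.7
  expect_equal(ubiquitin_partition(sc, zd, 0)$ratio_in_out, r0$ratio_in_out,
               tolerance = 1e-12)
})

test_that("the dilation radius follows the ceiling rule and grows with the annulus", {
  zd <- matrix(FALSE, 40, 40); zd[20, 20] <- TRUE
  img <- mk(matrix(1, 40, 40))
  radii <- vapply(c(0.1, 0.25, 0.3, 0.65, 1.0), function(a) {
    ubiquitin_partition(img, zd * 1, annulus_um = a)$radius_px
  }, integer(1))
  expect_identical(radii, c(1L, 1L, 2L, 3L, 4L))   # ceiling(a / 0.25)
  expect_true(all(diff(radii) >= 0))
})

test_that("partition contracts: mask containment and whole-cell compartments error", {
  zd <- matrix(FALSE, 20, 20); zd[5:15, 5:15] <- TRUE
  img <- mk(matrix(1, 20, 20))
  expect_error(ubiquitin_partition(img, zd * 1, annulus_um = 10),
               class = "cq_contract_error")   # compartment covers the cell
  cellm <- matrix(FALSE, 20, 20); cellm[8:12, 8:12] <- TRUE
  expect_error(ubiquitin_partition(img, zd * 1, cell_mask = cellm),
               class = "cq_contract_error")   # zdisc outside cell mask
})
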