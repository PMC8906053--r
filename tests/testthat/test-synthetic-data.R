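# The generators are first-class code: their statistical structure and
# ground truth are what every downstream recovery test leans on.

test_that("paced calcium trains have exact beat times and amplitudes", {
  p <- calcium_sim_params(stim_freq_hz = 0.5, n_beats = 10, spont_rate_hz = 0,
                          noise_sd = 0, seed = 1)
  g <- gen_calcium_trace(p, 22)
  beats <- g$events$time_s[g$events$type == "stim"]
  expect_length(beats, 10L)
  expect_equal(diff(beats), rep(2, 9))
  expect_equal(sum(g$events$type == "spont"), 0L)

  # isolated beats: peak equals baseline_f0 * (1 + amplitude); use a slow
  # rate so residual superposition from the previous beat is negligible
  p2 <- calcium_sim_params(stim_freq_hz = 0.2, n_beats = 3, noise_sd = 0,
                           decay_tau_s = 0.4, seed = 1)
  g2 <- gen_calcium_trace(p2, 16)
  expect_equal(max(g2$trace$F), p2$baseline_f0 * (1 + p2$amplitude),
               tolerance = 1e-3)
})

test_that("spontaneous event counts are seed-reproducible and flagged with hosts", {
  p <- calcium_sim_params(spont_rate_hz = 0.1, seed = 42)
  g1 <- gen_calcium_trace(p, 200)
  g2 <- gen_calcium_trace(p, 200)
  expect_identical(g1$trace$F, g2$trace$F)           # bit-reproducible
  expect_identical(g1$events, g2$events)
  n_sp <- sum(g1$events$type == "spont")
  expect_gt(n_sp, 5)                                 # ~20 expected at 0.1 Hz
  # an event inside a beat's pulse support carries that beat's index
  sp <- g1$events[g1$events$type == "spont", ]
  beats <- g1$events$time_s[g1$events$type == "stim"]
  hosted <- sp[!is.na(sp$host_beat), ]
  if (nrow(hosted) > 0) {
    expect_true(all(hosted$time_s >= beats[hosted$host_beat]))
  }
  expect_error(calcium_sim_params(spont_amp_frac = 1.2),
               class = "cq_contract_error")
})

test_that("Boussinesq forward field is antisymmetric, linear in 1/E and ~1/r far off", {
  adh <- dipole_adhesions(f = 60, sep = 40)
  p1 <- traction_sim_params(adhesions = adh, modulus_pa = 10000, seed = 1)
  u1 <- boussinesq_forward(p1, grid_n = 32)
  # antisymmetry about the dipole midpoint (64, 64): the contractile
  # pair maps onto itself under point reflection with force sign flip,
  # so u(2m - x) = -u(x)
  probe <- tibble::tibble(x_um = c(54, 74), y_um = c(60, 68))
  up <- boussinesq_forward(p1, at = probe)
  expect_equal(up$ux_um[1], -up$ux_um[2], tolerance = 1e-10)
  expect_equal(up$uy_um[1], -up$uy_um[2], tolerance = 1e-10)

  # doubling E halves all displacements
  p2 <- traction_sim_params(adhesions = adh, modulus_pa = 20000, seed = 1)
  u2 <- boussinesq_forward(p2, grid_n = 32)
  expect_equal(u2$ux_um, u1$ux_um / 2, tolerance = 1e-12)

  # single force: far-field magnitude decays as 1/r (evaluate the
  # Green's function at two radii; companion force far away to balance)
  adh2 <- data.frame(x_um = c(64, 6400), y_um = c(64, 64),
                     fx_nn = c(0, 0), fy_nn = c(50, -50), radius_um = 1)
  p3 <- traction_sim_params(adhesions = adh2, field_size_um = 12800, seed = 1)
  r12 <- boussinesq_forward(p3, at = tibble::tibble(x_um = c(64 + 40, 64 + 80),
                                                    y_um = c(64, 64)))
  mag <- sqrt(r12$ux_um^2 + r12$uy_um^2)
  expect_equal(mag[1] / mag[2], 2, tolerance = 0.01)

  # unbalanced sets are rejected
  expect_error(traction_sim_params(
    adhesions = data.frame(x_um = 1, y_um = 1, fx_nn = 10, fy_nn = 0,
                           radius_um = 1)), class = "cq_contract_error")
})

test_that("bead image pairs render displacement faithfully and deterministically", {
  adh <- dipole_adhesions()
  p <- traction_sim_params(adhesions = adh, noise_sd = 0, seed = 5)
  # zero field -> identical frames
  g0 <- gen_bead_images(p, displacement_fn = function(x, y)
    list(ux = rep(0, length(x)), uy = rep(0, length(x))))
  expect_identical(g0$relaxed$pixels, g0$deformed$pixels)
  # pure translation by exactly one pixel -> shifted image
  g1 <- gen_bead_images(p, displacement_fn = function(x, y)
    list(ux = rep(0.5, length(x)), uy = rep(0, length(x))))
  a <- g1$relaxed$pixels; b <- g1$deformed$pixels
  expect_lt(max(abs(b[, 2:ncol(b)] - a[, 1:(ncol(a) - 1)])),
            1e-6 * max(a))
  # determinism under seed
  p2 <- traction_sim_params(adhesions = adh, noise_sd = 0.02, seed = 11)
  ga <- gen_bead_images(p2)
  gb <- gen_bead_images(p2)
  expect_identical(ga$relaxed$pixels, gb$relaxed$pixels)
  expect_identical(ga$deformed$pixels, gb$deformed$pixels)
})

test_that("FRAP curves follow the closed form and encode the mobile fraction", {
  # single k, no immobile pool, no drift/noise: normalized recovery is
  # exactly (1 - bd) + bd (1 - exp(-k t))
  p <- frap_sim_params(k_true_per_s = 0.02, bleach_depth = 0.8,
                       noise_sd = 0, seed = 1)
  g <- gen_frap_curves(p)
  cv <- normalize_frap(g$traces, n_prebleach = p$n_prebleach)
  post <- cv[cv$time_s >= 0, ]
  expect_equal(post$intensity,
               0.2 + 0.8 * (1 - exp(-0.02 * post$time_s)), tolerance = 1e-9)
  # immobile fraction 0.3 -> plateau 1 - 0.8*0.3 = 0.76, mobile 0.7
  p2 <- frap_sim_params(k_true_per_s = 0.05, immobile_frac = 0.3,
                        noise_sd = 0, seed = 1)
  g2 <- gen_frap_curves(p2)
  expect_equal(g2$truth$mobile_fraction, 0.7)
  cv2 <- normalize_frap(g2$traces, n_prebleach = 5)
  expect_equal(tail(cv2$intensity, 1), 1 - 0.8 * 0.3, tolerance = 1e-3)
  expect_error(frap_sim_params(k_true_per_s = 0.02, bleach_depth = 1.5),
               class = "cq_contract_error")
})

test_that("striation patches carry the requested angles, concentration and spacing", {
  # kappa = Inf: every ground-truth angle equals the mean
  g <- gen_striated_image(striation_sim_params(mean_angle_deg = 90,
                                               angle_kappa = Inf, seed = 1))
  expect_true(all(g$truth$angle_deg == 90))

  # kappa = 0: circular variance of the axial sampler ~ 1 at n >= 500
  ang <- withr::with_seed(7, cardioquant:::sample_axial_angles(600, 90, 0))
  R <- cardioquant:::axial_stats(ang)$resultant
  expect_lt(R, 0.1)    # circular variance 1 - R ~ 1

  # dominant spatial frequency of a patch profile = 1 / spacing
  p <- striation_sim_params(sarcomere_spacing_um = 1.9, pixel_size_um = 0.1,
                            mean_angle_deg = 90, angle_kappa = Inf,
                            noise_sd = 0, seed = 2)
  g2 <- gen_striated_image(p)
  # Z-disc lines at 90 deg vary along x: take one row
  prof <- g2$image$pixels[10, 1:128]
  sp <- Mod(fft(prof - mean(prof)))^2
  freq <- (seq_along(prof) - 1) / (length(prof) * 0.1)
  peak_f <- freq[which.max(sp[2:(length(prof) / 2)]) + 1]
  expect_equal(1 / peak_f, 1.9, tolerance = 0.05)

  expect_error(striation_sim_params(sarcomere_spacing_um = 0.2,
                                    pixel_size_um = 0.1),
               class = "cq_contract_error")
})

test_that("partition images hit the requested intensity ratio", {
  mask <- matrix(FALSE, 40, 40); mask[11:20, ] <- TRUE
  g <- gen_partition_image(mask, 0.25, ratio_true = 1.0, noise_sd = 0)
  expect_equal(stats::sd(g$signal$pixels), 0)      # flat image
  g2 <- gen_partition_image(mask, 0.25, ratio_true = 2.0, noise_sd = 0)
  expect_equal(mean(g2$signal$pixels[mask]) / mean(g2$signal$pixels[!mask]), 2)
  # Monte-Carlo recovery of ratio 1.5 under noise, 20 seeds
  ratios <- vapply(1:20, function(s) {
    gi <- gen_partition_image(mask, 0.25, ratio_true = 1.5, noise_sd = 10,
                              seed = s)
    r <- ubiquitin_partition(gi$signal, mask * 1, annulus_um = 0)
    r$ratio_in_out
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1.5), 3 * se + 1e-3)
})

test_that("junction profiles place resolvable peaks and honour n = 0", {
  g0 <- gen_junction_profile(0.5, 0, noise_sd = 0)
  expect_equal(stats::sd(g0$profile$intensity), 0)
  g <- gen_junction_profile(0.5, 7, noise_sd = 0, seed = 3)
  expect_equal(nrow(g$truth), 7L)
  expect_true(min(diff(sort(g$truth$position_um))) >= 20)
  expect_error(gen_junction_profile(0.05, 40), class = "cq_contract_error")
})
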