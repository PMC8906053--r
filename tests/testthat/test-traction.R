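# Traction force microscopy: reference-frame choice, PIV accuracy, FTTC
# inversion properties and the forward-inverse round trip.

test_that("the most relaxed frame is selected as reference", {
  adh <- dipole_adhesions()
  p <- traction_sim_params(adhesions = adh, field_size_um = 64,
                           noise_sd = 0.01, seed = 2)
  # mostly-diastolic video: the pixelwise median is the relaxed state;
  # three identical relaxed frames also exercise the lowest-index tie-break
  frames <- lapply(c(0, 1, 0.8, 0, 0), function(a) {
    g <- gen_bead_images(p, displacement_fn = function(x, y)
      list(ux = rep(0.4 * a, length(x)), uy = rep(0, length(x))))
    if (a == 0) g$relaxed else g$deformed
  })
  st <- image_stack(frames, 0.05)
  expect_equal(suppressMessages(select_reference_frame(st)), 1L)

  # all-identical frames tie-break to the lowest index
  same <- image_stack(rep(frames[1], 3), 0.05)
  expect_equal(suppressMessages(select_reference_frame(same)), 1L)
  expect_error(select_reference_frame(image_stack(frames[1], 0.05)),
               class = "cq_contract_error")
})

test_that("PIV recovers a uniform shift within 0.05 um per vector", {
  adh <- dipole_adhesions()
  p <- traction_sim_params(adhesions = adh, seed = 1, noise_sd = 0)
  g <- gen_bead_images(p, displacement_fn = function(x, y)
    list(ux = rep(0.5, length(x)), uy = rep(0, length(x))))
  pv <- piv_displacement(g$relaxed, g$deformed)
  err <- sqrt((pv$ux_um - 0.5)^2 + pv$uy_um^2)
  expect_lt(max(err), 0.05)
  expect_lt(sqrt(mean(err^2)), 0.02)
})

test_that("PIV noise floor on identical-field images is small", {
  adh <- dipole_adhesions()
  p <- traction_sim_params(adhesions = adh, seed = 2)  # default 2% noise
  g <- gen_bead_images(p, displacement_fn = function(x, y)
    list(ux = rep(0, length(x)), uy = rep(0, length(x))))
  pv <- piv_displacement(g$relaxed, g$deformed)
  expect_lt(max(sqrt(pv$ux_um^2 + pv$uy_um^2)), 0.02)
})

test_that("PIV tracks the Boussinesq dipole field (pooled R^2 >= 0.9)", {
  adh <- dipole_adhesions()
  p <- traction_sim_params(adhesions = adh, seed = 1)
  g <- gen_bead_images(p)
  pv <- piv_displacement(g$relaxed, g$deformed)
  truth <- boussinesq_forward(p, at = pv[, c("x_um", "y_um")])
  expect_gte(field_r2(pv$ux_um, pv$uy_um, truth$ux_um, truth$uy_um), 0.9)
})

test_that("FTTC inversion is linear, drift-invariant and null on zero input", {
  adh <- dipole_adhesions()
  p <- traction_sim_params(adhesions = adh, seed = 3)
  g <- gen_bead_images(p)
  pv <- piv_displacement(g$relaxed, g$deformed)

  zero <- pv; zero$ux_um <- 0; zero$uy_um <- 0
  t0 <- fttc_inversion(zero, 1e4, 0.5, lambda = 1e-3)
  expect_equal(max(abs(c(t0$tx_pa, t0$ty_pa))), 0)

  t1 <- fttc_inversion(pv, 1e4, 0.5, lambda = 1e-3)
  # doubling E (with lambda scaled to keep the operator identical)
  t2 <- fttc_inversion(pv, 2e4, 0.5, lambda = 5e-4)
  expect_equal(t2$tx_pa, 2 * t1$tx_pa, tolerance = 1e-12)
  expect_equal(t2$ty_pa, 2 * t1$ty_pa, tolerance = 1e-12)

  # adding a uniform displacement changes nothing (zero-frequency removal)
  shifted <- pv; shifted$ux_um <- shifted$ux_um + 0.7
  t3 <- fttc_inversion(shifted, 1e4, 0.5, lambda = 1e-3)
  expect_equal(t3$tx_pa, t1$tx_pa, tolerance = 1e-8)

  expect_error(fttc_inversion(pv, 1e4, 0.5, lambda = -1),
               class = "cq_contract_error")
  nan_field <- pv; nan_field$ux_um[3] <- NaN
  expect_error(fttc_inversion(nan_field, 1e4, 0.5),
               class = "cq_contract_error")
})

test_that("total force unit arithmetic is exact and additive under masks", {
  # uniform 100 Pa over a 1000 um^2 grid -> 100 Pa um^2 * 1e-3 = 100 nN
  n <- 10
  tf <- tibble::tibble(
    x_um = rep(seq(5, 95, by = 10), n) ,
    y_um = rep(seq(5, 95, by = 10), each = n),
    tx_pa = 100, ty_pa = 0)
  attr(tf, "grid_spacing_um") <- sqrt(1000 / (n * n))
  attr(tf, "grid_dim") <- c(n, n)
  class(tf) <- c("traction_field", class(tibble::tibble()))
  expect_equal(total_force(tf), 100)
  half <- rep(c(TRUE, FALSE), length.out = n * n)
  expect_equal(total_force(tf, half) + total_force(tf, !half), 100)
  expect_error(total_force(tf, rep(FALSE, n * n)), class = "cq_contract_error")

  zf <- tf; zf$tx_pa <- 0
  expect_equal(total_force(zf), 0)
})

test_that("forward -> render -> PIV -> FTTC recovers total force within 10% (median of seeds)", {
  errs <- vapply(1:5, function(s) {
    n_adh <- withr::with_seed(500 + s, sample(2:6, 1))
    adh <- withr::with_seed(1000 + s, random_adhesion_set(n_adh))
    p <- traction_sim_params(adhesions = adh, seed = s)
    g <- gen_bead_images(p)
    pv <- piv_displacement(g$relaxed, g$deformed, overlap_frac = 0.75)
    tf <- suppressMessages(fttc_inversion(pv, 1e4, 0.5))
    cx <- mean(adh$x_um); cy <- mean(adh$y_um)
    rmax <- max(sqrt((adh$x_um - cx)^2 + (adh$y_um - cy)^2)) + 8
    Fm <- total_force(tf, function(x, y) sqrt((x - cx)^2 + (y - cy)^2) <= rmax)
    abs(Fm / sum(sqrt(adh$fx_nn^2 + adh$fy_nn^2)) - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("contraction metrics recover prescribed velocities and flat statics", {
  adh <- dipole_adhesions(sep = 48, centre = 48)
  p <- traction_sim_params(adhesions = adh, field_size_um = 96,
                           noise_sd = 0.01, seed = 7)
  nfr <- 31; dt <- 1 / 30
  amp <- sin(pi * (0:(nfr - 1)) * dt)^2   # one 1-s beat
  frames <- lapply(seq_len(nfr), function(i) {
    g <- gen_bead_images(p, displacement_fn = function(x, y)
      list(ux = rep(0.4 * amp[i], length(x)), uy = rep(0, length(x))))
    if (amp[i] == 0) g$relaxed else g$deformed
  })
  st <- image_stack(frames, dt)
  cfg <- assay_config(pixel_size_um = 0.5, frame_interval_s = dt)
  cm <- suppressMessages(contraction_metrics(st, cfg))
  v_true <- 0.4 * pi   # max |d/dt| of 0.4 sin^2(pi t)
  expect_equal(cm$contraction_velocity_um_s, v_true, tolerance = 0.1)
  expect_equal(cm$relaxation_velocity_um_s, v_true, tolerance = 0.1)
  expect_equal(cm$peak_force_nn, max(cm$timeseries$total_force_nn))

  static <- image_stack(rep(frames[1], 6), dt)
  cs <- suppressMessages(contraction_metrics(static, cfg))
  expect_lt(cs$contraction_velocity_um_s, 0.05)
  expect_lt(max(cs$timeseries$total_force_nn) -
              min(cs$timeseries$total_force_nn), 2)
  expect_error(contraction_metrics(image_stack(frames[1:4], dt), cfg),
               class = "cq_contract_error")
})
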