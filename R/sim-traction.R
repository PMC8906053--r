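# Synthetic traction-force microscopy data: an elastic half-space forward
# model (direct spatial summation -- deliberately independent of the
# Fourier-space inversion it is used to test) and a fluorescent-bead
# image renderer.

#' Parameters for the traction simulator
#'
#' Focal adhesions are tangential disc loads on the surface of an elastic
#' half-space (the hydrogel). The force set must balance: the vector sum
#' over adhesions is forced to zero, as for any self-equilibrated cell.
#'
#' @param field_size_um Side length of the square field of view (um).
#' @param pixel_size_um Micrometres per pixel of the rendered bead images.
#' @param modulus_pa Substrate Young's modulus (default 10000 Pa).
#' @param poisson_ratio Substrate Poisson ratio (default 0.5).
#' @param adhesions Tibble/data frame with columns `x_um`, `y_um`,
#'   `fx_nn`, `fy_nn`, `radius_um`: adhesion centres, force vectors and
#'   disc radii. Forces must sum to zero (tolerance 1e-6 of total |F|).
#' @param bead_density_per_um2 Bead surface density.
#' @param bead_sigma_um Gaussian bead spot SD (um).
#' @param noise_sd Additive image noise SD as a fraction of unit bead peak.
#' @param seed Optional RNG seed.
#' @return A `traction_sim_params` object.
#' @export
traction_sim_params <- function(field_size_um = 128,
                                pixel_size_um = 0.5,
                                modulus_pa = 10000,
                                poisson_ratio = 0.5,
                                adhesions,
                                bead_density_per_um2 = 0.15,
                                bead_sigma_um = 0.4,
                                noise_sd = 0.02,
                                seed = NULL) {
  check_number(field_size_um, "field_size_um", min = 0, strict_min = TRUE)
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_number(modulus_pa, "modulus_pa", min = 0, strict_min = TRUE)
  check_number(poisson_ratio, "poisson_ratio", min = 0, max = 0.5)
  adhesions <- tibble::as_tibble(adhesions)
  req <- c("x_um", "y_um", "fx_nn", "fy_nn", "radius_um")
  if (!all(req %in% names(adhesions))) {
    stop_contract("`adhesions` needs columns: %s", paste(req, collapse = ", "))
  }
  if (any(adhesions$radius_um <= 0)) stop_contract("adhesion radii must be > 0")
  ftot <- sum(sqrt(adhesions$fx_nn^2 + adhesions$fy_nn^2))
  if (ftot <= 0) stop_contract("adhesion set carries zero force")
  imbalance <- sqrt(sum(adhesions$fx_nn)^2 + sum(adhesions$fy_nn)^2)
  if (imbalance > 1e-6 * ftot) {
    stop_contract("force balance violated: |sum F| = %.3g nN (%.2g%% of total)",
                  imbalance, 100 * imbalance / ftot)
  }
  check_number(bead_density_per_um2, "bead_density_per_um2", min = 0,
               strict_min = TRUE)
  check_number(bead_sigma_um, "bead_sigma_um", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(list(field_size_um = field_size_um, pixel_size_um = pixel_size_um,
                 modulus_pa = modulus_pa, poisson_ratio = poisson_ratio,
                 adhesions = adhesions,
                 bead_density_per_um2 = bead_density_per_um2,
                 bead_sigma_um = bead_sigma_um, noise_sd = noise_sd,
                 seed = seed),
            class = "traction_sim_params")
}

#' Random balanced adhesion set
#'
#' Convenience sampler: `n` adhesions at random positions in the central
#' part of the field, random force directions/magnitudes, with the net
#' force removed by subtracting the mean force vector (keeping the set
#' balanced by construction).
#'
#' @param n Number of adhesions (>= 2).
#' @param field_size_um Field side length (um).
#' @param force_scale_nn Typical per-adhesion force magnitude (nN).
#' @param radius_um Disc radius (um).
#' @param min_sep_um Minimum centre-to-centre separation (um). The
#'   force-transmitting sites of a contracting cardiomyocyte (cell ends,
#'   costameres) are tens of micrometres apart; a +/- force pair much
#'   closer than the displacement-measurement resolution would be a
#'   physically unresolvable dipole.
#' @return Adhesion tibble suitable for [traction_sim_params()].
#' @export
random_adhesion_set <- function(n, field_size_um = 128, force_scale_nn = 50,
                                radius_um = 4, min_sep_um = 25) {
  if (n < 2) stop_contract("need >= 2 adhesions to balance forces")
  lo <- 0.28 * field_size_um; hi <- 0.72 * field_size_um
  repeat {
    x <- runif(n, lo, hi); y <- runif(n, lo, hi)
    if (min(stats::dist(cbind(x, y))) >= min_sep_um) break
  }
  th <- runif(n, 0, 2 * pi)
  mag <- force_scale_nn * runif(n, 0.5, 1.5)
  fx <- mag * cos(th); fy <- mag * sin(th)
  fx <- fx - mean(fx); fy <- fy - mean(fy)
  tibble::tibble(x_um = x, y_um = y, fx_nn = fx, fy_nn = fy,
                 radius_um = radius_um)
}

# Boussinesq/Cerruti surface Green's function: in-plane displacement (um)
# at targets (tx, ty) due to tangential point forces (fx, fy in nN) at
# sources (sx, sy), on a half-space with Young's modulus E (Pa), Poisson
# ratio nu. Plummer softening eps_um keeps on-source values finite.
# Unit bookkeeping: nN / (Pa * um) = 1e-9 N / (1e-9 N/um^2 * um) = um.
boussinesq_point_sum <- function(tx, ty, sx, sy, fx, fy, modulus_pa,
                                 poisson_ratio, eps_um = 0) {
  nu <- poisson_ratio
  pref <- (1 + nu) / (pi * modulus_pa) * 1e3  # nN, um -> um (1 nN/um = 1e3 Pa*um)
  ux <- numeric(length(tx)); uy <- numeric(length(tx))
  for (j in seq_along(sx)) {
    dx <- tx - sx[j]; dy <- ty - sy[j]
    r2 <- dx^2 + dy^2 + eps_um^2
    r <- sqrt(r2)
    ux <- ux + pref * (((1 - nu) / r + nu * dx^2 / (r * r2)) * fx[j] +
                         (nu * dx * dy / (r * r2)) * fy[j])
    uy <- uy + pref * ((nu * dx * dy / (r * r2)) * fx[j] +
                         ((1 - nu) / r + nu * dy^2 / (r * r2)) * fy[j])
  }
  list(ux = ux, uy = uy)
}

# Decompose each adhesion disc into point loads on a hexagonal-ish grid.
disc_sources <- function(adh, pitch_frac = 1 / 3) {
  out <- vector("list", nrow(adh))
  for (i in seq_len(nrow(adh))) {
    R <- adh$radius_um[i]
    pitch <- R * pitch_frac
    g <- seq(-R, R, by = pitch)
    pts <- expand.grid(dx = g, dy = g)
    pts <- pts[pts$dx^2 + pts$dy^2 <= R^2, , drop = FALSE]
    n <- nrow(pts)
    out[[i]] <- tibble::tibble(x = adh$x_um[i] + pts$dx,
                               y = adh$y_um[i] + pts$dy,
                               fx = adh$fx_nn[i] / n,
                               fy = adh$fy_nn[i] / n,
                               eps = pitch / 2)
  }
  dplyr::bind_rows(out)
}

#' Forward elastic half-space displacement (direct summation oracle)
#'
#' Evaluates the surface displacement of an elastic half-space under the
#' balanced tangential disc loads of `p`, by direct spatial summation of
#' the Boussinesq/Cerruti surface Green's function over disc sample
#' points. Slow and simple by design: this is the forward oracle the
#' Fourier-space inversion ([fttc_inversion()]) is validated against, and
#' shares no code with it.
#'
#' @param p A [traction_sim_params()].
#' @param at Optional tibble of target positions (`x_um`, `y_um`). By
#'   default a regular grid of `grid_n` x `grid_n` points over the field.
#' @param grid_n Grid points per side for the default target grid.
#' @return A `displacement_field` tibble (`x_um`, `y_um`, `ux_um`,
#'   `uy_um`) with grid attributes when evaluated on the default grid.
#' @export
boussinesq_forward <- function(p, at = NULL, grid_n = 32) {
  stopifnot(inherits(p, "traction_sim_params"))
  src <- disc_sources(p$adhesions)
  if (is.null(at)) {
    spacing <- p$field_size_um / grid_n
    ax <- spacing * (seq_len(grid_n) - 0.5)
    at <- tidyr::expand_grid(y_um = ax, x_um = ax)[, c("x_um", "y_um")]
    regular <- TRUE
  } else {
    at <- tibble::as_tibble(at)
    regular <- FALSE
  }
  u <- boussinesq_point_sum(at$x_um, at$y_um, src$x, src$y, src$fx, src$fy,
                            p$modulus_pa, p$poisson_ratio,
                            eps_um = max(src$eps))
  out <- tibble::tibble(x_um = at$x_um, y_um = at$y_um,
                        ux_um = u$ux, uy_um = u$uy,
                        quality = 1, replaced = FALSE)
  if (regular) {
    attr(out, "grid_spacing_um") <- spacing
    attr(out, "grid_dim") <- c(grid_n, grid_n)
  }
  class(out) <- c("displacement_field", class(tibble::tibble()))
  out
}

# Render Gaussian bead spots at (bx, by) um into an npx x npx image.
render_beads <- function(bx, by, npx, pixel_size_um, sigma_um, amp = 1) {
  img <- matrix(0, npx, npx)
  s_px <- sigma_um / pixel_size_um
  half <- ceiling(4 * s_px)
  for (i in seq_along(bx)) {
    cx <- bx[i] / pixel_size_um + 0.5  # pixel centre coordinates (1-based)
    cy <- by[i] / pixel_size_um + 0.5
    jx <- max(1, floor(cx - half)):min(npx, ceiling(cx + half))
    jy <- max(1, floor(cy - half)):min(npx, ceiling(cy + half))
    if (length(jx) == 0L || length(jy) == 0L) next
    gx <- exp(-((jx - cx)^2) / (2 * s_px^2))
    gy <- exp(-((jy - cy)^2) / (2 * s_px^2))
    img[jy, jx] <- img[jy, jx] + amp * outer(gy, gx)
  }
  img
}

#' Generate a relaxed/deformed bead image pair with ground truth
#'
#' Beads are Gaussian spots at uniform-random positions; the deformed
#' frame renders each bead displaced by the true elastic field (from
#' [boussinesq_forward()], or a user-supplied analytic field). Gaussian
#' read noise is added to both frames.
#'
#' @param p A [traction_sim_params()].
#' @param displacement_fn Optional function `(x_um, y_um) -> list(ux, uy)`
#'   overriding the Boussinesq field (e.g. a uniform shift for tests).
#' @param grid_n Grid resolution for the returned true field.
#' @return List with `relaxed`, `deformed` ([image_frame()]s),
#'   `true_field` (a `displacement_field` tibble on a regular grid),
#'   `beads` (positions and their true displacements), and `params`.
#' @export
gen_bead_images <- function(p, displacement_fn = NULL, grid_n = 32) {
  stopifnot(inherits(p, "traction_sim_params"))
  with_seed_opt(p$seed, {
    npx <- round(p$field_size_um / p$pixel_size_um)
    n_beads <- rpois(1, p$bead_density_per_um2 * p$field_size_um^2)
    bx <- runif(n_beads, 0, p$field_size_um)
    by <- runif(n_beads, 0, p$field_size_um)
    if (is.null(displacement_fn)) {
      src <- disc_sources(p$adhesions)
      ub <- boussinesq_point_sum(bx, by, src$x, src$y, src$fx, src$fy,
                                 p$modulus_pa, p$poisson_ratio,
                                 eps_um = max(src$eps))
      true_field <- boussinesq_forward(p, grid_n = grid_n)
    } else {
      ub <- displacement_fn(bx, by)
      spacing <- p$field_size_um / grid_n
      ax <- spacing * (seq_len(grid_n) - 0.5)
      gr <- tidyr::expand_grid(y_um = ax, x_um = ax)[, c("x_um", "y_um")]
      ug <- displacement_fn(gr$x_um, gr$y_um)
      true_field <- tibble::tibble(x_um = gr$x_um, y_um = gr$y_um,
                                   ux_um = ug$ux, uy_um = ug$uy,
                                   quality = 1, replaced = FALSE)
      attr(true_field, "grid_spacing_um") <- spacing
      attr(true_field, "grid_dim") <- c(grid_n, grid_n)
      class(true_field) <- c("displacement_field", class(tibble::tibble()))
    }
    relaxed <- render_beads(bx, by, npx, p$pixel_size_um, p$bead_sigma_um)
    deformed <- render_beads(bx + ub$ux, by + ub$uy, npx, p$pixel_size_um,
                             p$bead_sigma_um)
    if (p$noise_sd > 0) {
      relaxed <- relaxed + rnorm(length(relaxed), 0, p$noise_sd)
      deformed <- deformed + rnorm(length(deformed), 0, p$noise_sd)
    }
    scale <- 65535 / max(relaxed, deformed, 1e-9)
    mk <- function(m) image_frame(pmax(m, 0) * scale, p$pixel_size_um,
                                  channel_label = "beads", bit_depth = 16L)
    list(relaxed = mk(relaxed), deformed = mk(deformed),
         true_field = true_field,
         beads = tibble::tibble(x_um = bx, y_um = by,
                                ux_um = ub$ux, uy_um = ub$uy),
         params = p)
  })
}
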