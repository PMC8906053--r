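# Synthetic alpha-actinin striation images: patches of parallel Z-disc
# lines with angles drawn from an axial von Mises distribution, plus
# ground-truth per-patch angles.

#' Parameters for the striated-image simulator
#'
#' Angles are orientations (period 180 degrees); they are sampled by the
#' standard axial construction: draw `2*theta` from a von Mises
#' distribution with mean `2*mean_angle_deg` and concentration
#' `angle_kappa`, then halve. `kappa = Inf` gives a single angle,
#' `kappa = 0` the uniform orientation distribution.
#'
#' @param image_size_um Side length of the square image (um).
#' @param pixel_size_um Micrometres per pixel (default 0.1).
#' @param sarcomere_spacing_um Z-disc spacing (default 1.9 um).
#' @param mean_angle_deg Mean Z-disc line orientation, degrees CCW from
#'   +x in \[0, 180).
#' @param angle_kappa Von Mises concentration (>= 0; `Inf` allowed).
#' @param patch_size_um Side of the independently oriented patches.
#' @param zdisc_intensity,background_intensity Rendered intensities.
#' @param zdisc_duty Z-disc line thickness as a fraction of the spacing.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Optional RNG seed.
#' @return A `striation_sim_params` object.
#' @export
striation_sim_params <- function(image_size_um = 51.2,
                                 pixel_size_um = 0.1,
                                 sarcomere_spacing_um = 1.9,
                                 mean_angle_deg = 90,
                                 angle_kappa = Inf,
                                 patch_size_um = 12.8,
                                 zdisc_intensity = 150,
                                 background_intensity = 50,
                                 zdisc_duty = 0.3,
                                 noise_sd = 5,
                                 seed = NULL) {
  check_number(image_size_um, "image_size_um", min = 0, strict_min = TRUE)
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_number(sarcomere_spacing_um, "sarcomere_spacing_um", min = 0,
               strict_min = TRUE)
  if (sarcomere_spacing_um / pixel_size_um < 3) {
    stop_contract("sarcomere spacing below 3 pixels is unresolvable")
  }
  if (!(is.numeric(angle_kappa) && length(angle_kappa) == 1L &&
        (is.infinite(angle_kappa) || angle_kappa >= 0))) {
    stop_contract("angle_kappa must be >= 0 (Inf allowed)")
  }
  check_number(patch_size_um, "patch_size_um", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(list(image_size_um = image_size_um, pixel_size_um = pixel_size_um,
                 sarcomere_spacing_um = sarcomere_spacing_um,
                 mean_angle_deg = mean_angle_deg, angle_kappa = angle_kappa,
                 patch_size_um = patch_size_um,
                 zdisc_intensity = zdisc_intensity,
                 background_intensity = background_intensity,
                 zdisc_duty = zdisc_duty, noise_sd = noise_sd, seed = seed),
            class = "striation_sim_params")
}

# Von Mises sampler (Best & Fisher rejection algorithm); kappa = 0 ->
# uniform, kappa = Inf -> point mass at mu. Angles in radians.
rvonmises <- function(n, mu, kappa) {
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# Sample n axial orientations (deg in [0, 180)).
sample_axial_angles <- function(n, mean_deg, kappa) {
  th2 <- rvonmises(n, 2 * mean_deg * pi / 180, kappa)
  (th2 * 180 / pi / 2) %% 180
}

#' Generate a striated image with ground-truth patch angles
#'
#' The image is tiled into square patches; each patch is rendered as
#' parallel Z-disc lines (thickness `zdisc_duty * spacing`) at an angle
#' drawn from the axial von Mises distribution.
#'
#' @param p A [striation_sim_params()].
#' @return List with `image` (an [image_frame()]), `truth` (tibble of
#'   patch centres and angles), and `params`.
#' @export
gen_striated_image <- function(p) {
  stopifnot(inherits(p, "striation_sim_params"))
  with_seed_opt(p$seed, {
    npx <- round(p$image_size_um / p$pixel_size_um)
    patch_px <- round(p$patch_size_um / p$pixel_size_um)
    n_tiles <- floor(npx / patch_px)
    if (n_tiles < 1) stop_contract("image smaller than one patch")
    angles <- sample_axial_angles(n_tiles^2, p$mean_angle_deg, p$angle_kappa)
    img <- matrix(p$background_intensity, npx, npx)
    truth <- vector("list", n_tiles^2)
    k <- 0
    for (iy in seq_len(n_tiles)) {
      for (ix in seq_len(n_tiles)) {
        k <- k + 1
        ang <- angles[k]
        rows <- ((iy - 1) * patch_px + 1):(iy * patch_px)
        cols <- ((ix - 1) * patch_px + 1):(ix * patch_px)
        # physical coordinates of patch pixels (pixel centres)
        xs <- (cols - 0.5) * p$pixel_size_um
        ys <- (rows - 0.5) * p$pixel_size_um
        # distance along the striation normal (Z-disc lines run along `ang`)
        nrm <- (ang + 90) * pi / 180
        dmat <- outer(ys * sin(nrm), xs * cos(nrm), `+`)
        phase <- (dmat / p$sarcomere_spacing_um) %% 1
        on_line <- phase < p$zdisc_duty
        img[rows, cols] <- p$background_intensity +
          (p$zdisc_intensity - p$background_intensity) * on_line
        truth[[k]] <- tibble::tibble(
          x_um = mean(xs), y_um = mean(ys), angle_deg = ang)
      }
    }
    if (p$noise_sd > 0) img <- img + rnorm(length(img), 0, p$noise_sd)
    img <- pmax(img, 0)
    list(image = image_frame(img, p$pixel_size_um,
                             channel_label = "alpha-actinin"),
         truth = dplyr::bind_rows(truth),
         params = p)
  })
}
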