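# Traction force microscopy: PIV bead tracking, regularized Fourier
# transform traction cytometry (FTTC) on an elastic half-space, total
# force, and per-contraction velocity metrics.

#' Select the most relaxed reference frame of a bead stack
#'
#' Returns the index of the frame minimizing the summed absolute
#' difference to the pixelwise median frame — in a beating-cell video the
#' diastolic (undeformed) state. Ties break to the lowest index.
#'
#' @param stack An [image_stack()] with >= 2 frames.
#' @return Integer frame index.
#' @export
select_reference_frame <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack)
  if (n < 2L) stop_contract("need >= 2 frames to pick a reference")
  arr <- vapply(stack$frames, function(f) as.numeric(f$pixels),
                numeric(length(stack$frames[[1]]$pixels)))
  med <- matrixStats_rowMedians(arr)
  score <- colSums(abs(arr - med))
  idx <- which.min(score)
  cq_log("reference frame %d (of %d)", idx, n)
  idx
}

# rowMedians without the matrixStats dependency
matrixStats_rowMedians <- function(m) apply(m, 1L, stats::median)

# FFT-based cross-correlation of two equal-size windows (means removed,
# normalized by the product of SDs so the peak is a correlation
# coefficient in [-1, 1] for aligned content).
window_xcorr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NULL)
  n <- nrow(a)
  # zero-pad to 2n to avoid wrap-around
  pa <- matrix(0, 2 * n, 2 * n); pa[1:n, 1:n] <- a
  pb <- matrix(0, 2 * n, 2 * n); pb[1:n, 1:n] <- b
  # R's inverse fft is unnormalized: divide by the padded length
  cc <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / length(pa) / (na * nb)
  # unbiased estimate: undo the triangular overlap weighting of the
  # zero-padded correlation (which biases peaks toward zero shift)
  sh <- c(0:(n - 1), -(n:1))
  wt <- n / pmax(n - abs(sh), 1)
  cc * outer(wt, wt)
}

# Exact normalized cross-correlation of two windows at integer shift
# (dy, dx), computed over the valid overlap only (Pearson coefficient).
ncc_at <- function(a, b, dy, dx) {
  n <- nrow(a)
  ra <- max(1, 1 - dy):min(n, n - dy)
  ca <- max(1, 1 - dx):min(n, n - dx)
  if (length(ra) < 4 || length(ca) < 4) return(NA_real_)
  av <- a[ra, ca]
  bv <- b[ra + dy, ca + dx]
  av <- av - mean(av); bv <- bv - mean(bv)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(NA_real_)
  sum(av * bv) / den
}

# 3-point Gaussian sub-pixel interpolation along one axis.
subpixel_gauss <- function(cm1, c0, cp1) {
  if (cm1 <= 0 || c0 <= 0 || cp1 <= 0 || c0 < cm1 || c0 < cp1) {
    # parabolic fallback when log-Gaussian is undefined
    den <- cm1 - 2 * c0 + cp1
    return(if (den == 0) 0 else 0.5 * (cm1 - cp1) / den)
  }
  den <- 2 * (log(cm1) - 2 * log(c0) + log(cp1))
  if (den == 0) return(0)
  (log(cm1) - log(cp1)) / den
}

#' PIV displacement field between two bead images
#'
#' Windowed normalized cross-correlation with 3-point Gaussian sub-pixel
#' peak interpolation in x and y. Vectors whose correlation peak falls
#' below `quality_min` are replaced by the median of their neighbours and
#' flagged.
#'
#' @param reference,deformed [image_frame()]s of equal shape/pixel size.
#' @param window_size_um Interrogation window side (um).
#' @param overlap_frac Window overlap fraction (default 0.5).
#' @param quality_min Minimum acceptable correlation peak (default 0.3).
#' @param max_disp_frac Largest credible displacement as a fraction of
#'   the window size; larger peaks are treated as failures.
#' @return A `displacement_field` tibble: `x_um`, `y_um`, `ux_um`,
#'   `uy_um`, `quality`, `replaced`, with grid attributes.
#' @export
piv_displacement <- function(reference, deformed, window_size_um = 12,
                             overlap_frac = 0.5, quality_min = 0.3,
                             max_disp_frac = 1 / 3) {
  stopifnot(inherits(reference, "image_frame"), inherits(deformed, "image_frame"))
  if (!identical(dim(reference$pixels), dim(deformed$pixels))) {
    stop_contract("reference and deformed frames differ in shape")
  }
  if (reference$pixel_size_um != deformed$pixel_size_um) {
    stop_contract("reference and deformed frames differ in pixel size")
  }
  px <- reference$pixel_size_um
  w <- 2L * max(2L, round(window_size_um / px / 2))  # even window in pixels
  npx <- dim(reference$pixels)
  step <- max(1L, round(w * (1 - overlap_frac)))
  xs <- seq(1L, npx[2] - w + 1L, by = step)
  ys <- seq(1L, npx[1] - w + 1L, by = step)
  if (length(xs) == 0L || length(ys) == 0L) {
    stop_contract("image smaller than one PIV window")
  }
  max_px <- max(1, floor(w * max_disp_frac))
  res <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      k <- k + 1L
      rw <- ys[iy]:(ys[iy] + w - 1L)
      cw <- xs[ix]:(xs[ix] + w - 1L)
      a <- reference$pixels[rw, cw]
      b <- deformed$pixels[rw, cw]
      cc <- window_xcorr(a, b)
      ok <- !is.null(cc)
      dx <- dy <- 0; q <- 0
      if (ok) {
        n2 <- nrow(cc)
        # admissible circular shifts: [-max_px, max_px]
        shift_of <- function(i) ifelse(i - 1L <= n2 / 2, i - 1L, i - 1L - n2)
        rows_ok <- which(abs(shift_of(seq_len(n2))) <= max_px)
        sub <- cc[rows_ok, rows_ok, drop = FALSE]
        pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        sy <- shift_of(rows_ok[pk[1]]); sx <- shift_of(rows_ok[pk[2]])
        # refine with exact overlap-normalized correlation around the
        # integer peak (removes the padding/weighting bias of the FFT
        # correlogram from the sub-pixel fit)
        nb <- outer(-1:1, -1:1,
                    Vectorize(function(ddy, ddx) ncc_at(a, b, sy + ddy, sx + ddx)))
        if (any(is.na(nb))) {
          q <- max(0, sub[pk[1], pk[2]])
        } else {
          # re-centre on the best exact value if it moved
          ctr <- which(nb == max(nb), arr.ind = TRUE)[1, ]
          if (any(ctr != c(2, 2))) {
            sy <- sy + (ctr[1] - 2L); sx <- sx + (ctr[2] - 2L)
            nb <- outer(-1:1, -1:1,
                        Vectorize(function(ddy, ddx) ncc_at(a, b, sy + ddy, sx + ddx)))
          }
          q <- nb[2, 2]
          if (!any(is.na(nb))) {
            dy <- sy + subpixel_gauss(nb[1, 2], nb[2, 2], nb[3, 2])
            dx <- sx + subpixel_gauss(nb[2, 1], nb[2, 2], nb[2, 3])
          } else {
            dy <- sy; dx <- sx
          }
        }
        if (is.na(q)) q <- 0
      }
      res[[k]] <- tibble::tibble(
        x_um = (xs[ix] - 1 + w / 2) * px,
        y_um = (ys[iy] - 1 + w / 2) * px,
        ux_um = dx * px, uy_um = dy * px,
        quality = max(0, min(1, q)))
    }
  }
  out <- dplyr::bind_rows(res)
  out$replaced <- out$quality < quality_min
  if (any(out$replaced)) {
    # replace poor vectors by the median of their 8-neighbourhood
    nxg <- length(xs); nyg <- length(ys)
    ux <- matrix(out$ux_um, nyg, nxg, byrow = TRUE)
    uy <- matrix(out$uy_um, nyg, nxg, byrow = TRUE)
    bad <- matrix(out$replaced, nyg, nxg, byrow = TRUE)
    for (iy in seq_len(nyg)) for (ix in seq_len(nxg)) {
      if (!bad[iy, ix]) next
      ry <- max(1, iy - 1):min(nyg, iy + 1)
      rx <- max(1, ix - 1):min(nxg, ix + 1)
      good <- !bad[ry, rx]
      if (any(good)) {
        ux[iy, ix] <- stats::median(ux[ry, rx][good])
        uy[iy, ix] <- stats::median(uy[ry, rx][good])
      } else {
        ux[iy, ix] <- 0; uy[iy, ix] <- 0
      }
    }
    out$ux_um <- as.vector(t(ux))
    out$uy_um <- as.vector(t(uy))
    cq_log("replaced %d / %d low-quality PIV vectors", sum(out$replaced),
           nrow(out))
  }
  attr(out, "grid_spacing_um") <- step * px
  attr(out, "grid_dim") <- c(length(ys), length(xs))
  attr(out, "window_size_um") <- w * px
  class(out) <- c("displacement_field", class(tibble::tibble()))
  out
}

# Bilinearly resample a displacement field onto a regular n x n grid
# spanning its bounding box. Used when the input grid is irregular.
regularize_field <- function(d, n) {
  xr <- range(d$x_um); yr <- range(d$y_um)
  ax <- seq(xr[1], xr[2], length.out = n)
  ay <- seq(yr[1], yr[2], length.out = n)
  interp1 <- function(v) {
    # inverse-distance interpolation (k = 4 nearest), adequate for mild
    # irregularity
    g <- tidyr::expand_grid(y_um = ay, x_um = ax)[, c("x_um", "y_um")]
    vapply(seq_len(nrow(g)), function(i) {
      d2 <- (d$x_um - g$x_um[i])^2 + (d$y_um - g$y_um[i])^2
      o <- order(d2)[1:4]
      w <- 1 / pmax(d2[o], 1e-12)
      sum(w * v[o]) / sum(w)
    }, numeric(1))
  }
  g <- tidyr::expand_grid(y_um = ay, x_um = ax)[, c("x_um", "y_um")]
  out <- tibble::tibble(x_um = g$x_um, y_um = g$y_um,
                        ux_um = interp1(d$ux_um), uy_um = interp1(d$uy_um),
                        quality = 1, replaced = FALSE)
  attr(out, "grid_spacing_um") <- ax[2] - ax[1]
  attr(out, "grid_dim") <- c(n, n)
  class(out) <- c("displacement_field", class(tibble::tibble()))
  out
}

field_matrices <- function(d) {
  gd <- attr(d, "grid_dim")
  if (is.null(gd)) stop_contract("displacement field lacks grid attributes")
  list(ux = matrix(d$ux_um, gd[1], gd[2], byrow = TRUE),
       uy = matrix(d$uy_um, gd[1], gd[2], byrow = TRUE))
}

# Half-space Green's operator in Fourier space (Butler et al. form):
# u~(k) = G~(k) T~(k), with
# G~ = 2(1+nu) / (E k^3) * [ (1-nu)k^2 + nu ky^2,  -nu kx ky ;
#                            -nu kx ky,            (1-nu)k^2 + nu kx^2 ]
# Units: k in rad/um, E in Pa, u in um -> T in Pa after the nN/um
# conversion folded into the 1e3 factor of the forward model's prefactor;
# here everything stays in Pa and um: G~ has units um/Pa * 1e-3? No --
# 1/(Pa * um^-1) = um/Pa * 1e0; the 1e3 arises only for nN point forces.
# With T in Pa and u in um, G~ = 2(1+nu)/(E k) * M / k^2 has units
# 1/(Pa um^-1) = um/Pa: consistent. (Traction in Pa = nN/um^2 * 1e3.)
fttc_solve <- function(ux, uy, spacing_um, modulus_pa, poisson_ratio, lambda,
                       window_size_um = NULL) {
  n1 <- nrow(ux); n2 <- ncol(ux)
  Ux <- fft(ux); Uy <- fft(uy)
  kx1 <- 2 * pi * c(0:(floor(n2 / 2)), -((ceiling(n2 / 2) - 1):1)) / (n2 * spacing_um)
  ky1 <- 2 * pi * c(0:(floor(n1 / 2)), -((ceiling(n1 / 2) - 1):1)) / (n1 * spacing_um)
  KX <- matrix(kx1, n1, n2, byrow = TRUE)
  KY <- matrix(ky1, n1, n2)
  K <- sqrt(KX^2 + KY^2)
  if (!is.null(window_size_um) && window_size_um > 0) {
    # inverse-filter the PIV interrogation-window averaging (a w x w
    # moving average has MTF sinc(kx w/2) sinc(ky w/2)); the correction
    # is floored so noise at wavelengths near the window size is not
    # blown up
    sinc <- function(z) ifelse(z == 0, 1, sin(z) / z)
    H <- sinc(KX * window_size_um / 2) * sinc(KY * window_size_um / 2)
    H <- sign(H) * pmax(abs(H), 0.25)
    Ux <- Ux / H; Uy <- Uy / H
  }
  nu <- poisson_ratio; E <- modulus_pa
  pref <- 2 * (1 + nu) / (E * pmax(K, 1e-30)^3)
  Gxx <- pref * ((1 - nu) * K^2 + nu * KY^2)
  Gyy <- pref * ((1 - nu) * K^2 + nu * KX^2)
  Gxy <- pref * (-nu * KX * KY)
  # Tikhonov: T = (G'G + lambda^2 I)^-1 G' U per wavevector (G symmetric)
  A11 <- Gxx^2 + Gxy^2 + lambda^2
  A22 <- Gxy^2 + Gyy^2 + lambda^2
  A12 <- Gxy * (Gxx + Gyy)
  det <- A11 * A22 - A12^2
  B1 <- Gxx * Ux + Gxy * Uy   # G' U
  B2 <- Gxy * Ux + Gyy * Uy
  Tx <- (A22 * B1 - A12 * B2) / det
  Ty <- (A11 * B2 - A12 * B1) / det
  Tx[1, 1] <- 0; Ty[1, 1] <- 0   # remove rigid drift / net force offset
  tx <- Re(fft(Tx, inverse = TRUE)) / (n1 * n2)
  ty <- Re(fft(Ty, inverse = TRUE)) / (n1 * n2)
  # residual and solution norms in Fourier domain (Parseval) for L-curve
  Rx <- Gxx * Tx + Gxy * Ty - Ux
  Ry <- Gxy * Tx + Gyy * Ty - Uy
  Rx[1, 1] <- 0; Ry[1, 1] <- 0
  list(tx = tx, ty = ty,
       resid_norm = sqrt(sum(Mod(Rx)^2 + Mod(Ry)^2)),
       sol_norm = sqrt(sum(Mod(Tx)^2 + Mod(Ty)^2)))
}

# L-curve corner: maximum curvature of (log resid, log sol) over a lambda
# grid scaled to the Green's operator magnitude.
lcurve_lambda <- function(ux, uy, spacing_um, modulus_pa, poisson_ratio,
                          n_lambda = 25, window_size_um = NULL) {
  # reference scale: |G| at the fundamental wavenumber
  k0 <- 2 * pi / (max(dim(ux)) * spacing_um)
  g0 <- 2 * (1 + poisson_ratio) / (modulus_pa * k0)
  lams <- g0 * 10^seq(-6, 1, length.out = n_lambda)
  rho <- eta <- numeric(n_lambda)
  for (i in seq_along(lams)) {
    s <- fttc_solve(ux, uy, spacing_um, modulus_pa, poisson_ratio, lams[i],
                    window_size_um = window_size_um)
    rho[i] <- log(s$resid_norm + 1e-300)
    eta[i] <- log(s$sol_norm + 1e-300)
  }
  # discrete curvature
  d1r <- diff(rho); d1e <- diff(eta)
  kappa <- numeric(n_lambda - 2)
  for (i in seq_len(n_lambda - 2)) {
    x1 <- rho[i]; x2 <- rho[i + 1]; x3 <- rho[i + 2]
    y1 <- eta[i]; y2 <- eta[i + 1]; y3 <- eta[i + 2]
    a <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    b <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
    c <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
    area2 <- abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
    kappa[i] <- if (a * b * c > 0) 4 * area2 / (a * b * c) else 0
  }
  lams[which.max(kappa) + 1L]
}

#' Regularized Fourier-transform traction cytometry (FTTC)
#'
#' Inverts the elastic half-space Green's operator in Fourier space with
#' Tikhonov regularization; the zero-frequency component is set to zero,
#' removing rigid drift (and making the result invariant to a uniform
#' displacement offset).
#'
#' By default (`lambda = NULL`) the regularization is resolution-matched:
#' `lambda = 3 (1 + nu) / (E k_ny)` with `k_ny` the grid Nyquist
#' wavenumber, i.e. 1.5x the Green's-operator gain at the finest
#' resolvable wavelength, which damps sub-resolution modes by >= 70%
#' while leaving well-resolved modes essentially untouched. An L-curve
#' corner choice (`lambda = "lcurve"`) is also available; note that on a
#' band-limited displacement grid the noise-amplification branch of the
#' L-curve is bounded and the corner is often degenerate.
#'
#' @param d A `displacement_field` on a regular grid (irregular input is
#'   resampled with a log message).
#' @param modulus_pa Substrate Young's modulus (Pa).
#' @param poisson_ratio Substrate Poisson ratio.
#' @param lambda Tikhonov parameter (>= 0), `NULL` for the
#'   resolution-matched default, or `"lcurve"` for the L-curve corner.
#' @param mtf_correction If `TRUE` and the field carries a PIV window
#'   size, inverse-filter the interrogation-window averaging (sinc^2
#'   MTF, floored) before inversion. Off by default: it trades bias for
#'   noise and needs correspondingly stronger regularization.
#' @return A `traction_field` tibble: `x_um`, `y_um`, `tx_pa`, `ty_pa`,
#'   with attributes `grid_spacing_um`, `grid_dim`, `lambda`.
#' @export
fttc_inversion <- function(d, modulus_pa, poisson_ratio = 0.5, lambda = NULL,
                           mtf_correction = FALSE) {
  if (is.numeric(lambda) && lambda < 0) stop_contract("lambda must be >= 0")
  if (any(!is.finite(d$ux_um)) || any(!is.finite(d$uy_um))) {
    stop_contract("displacement field contains non-finite vectors")
  }
  if (is.null(attr(d, "grid_dim"))) {
    cq_log("irregular displacement grid; resampling to a regular grid")
    d <- regularize_field(d, 2^ceiling(log2(sqrt(nrow(d)))))
  }
  m <- field_matrices(d)
  spacing <- attr(d, "grid_spacing_um")
  win <- if (mtf_correction) attr(d, "window_size_um") else NULL
  if (is.null(lambda)) {
    k_ny <- pi / spacing
    lambda <- 3 * (1 + poisson_ratio) / (modulus_pa * k_ny)
    cq_log("resolution-matched lambda = %.3g", lambda)
  } else if (identical(lambda, "lcurve")) {
    lambda <- lcurve_lambda(m$ux, m$uy, spacing, modulus_pa, poisson_ratio,
                            window_size_um = win)
    cq_log("L-curve lambda = %.3g", lambda)
  }
  s <- fttc_solve(m$ux, m$uy, spacing, modulus_pa, poisson_ratio, lambda,
                  window_size_um = win)
  out <- tibble::tibble(x_um = d$x_um, y_um = d$y_um,
                        tx_pa = as.vector(t(s$tx)),
                        ty_pa = as.vector(t(s$ty)))
  attr(out, "grid_spacing_um") <- spacing
  attr(out, "grid_dim") <- attr(d, "grid_dim")
  attr(out, "modulus_pa") <- modulus_pa
  attr(out, "poisson_ratio") <- poisson_ratio
  attr(out, "lambda") <- lambda
  class(out) <- c("traction_field", class(tibble::tibble()))
  out
}

#' Total traction force
#'
#' `sum(|T| * dA)` over the grid (optionally restricted to a cell mask),
#' converted to nanonewtons: 1 Pa um^2 = 1e-3 nN.
#'
#' @param t A `traction_field`.
#' @param cell_mask Optional logical vector (one entry per grid node) or
#'   predicate `function(x_um, y_um) -> logical`.
#' @return Total force in nN.
#' @export
total_force <- function(t, cell_mask = NULL) {
  stopifnot(inherits(t, "traction_field"))
  dA <- attr(t, "grid_spacing_um")^2
  keep <- rep(TRUE, nrow(t))
  if (!is.null(cell_mask)) {
    keep <- if (is.function(cell_mask)) cell_mask(t$x_um, t$y_um) else cell_mask
    if (!any(keep)) stop_contract("cell mask selects no grid nodes")
  }
  sum(sqrt(t$tx_pa[keep]^2 + t$ty_pa[keep]^2)) * dA * 1e-3
}

#' Contraction time series from a bead-image stack
#'
#' Runs PIV of every frame against the most relaxed reference frame,
#' inverts each displacement field to traction, and reports total force
#' and mean displacement over time plus contraction/relaxation
#' velocities (extrema of the central-difference derivative of the mean
#' displacement magnitude).
#'
#' @param stack An [image_stack()] of bead images (>= 5 frames).
#' @param cfg An [assay_config()] (substrate modulus, Poisson ratio).
#' @param window_size_um PIV window (um).
#' @param lambda FTTC regularization; `NULL` = L-curve on the frame of
#'   largest mean displacement, then reused for all frames.
#' @param cell_mask Optional mask passed to [total_force()].
#' @return A `contraction_series` list: `timeseries` tibble (`time_s`,
#'   `total_force_nn`, `mean_displacement_um`), `contraction_velocity_um_s`,
#'   `relaxation_velocity_um_s`, `peak_force_nn`, `reference_frame`.
#' @export
contraction_metrics <- function(stack, cfg, window_size_um = 12,
                                lambda = NULL, cell_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "assay_config"))
  n <- length(stack)
  if (n < 5L) stop_contract("need >= 5 frames for contraction metrics")
  ref_idx <- select_reference_frame(stack)
  ref <- stack$frames[[ref_idx]]
  fields <- lapply(seq_len(n), function(i) {
    if (i == ref_idx) NULL else
      piv_displacement(ref, stack$frames[[i]], window_size_um = window_size_um)
  })
  mean_disp <- vapply(seq_len(n), function(i) {
    if (i == ref_idx) 0 else
      mean(sqrt(fields[[i]]$ux_um^2 + fields[[i]]$uy_um^2))
  }, numeric(1))
  if (is.null(lambda)) {
    i_first <- which(vapply(fields, Negate(is.null), logical(1)))[1]
    spacing <- attr(fields[[i_first]], "grid_spacing_um")
    lambda <- 3 * (1 + cfg$poisson_ratio) /
      (cfg$substrate_modulus_pa * pi / spacing)
    cq_log("contraction series lambda = %.3g", lambda)
  }
  force <- vapply(seq_len(n), function(i) {
    if (i == ref_idx) return(0)
    tf <- fttc_inversion(fields[[i]], cfg$substrate_modulus_pa,
                         cfg$poisson_ratio, lambda = lambda)
    total_force(tf, cell_mask)
  }, numeric(1))
  dt <- stack$frame_interval_s
  tt <- (seq_len(n) - 1) * dt
  # central difference on a 3-frame window
  dudt <- rep(NA_real_, n)
  dudt[2:(n - 1)] <- (mean_disp[3:n] - mean_disp[1:(n - 2)]) / (2 * dt)
  structure(list(
    timeseries = tibble::tibble(time_s = tt, total_force_nn = force,
                                mean_displacement_um = mean_disp,
                                d_displacement_dt = dudt),
    contraction_velocity_um_s = max(dudt, na.rm = TRUE),
    relaxation_velocity_um_s = abs(min(dudt, na.rm = TRUE)),
    peak_force_nn = max(force),
    reference_frame = ref_idx,
    lambda = lambda),
    class = "contraction_series")
}

#' @export
print.contraction_series <- function(x, ...) {
  cat(sprintf(paste0("<contraction_series> %d frames; peak force %.3g nN; ",
                     "v_con %.3g um/s; v_rel %.3g um/s\n"),
              nrow(x$timeseries), x$peak_force_nn,
              x$contraction_velocity_um_s, x$relaxation_velocity_um_s))
  invisible(x)
}
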