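# Shared internal helpers: logging, validation, robust statistics,
# thresholding and seeded evaluation.

cq_log <- function(fmt, ...) {
  if (isTRUE(getOption("cardioquant.quiet", FALSE))) return(invisible(NULL))
  inform(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 sprintf(fmt, ...)))
}

cq_warn <- function(fmt, ...) {
  warn(sprintf(fmt, ...))
}

# Consistent error classes so callers/tests can distinguish contract
# violations (bad arguments), format problems (bad files) and signal
# problems (pathological data).
cq_stop <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "cardioquant_error"))
}
stop_contract <- function(fmt, ...) cq_stop("cq_contract_error", fmt, ...)
stop_format   <- function(fmt, ...) cq_stop("cq_format_error", fmt, ...)
stop_signal   <- function(fmt, ...) cq_stop("cq_signal_error", fmt, ...)
stop_fit      <- function(fmt, ...) cq_stop("cq_fit_error", fmt, ...)

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_null = FALSE, strict_min = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_contract("`%s` must be a number, not NULL", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_contract("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) {
    stop_contract("`%s` must be > %g (got %g)", name, min, x)
  }
  if (!strict_min && x < min) {
    stop_contract("`%s` must be >= %g (got %g)", name, min, x)
  }
  if (x > max) stop_contract("`%s` must be <= %g (got %g)", name, max, x)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; NULL seed means "use the current stream".
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Robust noise SD from the median absolute successive difference.
# For white Gaussian noise, diff(x) has SD sigma*sqrt(2) and the MAD of a
# centred Gaussian is 0.6745 sigma, hence the denominator.
robust_noise_sd <- function(x) {
  dx <- diff(x)
  stats::median(abs(dx)) / (sqrt(2) * 0.6745)
}

# Otsu threshold on a numeric vector (maximises between-class variance on
# an n_bins histogram). Returns NA for degenerate (constant) input.
# Kept in-package because the assays threshold within arbitrary masks,
# which image-level implementations do not support.
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop_contract("no finite values to threshold")
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  h <- graphics::hist(values, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  # between-class variance for threshold after bin k
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  # threshold midway between the chosen bin and the next
  (mids[k] + mids[min(k + 1L, length(mids))]) / 2
}

# Linear interpolation of the time at which `x` first crosses `level`
# moving forward from index i0 (inclusive); direction "up" or "down".
crossing_time <- function(t, x, level, i0, i1, direction = c("up", "down")) {
  direction <- match.arg(direction)
  idx <- seq(i0, i1)
  xx <- x[idx]
  hit <- if (direction == "up") which(xx >= level) else which(xx <= level)
  if (length(hit) == 0L) return(NA_real_)
  j <- idx[hit[1L]]
  if (j == i0) return(t[j])
  x0 <- x[j - 1L]; x1 <- x[j]
  if (x1 == x0) return(t[j])
  t[j - 1L] + (level - x0) / (x1 - x0) * (t[j] - t[j - 1L])
}

# Axial (period-180 degrees) circular statistics via angle doubling.
# Returns resultant length, mean angle in [0, 180) and circular SD (deg).
axial_stats <- function(angles_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  stopifnot(length(weights) == length(angles_deg))
  th <- 2 * angles_deg * pi / 180
  w <- weights / sum(weights)
  C <- sum(w * cos(th)); S <- sum(w * sin(th))
  R <- sqrt(C^2 + S^2)
  mean_deg <- (atan2(S, C) * 180 / pi / 2) %% 180
  sd_deg <- if (R > 0) sqrt(-2 * log(R)) * 180 / pi / 2 else Inf
  list(resultant = R, mean_deg = mean_deg, sd_deg = sd_deg)
}

`%||%` <- rlang::`%||%`
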