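# Gap-FRAP analysis: double normalization (reference-cell ratio, then
# pre-bleach scaling), multi-exponential recovery fitting and the
# amplitude-weighted rate constant k_FRAP.

#' Normalize a FRAP recording
#'
#' `F(t) = [(B(t) - bg) / (R(t) - bg)]` scaled by the mean of the same
#' ratio over the pre-bleach frames, so the pre-bleach level is exactly 1
#' and shared acquisition photobleach cancels. Time is re-zeroed at the
#' first post-bleach frame. When `n_prebleach` is `NULL` the bleach frame
#' is identified as the largest single-frame drop of the bleach series.
#'
#' @param traces Data frame with columns `time_s`, `bleach`, `reference`,
#'   `background` (equal length, shared time base), or separate vectors
#'   via the other arguments.
#' @param n_prebleach Number of pre-bleach frames (>= 1), or `NULL` to
#'   auto-detect.
#' @return A `frap_curve` tibble (`time_s`, `intensity`) with attributes
#'   `pre_bleach_level` (raw ratio), `bleach_depth`, `n_prebleach`.
#' @export
normalize_frap <- function(traces, n_prebleach = NULL) {
  traces <- tibble::as_tibble(traces)
  req <- c("time_s", "bleach", "reference", "background")
  if (!all(req %in% names(traces))) {
    stop_contract("`traces` needs columns: %s", paste(req, collapse = ", "))
  }
  B <- traces$bleach; R <- traces$reference; bg <- traces$background
  den <- R - bg
  if (any(den <= 0)) {
    stop_signal("reference minus background <= 0 at sample %d",
                which(den <= 0)[1])
  }
  num <- B - bg
  if (any(num <= 0)) {
    stop_signal("bleach signal does not exceed background at sample %d",
                which(num <= 0)[1])
  }
  ratio <- num / den
  if (is.null(n_prebleach)) {
    drop <- diff(ratio)
    n_prebleach <- which.min(drop)   # frame before the largest drop
    cq_log("bleach frame auto-detected after frame %d", n_prebleach)
  }
  if (n_prebleach < 1L || n_prebleach >= length(ratio)) {
    stop_contract("n_prebleach must be in [1, n_samples - 1]")
  }
  pre <- mean(ratio[seq_len(n_prebleach)])
  f <- ratio / pre
  t0 <- traces$time_s[n_prebleach + 1L]
  out <- tibble::tibble(time_s = traces$time_s - t0, intensity = f)
  attr(out, "pre_bleach_level") <- pre
  attr(out, "bleach_depth") <- 1 - f[n_prebleach + 1L]
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  class(out) <- c("frap_curve", class(tibble::tibble()))
  out
}

#' Fit the FRAP recovery and compute k_FRAP
#'
#' Least-squares fit of `F(t) = F_inf - sum_i A_i exp(-k_i t)` to the
#' post-bleach samples, with 1 or 2 components (model order chosen by
#' corrected AIC when `n_components = NULL`). The amplitude-weighted rate
#' constant is `k_FRAP = sum(A_i k_i) / sum(A_i)`. A fit with a negative
#' amplitude falls back to one component. Curves with no measurable
#' recovery report `k_frap = NA` and mobile fraction ~0.
#'
#' @param curve A [normalize_frap()] output.
#' @param n_components 1, 2, or `NULL` (AICc selection).
#' @return A `frap_fit` object; see [tidy.frap_fit()] and
#'   [glance.frap_fit()].
#' @export
fit_recovery <- function(curve, n_components = NULL) {
  stopifnot(inherits(curve, "frap_curve"))
  post <- curve[curve$time_s >= 0, ]
  if (nrow(post) < 10L) stop_contract("need >= 10 post-bleach samples")
  t <- post$time_s; y <- post$intensity
  f0 <- y[1L]
  plateau0 <- mean(tail(y, max(3L, nrow(post) %/% 10)))
  total_amp <- plateau0 - f0
  if (total_amp < 0.02 * (1 - f0) || (1 - f0) <= 0) {
    # no measurable recovery (e.g. an isolated cell): rate undefined
    fitobj <- list(components = tibble::tibble(amplitude = numeric(0),
                                               k_per_s = numeric(0)),
                   plateau = plateau0, f0 = f0,
                   mobile_fraction = max(0, total_amp / max(1 - f0, 1e-12)),
                   k_frap_per_s = NA_real_, r2 = NA_real_,
                   n_components = 0L, curve = curve)
    class(fitobj) <- "frap_fit"
    return(fitobj)
  }
  t_half <- t[which(y - f0 >= 0.5 * total_amp)[1L]]
  k0 <- log(2) / max(t_half, t[2])
  fit_n <- function(nc) {
    if (nc == 1L) {
      form <- y ~ Finf - A1 * exp(-k1 * t)
      start <- list(Finf = plateau0, A1 = total_amp, k1 = k0)
      lower <- c(0, 0, 1e-8)
    } else {
      form <- y ~ Finf - A1 * exp(-k1 * t) - A2 * exp(-k2 * t)
      start <- list(Finf = plateau0, A1 = total_amp / 2, k1 = 3 * k0,
                    A2 = total_amp / 2, k2 = k0 / 3)
      lower <- c(0, 0, 1e-8, 0, 1e-8)
    }
    tryCatch(minpack.lm::nlsLM(form, data = data.frame(t = t, y = y),
                               start = start, lower = lower,
                               control = minpack.lm::nls.lm.control(maxiter = 500)),
             error = function(e) NULL)
  }
  aicc <- function(fit) {
    rss <- sum(stats::resid(fit)^2)
    n <- length(t); p <- length(coef(fit)) + 1
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
  }
  pick <- function() {
    if (!is.null(n_components)) {
      f <- fit_n(n_components)
      if (is.null(f) && n_components == 2L) {
        cq_log("2-component fit failed; falling back to 1 component")
        f <- fit_n(1L)
      }
      if (is.null(f)) stop_fit("recovery fit did not converge")
      return(f)
    }
    f1 <- fit_n(1L); f2 <- fit_n(2L)
    if (is.null(f1) && is.null(f2)) stop_fit("recovery fit did not converge")
    if (is.null(f2)) return(f1)
    if (is.null(f1)) return(f2)
    # degenerate second component (zero amplitude or equal rates) -> 1
    cf2 <- coef(f2)
    if (cf2[["A2"]] < 1e-6 || cf2[["A1"]] < 1e-6) return(f1)
    if (aicc(f2) < aicc(f1)) f2 else f1
  }
  fit <- pick()
  cf <- coef(fit)
  ks <- cf[grep("^k", names(cf))]
  As <- cf[grep("^A", names(cf))]
  ord <- order(ks, decreasing = TRUE)
  comp <- tibble::tibble(amplitude = unname(As[ord]),
                         k_per_s = unname(ks[ord]))
  plateau <- unname(cf[["Finf"]])
  rss <- sum(stats::resid(fit)^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  fitobj <- list(
    components = comp,
    plateau = plateau,
    f0 = f0,
    mobile_fraction = min(1, max(0, (plateau - f0) / (1 - f0))),
    k_frap_per_s = sum(comp$amplitude * comp$k_per_s) / sum(comp$amplitude),
    r2 = r2,
    n_components = nrow(comp),
    curve = curve)
  class(fitobj) <- "frap_fit"
  fitobj
}

#' Mobile fraction of a FRAP recovery
#'
#' `(plateau - F(0+)) / (1 - F(0+))` with the pre-bleach level defined as
#' 1 by the normalization.
#'
#' @param curve A `frap_curve` (used for F(0+)).
#' @param fit A `frap_fit` (used for the plateau).
#' @return Mobile fraction in \[0, 1\].
#' @export
mobile_fraction <- function(curve, fit) {
  stopifnot(inherits(fit, "frap_fit"))
  f0 <- curve$intensity[which(curve$time_s >= 0)[1L]]
  min(1, max(0, (fit$plateau - f0) / (1 - f0)))
}

#' @export
print.frap_fit <- function(x, ...) {
  if (is.na(x$k_frap_per_s)) {
    cat(sprintf("<frap_fit> no measurable recovery (mobile fraction %.3f)\n",
                x$mobile_fraction))
  } else {
    cat(sprintf("<frap_fit> %d component(s); k_FRAP = %.4g /s; mobile fraction = %.3f; R2 = %.4f\n",
                x$n_components, x$k_frap_per_s, x$mobile_fraction, x$r2))
  }
  invisible(x)
}

#' Tidy a FRAP fit: one row per exponential component
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `amplitude`, `k_per_s`.
#' @export
tidy.frap_fit <- function(x, ...) {
  if (nrow(x$components) == 0L) {
    return(tibble::tibble(term = character(0), amplitude = numeric(0),
                          k_per_s = numeric(0)))
  }
  tibble::tibble(term = paste0("component_", seq_len(nrow(x$components))),
                 amplitude = x$components$amplitude,
                 k_per_s = x$components$k_per_s)
}

#' One-row summary of a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return Tibble with `k_frap_per_s`, `mobile_fraction`, `plateau`,
#'   `n_components`, `r2`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(k_frap_per_s = x$k_frap_per_s,
                 mobile_fraction = x$mobile_fraction,
                 plateau = x$plateau,
                 n_components = x$n_components,
                 r2 = x$r2)
}
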