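# Synthetic gap-FRAP bleach/recovery series with a non-bleached reference
# cell and a background trace, plus exact ground truth.

#' Parameters for the FRAP simulator
#'
#' The bleached-ROI recovery follows
#' `F(t) = plateau - sum_i A_i * exp(-k_i * t)` for t >= 0 (post-bleach),
#' with `F(0+) = 1 - bleach_depth` and plateau
#' `1 - bleach_depth * immobile_frac` (all relative to the pre-bleach
#' level). Both the ROI and the reference cell decay by a shared
#' multiplicative acquisition photobleach `exp(-reference_drift * t)`,
#' which the reference normalization in [normalize_frap()] must cancel.
#'
#' @param components Tibble/data frame with columns `amplitude` (> 0,
#'   relative weights) and `k_per_s` (> 0): the recovery components. A
#'   single rate can be given via `k_true_per_s` instead.
#' @param k_true_per_s Shortcut for a single-component recovery.
#' @param immobile_frac Immobile fraction in \[0, 1\].
#' @param bleach_depth Fraction of signal removed by the bleach (0, 1].
#' @param pre_bleach_level Raw pre-bleach ROI intensity (detector units).
#' @param span_s Post-bleach acquisition span (default 300 s = 5 min).
#' @param interval_s Sampling interval (default 2 s).
#' @param n_prebleach Number of pre-bleach frames.
#' @param noise_sd Additive Gaussian noise SD as a fraction of
#'   `pre_bleach_level`.
#' @param reference_drift Shared multiplicative photobleach rate (per s).
#' @param background_level Constant background as a fraction of
#'   `pre_bleach_level`.
#' @param seed Optional RNG seed.
#' @return A `frap_sim_params` object.
#' @export
frap_sim_params <- function(components = NULL,
                            k_true_per_s = NULL,
                            immobile_frac = 0,
                            bleach_depth = 0.8,
                            pre_bleach_level = 1000,
                            span_s = 300,
                            interval_s = 2,
                            n_prebleach = 5L,
                            noise_sd = 0.02,
                            reference_drift = 0,
                            background_level = 0.02,
                            seed = NULL) {
  if (is.null(components)) {
    if (is.null(k_true_per_s)) stop_contract("give `components` or `k_true_per_s`")
    components <- tibble::tibble(amplitude = 1, k_per_s = k_true_per_s)
  }
  components <- tibble::as_tibble(components)
  if (!all(c("amplitude", "k_per_s") %in% names(components))) {
    stop_contract("`components` needs columns amplitude, k_per_s")
  }
  if (any(components$amplitude <= 0)) stop_contract("amplitudes must be > 0")
  if (any(components$k_per_s <= 0)) stop_contract("rates k_i must be > 0")
  check_number(immobile_frac, "immobile_frac", min = 0, max = 1)
  if (bleach_depth <= 0 || bleach_depth > 1) {
    stop_contract("bleach_depth must be in (0, 1]")
  }
  check_number(pre_bleach_level, "pre_bleach_level", min = 0, strict_min = TRUE)
  check_number(span_s, "span_s", min = 0, strict_min = TRUE)
  check_number(interval_s, "interval_s", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(reference_drift, "reference_drift", min = 0)
  structure(list(components = components, immobile_frac = immobile_frac,
                 bleach_depth = bleach_depth,
                 pre_bleach_level = pre_bleach_level, span_s = span_s,
                 interval_s = interval_s, n_prebleach = as.integer(n_prebleach),
                 noise_sd = noise_sd, reference_drift = reference_drift,
                 background_level = background_level, seed = seed),
            class = "frap_sim_params")
}

#' Generate synthetic FRAP traces (bleach ROI, reference cell, background)
#'
#' @param p A [frap_sim_params()].
#' @return List with `traces` (tibble: `time_s`, `bleach`, `reference`,
#'   `background`), `truth` (the true k set, amplitude-weighted k, mobile
#'   fraction), and `params`. The amplitude-weighted truth is
#'   `k_frap = sum(A_i k_i) / sum(A_i)`.
#' @export
gen_frap_curves <- function(p) {
  stopifnot(inherits(p, "frap_sim_params"))
  with_seed_opt(p$seed, {
    t_pre <- -rev(seq_len(p$n_prebleach)) * p$interval_s
    t_post <- seq(0, p$span_s, by = p$interval_s)
    tt <- c(t_pre, t_post)
    A <- p$components$amplitude / sum(p$components$amplitude)
    k <- p$components$k_per_s
    mobile <- 1 - p$immobile_frac
    # relative recovery curve (pre-bleach level == 1)
    rec <- function(t) {
      (1 - p$bleach_depth) + p$bleach_depth * mobile *
        colSums(A * (1 - exp(-outer(k, t))))
    }
    rel <- c(rep(1, length(t_pre)), rec(t_post))
    plateau <- 1 - p$bleach_depth * p$immobile_frac
    if (plateau > 1 + 1e-12) stop_contract("plateau exceeds pre-bleach level")
    drift <- exp(-p$reference_drift * (tt - tt[1]))
    bg <- p$background_level * p$pre_bleach_level
    n <- length(tt)
    noise <- function() rnorm(n, 0, p$noise_sd * p$pre_bleach_level)
    traces <- tibble::tibble(
      time_s = tt - tt[1],
      bleach = p$pre_bleach_level * rel * drift + bg + noise(),
      reference = 0.9 * p$pre_bleach_level * drift + bg + noise(),
      background = bg + noise()
    )
    truth <- list(k_per_s = k, amplitudes = A,
                  k_frap = sum(A * k) / sum(A),
                  mobile_fraction = mobile,
                  plateau = plateau,
                  bleach_frame = length(t_pre) + 1L)
    list(traces = traces, truth = truth, params = p)
  })
}
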