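# Calcium-transient analysis: ratio/dF-F0 normalization, transient
# detection, spontaneous-release-event classification with the
# contaminated-beat exclusion rule, per-beat kinetics and per-cell
# summaries.

#' Ratiometric trace: R = (F410 - bg410) / (F485 - bg485)
#'
#' Converts an Indo-1 two-channel record into a single-channel ratio
#' trace. Missing backgrounds default to zero with a warning (signals are
#' expected to be background-subtracted upstream if no values are known).
#'
#' @param t A two-channel [trace_record()] (`F410`, `F485`).
#' @return A single-channel `trace_record` whose `F` column holds R.
#' @export
compute_ratio_trace <- function(t) {
  stopifnot(inherits(t, "trace_record"))
  if (!all(c("F410", "F485") %in% names(t))) {
    stop_contract("compute_ratio_trace needs channels F410 and F485")
  }
  bg <- attr(t, "background")
  if (is.null(bg)) {
    cq_warn("no per-channel backgrounds on trace; defaulting to 0")
    bg <- c(F410 = 0, F485 = 0)
  }
  b410 <- bg[["F410"]] %||% 0
  b485 <- bg[["F485"]] %||% 0
  den <- t$F485 - b485
  bad <- which(den <= 0)
  if (length(bad)) {
    stop_signal("background-subtracted F485 <= 0 at sample %d", bad[1])
  }
  trace_record(t$time_s, list(F = (t$F410 - b410) / den),
               stim_freq_hz = attr(t, "stim_freq_hz"))
}

#' Normalize a single-channel trace to dF/F0
#'
#' F0 is a low percentile of the raw trace (default the 10th), the
#' standard surrogate for resting fluorescence in beating cells.
#'
#' @param t A single-channel [trace_record()].
#' @param f0_percentile Percentile (0-100) used for F0.
#' @return A `trace_record` whose `F` column holds dF/F0; F0 is attached
#'   as attribute `f0`.
#' @export
normalize_df_f0 <- function(t, f0_percentile = 10) {
  stopifnot(inherits(t, "trace_record"))
  if (!identical(trace_channels(t), "F")) {
    stop_contract("normalize_df_f0 needs a single channel 'F'")
  }
  f0 <- unname(quantile(t$F, f0_percentile / 100))
  if (f0 <= 0) stop_signal("F0 (%gth percentile) is %.3g <= 0", f0_percentile, f0)
  cq_log("dF/F0 normalization with F0 = %.4g (%gth percentile)", f0,
         f0_percentile)
  out <- trace_record(t$time_s, list(F = (t$F - f0) / f0),
                      stim_freq_hz = attr(t, "stim_freq_hz"))
  attr(out, "f0") <- f0
  out
}

# Centred moving average of width `smooth_s` seconds (odd sample count,
# edges padded by replication). Width 0 disables smoothing.
smooth_trace <- function(x, time_s, smooth_s) {
  if (smooth_s <= 0) return(x)
  dt <- stats::median(diff(time_s))
  w <- 2L * floor(smooth_s / dt / 2) + 1L
  if (w < 3L) return(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}

# Local maxima indices of x (strict on the left, non-strict right so flat
# tops report their first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of each peak: height above the higher of the two
# key saddles (lowest point between the peak and the nearest higher peak
# or trace end on each side).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- 1L; right <- length(x)
    higher_l <- peaks[peaks < p & x[peaks] > x[p]]
    if (length(higher_l)) left <- max(higher_l)
    higher_r <- peaks[peaks > p & x[peaks] > x[p]]
    if (length(higher_r)) right <- min(higher_r)
    saddle_l <- min(x[left:p])
    saddle_r <- min(x[p:right])
    x[p] - max(saddle_l, saddle_r)
  }, numeric(1))
}

#' Detect calcium transients in a normalized trace
#'
#' Peaks are local maxima whose topographic prominence exceeds
#' `prominence_mult` times the robust noise SD (estimated from the median
#' absolute successive difference). Each peak gets an onset (last
#' pre-peak crossing of baseline + 10% amplitude), an end (first
#' post-peak return to that level, or the next onset), and an amplitude
#' relative to the local pre-peak baseline. Overlapping transients split
#' at the inter-peak minimum.
#'
#' Peak geometry is evaluated on a lightly smoothed copy of the trace
#' (centred moving average, `smooth_s` wide): at typical sampling rates
#' the topographic prominence of raw noise exceeds any fixed multiple of
#' the per-sample SD over a long trace, while transients (hundreds of
#' milliseconds wide) are unaffected by ~50 ms smoothing. The noise SD
#' is always estimated from the raw trace.
#'
#' @param trace A normalized single-channel [trace_record()].
#' @param prominence_mult Prominence threshold in robust noise SDs.
#' @param onset_frac Fraction of amplitude defining onset/end crossings.
#' @param smooth_s Moving-average width (s) for peak geometry.
#' @return A tibble of transients: `onset_s`, `peak_s`, `end_s`,
#'   `amplitude`, `baseline_level`, `peak_index`, `is_spontaneous`
#'   (`NA` until classified), `host_excluded`.
#' @export
detect_transients <- function(trace, prominence_mult = 4, onset_frac = 0.1,
                              smooth_s = 0.05) {
  stopifnot(inherits(trace, "trace_record"))
  sigma <- robust_noise_sd(trace$F)
  x <- smooth_trace(trace$F, trace$time_s, smooth_s)
  tt <- trace$time_s
  peaks <- local_maxima(x)
  if (length(peaks) == 0L) return(empty_transients())
  prom <- peak_prominence(x, peaks)
  keep <- prom >= prominence_mult * sigma & prom > 0
  peaks <- peaks[keep]
  if (length(peaks) == 0L) return(empty_transients())
  n <- length(peaks)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- peaks[i]
    lo <- if (i == 1L) 1L else peaks[i - 1L]
    hi <- if (i == n) length(x) else peaks[i + 1L]
    # local baseline: minimum between previous peak (or start) and peak
    base_idx <- lo - 1L + which.min(x[lo:p])
    baseline <- x[base_idx]
    amp <- x[p] - baseline
    level <- baseline + onset_frac * amp
    # onset: last pre-peak crossing of the level moving backwards
    pre <- x[base_idx:p]
    below <- which(pre <= level)
    onset_i <- if (length(below)) base_idx - 1L + max(below) else base_idx
    onset_s <- crossing_time(tt, x, level, onset_i, p, "up") %||% tt[onset_i]
    if (is.na(onset_s)) onset_s <- tt[onset_i]
    # end: first post-peak return to the level, else valley before next peak
    valley_idx <- p - 1L + which.min(x[p:hi])
    end_s <- crossing_time(tt, x, level, p, valley_idx, "down")
    if (is.na(end_s)) end_s <- tt[valley_idx]
    out[[i]] <- tibble::tibble(
      onset_s = onset_s, peak_s = tt[p], end_s = end_s,
      amplitude = amp, baseline_level = baseline, peak_index = p)
  }
  res <- dplyr::bind_rows(out)
  res$is_spontaneous <- NA
  res$host_excluded <- FALSE
  res
}

empty_transients <- function() {
  tibble::tibble(onset_s = numeric(0), peak_s = numeric(0), end_s = numeric(0),
                 amplitude = numeric(0), baseline_level = numeric(0),
                 peak_index = integer(0), is_spontaneous = logical(0),
                 host_excluded = logical(0))
}

# Estimate the dominant beating period from inter-peak intervals (mode of
# the lag distribution via a kernel density; median fallback for few
# intervals).
estimate_period <- function(peak_s) {
  iv <- diff(peak_s)
  if (length(iv) == 0L) return(NA_real_)
  if (length(iv) < 4L) return(stats::median(iv))
  d <- density(iv, bw = "SJ", adjust = 1)
  d$x[which.max(d$y)]
}

#' Classify spontaneous release events and flag contaminated beats
#'
#' Transients are matched against the dominant rhythm grid (the
#' stimulation frequency when given, else the mode of the inter-peak
#' interval distribution). Each grid slot is claimed by the
#' largest-amplitude transient within 25% of the period of the slot time;
#' these rhythm-locked beats define the reference amplitude. Any
#' unclaimed transient with amplitude below `alpha` times the median
#' rhythm-locked amplitude is labelled spontaneous — operationalizing
#' "lower amplitude and random occurrence". Finally, any rhythm-locked
#' beat whose transient window contains a spontaneous event is flagged
#' `host_excluded` and dropped from kinetics averaging downstream.
#'
#' When the originating `trace` is supplied, a fused-event resolution
#' stage runs as well: release events that superpose with a stimulated
#' beat produce no separate fluorescence peak, but they do produce a
#' second maximum of the upstroke velocity dF/dt. Extra upstrokes inside
#' a beat window are appended as spontaneous events (column
#' `fused = TRUE`) when their amplitude (intensity rise across the
#' upstroke) stays below the median rhythm-locked amplitude, and their
#' host beat is flagged. Without the trace, fused events are invisible
#' and their host beats cannot be excluded.
#'
#' @param transients Tibble from [detect_transients()].
#' @param stim_freq_hz Stimulation frequency (Hz), or `NULL` to infer the
#'   rhythm from the trace (spontaneously beating preparations).
#' @param alpha Amplitude cutoff as a fraction of the median rhythm-locked
#'   amplitude (default 0.5).
#' @param grid_tol_frac Half-width of a grid slot as a fraction of the
#'   period (default 0.25).
#' @param trace Optional normalized [trace_record()] enabling fused-event
#'   resolution via upstroke analysis.
#' @param upstroke_mult Threshold for upstroke maxima, in robust SDs of
#'   the smoothed dF/dt (default 6).
#' @param smooth_s Moving-average width (s) for the derivative.
#' @return The transient tibble with `is_spontaneous` and `host_excluded`
#'   filled in (fused events appended, flagged by `fused`), plus
#'   attributes `period_s` and `grid_origin_s`.
#' @export
classify_spontaneous <- function(transients, stim_freq_hz = NULL,
                                 alpha = 0.5, grid_tol_frac = 0.25,
                                 trace = NULL, upstroke_mult = 6,
                                 smooth_s = 0.05) {
  tr <- transients
  tr$fused <- rep(FALSE, nrow(tr))
  if (nrow(tr) == 0L) return(tr)
  if (is.null(stim_freq_hz) && nrow(tr) < 2L) {
    stop_contract("need >= 2 transients to infer the rhythm; give stim_freq_hz")
  }
  period <- if (!is.null(stim_freq_hz)) 1 / stim_freq_hz else
    estimate_period(tr$peak_s)
  # grid origin: circular mean of peak phases modulo the period
  ph <- 2 * pi * (tr$peak_s %% period) / period
  origin <- atan2(mean(sin(ph)), mean(cos(ph))) / (2 * pi) * period
  origin <- origin %% period
  k_min <- floor((min(tr$peak_s) - origin) / period)
  k_max <- ceiling((max(tr$peak_s) - origin) / period)
  slots <- origin + period * seq(k_min, k_max)
  tol <- grid_tol_frac * period
  locked <- rep(FALSE, nrow(tr))
  for (s in slots) {
    cand <- which(abs(tr$peak_s - s) <= tol & !locked)
    if (length(cand)) locked[cand[which.max(tr$amplitude[cand])]] <- TRUE
  }
  if (!any(locked)) {
    cq_warn("degenerate rhythm: no transient matched the grid; all retained as spontaneous")
    tr$is_spontaneous <- TRUE
    tr$host_excluded <- FALSE
    attr(tr, "period_s") <- period
    attr(tr, "grid_origin_s") <- origin
    return(tr)
  }
  ref_amp <- stats::median(tr$amplitude[locked])
  tr$is_spontaneous <- !locked & tr$amplitude < alpha * ref_amp
  # unclaimed, full-amplitude transients (ectopic beats) stay non-spontaneous

  # typical beat duration: a contaminated beat's end is truncated at the
  # split valley, so the host window uses the median locked duration,
  # widened 25% so exclusion errs conservative at the decay tail
  med_dur <- stats::median(tr$end_s[locked] - tr$onset_s[locked])

  if (!is.null(trace)) {
    fused <- resolve_fused_events(trace, tr, locked, ref_amp, med_dur,
                                  upstroke_mult, smooth_s)
    if (nrow(fused) > 0L) {
      tr <- dplyr::bind_rows(tr, fused)
      tr <- tr[order(tr$peak_s), ]
      # re-derive the locked flags from slot membership after the merge
      locked <- rep(FALSE, nrow(tr))
      for (s in slots) {
        cand <- which(abs(tr$peak_s - s) <= tol & !tr$fused & !locked)
        if (length(cand)) locked[cand[which.max(tr$amplitude[cand])]] <- TRUE
      }
    }
  }
  # hosting is judged by the event's onset: a release starting anywhere
  # inside the beat's transient contaminates its kinetics
  sp_onsets <- tr$onset_s[tr$is_spontaneous]
  tr$host_excluded <- locked & !tr$is_spontaneous &
    vapply(seq_len(nrow(tr)), function(i)
      any(sp_onsets > tr$onset_s[i] &
            sp_onsets < tr$onset_s[i] + 1.25 * med_dur), logical(1))

  if (!is.null(trace)) {
    # coincident fusions: an event released within ~a rise time of the
    # stimulus leaves no second upstroke, but calcium release superposes,
    # so the host beat's amplitude exceeds the rhythm median by the event
    # amplitude. Flag locked beats whose amplitude excess clears both the
    # beat-to-beat spread (6 MADs) and a 10% floor.
    amp_locked <- tr$amplitude[locked & !tr$host_excluded]
    if (length(amp_locked) >= 4L) {
      med_amp <- stats::median(amp_locked)
      thr <- max(6 * stats::mad(amp_locked), 0.1 * med_amp)
      cand <- which(locked & !tr$host_excluded &
                      tr$amplitude > med_amp + thr)
      if (length(cand)) {
        extra <- tibble::tibble(
          onset_s = tr$onset_s[cand], peak_s = tr$peak_s[cand],
          end_s = tr$end_s[cand],
          amplitude = tr$amplitude[cand] - med_amp,
          baseline_level = tr$baseline_level[cand],
          peak_index = tr$peak_index[cand],
          is_spontaneous = TRUE, host_excluded = FALSE, fused = TRUE)
        tr$host_excluded[cand] <- TRUE
        tr <- dplyr::bind_rows(tr, extra)
        locked <- c(locked, rep(FALSE, nrow(extra)))
        ord <- order(tr$peak_s)
        locked <- locked[ord]
        tr <- tr[ord, ]
      }
    }
  }
  attr(tr, "period_s") <- period
  attr(tr, "grid_origin_s") <- origin
  attr(tr, "rhythm_locked") <- locked
  tr
}

# Upstroke analysis: find dF/dt maxima above `upstroke_mult` robust SDs;
# upstrokes not explained by an existing transient's rise are fused
# release events. Returns synthetic transient rows (possibly empty).
resolve_fused_events <- function(trace, tr, locked, ref_amp, med_dur,
                                 upstroke_mult, smooth_s,
                                 deriv_smooth_s = 0.03, min_sep_s = 0.03) {
  tt <- trace$time_s
  dt <- stats::median(diff(tt))
  # the derivative stage uses lighter smoothing than peak detection:
  # resolving two upstrokes ~0.1 s apart needs the finer time scale
  x <- smooth_trace(trace$F, tt, deriv_smooth_s)
  d <- smooth_trace(c(0, diff(x)) / dt, tt, deriv_smooth_s)
  sig_d <- stats::mad(d)
  if (sig_d == 0) return(empty_transients()[0, ])
  up <- local_maxima(d)
  up <- up[d[up] > upstroke_mult * sig_d]
  if (length(up) > 1L) up <- up[c(TRUE, diff(tt[up]) > min_sep_s)]
  # each transient explains exactly one upstroke — the strongest within
  # its rising limb; all other upstrokes are fused release events
  explained <- rep(FALSE, length(up))
  for (i in seq_len(nrow(tr))) {
    inwin <- which(tt[up] >= tr$onset_s[i] - 2 * smooth_s &
                     tt[up] <= tr$peak_s[i] + 2 * smooth_s)
    if (length(inwin)) explained[inwin[which.max(d[up[inwin]])]] <- TRUE
  }
  extra <- up[!explained]
  if (length(extra) == 0L) return(empty_transients()[0, ])
  rows <- lapply(extra, function(u) {
    # upstroke extent: run of dF/dt above 2 robust SDs around the maximum
    i0 <- u; while (i0 > 1L && d[i0 - 1L] > 2 * sig_d) i0 <- i0 - 1L
    i1 <- u; while (i1 < length(d) && d[i1 + 1L] > 2 * sig_d) i1 <- i1 + 1L
    amp <- x[i1] - x[i0]
    if (!(amp > 0) || amp >= ref_amp) return(NULL)  # not a lower-amplitude event
    tibble::tibble(onset_s = tt[i0], peak_s = tt[i1],
                   end_s = min(tt[i1] + med_dur, tt[length(tt)]),
                   amplitude = amp, baseline_level = x[i0],
                   peak_index = i1, is_spontaneous = TRUE,
                   host_excluded = FALSE, fused = TRUE)
  })
  dplyr::bind_rows(Filter(Negate(is.null), rows))
}

#' Kinetics of one calcium transient
#'
#' Threshold-crossing times are linearly interpolated between samples;
#' tau comes from a least-squares monoexponential fit to the decay
#' segment between 90% and 10% of the amplitude. Spontaneous or
#' contaminated (host-excluded) transients are refused: they are excluded
#' from kinetic analysis by design.
#'
#' The decay-fit window defaults to 70%-10% of the amplitude: the upper
#' bound keeps the fit clear of the peak neighbourhood, where the finite
#' upstroke still contributes to the signal and would bias tau upward
#' for fast decays.
#'
#' @param trace The normalized [trace_record()] the transient came from.
#' @param transient One row of the classified transient tibble.
#' @param fit_hi,fit_lo Decay-fit window as fractions of amplitude.
#' @param smooth_s Moving-average width (s) for crossing geometry,
#'   matching [detect_transients()]; the tau fit always runs on the raw
#'   samples.
#' @return One-row tibble: `rise_time_s`, `t50_peak_s`, `t90_peak_s`,
#'   `t50_base_s`, `t90_base_s`, `tau_s`, `r2_fit`.
#' @export
transient_kinetics <- function(trace, transient, fit_hi = 0.7, fit_lo = 0.1,
                               smooth_s = 0.05) {
  stopifnot(inherits(trace, "trace_record"), nrow(transient) == 1L)
  if (isTRUE(transient$is_spontaneous)) {
    stop_contract("spontaneous events are excluded from kinetic analysis")
  }
  if (isTRUE(transient$host_excluded)) {
    stop_contract("beats contaminated by a spontaneous event are excluded from kinetic analysis")
  }
  x_raw <- trace$F; tt <- trace$time_s
  x <- smooth_trace(x_raw, tt, smooth_s)
  i_on <- findInterval(transient$onset_s, tt)
  i_pk <- transient$peak_index
  i_end <- max(findInterval(transient$end_s, tt), i_pk + 1L)
  # allow the boundary sample itself to satisfy the 90%-return crossing
  i_end2 <- min(length(x), i_end + 2L)
  base <- transient$baseline_level
  amp <- transient$amplitude
  lvl <- function(f) base + f * amp
  t50p <- crossing_time(tt, x, lvl(0.5), i_on, i_pk, "up")
  t90p <- crossing_time(tt, x, lvl(0.9), i_on, i_pk, "up")
  t50b <- crossing_time(tt, x, lvl(0.5), i_pk, i_end2, "down")
  t90b <- crossing_time(tt, x, lvl(0.1), i_pk, i_end2, "down")
  # decay segment: contiguous run from the first crossing below fit_hi to
  # the first crossing below fit_lo (value-filtering would let noisy
  # diastolic samples leak in and flatten the fit)
  seg <- seq(i_pk, i_end)
  below_hi <- which(x[seg] <= lvl(fit_hi))
  if (length(below_hi) == 0L) stop_fit("decay never falls below the fit window")
  i_start <- seg[below_hi[1L]]
  after <- seq(i_start, i_end)
  below_lo <- which(x[after] <= lvl(fit_lo))
  i_stop <- if (length(below_lo)) after[below_lo[1L]] else i_end
  inwin <- seq(i_start, i_stop)
  if (length(inwin) < 4L) {
    stop_fit("decay segment has %d samples (< 4); beat excluded",
             length(inwin))
  }
  td <- tt[inwin] - tt[inwin[1]]
  xd <- x_raw[inwin]
  # log-linear start, then nonlinear refinement with free offset
  pos <- xd - base > amp * 1e-4
  tau0 <- if (sum(pos) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(xd[pos] - base) ~ td[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else NA_real_
  } else NA_real_
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(td) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(xd ~ C + A * exp(-td / tau),
                      start = list(C = base, A = xd[1] - base, tau = tau0),
                      lower = c(-Inf, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- unname(coef(fit)[["tau"]])
    rss <- sum(stats::resid(fit)^2)
  } else if (is.finite(tau0) && tau0 > 0 && all(xd > base)) {
    # exact-exponential data can defeat the nonlinear solver (zero
    # residuals -> singular gradient); the log-linear fit is then exact
    tau <- tau0
    rss <- sum((xd - (base + (xd[1] - base) * exp(-td / tau0)))^2)
  } else {
    stop_fit("decay fit did not converge")
  }
  r2 <- 1 - rss / sum((xd - mean(xd))^2)
  peak_t <- transient$peak_s
  tibble::tibble(
    rise_time_s = peak_t - transient$onset_s,
    t50_peak_s = t50p - transient$onset_s,
    t90_peak_s = t90p - transient$onset_s,
    t50_base_s = t50b - peak_t,
    t90_base_s = t90b - peak_t,
    tau_s = tau,
    r2_fit = r2)
}

#' Per-cell calcium summary
#'
#' Beat rate counts rhythm-locked transients only; spontaneous-event
#' frequency counts spontaneous labels; kinetic means run over included
#' beats (not spontaneous, not host-excluded, kinetics computable). For
#' ratiometric input the baseline ratio is the median of R outside all
#' transient windows.
#'
#' @param trace The normalized (or ratio) [trace_record()].
#' @param transients Classified transient tibble.
#' @param kinetics Optional precomputed kinetics tibble (one row per
#'   included beat); computed on the fly if `NULL`.
#' @param ratio_trace Optional raw ratio `trace_record` for the baseline
#'   ratio (Indo-1 preparations).
#' @return One-row tibble (class `cell_calcium_summary`).
#' @export
summarize_cell <- function(trace, transients, kinetics = NULL,
                           ratio_trace = NULL) {
  stopifnot(inherits(trace, "trace_record"))
  duration <- diff(range(trace$time_s))
  locked <- attr(transients, "rhythm_locked") %||%
    (!transients$is_spontaneous %in% TRUE)
  n_sp <- sum(transients$is_spontaneous %in% TRUE)
  included <- which(!(transients$is_spontaneous %in% TRUE) &
                      !transients$host_excluded)
  if (is.null(kinetics)) {
    kin_rows <- lapply(included, function(i) {
      tryCatch(transient_kinetics(trace, transients[i, ]),
               cq_fit_error = function(e) {
                 cq_log("beat %d dropped from kinetics: %s", i,
                        conditionMessage(e))
                 NULL
               })
    })
    kinetics <- dplyr::bind_rows(kin_rows)
  }
  kin_means <- if (nrow(kinetics) > 0) {
    dplyr::summarise(kinetics, dplyr::across(dplyr::everything(),
                                             ~ mean(.x, na.rm = TRUE)))
  } else {
    tibble::as_tibble(setNames(as.list(rep(NA_real_, 7)),
                               c("rise_time_s", "t50_peak_s", "t90_peak_s",
                                 "t50_base_s", "t90_base_s", "tau_s", "r2_fit")))
  }
  baseline_ratio <- NA_real_
  if (!is.null(ratio_trace)) {
    outside <- rep(TRUE, nrow(ratio_trace))
    for (i in seq_len(nrow(transients))) {
      outside[ratio_trace$time_s >= transients$onset_s[i] &
                ratio_trace$time_s <= transients$end_s[i]] <- FALSE
    }
    baseline_ratio <- stats::median(ratio_trace$F[outside])
  }
  out <- tibble::tibble(
    beat_rate_hz = sum(locked) / duration,
    n_transients = sum(!transients$is_spontaneous %in% TRUE),
    n_spontaneous = n_sp,
    spont_freq_hz = n_sp / duration,
    has_spontaneous = n_sp > 0,
    n_included_beats = nrow(kinetics),
    baseline_ratio = baseline_ratio)
  dplyr::bind_cols(out, dplyr::rename_with(kin_means, ~ paste0("mean_", .x)))
}
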