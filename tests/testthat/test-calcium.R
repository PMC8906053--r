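# Calcium transient analysis: normalization, detection, spontaneous
# classification, the exclusion rule, kinetics and per-cell summaries.

test_that("ratio traces follow R = (F410-bg)/(F485-bg) with background cancellation", {
  tt <- seq(0, 1, 0.1)
  t1 <- trace_record(tt, list(F410 = rep(4, 11), F485 = rep(2, 11)))
  r1 <- suppressWarnings(compute_ratio_trace(t1))
  expect_equal(r1$F, rep(2, 11))

  # backgrounds subtract channel-wise: F410 - 10 = 2 (F485 - 10) -> R = 2
  f485 <- 10 + seq(1, 11)
  t2 <- trace_record(tt, list(F410 = 2 * f485 - 10, F485 = f485),
                     background = c(F410 = 10, F485 = 10))
  expect_equal(compute_ratio_trace(t2)$F, rep(2, 11))

  # denominator touching the background is a signal error
  t3 <- trace_record(tt, list(F410 = rep(4, 11), F485 = c(rep(2, 10), 10)),
                     background = c(F410 = 0, F485 = 10))
  expect_error(compute_ratio_trace(t3), class = "cq_signal_error")
})

test_that("dF/F0 normalization uses the low percentile as F0", {
  tt <- seq(0, 10, 0.01)
  t1 <- trace_record(tt, list(F = rep(5, length(tt))))
  expect_equal(suppressMessages(normalize_df_f0(t1))$F, rep(0, length(tt)))

  # floor 100, peaks to 300 -> peak dF/F0 = 2 when F0 captures the floor
  f <- rep(100, length(tt))
  f[tt %% 2 > 1.0 & tt %% 2 < 1.2] <- 300
  t2 <- trace_record(tt, list(F = f))
  expect_equal(max(suppressMessages(normalize_df_f0(t2))$F), 2)

  t3 <- trace_record(tt, list(F = rep(0, length(tt))))
  expect_error(suppressMessages(normalize_df_f0(t3)), class = "cq_signal_error")
})

test_that("detection finds every beat of a paced train and nothing in noise", {
  p <- calcium_sim_params(n_beats = 10, spont_rate_hz = 0, seed = 3)
  g <- gen_calcium_trace(p, 22)
  tr <- suppressMessages(normalize_df_f0(g$trace))
  d <- detect_transients(tr)
  expect_equal(nrow(d), 10L)
  beats <- g$events$time_s[g$events$type == "stim"]
  t_pk <- 0.05 * log(1 + 0.5 / 0.05)  # analytic pulse peak delay
  expect_lt(max(abs(d$peak_s - (beats + t_pk))), 0.06 + 1 / p$sample_rate_hz)
  expect_true(all(d$onset_s < d$peak_s & d$peak_s < d$end_s))
  expect_true(all(d$amplitude > 0))

  flat <- trace_record(seq(0, 60, 0.01),
                       list(F = withr::with_seed(5, rnorm(6001, 0, 0.05))))
  expect_equal(nrow(detect_transients(flat)), 0L)
})

test_that("merged beats split at the inter-peak valley", {
  tt <- seq(0, 4, 0.01)
  pulse <- function(t0) ifelse(tt < t0, 0,
                               (1 - exp(-(tt - t0) / 0.05)) * exp(-(tt - t0) / 0.4))
  x <- pulse(1) + pulse(1.8)
  d <- detect_transients(trace_record(tt, list(F = x)))
  expect_equal(nrow(d), 2L)
  expect_lte(d$end_s[1], d$onset_s[2] + 0.05)  # shared boundary at the valley
})

test_that("spontaneous labels recover injected events with high sensitivity and precision", {
  tp <- fp <- fn <- 0L
  for (s in 1:20) {
    p <- calcium_sim_params(spont_rate_hz = 0.05, spont_amp_frac = 0.4,
                            seed = s)
    g <- gen_calcium_trace(p, 200)
    tr <- suppressMessages(normalize_df_f0(g$trace))
    d <- classify_spontaneous(detect_transients(tr), stim_freq_hz = 0.5,
                              trace = tr)
    m <- match_events(d$peak_s[d$is_spontaneous %in% TRUE],
                      g$events$time_s[g$events$type == "spont"])
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fn), 0.9)   # sensitivity
  expect_gte(tp / (tp + fp), 0.9)   # precision
})

test_that("no spontaneous labels arise without injected events", {
  p <- calcium_sim_params(spont_rate_hz = 0, seed = 9)
  g <- gen_calcium_trace(p, 60)
  tr <- suppressMessages(normalize_df_f0(g$trace))
  d <- classify_spontaneous(detect_transients(tr), 0.5, trace = tr)
  expect_equal(sum(d$is_spontaneous %in% TRUE), 0L)
})

test_that("spontaneous labels are invariant to positive rescaling of the trace", {
  p <- calcium_sim_params(spont_rate_hz = 0.05, seed = 4)
  g <- gen_calcium_trace(p, 120)
  tr <- suppressMessages(normalize_df_f0(g$trace))
  d1 <- classify_spontaneous(detect_transients(tr), 0.5, trace = tr)
  tr2 <- tr
  tr2$F <- tr2$F * 37.3
  d2 <- classify_spontaneous(detect_transients(tr2), 0.5, trace = tr2)
  expect_identical(d1$is_spontaneous, d2$is_spontaneous)
  expect_identical(d1$host_excluded, d2$host_excluded)
})

test_that("beats hosting a resolvable spontaneous event are excluded", {
  # construct: paced train plus one event injected mid-window of beat 3
  p <- calcium_sim_params(n_beats = 8, spont_rate_hz = 0, noise_sd = 1,
                          seed = 6)
  g <- gen_calcium_trace(p, 18)
  tt <- g$trace$time_s
  beats <- g$events$time_s[g$events$type == "stim"]
  ev_t <- beats[3] + 0.6
  pulse <- cardioquant:::ca_pulse(tt - ev_t, 0.05, 0.5)
  f <- g$trace$F + 0.4 * p$amplitude * p$baseline_f0 * pulse
  tr <- suppressMessages(normalize_df_f0(
    trace_record(tt, list(F = f), stim_freq_hz = 0.5)))
  d <- classify_spontaneous(detect_transients(tr), 0.5, trace = tr)
  locked <- attr(d, "rhythm_locked")
  i3 <- which(locked)[3]
  expect_true(d$host_excluded[i3])
  expect_equal(sum(d$host_excluded), 1L)
  expect_equal(sum(d$is_spontaneous %in% TRUE), 1L)
  # excluded beats refuse kinetic analysis
  expect_error(transient_kinetics(tr, d[i3, ]), class = "cq_contract_error")
  sp_i <- which(d$is_spontaneous %in% TRUE)
  expect_error(transient_kinetics(tr, d[sp_i, ]), class = "cq_contract_error")
})

test_that("kinetics reproduce closed forms on clean pulses", {
  # pure exponential decay from a peak: t50_base = tau ln 2
  tau <- 0.5
  tt <- seq(0, 6, 0.005)
  x <- ifelse(tt < 1, 0, exp(-(tt - 1) / tau))
  tr <- trace_record(tt, list(F = x))
  d <- detect_transients(tr, smooth_s = 0)
  k <- transient_kinetics(tr, d[1, ], smooth_s = 0)
  expect_equal(k$t50_base_s, tau * log(2), tolerance = 0.01)

  # noise-free synthetic beat: tau recovered within 2%
  p <- calcium_sim_params(n_beats = 6, noise_sd = 0, decay_tau_s = 0.5,
                          seed = 1)
  g <- gen_calcium_trace(p, 14)
  trn <- suppressMessages(normalize_df_f0(g$trace))
  dn <- classify_spontaneous(detect_transients(trn), 0.5)
  kk <- transient_kinetics(trn, dn[3, ])
  expect_equal(kk$tau_s, 0.5, tolerance = 0.02)
  expect_gt(kk$r2_fit, 0.999)
  expect_lt(kk$t50_peak_s, kk$t90_peak_s)
  expect_lt(kk$t50_base_s, kk$t90_base_s)

  # a decay segment too short to fit raises a kinetics error
  tt2 <- seq(0, 2, 0.2)
  x2 <- c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  tr2 <- trace_record(tt2, list(F = x2))
  d2 <- detect_transients(tr2, smooth_s = 0)
  expect_error(transient_kinetics(tr2, d2[1, ], smooth_s = 0),
               class = "cq_fit_error")
})

test_that("tau recovery holds across the tau x SNR grid (median over 20 seeds)", {
  grid <- expand.grid(tau = c(0.2, 0.5, 1.0), snr = c(20, 5))
  for (i in seq_len(nrow(grid))) {
    tau <- grid$tau[i]; snr <- grid$snr[i]
    period <- max(2, 6 * tau)   # pacing slow enough to resolve the decay
    fits <- vapply(1:20, function(s) {
      p <- calcium_sim_params(stim_freq_hz = 1 / period, n_beats = 8,
                              decay_tau_s = tau,
                              noise_sd = 2.0 * 100 / snr, seed = s)
      g <- gen_calcium_trace(p, 8.5 * period)
      tr <- suppressMessages(normalize_df_f0(g$trace))
      d <- classify_spontaneous(detect_transients(tr), 1 / period)
      inc <- which(!(d$is_spontaneous %in% TRUE) & !d$host_excluded)
      taus <- vapply(inc, function(j) {
        tryCatch(transient_kinetics(tr, d[j, ])$tau_s,
                 error = function(e) NA_real_)
      }, numeric(1))
      stats::median(taus, na.rm = TRUE)
    }, numeric(1))
    tol <- if (snr == 20) 0.05 else 0.15
    expect_lt(abs(stats::median(fits) - tau) / tau, tol,
              label = sprintf("median tau error at tau=%g SNR=%g", tau, snr))
  }
})

test_that("the exclusion rule removes spontaneous-event contamination from cell means", {
  # same seed with and without injected events: mean tau over included
  # beats must agree within the clean run's Monte-Carlo spread
  mean_tau <- function(rate, s) {
    p <- calcium_sim_params(spont_rate_hz = rate, seed = s)
    g <- gen_calcium_trace(p, 60)
    tr <- suppressMessages(normalize_df_f0(g$trace))
    d <- classify_spontaneous(detect_transients(tr), 0.5, trace = tr)
    summarize_cell(tr, d)$mean_tau_s
  }
  clean <- vapply(1:8, function(s) mean_tau(0, s), numeric(1))
  events <- vapply(1:8, function(s) mean_tau(0.08, s), numeric(1))
  ci <- 3 * stats::sd(clean) / sqrt(length(clean))
  expect_lt(abs(mean(events) - mean(clean)), max(ci, 0.01))
})

test_that("cell summaries count rates and baseline correctly", {
  p <- calcium_sim_params(n_beats = 10, spont_rate_hz = 0, seed = 2)
  g <- gen_calcium_trace(p, 20)
  tr <- suppressMessages(normalize_df_f0(g$trace))
  d <- classify_spontaneous(detect_transients(tr), 0.5, trace = tr)
  s <- summarize_cell(tr, d)
  expect_equal(s$beat_rate_hz, 0.5, tolerance = 0.01)
  expect_equal(s$n_spontaneous, 0L)
  expect_false(s$has_spontaneous)
  expect_equal(s$spont_freq_hz, 0)
  # ratiometric baseline: median of R outside transients
  rt <- trace_record(tr$time_s, list(F = rep(1.0, nrow(tr))))
  s2 <- summarize_cell(tr, d, ratio_trace = rt)
  expect_equal(s2$baseline_ratio, 1.0)
})
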