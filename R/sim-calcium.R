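# Synthetic calcium transient trains with injected spontaneous release
# events and exact ground truth, emulating Fluo-4 recordings of paced or
# spontaneously beating cardiomyocytes.

#' Parameters for the calcium-trace simulator
#'
#' The transient waveform is the product pulse
#' `(1 - exp(-t/rise_tau_s)) * exp(-t/decay_tau_s)`, rescaled so its peak
#' equals `amplitude` (in dF/F0 units). Spontaneous release events are
#' identical pulses scaled by `spont_amp_frac` at homogeneous-Poisson
#' times, reproducing their lower amplitude and random occurrence.
#'
#' @param stim_freq_hz Pacing frequency (default 0.5 Hz field stimulation).
#' @param n_beats Number of stimulated beats; `NULL` fills the duration.
#' @param amplitude Peak dF/F0 of a stimulated transient.
#' @param rise_tau_s,decay_tau_s Rise and decay time constants (s).
#' @param baseline_f0 Resting fluorescence F0 (detector units).
#' @param noise_sd Additive Gaussian noise SD, detector units.
#' @param spont_rate_hz Poisson rate of spontaneous events (per second).
#' @param spont_amp_frac Spontaneous amplitude as a fraction of the
#'   transient amplitude; must be in (0, 1) — events are lower-amplitude.
#' @param sample_rate_hz Sampling rate of the rendered trace.
#' @param seed Optional RNG seed.
#' @return A `calcium_sim_params` object.
#' @export
calcium_sim_params <- function(stim_freq_hz = 0.5,
                               n_beats = NULL,
                               amplitude = 2.0,
                               rise_tau_s = 0.05,
                               decay_tau_s = 0.5,
                               baseline_f0 = 100,
                               noise_sd = 2,
                               spont_rate_hz = 0,
                               spont_amp_frac = 0.4,
                               sample_rate_hz = 100,
                               seed = NULL) {
  check_number(stim_freq_hz, "stim_freq_hz", min = 0, strict_min = TRUE)
  check_number(amplitude, "amplitude", min = 0, strict_min = TRUE)
  check_number(rise_tau_s, "rise_tau_s", min = 0, strict_min = TRUE)
  check_number(decay_tau_s, "decay_tau_s", min = 0, strict_min = TRUE)
  check_number(baseline_f0, "baseline_f0", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(spont_rate_hz, "spont_rate_hz", min = 0)
  if (!is.numeric(spont_amp_frac) || spont_amp_frac <= 0 || spont_amp_frac >= 1) {
    stop_contract("spont_amp_frac must be in (0, 1): spontaneous events are lower-amplitude than stimulated transients")
  }
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  structure(list(stim_freq_hz = stim_freq_hz, n_beats = n_beats,
                 amplitude = amplitude, rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s, baseline_f0 = baseline_f0,
                 noise_sd = noise_sd, spont_rate_hz = spont_rate_hz,
                 spont_amp_frac = spont_amp_frac,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "calcium_sim_params")
}

# Normalized product pulse: zero for t < 0, peak value 1 at
# t* = rise * log(1 + decay/rise).
ca_pulse <- function(t, rise, decay) {
  s <- ifelse(t < 0, 0, (1 - exp(-t / rise)) * exp(-t / decay))
  t_pk <- rise * log(1 + decay / rise)
  s / ((1 - exp(-t_pk / rise)) * exp(-t_pk / decay))
}

# Time after pulse onset at which the pulse last exceeds `frac` of its
# peak (numeric bracketing on the decay limb).
ca_pulse_support <- function(rise, decay, frac = 0.1) {
  t_pk <- rise * log(1 + decay / rise)
  f <- function(t) ca_pulse(t, rise, decay) - frac
  upper <- t_pk + decay * 10
  stats::uniroot(f, c(t_pk, upper))$root
}

#' Generate a synthetic calcium trace with ground truth
#'
#' Renders a paced transient train plus Poisson-timed spontaneous release
#' events and additive Gaussian noise. The ground-truth event table marks
#' each spontaneous event's host beat (the stimulated beat whose pulse is
#' still above 10% of its amplitude when the event fires), so the
#' contaminated-beat exclusion rule is testable.
#'
#' @param p A [calcium_sim_params()].
#' @param duration_s Trace duration; must cover at least 2 beats.
#' @return A list with `trace` (a [trace_record()], channel `F`),
#'   `events` (tibble: `time_s`, `type` stim/spont, `host_beat`), and the
#'   parameter set.
#' @export
gen_calcium_trace <- function(p, duration_s) {
  stopifnot(inherits(p, "calcium_sim_params"))
  period <- 1 / p$stim_freq_hz
  check_number(duration_s, "duration_s", min = 2 * period)
  with_seed_opt(p$seed, {
    t0 <- period / 2
    n_beats <- p$n_beats %||% floor((duration_s - t0) / period + 1e-9)
    if (n_beats < 2) stop_contract("duration must cover >= 2 beats")
    beat_times <- t0 + period * (seq_len(n_beats) - 1)
    if (any(beat_times > duration_s)) {
      stop_contract("duration_s too short for %d beats at %.3g Hz",
                    n_beats, p$stim_freq_hz)
    }
    n_sp <- rpois(1, p$spont_rate_hz * duration_s)
    sp_times <- sort(runif(n_sp, 0, duration_s - period / 4))
    tt <- seq(0, duration_s, by = 1 / p$sample_rate_hz)
    sig <- rep(0, length(tt))
    for (bt in beat_times) {
      sig <- sig + p$amplitude * ca_pulse(tt - bt, p$rise_tau_s, p$decay_tau_s)
    }
    for (st in sp_times) {
      sig <- sig + p$spont_amp_frac * p$amplitude *
        ca_pulse(tt - st, p$rise_tau_s, p$decay_tau_s)
    }
    f <- p$baseline_f0 * (1 + sig) + rnorm(length(tt), 0, p$noise_sd)
    f[f < 0] <- 0
    support <- ca_pulse_support(p$rise_tau_s, p$decay_tau_s, 0.1)
    host <- vapply(sp_times, function(st) {
      inside <- which(st >= beat_times & st <= beat_times + support)
      if (length(inside)) inside[length(inside)] else NA_integer_
    }, integer(1))
    events <- dplyr::bind_rows(
      tibble::tibble(time_s = beat_times, type = "stim",
                     host_beat = NA_integer_),
      tibble::tibble(time_s = sp_times, type = "spont", host_beat = host)
    ) |> dplyr::arrange(.data$time_s)
    list(trace = trace_record(tt, list(F = f), stim_freq_hz = p$stim_freq_hz),
         events = events,
         params = p)
  })
}
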