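#' Configuration for the fluorescence trace simulator
#'
#' Emulates dual glutamate/calcium recordings: a quiescent baseline until
#' the onset of spontaneous activity, a train of oscillatory transients,
#' sensor noise, and induced responses at two food-cue removal cycles
#' (20 s and 10 s) appended after the 540 s spontaneous window.
#'
#' @param onset_time spontaneous-activity onset (s).
#' @param transient_interval mean spacing of post-onset events (s).
#' @param interval_jitter_sd jitter of periodic event times (s).
#' @param periodic periodic (TRUE) or Poisson (FALSE) event times.
#' @param ca_amplitude,glu_amplitude transient amplitudes (a.u.).
#' @param ca_rise,ca_decay,glu_rise,glu_decay kernel time constants (s);
#'   transients are alpha-function-like differences of exponentials.
#' @param glu_lead glutamate precedes calcium by this lag (s).
#' @param noise_sd additive Gaussian sensor noise (a.u.).
#' @param record_duration spontaneous window length (s).
#' @param cue_removals list of c(start_s, length_s) food-cue removals.
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @return validated list of class \code{trace_sim_config}.
#' @export
trace_sim_config <- function(onset_time = 120, transient_interval = 25,
                             interval_jitter_sd = 2, periodic = TRUE,
                             ca_amplitude = 1, glu_amplitude = 1,
                             ca_rise = 1, ca_decay = 8, glu_rise = 0.5,
                             glu_decay = 3, glu_lead = 3,
                             noise_sd = 0.02, record_duration = 540,
                             cue_removals = list(c(560, 20), c(610, 10)),
                             frame_rate = 1, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(onset_time >= 0, onset_time <= record_duration,
            transient_interval > 0, interval_jitter_sd >= 0,
            ca_rise > 0, ca_decay > 0, glu_rise > 0, glu_decay > 0,
            noise_sd >= 0, record_duration > 0, frame_rate > 0)
  structure(cfg, class = "trace_sim_config")
}

# alpha-function-like transient: difference of exponentials, peak 1, 0 for t<0
transient_kernel <- function(t, rise, decay) {
  if (rise >= decay) rise <- decay * 0.99
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  pk <- exp(-tp / decay) - exp(-tp / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / pk)
}

#' Simulate a paired glutamate/calcium trace
#'
#' Glutamate is a sum of fast transient kernels at the event times;
#' calcium is a slower kernel train lagged by \code{glu_lead}. Both sit on
#' a flat baseline before \code{onset_time}, carry additive Gaussian
#' noise, and show an induced transient at each food-cue removal. Events
#' falling after the record end are truncated.
#'
#' @param config a \code{trace_sim_config}.
#' @return list with \code{glutamate} and \code{calcium}
#'   (\code{fluorescence_trace}s) and \code{truth} (event times, onset,
#'   cue-removal starts).
#' @export
simulate_trace_pair <- function(config = trace_sim_config()) {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  dt <- 1 / config$frame_rate
  cue_starts <- vapply(config$cue_removals, `[`, numeric(1), 1L)
  total <- max(config$record_duration,
               if (length(cue_starts)) max(vapply(config$cue_removals,
                                                  sum, numeric(1))) + 20
               else 0)
  time_s <- seq(0, total, by = dt)
  # event times (spontaneous transients)
  if (config$periodic) {
    k <- ceiling((total - config$onset_time) / config$transient_interval)
    ev <- config$onset_time + (0:k) * config$transient_interval +
      stats::rnorm(k + 1L, 0, config$interval_jitter_sd)
  } else {
    ev <- config$onset_time +
      cumsum(stats::rexp(ceiling(4 * total / config$transient_interval),
                         1 / config$transient_interval))
  }
  ev <- sort(ev[ev >= config$onset_time & ev <= total])
  sum_kern <- function(times, amp, rise, decay, lag = 0) {
    out <- numeric(length(time_s))
    for (te in times)
      out <- out + amp * transient_kernel(time_s - te - lag, rise, decay)
    out
  }
  glu <- sum_kern(ev, config$glu_amplitude, config$glu_rise,
                  config$glu_decay)
  ca <- sum_kern(ev, config$ca_amplitude, config$ca_rise, config$ca_decay,
                 lag = config$glu_lead)
  # induced responses at food-cue removals, same scale as spontaneous events
  glu <- glu + sum_kern(cue_starts, config$glu_amplitude,
                        config$glu_rise, config$glu_decay)
  ca <- ca + sum_kern(cue_starts, config$ca_amplitude,
                      config$ca_rise, config$ca_decay)
  glu <- glu + stats::rnorm(length(time_s), 0, config$noise_sd)
  ca <- ca + stats::rnorm(length(time_s), 0, config$noise_sd)
  mk <- function(f, ch) fluorescence_trace(
    time_s = time_s, f = f, channel = ch,
    cue_removal_times = cue_starts,
    record_duration = config$record_duration)
  list(glutamate = mk(glu, "glutamate"), calcium = mk(ca, "calcium"),
       truth = list(event_times = ev, onset_time = config$onset_time,
                    cue_starts = cue_starts, glu_lead = config$glu_lead))
}

#' Simulate coupled head-motion and calcium traces
#'
#' Alternating calcium high/low episodes (smooth transitions between two
#' levels) with a head-position trace whose per-episode net displacement
#' sign agrees with the calcium state (high -> backward, low -> forward)
#' with probability \code{(1 + phi_target) / 2}, planting a known phi
#' coefficient.
#'
#' @param phi_target planted association in [0, 1].
#' @param seed integer seed.
#' @param n_episodes number of high/low episodes.
#' @param episode_mean_s mean episode length (s).
#' @param drift_speed head drift magnitude (units/s).
#' @param noise_sd additive noise on both channels.
#' @return list with \code{motion} (numeric head position),
#'   \code{calcium} (\code{fluorescence_trace}) and \code{truth}
#'   (episode table with planted states and motion signs).
#' @export
simulate_motion_calcium <- function(phi_target, seed = 1L,
                                    n_episodes = 30L, episode_mean_s = 20,
                                    drift_speed = 0.5, noise_sd = 0.05) {
  stopifnot(phi_target >= 0, phi_target <= 1)
  set.seed(seed)
  dur <- pmax(8L, stats::rpois(n_episodes, episode_mean_s))
  states <- rep(c("low", "high"), length.out = n_episodes)
  agree <- stats::runif(n_episodes) < (1 + phi_target) / 2
  # expected motion: high -> backward (negative), low -> forward
  sgn <- ifelse((states == "high") == agree, -1, 1)
  n <- sum(dur)
  level <- rep(ifelse(states == "high", 1, 0), times = dur)
  drift <- rep(sgn * drift_speed, times = dur)
  ca <- gaussian_smooth(level, 2, 1) + stats::rnorm(n, 0, noise_sd)
  pos <- cumsum(drift + stats::rnorm(n, 0, noise_sd))
  ends <- cumsum(dur)
  truth <- data.frame(start = c(1L, head(ends, -1L) + 1L), end = ends,
                      state = states, motion_sign = sgn,
                      stringsAsFactors = FALSE)
  list(motion = pos,
       calcium = fluorescence_trace((seq_len(n) - 1L), ca, "calcium",
                                    record_duration = n),
       truth = list(episodes = truth, phi_target = phi_target))
}
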