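#' Configuration for the track simulator
#'
#' Defaults mirror the locomotion assay conditions: 30-minute recordings
#' at two frames per second, crawl speed about 0.25 mm/s, reversal hazard
#' \code{r(t) = r0 + delta_r exp(-t / tau)} with tau = 20 s, and brief
#' backward bouts.
#'
#' @param r0 baseline forward->backward hazard (1/s).
#' @param delta_r hazard enhancement at forward-bout start (1/s).
#' @param tau enhancement decay time (s).
#' @param backward_rate backward->forward hazard (1/s), applied after the
#'   minimum reversal duration has elapsed.
#' @param min_backward_s minimum backward-bout duration (s): a reversal
#'   involves at least about one body bend, so sub-second reversals are
#'   not generated.
#' @param turn_prob_forward per-step probability of entering a forward
#'   turn while crawling forward.
#' @param turn_exit_prob per-step probability of leaving a turn substate.
#' @param omega_prob probability a backward bout ends through an omega
#'   turn.
#' @param speed crawl speed (mm/s).
#' @param heading_sd per-step heading diffusion while crawling (radians).
#' @param turn_heading_sd per-step heading change while turning (radians).
#' @param elong_scale mean body elongation (mm).
#' @param elong_mean_turn mean relative elongation while turning (< 1).
#' @param elong_sd_turn sd of relative elongation while turning.
#' @param pos_noise_sd centroid position noise (mm).
#' @param frame_rate frames per second.
#' @param duration recording length (s).
#' @param n_worms number of animals.
#' @param lost_rate rate of simulated tracking losses (1/s); losses split
#'   a worm's trajectory into censored track fragments, exercising the
#'   censoring-aware survival estimator. 0 disables.
#' @param seed integer seed.
#' @return validated list of class \code{track_sim_config}.
#' @export
track_sim_config <- function(r0 = 0.02, delta_r = 0, tau = 20,
                             backward_rate = 0.5, min_backward_s = 1,
                             turn_prob_forward = 0.005,
                             turn_exit_prob = 0.3, omega_prob = 0.5,
                             speed = 0.25, heading_sd = 0.15,
                             turn_heading_sd = 0.6, elong_scale = 1,
                             elong_mean_turn = 0.7, elong_sd_turn = 0.1,
                             pos_noise_sd = 0.01, frame_rate = 2,
                             duration = 1800, n_worms = 20,
                             lost_rate = 0, seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, as.numeric, numeric(1))
  if (!all(is.finite(num))) stop("all config values must be finite")
  stopifnot(r0 >= 0, delta_r >= 0, tau > 0, backward_rate >= 0,
            turn_prob_forward >= 0, turn_prob_forward <= 1,
            turn_exit_prob >= 0, turn_exit_prob <= 1,
            omega_prob >= 0, omega_prob <= 1, speed >= 0,
            min_backward_s >= 0,
            heading_sd >= 0, elong_scale > 0, elong_mean_turn < 1,
            elong_mean_turn > 0, frame_rate > 0, duration > 0,
            n_worms >= 1, lost_rate >= 0)
  structure(cfg, class = "track_sim_config")
}

#' Simulate worm tracks with known locomotion states
#'
#' Discrete-time simulation at the observation frame rate. Each animal
#' alternates forward and backward periods: during a forward period the
#' per-step reversal probability is \code{1 - exp(-r(t_bout) dt)} with
#' \code{r(t) = r0 + delta_r exp(-t / tau)} and \code{t_bout} the time
#' since the period began, so forward-bout durations follow the planted
#' survival law. Backward periods end at constant hazard
#' \code{backward_rate}; with probability \code{omega_prob} the
#' backward->forward transition passes through an omega turn, and forward
#' crawling can enter brief forward turns. Turn substates modulate only
#' the observables (depressed elongation, rapid reorientation), not the
#' reversal clock.
#'
#' Observables per frame: centroid (crawl displacement \code{speed * dt}
#' along the heading, reversed while backward, plus position noise), the
#' body-axis unit vector (random sign each frame, as in real tracking
#' where head and tail are indistinguishable), and elongation (Gaussian,
#' mean \code{elong_scale} and relative sd 0.075 while crawling; reduced
#' mean while turning).
#'
#' Tracks spanning the full assay start uncensored (the forward-bout
#' clock is known to start at frame 0) and end censored; simulated
#' tracking losses (\code{lost_rate > 0}) split trajectories into
#' fragments censored on both cut sides.
#'
#' @param config a \code{track_sim_config}.
#' @return list with \code{tracks} (list of \code{worm_track}) and
#'   \code{truth}: per-track data frames of true per-frame states, plus
#'   the planted parameters.
#' @export
simulate_track <- function(config = track_sim_config()) {
  stopifnot(inherits(config, "track_sim_config"))
  set.seed(config$seed)
  dt <- 1 / config$frame_rate
  n <- round(config$duration * config$frame_rate)
  rel_sd <- 0.075
  tracks <- list()
  truth <- list()
  for (wi in seq_len(config$n_worms)) {
    state <- character(n)
    theta <- numeric(n)
    pos <- matrix(0, n, 2L)
    elong <- numeric(n)
    cur <- "forward_crawl"
    bout_age <- 0L          # steps since forward period began
    back_age <- 0L          # frames spent in the current backward bout
    min_back <- round(config$min_backward_s * config$frame_rate)
    theta[1L] <- stats::runif(1, 0, 2 * pi)
    pos[1L, ] <- stats::runif(2, 0, 50)
    for (t in seq_len(n)) {
      state[t] <- cur
      in_forward <- cur %in% c("forward_crawl", "forward_turn",
                               "omega_turn")
      elong[t] <- if (cur %in% c("forward_turn", "omega_turn"))
        stats::rnorm(1, config$elong_mean_turn, config$elong_sd_turn)
      else stats::rnorm(1, 1, rel_sd)
      elong[t] <- max(elong[t], 0.05) * config$elong_scale
      if (t == n) break
      # next-frame displacement and heading
      dtheta <- if (cur %in% c("forward_turn", "omega_turn"))
        stats::rnorm(1, 0, config$turn_heading_sd)
      else stats::rnorm(1, 0, config$heading_sd)
      step_speed <- if (cur %in% c("forward_turn", "omega_turn"))
        0.3 * config$speed else config$speed
      dir <- if (cur == "backward_crawl") -1 else 1
      theta[t + 1L] <- theta[t] + dtheta
      pos[t + 1L, ] <- pos[t, ] +
        dir * step_speed * dt * c(cos(theta[t]), sin(theta[t])) +
        stats::rnorm(2, 0, config$pos_noise_sd)
      # state update
      if (in_forward) {
        haz <- config$r0 +
          config$delta_r * exp(-(bout_age * dt) / config$tau)
        if (stats::runif(1) < 1 - exp(-haz * dt)) {
          cur <- "backward_crawl"
          back_age <- 1L
        } else {
          bout_age <- bout_age + 1L
          if (cur == "forward_crawl") {
            if (stats::runif(1) < config$turn_prob_forward)
              cur <- "forward_turn"
          } else if (stats::runif(1) < config$turn_exit_prob) {
            cur <- "forward_crawl"
          }
        }
      } else {  # backward crawling
        if (back_age >= min_back &&
            stats::runif(1) < 1 - exp(-config$backward_rate * dt)) {
          cur <- if (stats::runif(1) < config$omega_prob) "omega_turn"
          else "forward_crawl"
          bout_age <- 0L
        } else {
          back_age <- back_age + 1L
        }
      }
    }
    axis <- cbind(cos(theta), sin(theta))
    flip <- sample(c(-1, 1), n, replace = TRUE)
    axis <- axis * flip
    time_s <- (seq_len(n) - 1L) * dt
    period <- ifelse(state == "backward_crawl", "backward", "forward")
    # split at simulated tracking losses
    cuts <- integer(0)
    if (config$lost_rate > 0) {
      tl <- cumsum(stats::rexp(50, config$lost_rate))
      cuts <- unique(floor(tl[tl < config$duration] * config$frame_rate))
      cuts <- cuts[cuts > 1L & cuts < n - 1L]
    }
    bounds <- sort(unique(c(0L, cuts, n)))
    for (k in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      if (length(idx) < 10L) next
      id <- sprintf("w%03d_%d", wi, k)
      tracks[[id]] <- worm_track(
        track_id = id, time_s = time_s[idx],
        x_mm = pos[idx, 1L], y_mm = pos[idx, 2L],
        axis_x = axis[idx, 1L], axis_y = axis[idx, 2L],
        elongation_mm = elong[idx],
        censored_start = !(bounds[k] == 0L),
        censored_end = TRUE)
      truth[[id]] <- data.frame(frame = idx - 1L, state = state[idx],
                                period = period[idx],
                                stringsAsFactors = FALSE)
    }
  }
  list(tracks = tracks,
       truth = list(states = truth,
                    params = config[c("r0", "delta_r", "tau",
                                      "backward_rate")],
                    delta_l = config$tau * config$delta_r,
                    ri = config$tau * config$delta_r / log(2)))
}
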