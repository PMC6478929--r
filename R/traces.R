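#' Construct a fluorescence trace
#'
#' A 1 frame/s fluorescence record from one animal: raw intensity for one
#' channel (calcium or glutamate), the food-cue removal times used to
#' check responsiveness, and the nominal duration of the pre-cue
#' spontaneous-activity window (540 s).
#'
#' @param time_s sample times (s), uniform 1 s steps expected.
#' @param f raw intensity (a.u.).
#' @param channel \code{"calcium"} or \code{"glutamate"}.
#' @param animal_id,genotype labels.
#' @param cue_removal_times times of food-cue removals (s).
#' @param record_duration spontaneous-activity window length (s).
#' @return object of class \code{fluorescence_trace}.
#' @export
fluorescence_trace <- function(time_s, f, channel = c("calcium", "glutamate"),
                               animal_id = "a1", genotype = "wt",
                               cue_removal_times = numeric(0),
                               record_duration = 540) {
  channel <- match.arg(channel)
  stopifnot(length(time_s) == length(f), length(time_s) >= 2L)
  stop_if_not_finite(f, "f")
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("non-uniform sampling: gap at index ",
         which.max(abs(dt - mean(dt))))
  structure(list(time_s = time_s, f = f, channel = channel,
                 animal_id = animal_id, genotype = genotype,
                 cue_removal_times = cue_removal_times,
                 record_duration = record_duration, dt = mean(dt)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s/%s %s, %d frames at %.3g s\n",
              x$animal_id, x$genotype, x$channel, length(x$f), x$dt))
  invisible(x)
}

# Gaussian low-pass filter: kernel truncated at +/- 4 sd, reflect boundary.
gaussian_smooth <- function(x, sd_s, dt) {
  if (sd_s <= 0) return(x)
  m <- max(1L, ceiling(4 * sd_s / dt))
  k <- exp(-((-m:m) * dt)^2 / (2 * sd_s^2))
  k <- k / sum(k)
  n <- length(x)
  pad <- c(rev(x[seq_len(min(m, n))]), x, rev(x[n + 1L - seq_len(min(m, n))]))
  if (m > n) {  # very short traces: extend reflection cyclically
    while (length(pad) < n + 2L * m)
      pad <- c(pad[1L], pad, pad[length(pad)])
  }
  y <- stats::filter(pad, k, sides = 2L)
  as.numeric(y[(length(pad) - n) / 2 + seq_len(n)])
}

#' Condition a fluorescence or motion trace
#'
#' Gaussian low-pass filtering (shot-noise removal; kernel truncated at
#' +/- 4 sd with reflected boundaries) followed by normalization: either
#' min/max scaling so the minimum is 0 and the maximum is 1, or zero-mean
#' unit-variance scaling (used for the head-motion analysis).
#'
#' @param trace a \code{fluorescence_trace} or numeric vector.
#' @param smooth_sd filter standard deviation (s); 0 skips smoothing.
#' @param normalization \code{"minmax"} or \code{"unit_variance"}.
#' @param dt frame interval (s), taken from the trace when available.
#' @return object of class \code{conditioned_trace}: list with \code{f}
#'   (conditioned signal), \code{time_s}, \code{dt}, \code{smooth_sd},
#'   \code{normalization} and the originating trace metadata.
#' @export
condition_trace <- function(trace, smooth_sd = 1,
                            normalization = c("minmax", "unit_variance"),
                            dt = NULL) {
  normalization <- match.arg(normalization)
  if (inherits(trace, "fluorescence_trace")) {
    x <- trace$f; dt <- trace$dt; time_s <- trace$time_s
    meta <- trace[c("channel", "animal_id", "genotype",
                    "cue_removal_times", "record_duration")]
  } else {
    x <- as.numeric(trace)
    dt <- dt %||% 1
    time_s <- (seq_along(x) - 1L) * dt
    meta <- list()
  }
  if (length(x) < 3L) stop("trace must have at least 3 samples")
  y <- gaussian_smooth(x, smooth_sd, dt)
  if (normalization == "minmax") {
    rng <- range(y)
    if (diff(rng) == 0)
      stop("constant trace cannot be min/max normalized")
    y <- (y - rng[1L]) / diff(rng)
  } else {
    s <- stats::sd(y)
    if (s == 0) stop("constant trace cannot be scaled to unit variance")
    y <- (y - mean(y)) / s
  }
  structure(c(list(f = y, time_s = time_s, dt = dt, smooth_sd = smooth_sd,
                   normalization = normalization), meta),
            class = "conditioned_trace")
}

#' First derivative of a conditioned trace
#'
#' The derivative used throughout onset and responsiveness scoring is the
#' one-frame difference divided by twice the frame interval,
#' \code{(F(t_n) - F(t_(n-1))) / (2 dt)}. The activity thresholds (0.05,
#' 0.15, 0.1) are calibrated on this scale, so the formula is applied
#' literally. The first sample has no derivative and is omitted; the
#' returned series aligns with \code{time_s[-1]}.
#'
#' @param conditioned a \code{conditioned_trace} or numeric vector.
#' @param dt frame interval (s), taken from the object when available.
#' @return numeric vector of length \code{n - 1}.
#' @export
trace_derivative <- function(conditioned, dt = NULL) {
  if (inherits(conditioned, "conditioned_trace")) {
    x <- conditioned$f; dt <- conditioned$dt
  } else {
    x <- as.numeric(conditioned); dt <- dt %||% 1
  }
  if (length(x) < 2L) stop("need at least 2 samples")
  diff(x) / (2 * dt)
}

#' Food-cue responsiveness
#'
#' An animal is responsive when the derivative trace exceeds
#' \code{threshold} anywhere within \code{+/- window} seconds of at least
#' one food-cue removal. Only responsive animals enter the
#' spontaneous-activity analysis.
#'
#' @param conditioned a \code{conditioned_trace}.
#' @param cue_removal_times removal times (s); defaults to the trace's own.
#' @param threshold derivative threshold (default 0.05).
#' @param window half-width of the test window (s, default 5).
#' @return logical flag.
#' @export
classify_cue_response <- function(conditioned, cue_removal_times = NULL,
                                  threshold = 0.05, window = 5) {
  stopifnot(inherits(conditioned, "conditioned_trace"))
  cues <- cue_removal_times %||% conditioned$cue_removal_times
  if (is.null(cues) || length(cues) == 0L)
    stop("no cue removal times supplied")
  d <- trace_derivative(conditioned)
  td <- conditioned$time_s[-1L]
  any(vapply(cues, function(tc)
    any(d[td >= tc - window & td <= tc + window] > threshold, na.rm = TRUE),
    logical(1)))
}

#' Spontaneous-activity onset
#'
#' Scans the derivative over the pre-cue recording window and reports the
#' first time at which either (i) the derivative exceeds
#' \code{threshold_high} (default 0.15) at any single frame, or (ii) it
#' exceeds \code{threshold_low} (default 0.05) for two or more consecutive
#' frames (onset is the first frame of the run). Returns \code{NA} when
#' neither criterion is ever met (no spontaneous activity).
#'
#' @param conditioned a \code{conditioned_trace}.
#' @param record_duration length of the scanned window (s, default 540).
#' @param threshold_high,threshold_low the two derivative criteria.
#' @return onset time (s) or \code{NA_real_}.
#' @export
detect_onset <- function(conditioned, record_duration = NULL,
                         threshold_high = 0.15, threshold_low = 0.05) {
  stopifnot(inherits(conditioned, "conditioned_trace"))
  record_duration <- record_duration %||%
    (conditioned$record_duration %||% 540)
  d <- trace_derivative(conditioned)
  td <- conditioned$time_s[-1L]
  in_win <- td <= record_duration
  d <- d[in_win]; td <- td[in_win]
  hi <- d > threshold_high
  lo <- d > threshold_low
  run2 <- lo & c(lo[-1L], FALSE)  # frame starts a run of >= 2
  hit <- hi | run2
  if (!any(hit)) return(NA_real_)
  td[which(hit)[1L]]
}
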