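#' Peak lagged cross-correlation
#'
#' Pearson correlation between two equal-length, uniformly sampled traces
#' at every integer lag within \code{+/- max_lag}, returning the maximum
#' and the lag at which it occurs. Positive lag means channel A leads
#' channel B (A's fluctuations precede B's).
#'
#' @param trace_a,trace_b numeric vectors (or \code{conditioned_trace}s).
#' @param max_lag maximum lag magnitude (s).
#' @param dt sample interval (s).
#' @return list with \code{peak} (correlation), \code{lag_s}, and the full
#'   \code{lags}/\code{correlation} profiles.
#' @export
peak_crosscorr <- function(trace_a, trace_b, max_lag = 30, dt = 1) {
  getf <- function(x) if (inherits(x, "conditioned_trace")) x$f else
    as.numeric(x)
  a <- getf(trace_a); b <- getf(trace_b)
  if (inherits(trace_a, "conditioned_trace")) dt <- trace_a$dt
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant trace")
  L <- min(floor(max_lag / dt), length(a) - 3L)
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(a[seq_len(length(a) - k)], b[k + seq_len(length(b) - k)])
    else stats::cor(a[-k + seq_len(length(a) + k)], b[seq_len(length(b) + k)])
  }, numeric(1))
  i <- which.max(cc)
  list(peak = cc[i], lag_s = lags[i] * dt, lags = lags * dt,
       correlation = cc)
}

#' Phi coefficient of a 2x2 contingency table
#'
#' Pearson's correlation for two binary variables:
#' \code{(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))}.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return phi in [-1, 1].
#' @export
phi_coefficient <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  num <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
  den <- sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  if (den == 0) stop("degenerate table: a zero marginal")
  num / den
}

#' Calcium-state vs. motion-direction association
#'
#' Segments the calcium trace into high/low activity episodes and asks
#' whether high states co-occur with backward head motion. The calcium
#' signal is smoothed (sd 1.5 s), scaled to unit variance, and its
#' derivative computed; times where the derivative crosses +0.1 from below
#' mark transitions into the high state, and crossings of -0.1 from above
#' transitions into the low state. Head position is smoothed with sd 3 s.
#' For each episode the net position change determines the motion label
#' (increase = forward, decrease = backward); association between state
#' (high/low) and motion (backward/forward) is Pearson's phi coefficient.
#' Partial first/last episodes are kept when at least \code{min_frames}
#' long.
#'
#' @param motion head-position series (numeric or
#'   \code{conditioned_trace}); raw positions, smoothed internally when
#'   numeric.
#' @param calcium calcium series (numeric raw trace, conditioned
#'   internally; or an already unit-variance \code{conditioned_trace}).
#' @param dt frame interval (s).
#' @param threshold derivative crossing threshold (default 0.1).
#' @param pos_smooth_sd,ca_smooth_sd smoothing scales (s).
#' @param min_frames minimum episode length kept (frames).
#' @return list with \code{phi}, the 2x2 \code{table} (rows high/low,
#'   columns backward/forward) and the \code{episodes} data frame.
#' @export
calcium_state_phi <- function(motion, calcium, dt = 1, threshold = 0.1,
                              pos_smooth_sd = 3, ca_smooth_sd = 1.5,
                              min_frames = 3L) {
  pos <- if (inherits(motion, "conditioned_trace")) motion$f else
    gaussian_smooth(as.numeric(motion), pos_smooth_sd, dt)
  ca <- if (inherits(calcium, "conditioned_trace")) calcium else
    condition_trace(as.numeric(calcium), smooth_sd = ca_smooth_sd,
                    normalization = "unit_variance", dt = dt)
  stopifnot(length(pos) == length(ca$f))
  d <- trace_derivative(ca)              # aligned with frames 2..n
  up <- which(d[-1L] > threshold & d[-length(d)] <= threshold) + 2L
  down <- which(d[-1L] < -threshold & d[-length(d)] >= -threshold) + 2L
  trans <- sort(c(up, down))
  if (length(trans) < 1L) stop("fewer than 2 calcium-state episodes")
  state_after <- ifelse(trans %in% up, "high", "low")
  starts <- c(1L, trans)
  ends <- c(trans - 1L, length(pos))
  states <- c(ifelse(state_after[1L] == "high", "low", "high"), state_after)
  keep <- (ends - starts + 1L) >= min_frames
  ep <- data.frame(start = starts[keep], end = ends[keep],
                   state = states[keep], stringsAsFactors = FALSE)
  if (nrow(ep) < 2L) stop("fewer than 2 calcium-state episodes")
  ep$dpos <- pos[ep$end] - pos[ep$start]
  ep$motion <- ifelse(ep$dpos >= 0, "forward", "backward")
  tab <- matrix(0, 2L, 2L,
                dimnames = list(state = c("high", "low"),
                                motion = c("backward", "forward")))
  for (i in seq_len(nrow(ep)))
    tab[ep$state[i], ep$motion[i]] <- tab[ep$state[i], ep$motion[i]] + 1
  list(phi = phi_coefficient(tab), table = tab, episodes = ep)
}
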