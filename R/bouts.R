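#' Segment a posterior into forward/backward bouts
#'
#' A frame is backward when the inferred probability of backward crawling
#' (both sign states combined) exceeds one half, forward otherwise (turn
#' states therefore count toward forward periods). Consecutive frames with
#' the same label are merged into intervals; intervals touching a censored
#' track boundary are flagged, because their full duration is unobserved
#' (tracks are lost when worms exit the field of view or collide).
#'
#' Frames are indexed from 0 and intervals are half-open \code{[start,
#' end)}, so \code{end - start} is the bout duration in frames.
#'
#' @param posterior a \code{state_posterior}.
#' @param censored_start,censored_end whether the track's first/last frame
#'   is a censored boundary (TRUE for tracks cut by tracking loss).
#' @return object of class \code{bout_segmentation}: data frame with
#'   columns \code{start}, \code{end}, \code{label}
#'   (\code{"forward"}/\code{"backward"}), \code{censored}; attribute
#'   \code{dt} if present on the posterior.
#' @export
segment_bouts <- function(posterior, censored_start = TRUE,
                          censored_end = TRUE) {
  stopifnot(inherits(posterior, "state_posterior"))
  p_back <- rowSums(posterior$gamma[, backward_states(), drop = FALSE])
  lab <- ifelse(p_back > 0.5, "backward", "forward")
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  seg <- data.frame(start = starts, end = ends, label = runs$values,
                    censored = FALSE, stringsAsFactors = FALSE)
  if (isTRUE(censored_start)) seg$censored[1L] <- TRUE
  if (isTRUE(censored_end)) seg$censored[nrow(seg)] <- TRUE
  structure(seg, class = c("bout_segmentation", "data.frame"),
            dt = attr(posterior, "dt"))
}

#' Censoring-aware forward-bout survival curve
#'
#' Discrete-hazard (product-limit) estimate of the probability that a
#' forward bout lasts at least n steps. For each step index i since bout
#' start, the hazard is the fraction of at-risk bouts that end in a
#' reversal at that step; censored bouts leave the risk set without
#' counting as events. The survival curve is the running product
#' \code{p_f(n) = prod_{i < n} (1 - hazard(i))}, with \code{p_f(0) = 1}.
#'
#' @param segmentations a \code{bout_segmentation} or a list of them (one
#'   per track).
#' @param dt frame interval in seconds (used only to annotate the time
#'   axis; default 0.5 s, i.e. two frames per second).
#' @return object of class \code{survival_curve}: list with \code{steps}
#'   (0-based hazard indices), \code{hazard}, \code{n_at_risk},
#'   \code{n_events}, \code{p_f} (length \code{max_steps + 1}, for
#'   n = 0..max), and \code{dt}.
#' @export
forward_survival <- function(segmentations, dt = 0.5) {
  if (inherits(segmentations, "bout_segmentation"))
    segmentations <- list(segmentations)
  durs <- integer(0)
  evts <- logical(0)
  for (seg in segmentations) {
    fwd <- seg[seg$label == "forward", , drop = FALSE]
    if (nrow(fwd) == 0L) next
    durs <- c(durs, fwd$end - fwd$start)
    evts <- c(evts, !fwd$censored)
  }
  if (length(durs) == 0L) stop("no forward bouts in input")
  m <- max(durs)
  n_at_risk <- vapply(seq_len(m) - 1L,
                      function(i) sum(durs >= i + 1L), integer(1))
  n_events <- vapply(seq_len(m) - 1L,
                     function(i) sum(evts & durs == i + 1L), integer(1))
  hazard <- ifelse(n_at_risk > 0L, n_events / n_at_risk, 0)
  p_f <- cumprod(c(1, 1 - hazard))
  structure(list(steps = seq_len(m) - 1L, hazard = hazard,
                 n_at_risk = n_at_risk, n_events = n_events,
                 p_f = p_f, dt = dt),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %d bouts at entry, %d steps of %.3g s\n",
              x$n_at_risk[1L], length(x$hazard), x$dt))
  invisible(x)
}

#' Reversal rate in events per worm-minute
#'
#' Counts forward-to-backward transitions (forward bouts that end in an
#' observed reversal) and divides by the total observed track time.
#'
#' @param segmentations a \code{bout_segmentation} or list of them.
#' @param dt frame interval (s).
#' @return reversals per worm-minute.
#' @export
reversal_rate <- function(segmentations, dt = 0.5) {
  if (inherits(segmentations, "bout_segmentation"))
    segmentations <- list(segmentations)
  events <- 0L
  frames <- 0L
  for (seg in segmentations) {
    fwd <- seg[seg$label == "forward", , drop = FALSE]
    events <- events + sum(!fwd$censored)
    frames <- frames + max(seg$end)
  }
  total_min <- frames * dt / 60
  if (total_min <= 0) stop("total observed time must be positive")
  events / total_min
}
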