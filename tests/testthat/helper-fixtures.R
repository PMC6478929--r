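# Shared fixture builders. Everything is generated in code; no data files.

# observation series straight from vectors (bypasses track construction)
make_obs <- function(r, dx, dt = 0.5, censored_start = FALSE,
                     censored_end = TRUE) {
  structure(list(r = r, dx = dx, dt = dt, censored_start = censored_start,
                 censored_end = censored_end),
            class = "observation_series")
}

# a state_posterior with a prescribed backward probability per frame
make_posterior <- function(p_back) {
  n <- length(p_back)
  g <- matrix(0, n, 6L,
              dimnames = list(NULL, c("forward_plus", "forward_minus",
                                      "backward_plus", "backward_minus",
                                      "forward_turn", "omega_turn")))
  g[, "backward_plus"] <- p_back
  g[, "forward_plus"] <- 1 - p_back
  structure(list(gamma = g, xi_sum = matrix(0, 6, 6), loglik = 0),
            class = "state_posterior")
}

# bout segmentation from explicit intervals
make_seg <- function(lengths, labels, censored = rep(FALSE, length(lengths))) {
  ends <- cumsum(lengths)
  structure(data.frame(start = ends - lengths, end = ends, label = labels,
                       censored = censored, stringsAsFactors = FALSE),
            class = c("bout_segmentation", "data.frame"))
}

# an animal_spectrum with given amplitudes/weight
make_animal_spectrum <- function(amplitude, weight = 1,
                                 freq = seq_along(amplitude)) {
  structure(list(freq = freq, amplitude = amplitude, weight = weight),
            class = "animal_spectrum")
}

# a conditioned_trace carrying an arbitrary signal (already conditioned)
make_conditioned <- function(f, dt = 1, record_duration = NULL) {
  structure(list(f = f, time_s = (seq_along(f) - 1) * dt, dt = dt,
                 smooth_sd = 0, normalization = "minmax",
                 cue_removal_times = numeric(0),
                 record_duration = record_duration %||% (length(f) * dt)),
            class = "conditioned_trace")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force forward-backward: enumerate every state sequence
enumerate_posterior <- function(emis, trans, init) {
  T_ <- nrow(emis); K <- ncol(emis)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  probs <- apply(seqs, 1L, function(s) {
    p <- init[s[1L]] * emis[1L, s[1L]]
    if (T_ > 1L) for (t in 2:T_)
      p <- p * trans[s[t - 1L], s[t]] * emis[t, s[t]]
    p
  })
  z <- sum(probs)
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    gamma[t, k] <- sum(probs[seqs[, t] == k]) / z
  list(gamma = gamma, loglik = log(z))
}

# product-limit survival by brute force from (duration, event) pairs
brute_product_limit <- function(dur, event, n_max = max(dur)) {
  h <- numeric(n_max)
  for (i in seq_len(n_max) - 1L) {
    at_risk <- sum(dur >= i + 1L)
    if (at_risk > 0L) h[i + 1L] <- sum(event & dur == i + 1L) / at_risk
  }
  list(hazard = h, p_f = cumprod(c(1, 1 - h)))
}

# true forward/backward segmentation from simulator ground truth
seg_from_truth <- function(truth_df, censored_start = FALSE,
                           censored_end = TRUE) {
  lab <- ifelse(truth_df$period == "backward", "backward", "forward")
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  seg <- data.frame(start = ends - runs$lengths, end = ends,
                    label = runs$values, censored = FALSE,
                    stringsAsFactors = FALSE)
  if (censored_start) seg$censored[1L] <- TRUE
  if (censored_end) seg$censored[nrow(seg)] <- TRUE
  structure(seg, class = c("bout_segmentation", "data.frame"))
}

# decode one simulated cohort through the full pipeline and fit RI
decode_and_fit <- function(cfg, tau = 20) {
  sim <- simulate_track(cfg)
  obs <- lapply(sim$tracks, preprocess_track)
  bw <- baum_welch(obs)
  segs <- Map(function(p, o) segment_bouts(p, o$censored_start,
                                           o$censored_end),
              bw$posteriors, obs)
  sv <- forward_survival(segs, dt = 1 / cfg$frame_rate)
  list(sim = sim, bw = bw, segs = segs, survival = sv,
       fit = fit_reversal_model(sv, tau = tau))
}
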