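#' Six-state locomotion model
#'
#' The state alphabet is forward and backward crawling, each split by the
#' arbitrary sign convention linking the body-axis projection to movement
#' direction (\code{forward_plus}, \code{forward_minus},
#' \code{backward_plus}, \code{backward_minus}), plus \code{forward_turn}
#' and \code{omega_turn}. Permitted transitions: self-loops on every state;
#' reversals preserve the sign (forward+ <-> backward+, forward- <->
#' backward-); forward crawling <-> forward turn; and omega turns occur only
#' in the sequence backward crawling -> omega turn -> forward crawling
#' (either sign on exit). All other transition probabilities are
#' structurally zero and stay zero through re-estimation.
#'
#' Emission parameters are fixed, not fitted: the relative-elongation width
#' \code{sigma_r = 0.075} (close to the observed spread in moving worms) and
#' the direction-scoring velocity \code{c = 0.1} mm/s (a fraction of the
#' typical 0.25 mm/s crawl speed, so a worm must move a finite distance for
#' its direction to be scored with confidence).
#'
#' The default transition initializer gives backward -> forward a higher
#' per-frame rate (0.05) than forward -> backward (0.01). This asymmetry is
#' the only symmetry-breaking input: because backward bouts are much
#' shorter than forward bouts, Baum-Welch converges to an assignment in
#' which the longer-bout direction is labeled forward.
#'
#' @param transition optional 6 x 6 row-stochastic matrix respecting the
#'   permitted-transition mask.
#' @param initial optional length-6 initial state distribution.
#' @param sigma_r emission width for relative elongation (dimensionless).
#' @param c_vel direction-scoring velocity (mm/s).
#' @return object of class \code{hmm_model}.
#' @export
hmm_model <- function(transition = NULL, initial = NULL,
                      sigma_r = 0.075, c_vel = 0.1) {
  states <- hmm_states()
  mask <- hmm_transition_mask()
  if (is.null(transition)) {
    transition <- matrix(0, 6L, 6L, dimnames = list(states, states))
    transition["forward_plus", c("forward_plus", "backward_plus",
                                 "forward_turn")] <- c(0.95, 0.01, 0.04)
    transition["forward_minus", c("forward_minus", "backward_minus",
                                  "forward_turn")] <- c(0.95, 0.01, 0.04)
    transition["backward_plus", c("backward_plus", "forward_plus",
                                  "omega_turn")] <- c(0.93, 0.05, 0.02)
    transition["backward_minus", c("backward_minus", "forward_minus",
                                   "omega_turn")] <- c(0.93, 0.05, 0.02)
    transition["forward_turn", c("forward_turn", "forward_plus",
                                 "forward_minus")] <- c(0.8, 0.1, 0.1)
    transition["omega_turn", c("omega_turn", "forward_plus",
                               "forward_minus")] <- c(0.8, 0.1, 0.1)
  } else {
    transition <- as.matrix(transition)
    dimnames(transition) <- list(states, states)
  }
  if (is.null(initial)) initial <- rep(1 / 6, 6L)
  stopifnot(sigma_r > 0, c_vel > 0)
  if (any(transition[!mask] != 0))
    stop("transition matrix has positive mass outside the permitted mask")
  if (any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-8) stop("initial distribution must sum to 1")
  structure(list(states = states, transition = transition,
                 initial = setNames(as.numeric(initial), states),
                 sigma_r = sigma_r, c_vel = c_vel, mask = mask),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> 6 locomotion states; sigma_r =", x$sigma_r,
      ", c =", x$c_vel, "mm/s\n")
  print(round(x$transition, 4))
  invisible(x)
}

hmm_states <- function() {
  c("forward_plus", "forward_minus", "backward_plus", "backward_minus",
    "forward_turn", "omega_turn")
}

hmm_transition_mask <- function() {
  states <- hmm_states()
  mask <- matrix(FALSE, 6L, 6L, dimnames = list(states, states))
  diag(mask) <- TRUE
  mask["forward_plus", "backward_plus"] <- TRUE
  mask["backward_plus", "forward_plus"] <- TRUE
  mask["forward_minus", "backward_minus"] <- TRUE
  mask["backward_minus", "forward_minus"] <- TRUE
  mask[c("forward_plus", "forward_minus"), "forward_turn"] <- TRUE
  mask["forward_turn", c("forward_plus", "forward_minus")] <- TRUE
  mask[c("backward_plus", "backward_minus"), "omega_turn"] <- TRUE
  mask["omega_turn", c("forward_plus", "forward_minus")] <- TRUE
  mask
}

crawling_states <- function() {
  c("forward_plus", "forward_minus", "backward_plus", "backward_minus")
}

backward_states <- function() c("backward_plus", "backward_minus")

# permutation swapping the arbitrary +/- orientation labels
sign_swap_perm <- function() {
  states <- hmm_states()
  swapped <- c("forward_minus", "forward_plus", "backward_minus",
               "backward_plus", "forward_turn", "omega_turn")
  match(swapped, states)
}

#' Relative-elongation emission density
#'
#' For crawling states the relative elongation follows a Gaussian with mean
#' 1 and standard deviation \code{sigma_r}. For turning states the density
#' is uniform (value 1) on r <= 1 and decays as the same Gaussian for
#' r > 1; this factor is deliberately unnormalized — only likelihood ratios
#' between states matter under per-frame posterior normalization.
#'
#' @param r relative elongation (dimensionless, > 0); vectorized.
#' @param class \code{"crawling"} or \code{"turning"}.
#' @param sigma_r emission width.
#' @return likelihood factor, same length as \code{r}.
#' @export
r_emission <- function(r, class = c("crawling", "turning"),
                       sigma_r = 0.075) {
  class <- match.arg(class)
  if (class == "crawling") {
    exp(-(r - 1)^2 / (2 * sigma_r^2)) / (sigma_r * sqrt(2 * pi))
  } else {
    ifelse(r <= 1, 1, exp(-(r - 1)^2 / (2 * sigma_r^2)))
  }
}

#' Direction-scoring factor
#'
#' Probability factor distinguishing movement direction from the projected
#' displacement \code{dx} over one frame: \code{sig(dx / (c dt))} for
#' states in which the worm moves toward positive x (forward+ and
#' backward-), its complement for forward- and backward+, and 1/2 for the
#' turning states (direction uninformative). The sigmoid is
#' \code{sig(x) = (1 + erf(2 x)) / 2}, so displacements small compared with
#' \code{c dt} score near 1/2 and position noise in a motionless worm is
#' discounted.
#'
#' @param dx projected displacement (mm); vectorized.
#' @param dt frame interval (s).
#' @param state one of the six state labels.
#' @param c_vel scoring velocity (mm/s).
#' @return probability factor in (0, 1).
#' @export
direction_factor <- function(dx, dt, state, c_vel = 0.1) {
  stopifnot(dt > 0)
  state <- match.arg(state, hmm_states())
  sig <- (1 + erf(2 * dx / (c_vel * dt))) / 2
  switch(state,
         forward_plus = sig,
         backward_minus = sig,
         forward_minus = 1 - sig,
         backward_plus = 1 - sig,
         forward_turn = rep(0.5, length(dx)),
         omega_turn = rep(0.5, length(dx)))
}

#' Per-frame emission likelihood matrix
#'
#' Combines the relative-elongation density and the direction factor into
#' an (n - 1) x 6 matrix over frame pairs: row t covers observables
#' \code{r[t]} and \code{dx[t]} (displacement from frame t to t + 1).
#' Frames with non-finite observations receive a uniform row rather than
#' breaking the track. Entries are floored at a tiny positive value so the
#' forward-backward recursion never sees an all-zero row.
#'
#' @param obs an \code{observation_series}.
#' @param model an \code{hmm_model}.
#' @return numeric matrix, one column per state.
#' @export
emission_matrix <- function(obs, model) {
  stopifnot(inherits(obs, "observation_series"), inherits(model, "hmm_model"))
  n <- length(obs$dx)
  r <- obs$r[seq_len(n)]
  dx <- obs$dx
  bad <- !is.finite(r) | !is.finite(dx)
  r[bad] <- 1
  dx[bad] <- 0
  crawl <- r_emission(r, "crawling", model$sigma_r)
  turn <- r_emission(r, "turning", model$sigma_r)
  sig <- (1 + erf(2 * dx / (model$c_vel * obs$dt))) / 2
  em <- cbind(forward_plus = crawl * sig,
              forward_minus = crawl * (1 - sig),
              backward_plus = crawl * (1 - sig),
              backward_minus = crawl * sig,
              forward_turn = turn * 0.5,
              omega_turn = turn * 0.5)
  em[bad, ] <- 1
  pmax(em, 1e-300)
}

#' Forward-backward state inference
#'
#' Scaled forward-backward recursions over one track, returning the
#' per-frame posterior state probabilities, pairwise expected transition
#' counts and the total log-likelihood of the observations under the model.
#'
#' @param emissions emission matrix from [emission_matrix()] (or any
#'   strictly positive T x 6 matrix).
#' @param model an \code{hmm_model}.
#' @return object of class \code{state_posterior} with elements
#'   \code{gamma} (T x 6 posterior matrix), \code{xi_sum} (6 x 6 expected
#'   transition counts) and \code{loglik}.
#' @export
forward_backward <- function(emissions, model) {
  stopifnot(inherits(model, "hmm_model"))
  emissions <- as.matrix(emissions)
  if (any(emissions <= 0)) stop("emissions must be strictly positive")
  res <- forward_backward_cpp(emissions, model$transition, model$initial)
  dimnames(res$gamma) <- list(NULL, model$states)
  dimnames(res$xi_sum) <- list(model$states, model$states)
  structure(list(gamma = res$gamma, xi_sum = res$xi_sum,
                 loglik = res$loglik),
            class = "state_posterior")
}

#' @export
print.state_posterior <- function(x, ...) {
  cat(sprintf("<state_posterior> %d frames, loglik = %.3f\n",
              nrow(x$gamma), x$loglik))
  invisible(x)
}

#' Baum-Welch estimation of transition probabilities
#'
#' Iterates forward-backward inference and re-estimation of the transition
#' matrix (and initial distribution), pooled across all tracks of a movie.
#' Only the transition structure is estimated; the emission parameters
#' \code{sigma_r} and \code{c} are fixed model constants. Structural zeros
#' of the permitted-transition mask are preserved exactly (an expected
#' count through a zero entry is identically zero). The data log-likelihood
#' is non-decreasing across iterations; iteration stops when the relative
#' improvement drops below \code{tol} or at \code{max_iter}.
#'
#' @param tracks list of \code{observation_series} (or \code{worm_track}s,
#'   which are preprocessed first).
#' @param init_model starting \code{hmm_model}; must respect the mask and
#'   carry the backward->forward vs forward->backward rate asymmetry that
#'   anchors the absolute direction labels.
#' @param tol relative log-likelihood tolerance.
#' @param max_iter iteration cap.
#' @param tie_sign enforce invariance of the transition parameters under
#'   the sign-swap permutation (+ <-> -) by pooling the corresponding
#'   expected counts each M-step (default TRUE). The +/- split exists
#'   only to track the arbitrary body-axis orientation, so the behavioral
#'   rates cannot depend on it; without tying, re-estimation can drift
#'   into a labeling that repurposes a backward sign-state as a second
#'   long-lived forward state (they share the same direction factor),
#'   breaking the brief-backward-bout asymmetry that anchors absolute
#'   direction.
#' @return list with the fitted \code{model}, per-track \code{posteriors}
#'   (decoded under the final model), and the per-iteration
#'   \code{loglik_trace}.
#' @export
baum_welch <- function(tracks, init_model = hmm_model(), tol = 1e-6,
                       max_iter = 200L, tie_sign = TRUE) {
  if (inherits(tracks, "observation_series") || inherits(tracks, "worm_track"))
    tracks <- list(tracks)
  tracks <- lapply(tracks, function(tr) {
    if (inherits(tr, "worm_track")) preprocess_track(tr) else tr
  })
  stopifnot(length(tracks) >= 1L, inherits(init_model, "hmm_model"))
  model <- init_model
  emis <- lapply(tracks, emission_matrix, model = model)
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    xi_tot <- matrix(0, 6L, 6L)
    g1 <- numeric(6L)
    ll <- 0
    for (e in emis) {
      fb <- forward_backward_cpp(e, model$transition, model$initial)
      xi_tot <- xi_tot + fb$xi_sum
      g1 <- g1 + fb$gamma[1L, ]
      ll <- ll + fb$loglik
    }
    ll_trace <- c(ll_trace, ll)
    if (tie_sign) {
      p <- sign_swap_perm()
      xi_tot <- (xi_tot + xi_tot[p, p]) / 2
      g1 <- (g1 + g1[p]) / 2
    }
    trans_new <- xi_tot / pmax(rowSums(xi_tot), .Machine$double.xmin)
    # a state never visited keeps its previous row (its row sum is ~0)
    dead <- rowSums(xi_tot) <= 0
    trans_new[dead, ] <- model$transition[dead, ]
    init_new <- g1 / sum(g1)
    model <- hmm_model(transition = trans_new, initial = init_new,
                       sigma_r = model$sigma_r, c_vel = model$c_vel)
    if (iter > 1L) {
      rel <- (ll - ll_trace[iter - 1L]) /
        max(abs(ll_trace[iter - 1L]), .Machine$double.eps)
      if (abs(rel) < tol) break
    }
  }
  posteriors <- lapply(emis, forward_backward, model = model)
  list(model = model, posteriors = posteriors, loglik_trace = ll_trace)
}
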