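#' Model survival under a transiently enhanced reversal rate
#'
#' The reversal hazard after a time t of forward movement is modeled as
#' \code{r(t) = r0 + delta_r * exp(-t / tau)}: a baseline Poisson rate r0
#' plus a short-time enhancement delta_r decaying over tau. Integrating the
#' hazard gives \code{log p_f(t) = -r0 t - delta_l (1 - exp(-t / tau))}
#' with \code{delta_l = tau * delta_r}. The repetitive behavior index is
#' \code{RI = delta_l / ln 2}: at RI = 1, 50\% fewer worms are still moving
#' forward at long times than the baseline exponential predicts.
#'
#' @param t time since bout start (s); vectorized.
#' @param r0 baseline reversal rate (1/s).
#' @param delta_l dimensionless short-time excess (tau * delta_r).
#' @param tau decay time of the enhancement (s).
#' @return p_f(t), the probability of still moving forward at t.
#' @export
model_survival <- function(t, r0, delta_l, tau = 20) {
  stopifnot(tau > 0)
  exp(-r0 * t - delta_l * (1 - exp(-t / tau)))
}

#' Convert between repetitive index and excess reversal length
#'
#' \code{RI = delta_l / ln 2}; the log is natural, anchored by the model's
#' interpretation that RI = 1 corresponds to a 50\% asymptotic deficit in
#' forward survival (\code{exp(-ln 2) = 1/2}).
#'
#' @param ri repetitive behavior index.
#' @return \code{delta_l}.
#' @export
ri_to_delta_l <- function(ri) ri * log(2)

#' @rdname ri_to_delta_l
#' @param delta_l dimensionless excess.
#' @export
delta_l_to_ri <- function(delta_l) delta_l / log(2)

#' Fit the repetitive-reversal model to a survival curve
#'
#' Weighted least squares on \code{log p_f(t)}, which is exactly linear in
#' (r0, delta_l) once tau is fixed: regressors \code{-t} and
#' \code{-(1 - exp(-t / tau))}. tau is held at 20 s by default to keep a
#' consistent split of early vs. late reversal rates across lines;
#' \code{model = "poisson"} constrains delta_l = 0 (pure exponential null).
#' delta_l is unconstrained in sign; a negative estimate (anti-repetitive)
#' is reported as such and flagged.
#'
#' Bins run at native frame steps from n = 1 up to the last bin with at
#' least \code{min_at_risk} bouts at risk, and bins with \code{p_f = 0} are
#' dropped (their log is undefined). Default weights are inverse
#' Greenwood-type variances of \code{log p_f} accumulated from the
#' discrete hazards; pass \code{weights} (per-bin variances of log p_f,
#' e.g. across-movie SDs squared) to override.
#'
#' \code{boundary_offset = TRUE} (the default) adds a free intercept to
#' the regression. Posterior-threshold decoding cannot resolve bouts at
#' the single-frame scale, which depresses the hazard at the first step
#' or two; because log survival is cumulative, this appears as a constant
#' offset at every later bin. The intercept absorbs that segmentation
#' granularity. On survival curves that follow the model exactly the
#' intercept fits to 0, so noiseless recovery is unchanged.
#'
#' @param survival a \code{survival_curve}, or a data frame with columns
#'   \code{t_s} and \code{p_f} (and optionally \code{n_at_risk}).
#' @param weights optional per-bin variance of log p_f (same length as the
#'   included bins); the fit uses 1/variance weights.
#' @param tau fixed decay time (s).
#' @param model \code{"repetitive"} (free delta_l) or \code{"poisson"}
#'   (delta_l = 0).
#' @param min_at_risk drop bins once fewer bouts remain at risk.
#' @param boundary_offset include a free intercept absorbing
#'   bout-boundary segmentation granularity (see Details).
#' @return object of class \code{ri_fit}: estimates and standard errors for
#'   r0, delta_l and RI, the fixed tau, fitted log p_f, weighted residual
#'   sum of squares \code{S_min}, \code{dof}, and the chi-square p-value.
#' @export
fit_reversal_model <- function(survival, weights = NULL, tau = 20,
                               model = c("repetitive", "poisson"),
                               min_at_risk = 5L, boundary_offset = TRUE) {
  model <- match.arg(model)
  stopifnot(tau > 0)
  if (inherits(survival, "survival_curve")) {
    dt <- survival$dt
    n <- seq_along(survival$hazard)      # p_f(n) for n = 1..m
    t_s <- n * dt
    p_f <- survival$p_f[-1L]
    at_risk <- survival$n_at_risk
    var_g <- cumsum(ifelse(survival$hazard < 1,
                           survival$hazard /
                             ((1 - survival$hazard) * survival$n_at_risk), 0))
  } else {
    survival <- as.data.frame(survival)
    stopifnot(all(c("t_s", "p_f") %in% names(survival)))
    t_s <- survival$t_s
    p_f <- survival$p_f
    at_risk <- survival$n_at_risk %||% rep(Inf, length(t_s))
    var_g <- NULL
  }
  keep <- at_risk >= min_at_risk & p_f > 0
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(t_s) || length(weights) == sum(keep))
    if (length(weights) == length(t_s)) weights <- weights[keep]
  } else if (!is.null(var_g)) {
    v <- var_g[keep]
    floor_v <- if (any(v > 0)) min(v[v > 0]) / 2 else 1
    weights <- pmax(v, floor_v)
  } else {
    weights <- rep(1, sum(keep))
  }
  t_s <- t_s[keep]
  p_f <- p_f[keep]
  if (length(t_s) < (if (model == "repetitive") 3L else 2L))
    stop("too few usable bins with p_f > 0 to fit")
  y <- log(p_f)
  w <- 1 / weights
  x1 <- -t_s
  x2 <- -(1 - exp(-t_s / tau))
  if (model == "repetitive") {
    # delta_l is identified by the saturation of (1 - exp(-t/tau)); if the
    # observed times never approach tau the regressor is proportional to t
    if (max(t_s) < 0.2 * tau || abs(stats::cor(x1, x2)) > 1 - 1e-10)
      stop("non-identifiable fit: all times are small relative to tau, ",
           "r0 and delta_l cannot be separated")
    fit <- if (boundary_offset) stats::lm(y ~ x1 + x2, weights = w)
    else stats::lm(y ~ 0 + x1 + x2, weights = w)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    r0 <- est[["x1"]]; delta_l <- est[["x2"]]
    r0_se <- se[["x1"]]; dl_se <- se[["x2"]]
  } else {
    fit <- if (boundary_offset) stats::lm(y ~ x1, weights = w)
    else stats::lm(y ~ 0 + x1, weights = w)
    r0 <- stats::coef(fit)[["x1"]]
    r0_se <- sqrt(diag(stats::vcov(fit)))[["x1"]]
    delta_l <- 0; dl_se <- 0
  }
  fitted_log_pf <- as.numeric(stats::fitted(fit))
  s_min <- sum(w * stats::residuals(fit)^2)
  dof <- length(t_s)  # number of binned time points
  structure(list(r0 = r0, r0_se = r0_se,
                 delta_r = delta_l / tau,
                 delta_l = delta_l, delta_l_se = dl_se,
                 ri = delta_l_to_ri(delta_l),
                 ri_se = dl_se / log(2),
                 anti_repetitive = delta_l < 0,
                 tau = tau, model = model,
                 t_s = t_s, log_pf = y, fitted_log_pf = fitted_log_pf,
                 weights_var = weights,
                 s_min = s_min, dof = dof,
                 p_value = stats::pchisq(s_min, dof, lower.tail = FALSE)),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf(paste0("<ri_fit> model=%s, tau=%g s\n",
                     "  r0 = %.5f +/- %.5f 1/s\n",
                     "  delta_l = %.4f +/- %.4f  (RI = %.3f)%s\n",
                     "  S_min = %.2f on %d dof (p = %.3g)\n"),
              x$model, x$tau, x$r0, x$r0_se, x$delta_l, x$delta_l_se,
              x$ri, if (x$anti_repetitive) " [anti-repetitive]" else "",
              x$s_min, x$dof, x$p_value))
  invisible(x)
}

#' Asymptotic suppression of forward survival
#'
#' At long times the fitted survival sits a constant factor
#' \code{exp(-delta_l)} below the baseline exponential
#' \code{exp(-r0 t)}; this returns the percent deficit
#' \code{100 (1 - exp(-delta_l))}. An RI of 1 (delta_l = ln 2) gives 50\%:
#' half as many worms still moving forward as the baseline rate predicts.
#'
#' @param fit an \code{ri_fit}, or a numeric \code{delta_l} directly.
#' @return percent reduction.
#' @export
long_time_suppression <- function(fit) {
  delta_l <- if (inherits(fit, "ri_fit")) fit$delta_l else as.numeric(fit)
  100 * (1 - exp(-delta_l))
}

#' Weighted chi-square goodness of fit
#'
#' \code{S_min = sum(residual_i^2 / sigma_i^2)} over the binned time
#' points, compared with a chi-square distribution whose degrees of
#' freedom equal the number of binned points (set \code{subtract_params}
#' to subtract fitted-parameter counts instead).
#'
#' @param observed,fitted per-bin values (e.g. mean log survival).
#' @param sigma per-bin standard deviation (e.g. across movies).
#' @param subtract_params integer subtracted from the dof (default 0).
#' @return list with \code{s_min}, \code{dof}, \code{p_value} and the
#'   indices of bins excluded for zero sigma.
#' @export
chi_square_fit <- function(observed, fitted, sigma, subtract_params = 0L) {
  stopifnot(length(observed) == length(fitted),
            length(sigma) == length(observed))
  bad <- !(sigma > 0)
  if (any(bad)) warning(sum(bad), " bin(s) with zero sigma excluded")
  obs <- observed[!bad]; fit <- fitted[!bad]; sg <- sigma[!bad]
  s_min <- sum(((obs - fit) / sg)^2)
  dof <- length(obs) - subtract_params
  if (dof < 1L) stop("fewer than one degree of freedom")
  list(s_min = s_min, dof = dof,
       p_value = stats::pchisq(s_min, dof, lower.tail = FALSE),
       excluded = which(bad))
}

#' Residuals of an exponential fit, aggregated in time bins
#'
#' Difference (fit minus observed) between a baseline exponential survival
#' and the observed curve, averaged within requested time intervals. Under
#' a transiently enhanced reversal rate the deficit saturates by t of
#' order tau, so the positive residual concentrates in the earliest bins.
#'
#' @param survival a \code{survival_curve}.
#' @param exponential_fit an \code{ri_fit} with \code{model = "poisson"}
#'   (or any \code{ri_fit}; its r0/delta_l define the reference curve --
#'   for the usual profile pass the exponential null).
#' @param bin_edges increasing vector of time bin edges (s).
#' @return data frame with \code{bin_start}, \code{bin_end},
#'   \code{residual} (mean over bins; NA where a bin holds no points).
#' @export
residual_profile <- function(survival, exponential_fit, bin_edges) {
  stopifnot(inherits(survival, "survival_curve"),
            inherits(exponential_fit, "ri_fit"),
            length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  n <- seq_along(survival$hazard)
  t_s <- n * survival$dt
  obs <- survival$p_f[-1L]
  ref <- model_survival(t_s, exponential_fit$r0,
                        if (exponential_fit$model == "poisson") 0
                        else exponential_fit$delta_l,
                        exponential_fit$tau)
  idx <- cut(t_s, bin_edges, right = FALSE)
  res <- tapply(ref - obs, idx, mean)
  data.frame(bin_start = bin_edges[-length(bin_edges)],
             bin_end = bin_edges[-1L],
             residual = as.numeric(res))
}

#' Normalized fraction of multiply reversing animals
#'
#' Optogenetic stimulation assays score, for retinal-fed (+) and control
#' (-) groups, the total fraction of responding animals and the fraction
#' responding with multiple reversals. The light-specific repetitive
#' fraction is \code{(R_multiple+ - R_multiple-) / (R_total+ - R_total-)}.
#'
#' @param counts named list or vector with \code{r_multiple_plus},
#'   \code{r_multiple_minus}, \code{r_total_plus}, \code{r_total_minus}
#'   (fractions in [0, 1], multiple <= total within each group).
#' @return normalized fraction.
#' @export
normalized_r_multiple <- function(counts) {
  counts <- as.list(counts)
  need <- c("r_multiple_plus", "r_multiple_minus",
            "r_total_plus", "r_total_minus")
  if (!all(need %in% names(counts)))
    stop("counts must name ", paste(need, collapse = ", "))
  v <- vapply(counts[need], as.numeric, numeric(1))
  if (any(v < 0 | v > 1)) stop("fractions must lie in [0, 1]")
  if (v[["r_multiple_plus"]] > v[["r_total_plus"]] ||
      v[["r_multiple_minus"]] > v[["r_total_minus"]])
    stop("R_multiple cannot exceed R_total within a group")
  denom <- v[["r_total_plus"]] - v[["r_total_minus"]]
  if (denom <= 0)
    stop("no light-specific response: R_total+ must exceed R_total-")
  (v[["r_multiple_plus"]] - v[["r_multiple_minus"]]) / denom
}
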