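test_that("noiseless model curves are recovered to machine precision", {
  t <- seq(0.5, 200, 0.5)
  for (pars in list(c(0.01, log(2)), c(0.03, 0), c(0.02, -0.3),
                    c(0.005, 1.8))) {
    pf <- model_survival(t, pars[1L], pars[2L], tau = 20)
    fit <- suppressWarnings(
      fit_reversal_model(data.frame(t_s = t, p_f = pf), tau = 20))
    expect_equal(fit$r0, pars[1L], tolerance = 1e-9)
    expect_equal(fit$delta_l, pars[2L], tolerance = 1e-8)
    expect_equal(fit$ri, pars[2L] / log(2), tolerance = 1e-7)
    expect_equal(fit$anti_repetitive, pars[2L] < 0)
  }
})

test_that("a pure exponential gives RI = 0 and matches the Poisson fit", {
  t <- seq(0.5, 120, 0.5)
  pf <- model_survival(t, 0.02, 0, 20)
  rep_fit <- suppressWarnings(
    fit_reversal_model(data.frame(t_s = t, p_f = pf)))
  poi_fit <- suppressWarnings(
    fit_reversal_model(data.frame(t_s = t, p_f = pf), model = "poisson"))
  expect_equal(rep_fit$ri, 0, tolerance = 1e-8)
  expect_equal(rep_fit$r0, poi_fit$r0, tolerance = 1e-9)
})

test_that("nested models: Poisson weighted SSQ is never below the repetitive fit", {
  set.seed(13)
  t <- seq(0.5, 100, 0.5)
  for (rep in 1:10) {
    pf <- exp(log(model_survival(t, 0.02, 0.5, 20)) + rnorm(length(t),
                                                            0, 0.05))
    a <- fit_reversal_model(data.frame(t_s = t, p_f = pf))
    b <- fit_reversal_model(data.frame(t_s = t, p_f = pf),
                            model = "poisson")
    expect_gte(b$s_min, a$s_min - 1e-10)
  }
})

test_that("RI is invariant to consistent time-unit changes", {
  t <- seq(0.5, 150, 0.5)
  pf <- model_survival(t, 0.015, 0.9, 20)
  fit_s <- suppressWarnings(
    fit_reversal_model(data.frame(t_s = t, p_f = pf), tau = 20))
  fit_min <- suppressWarnings(
    fit_reversal_model(data.frame(t_s = t / 60, p_f = pf),
                       tau = 20 / 60))
  expect_equal(fit_s$ri, fit_min$ri, tolerance = 1e-8)
  expect_equal(fit_s$r0, fit_min$r0 / 60, tolerance = 1e-10)
})

test_that("non-identifiable designs are rejected with a clear message", {
  t <- seq(0.1, 0.5, 0.1)  # all times tiny relative to tau = 20
  pf <- exp(-0.02 * t)
  expect_error(fit_reversal_model(data.frame(t_s = t, p_f = pf),
                                  tau = 2000),
               "non-identifiable")
})

test_that("asymptotic suppression maps RI to the stated percent deficits", {
  expect_identical(long_time_suppression(ri_to_delta_l(1)), 50)
  expect_identical(long_time_suppression(ri_to_delta_l(0)), 0)
  expect_equal(long_time_suppression(ri_to_delta_l(2)), 75)
  f <- suppressWarnings(fit_reversal_model(
    data.frame(t_s = seq(0.5, 100, 0.5),
               p_f = model_survival(seq(0.5, 100, 0.5), 0.02, log(2),
                                    20))))
  expect_equal(long_time_suppression(f), 50, tolerance = 1e-6)
})

test_that("chi-square machinery matches hand arithmetic", {
  z <- chi_square_fit(rep(1, 10), rep(1, 10), rep(0.2, 10))
  expect_equal(z$s_min, 0)
  expect_equal(z$p_value, 1)
  expect_equal(z$dof, 10L)
  # residuals of 2 sigma at each of 10 bins: S = 10 * 4 = 40
  z2 <- chi_square_fit(rep(3, 10), rep(1, 10), rep(1, 10))
  expect_equal(z2$s_min, 40)
  # zero-sigma bins are excluded with a warning
  expect_warning(z3 <- chi_square_fit(1:5, 1:5, c(1, 1, 0, 1, 1)),
                 "zero sigma")
  expect_equal(z3$dof, 4L)
  expect_equal(z3$excluded, 3L)
})

test_that("residual profile is zero for a perfect fit and permutation-stable", {
  segs <- lapply(rep(c(4, 8, 12), 20), function(d) make_seg(d, "forward"))
  sv <- forward_survival(segs, dt = 0.5)
  fit <- fit_reversal_model(sv, model = "poisson", min_at_risk = 1L)
  prof <- residual_profile(sv, fit, bin_edges = c(0, 2, 4, 6))
  expect_equal(nrow(prof), 3L)
  # observed == reference curve gives identically zero residuals
  sv0 <- sv
  sv0$p_f <- c(1, model_survival(seq_along(sv$hazard) * 0.5, fit$r0, 0,
                                 fit$tau))
  prof0 <- residual_profile(sv0, fit, bin_edges = c(0, 2, 4, 6))
  expect_equal(prof0$residual, rep(0, 3), tolerance = 1e-12)
})

test_that("repetitive cohorts concentrate positive residual at early times", {
  cfg <- track_sim_config(delta_r = log(2) / 20, n_worms = 15,
                          duration = 1800, seed = 31)
  sim <- simulate_track(cfg)
  segs <- lapply(sim$truth$states, seg_from_truth)
  sv <- forward_survival(segs, dt = 0.5)
  expo <- fit_reversal_model(sv, model = "poisson")
  prof <- residual_profile(sv, expo, bin_edges = c(0, 30, 60, 90))
  # the survival deficit saturates by t ~ tau = 20 s: the first bin
  # carries the largest fit-minus-observed residual
  expect_gt(prof$residual[1L], 0)
  expect_equal(which.max(prof$residual), 1L)
})

test_that("fitted RI on Poisson cohorts is centered on zero", {
  set.seed(14)
  ri <- replicate(200, {
    dur <- 1L + rgeom(120, 1 - exp(-0.02 * 0.5))
    segs <- lapply(dur, function(d) make_seg(d, "forward"))
    fit_reversal_model(forward_survival(segs, 0.5),
                       boundary_offset = FALSE)$ri
  })
  expect_lt(abs(mean(ri)), 2 * sd(ri) / sqrt(length(ri)))
})

test_that("normalized multiple-reversal fraction follows the subtraction rule", {
  expect_equal(normalized_r_multiple(list(
    r_multiple_plus = 0.6, r_multiple_minus = 0,
    r_total_plus = 0.6, r_total_minus = 0)), 1)
  expect_equal(normalized_r_multiple(list(
    r_multiple_plus = 0.6, r_multiple_minus = 0.1,
    r_total_plus = 0.9, r_total_minus = 0.2)), 0.5 / 0.7)
  expect_equal(normalized_r_multiple(list(
    r_multiple_plus = 0.3, r_multiple_minus = 0.3,
    r_total_plus = 0.8, r_total_minus = 0.4)), 0)
  expect_error(normalized_r_multiple(list(
    r_multiple_plus = 0.3, r_multiple_minus = 0.1,
    r_total_plus = 0.5, r_total_minus = 0.5)), "light-specific")
  expect_error(normalized_r_multiple(list(
    r_multiple_plus = 0.9, r_multiple_minus = 0.1,
    r_total_plus = 0.5, r_total_minus = 0.1)), "exceed")
})
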