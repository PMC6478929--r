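test_that("all four generators are bit-identical under a fixed seed", {
  a <- simulate_track(track_sim_config(n_worms = 2, duration = 120,
                                       seed = 41))
  b <- simulate_track(track_sim_config(n_worms = 2, duration = 120,
                                       seed = 41))
  expect_identical(a, b)
  a <- simulate_trace_pair(trace_sim_config(seed = 42))
  b <- simulate_trace_pair(trace_sim_config(seed = 42))
  expect_identical(a, b)
  a <- simulate_motion_calcium(0.5, seed = 43)
  b <- simulate_motion_calcium(0.5, seed = 43)
  expect_identical(a, b)
  a <- simulate_expression(expr_sim_config(n_worm_genes = 200L,
                                           n_mouse_genes = 400L,
                                           seed = 44))
  b <- simulate_expression(expr_sim_config(n_worm_genes = 200L,
                                           n_mouse_genes = 400L,
                                           seed = 44))
  expect_identical(a, b)
})

test_that("track simulation conserves the frame count", {
  for (p in list(c(120, 2), c(90, 4), c(305, 2))) {
    cfg <- track_sim_config(n_worms = 1, duration = p[1L],
                            frame_rate = p[2L], seed = 45)
    sim <- simulate_track(cfg)
    expect_equal(sum(vapply(sim$tracks, nrow, integer(1))),
                 round(p[1L] * p[2L]))
  }
  # with simulated tracking losses the fragments still cover <= all frames
  cfg <- track_sim_config(n_worms = 3, duration = 600, lost_rate = 0.01,
                          seed = 46)
  sim <- simulate_track(cfg)
  expect_lte(sum(vapply(sim$tracks, nrow, integer(1))), 3 * 1200)
  expect_gt(length(sim$tracks), 3L)
  expect_true(any(vapply(sim$tracks, attr, logical(1), "censored_start")))
})

test_that("config validation rejects non-finite and out-of-range values", {
  expect_error(track_sim_config(r0 = NaN), "finite")
  expect_error(track_sim_config(r0 = -0.1))
  expect_error(track_sim_config(elong_mean_turn = 1.2))
  expect_error(trace_sim_config(onset_time = 600))
  expect_error(expr_sim_config(association_strength = 1.5))
})

test_that("crawling relative elongation is centered on one", {
  cfg <- track_sim_config(n_worms = 3, duration = 900, seed = 47)
  sim <- simulate_track(cfg)
  rel <- unlist(lapply(names(sim$tracks), function(id) {
    tr <- sim$tracks[[id]]
    crawl <- sim$truth$states[[id]]$state %in% c("forward_crawl",
                                                 "backward_crawl")
    tr$elongation_mm[crawl] / cfg$elong_scale
  }))
  se <- sd(rel) / sqrt(length(rel))
  expect_lt(abs(mean(rel) - 1), 3 * se)
})

test_that("forward-bout durations follow the planted survival law (DKW)", {
  # closed-form discrete survival implied by the per-step reversal
  # probability 1 - exp(-r(i dt) dt)
  for (ri in c(0, 1)) {
    cfg <- track_sim_config(delta_r = ri * log(2) / 20, n_worms = 10,
                            duration = 1800, seed = 48 + ri)
    sim <- simulate_track(cfg)
    dur <- unlist(lapply(sim$truth$states, function(df) {
      runs <- rle(df$period)
      k <- runs$values == "forward"
      k[length(k)] <- FALSE  # last bout censored by assay end
      runs$lengths[k]
    }))
    dt <- 0.5
    imax <- max(dur)
    haz <- 1 - exp(-(cfg$r0 + cfg$delta_r *
                       exp(-(0:(imax - 1)) * dt / cfg$tau)) * dt)
    s_true <- cumprod(1 - haz)           # P(duration > n frames)
    emp <- vapply(seq_len(imax), function(n) mean(dur > n), numeric(1))
    eps <- sqrt(log(2 / 0.01) / (2 * length(dur)))
    expect_lt(max(abs(emp - s_true)), eps)
  }
})

test_that("Poisson cohorts pass the exponential chi-square check", {
  # delta_r = 0 forces a pure Poisson process: the Eq.-style weighted
  # chi-square against an exponential fit should be non-significant at
  # alpha = 0.01 in (almost) every replicate
  n_sig <- 0L
  for (seed in 1:10) {
    curves <- lapply(1:5, function(m) {
      cfg <- track_sim_config(delta_r = 0, n_worms = 6, duration = 1800,
                              seed = 1000 * seed + m)
      sim <- simulate_track(cfg)
      sv <- forward_survival(lapply(sim$truth$states, seg_from_truth),
                             dt = 0.5)
      vapply(seq_len(100), function(n)
        if (n <= length(sv$hazard)) sv$p_f[n + 1L] else NA_real_,
        numeric(1))
    })
    M <- log(do.call(cbind, curves))
    keep <- rowSums(is.finite(M)) == 5L
    M <- M[keep, , drop = FALSE]
    t_s <- which(keep) * 0.5
    mu <- rowMeans(M)
    sg <- apply(M, 1L, sd)
    fit <- lm(mu ~ 0 + t_s, weights = 1 / sg^2)
    z <- chi_square_fit(mu, fitted(fit), sg)
    if (z$p_value < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("single-event noiseless traces peak within a rise time of the event", {
  cfg <- trace_sim_config(onset_time = 200, transient_interval = 1e5,
                          interval_jitter_sd = 0, noise_sd = 0,
                          cue_removals = list(), seed = 50)
  sim <- simulate_trace_pair(cfg)
  t_pk_glu <- sim$glutamate$time_s[which.max(sim$glutamate$f)]
  t_pk_ca <- sim$calcium$time_s[which.max(sim$calcium$f)]
  expect_lt(abs(t_pk_glu - 200), 5 * cfg$glu_rise)
  expect_lt(abs(t_pk_ca - (200 + cfg$glu_lead)), 5 * cfg$ca_rise)
  # flat baseline before onset
  expect_equal(sd(sim$calcium$f[sim$calcium$time_s < 195]), 0)
})

test_that("periodic transient trains peak at the planted frequency (Fourier oracle)", {
  cfg <- trace_sim_config(transient_interval = 25, interval_jitter_sd = 0,
                          noise_sd = 0.005, onset_time = 20,
                          cue_removals = list(), seed = 51)
  sim <- simulate_trace_pair(cfg)
  x <- sim$calcium$f - mean(sim$calcium$f)
  n <- length(x)
  spec <- Mod(fft(x))[2:floor(n / 2)]
  fgrid <- (1:(floor(n / 2) - 1)) / n
  band <- fgrid > 0.01 & fgrid < 0.2
  f_peak <- fgrid[band][which.max(spec[band])]
  expect_lt(abs(f_peak - 1 / 25), 0.005)
})

test_that("motion-calcium generator plants the requested association", {
  # phi_target = 1: every episode agrees
  mc <- simulate_motion_calcium(1, seed = 52, n_episodes = 50L)
  expect_true(all((mc$truth$episodes$state == "high") ==
                    (mc$truth$episodes$motion_sign < 0)))
  # phi_target = 0: planted table is near-independent
  mc0 <- simulate_motion_calcium(0, seed = 53, n_episodes = 50L)
  agree <- mean((mc0$truth$episodes$state == "high") ==
                  (mc0$truth$episodes$motion_sign < 0))
  expect_lt(abs(agree - 0.5), 0.25)
})

test_that("expression generator plants the target association and warns on density", {
  sim <- simulate_expression(expr_sim_config(seed = 54))
  tgt <- sim$truth$target_cell_type
  # direct count oracle: overlap of worm-enriched orthologs with each
  # cell type's enriched genes is maximal for the planted target
  orth <- split(sim$map$mouse_gene, sim$map$worm_gene)
  worm_orth <- unique(unlist(orth[intersect(sim$truth$worm_enriched,
                                            names(orth))]))
  overlap <- vapply(sim$truth$mouse_enriched, function(s)
    length(intersect(worm_orth, s)), numeric(1))
  expect_equal(names(which.max(overlap)), tgt)
  expect_warning(simulate_expression(
    expr_sim_config(n_worm_genes = 50L, n_mouse_genes = 40L,
                    ortholog_density = 30, seed = 55)), "density")
})
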