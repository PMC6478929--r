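#' Pipeline configuration
#'
#' Assembles the parameter blocks for an end-to-end run. Unknown keys in
#' any block are rejected up front. Every stochastic stage receives an
#' explicit seed derived deterministically from the global seed, so a
#' config reproduces its outputs bit for bit.
#'
#' @param seed global integer seed.
#' @param tracks named list of overrides for [track_sim_config()], or
#'   \code{NULL} to skip the locomotion stage.
#' @param traces named list of overrides for [trace_sim_config()], or
#'   \code{NULL} to skip the neural stage.
#' @param expression named list of overrides for [expr_sim_config()], or
#'   \code{NULL} to skip the enrichment stage.
#' @param tau fixed decay time for the reversal-model fit (s).
#' @param max_iter,tol Baum-Welch controls.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, tracks = list(), traces = list(),
                            expression = list(), tau = 20,
                            max_iter = 100L, tol = 1e-6) {
  check_keys <- function(ov, maker, block) {
    if (is.null(ov)) return(NULL)
    known <- names(formals(maker))
    bad <- setdiff(names(ov), known)
    if (length(bad))
      stop("unknown key(s) in '", block, "' block: ",
           paste(bad, collapse = ", "), call. = FALSE)
    ov
  }
  check_keys(tracks, track_sim_config, "tracks")
  check_keys(traces, trace_sim_config, "traces")
  check_keys(expression, expr_sim_config, "expression")
  structure(list(seed = as.integer(seed), tracks = tracks,
                 traces = traces, expression = expression, tau = tau,
                 max_iter = max_iter, tol = tol),
            class = "pipeline_config")
}

derive_seed <- function(seed, k) (seed * 7919L + k * 104729L) %% 2147483647L

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, for each requested stage: simulate tracks -> Baum-Welch
#' segmentation -> forward-bout survival -> repetitive-index fit;
#' simulate traces -> onset detection -> wavelet spectrum; simulate
#' expression -> enrichment/association grid. Writes interchange files
#' under \code{out_dir} when given, plus a run manifest (config
#' snapshot, per-stage seeds, input checksums, package version).
#' Identical config and seed reproduce identical outputs.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir optional output directory.
#' @return list with per-stage results and the \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(tracks = derive_seed(config$seed, 1L),
                traces = derive_seed(config$seed, 2L),
                expression = derive_seed(config$seed, 3L))
  results <- list()
  if (!is.null(config$tracks)) {
    tcfg <- do.call(track_sim_config,
                    utils::modifyList(list(seed = seeds$tracks),
                                      config$tracks))
    sim <- simulate_track(tcfg)
    obs <- lapply(sim$tracks, preprocess_track)
    bw <- baum_welch(obs, tol = config$tol, max_iter = config$max_iter)
    segs <- Map(function(p, o) segment_bouts(p, o$censored_start,
                                             o$censored_end),
                bw$posteriors, obs)
    surv <- forward_survival(segs, dt = 1 / tcfg$frame_rate)
    fit <- fit_reversal_model(surv, tau = config$tau)
    results$locomotion <- list(sim = sim, model = bw$model,
                               segmentations = segs, survival = surv,
                               fit = fit,
                               reversal_rate = reversal_rate(
                                 segs, dt = 1 / tcfg$frame_rate))
  }
  if (!is.null(config$traces)) {
    ncfg <- do.call(trace_sim_config,
                    utils::modifyList(list(seed = seeds$traces),
                                      config$traces))
    sim <- simulate_trace_pair(ncfg)
    cond <- condition_trace(sim$calcium)
    onset <- detect_onset(cond)
    spec <- wavelet_transform(cond)
    animal <- time_averaged_spectrum(
      spec, onset, end = ncfg$record_duration,
      record_duration = ncfg$record_duration)
    results$neural <- list(sim = sim, conditioned = cond, onset = onset,
                           responsive = classify_cue_response(cond),
                           spectrum = animal)
  }
  if (!is.null(config$expression)) {
    ecfg <- do.call(expr_sim_config,
                    utils::modifyList(list(seed = seeds$expression),
                                      config$expression))
    sim <- simulate_expression(ecfg)
    grid <- enrichment_grid(sim$worm, sim$mouse, sim$map)
    results$enrichment <- list(sim = sim, grid = grid,
                               association = association_score(grid))
  }
  manifest <- list(package_version =
                     as.character(utils::packageVersion("nemadyn")),
                   seed = config$seed, stage_seeds = seeds,
                   config = unclass(config),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(results$locomotion)) {
      write_tracks_csv(results$locomotion$sim$tracks,
                       file.path(out_dir, "tracks.csv"))
      write_survival_csv(results$locomotion$survival,
                         file.path(out_dir, "survival.csv"))
      write_fit_json(results$locomotion$fit,
                     file.path(out_dir, "ri_fit.json"))
      write_model_json(results$locomotion$model,
                       file.path(out_dir, "hmm_model.json"))
    }
    if (!is.null(results$enrichment)) {
      utils::write.table(results$enrichment$grid,
                         file.path(out_dir, "enrichment_grid.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest$checksums <- as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  c(results, list(manifest = manifest))
}
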