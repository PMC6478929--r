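#' Read and write interchange tables
#'
#' All file I/O in the package goes through these readers/writers.
#' Tracks and traces are CSV with unit-suffixed headers; expression
#' tables and ortholog maps are TSV; fitted models and statistics are
#' JSON. Readers validate the header against the expected schema (a
#' missing column raises an error naming it) and, for time series, the
#' uniformity of the time step (a skipped frame raises an error citing
#' the gap index).
#'
#' @name table_io
NULL

check_columns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

check_uniform_time <- function(time_s, path, id) {
  d <- diff(time_s)
  if (length(d) && (max(d) - min(d)) > 1e-6 * mean(d)) {
    gap <- which.max(abs(d - stats::median(d)))
    stop("non-uniform time step in '", path, "' (", id,
         "): gap at index ", gap, call. = FALSE)
  }
  invisible(time_s)
}

track_schema <- c("track_id", "frame", "time_s", "x_mm", "y_mm",
                  "axis_x", "axis_y", "elongation_mm")

#' @rdname table_io
#' @param tracks list of \code{worm_track}.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "worm_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id,
               frame = seq_len(nrow(tr)) - 1L,
               time_s = tr$time_s, x_mm = tr$x_mm, y_mm = tr$y_mm,
               axis_x = tr$axis_x, axis_y = tr$axis_y,
               elongation_mm = tr$elongation_mm,
               censored_start = attr(tr, "censored_start"),
               censored_end = attr(tr, "censored_end"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @return \code{read_tracks_csv}: named list of \code{worm_track}.
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, track_schema, path)
  out <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    check_uniform_time(d$time_s, path, d$track_id[1L])
    worm_track(d$track_id[1L], d$time_s, d$x_mm, d$y_mm, d$axis_x,
               d$axis_y, d$elongation_mm,
               censored_start = if ("censored_start" %in% names(d))
                 d$censored_start[1L] else TRUE,
               censored_end = if ("censored_end" %in% names(d))
                 d$censored_end[1L] else TRUE)
  })
  out[order(names(out))]
}

trace_schema <- c("animal_id", "genotype", "channel", "time_s", "f",
                  "cue_flag")

#' @rdname table_io
#' @param traces list of \code{fluorescence_trace}.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    cue <- rep(0L, length(tr$time_s))
    for (tc in tr$cue_removal_times)
      cue[which.min(abs(tr$time_s - tc))] <- 1L
    data.frame(animal_id = tr$animal_id, genotype = tr$genotype,
               channel = tr$channel, time_s = tr$time_s, f = tr$f,
               cue_flag = cue)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @return \code{read_traces_csv}: list of \code{fluorescence_trace},
#'   one per (animal, channel).
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, trace_schema, path)
  key <- paste(df$animal_id, df$channel, sep = ".")
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), ]
    check_uniform_time(d$time_s, path, key[1L])
    fluorescence_trace(d$time_s, d$f, d$channel[1L], d$animal_id[1L],
                       d$genotype[1L],
                       cue_removal_times = d$time_s[d$cue_flag > 0])
  })
}

#' @rdname table_io
#' @param table an \code{expression_table}.
#' @export
write_expression_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param species species tag for the table read.
#' @export
read_expression_tsv <- function(path, species = "worm") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, "gene_id", path)
  expression_table(df$gene_id, df[setdiff(names(df), "gene_id")],
                   species = species)
}

#' @rdname table_io
#' @param map an \code{ortholog_map}.
#' @export
write_ortholog_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_ortholog_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("worm_gene", "mouse_gene"), path)
  ortholog_map(df$worm_gene, df$mouse_gene)
}

#' @rdname table_io
#' @param survival a \code{survival_curve}.
#' @export
write_survival_csv <- function(survival, path) {
  n <- seq_along(survival$hazard)
  utils::write.csv(data.frame(t_s = n * survival$dt,
                              p_f = survival$p_f[-1L],
                              hazard = survival$hazard,
                              n_at_risk = survival$n_at_risk,
                              n_events = survival$n_events),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  check_columns(df, c("t_s", "p_f"), path)
  df
}

#' @rdname table_io
#' @param fit an \code{ri_fit} (or any list of scalars/vectors).
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname table_io
#' @param model an \code{hmm_model}.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(states = model$states,
                            transition = model$transition,
                            initial = model$initial,
                            sigma_r = model$sigma_r,
                            c_vel = model$c_vel),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname table_io
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_model(transition = as.matrix(j$transition),
            initial = j$initial, sigma_r = j$sigma_r, c_vel = j$c_vel)
}
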