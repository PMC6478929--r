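#' Configuration for the expression-table simulator
#'
#' @param n_worm_genes,n_mouse_genes gene counts.
#' @param n_cell_types mouse cell types.
#' @param ortholog_density expected mouse orthologs per worm gene.
#' @param enriched_fraction fraction of genes enriched (worm set; per
#'   mouse gene, probability of being enriched in one cell type).
#' @param association_strength probability that an ortholog of a
#'   worm-enriched gene is (re)assigned enriched in the planted target
#'   cell type. Setting it to the per-cell-type background rate
#'   \code{enriched_fraction / n_cell_types} plants no signal.
#' @param fe_scale log2 fold-enrichment magnitude of enriched genes.
#' @param seed integer seed.
#' @return validated list of class \code{expr_sim_config}.
#' @export
expr_sim_config <- function(n_worm_genes = 2000L, n_mouse_genes = 4000L,
                            n_cell_types = 5L, ortholog_density = 1.5,
                            enriched_fraction = 0.1,
                            association_strength = 0.6, fe_scale = 3,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_worm_genes > 0, n_mouse_genes > 0, n_cell_types >= 2,
            ortholog_density > 0, enriched_fraction >= 0,
            enriched_fraction <= 1, association_strength >= 0,
            association_strength <= 1, fe_scale > 0)
  structure(cfg, class = "expr_sim_config")
}

#' Simulate ortholog-linked expression tables with planted association
#'
#' Builds a worm table (single glial FE column), a mouse table
#' (\code{n_cell_types} FE columns), and a many-to-many ortholog map.
#' Each mouse gene is enriched in at most one uniformly chosen cell type
#' with probability \code{enriched_fraction}; the planted signal then
#' reassigns, with probability \code{association_strength}, one ortholog
#' of each worm-enriched gene to be enriched in the target cell type, so
#' that cell type shows elevated ortholog overlap with the worm-enriched
#' set while the others stay at background.
#'
#' @param config an \code{expr_sim_config}.
#' @return list with \code{worm}, \code{mouse}
#'   (\code{expression_table}s), \code{map} (\code{ortholog_map}) and
#'   \code{truth} (worm-enriched set, per-cell-type mouse enriched sets,
#'   target cell type).
#' @export
simulate_expression <- function(config = expr_sim_config()) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  wg <- sprintf("WBGene%05d", seq_len(config$n_worm_genes))
  mg <- sprintf("MGI%05d", seq_len(config$n_mouse_genes))
  cts <- paste0("ct", seq_len(config$n_cell_types))
  if (config$ortholog_density > config$n_mouse_genes / 4)
    warning("ortholog_density high relative to the mouse genome; ",
            "duplicate pairs collapsed")
  k <- pmin(stats::rpois(config$n_worm_genes, config$ortholog_density),
            config$n_mouse_genes)
  map <- ortholog_map(rep(wg, k), mg[unlist(lapply(k, function(ki)
    sample.int(config$n_mouse_genes, ki)))])
  # worm enriched set
  n_enr <- round(config$enriched_fraction * config$n_worm_genes)
  worm_enr <- sample(wg, n_enr)
  worm_fe <- stats::rnorm(config$n_worm_genes, 0, 0.4)
  worm_fe[wg %in% worm_enr] <- config$fe_scale +
    stats::rnorm(n_enr, 0, 0.25)
  # mouse enrichment assignment: background, then planted target
  assign_ct <- ifelse(stats::runif(config$n_mouse_genes) <
                        config$enriched_fraction,
                      sample(cts, config$n_mouse_genes, replace = TRUE),
                      NA_character_)
  target <- cts[1L]
  orth <- split(map$mouse_gene, map$worm_gene)
  for (g in intersect(worm_enr, names(orth))) {
    if (stats::runif(1) < config$association_strength) {
      pick <- sample(orth[[g]], 1L)
      assign_ct[match(pick, mg)] <- target
    }
  }
  mouse_fe <- matrix(stats::rnorm(config$n_mouse_genes *
                                    config$n_cell_types, 0, 0.4),
                     ncol = config$n_cell_types,
                     dimnames = list(NULL, cts))
  for (j in seq_along(cts)) {
    sel <- !is.na(assign_ct) & assign_ct == cts[j]
    mouse_fe[sel, j] <- config$fe_scale + stats::rnorm(sum(sel), 0, 0.25)
  }
  list(worm = expression_table(wg, data.frame(glia = worm_fe), "worm"),
       mouse = expression_table(mg, as.data.frame(mouse_fe), "mouse"),
       map = map,
       truth = list(worm_enriched = worm_enr,
                    mouse_enriched = split(mg[!is.na(assign_ct)],
                                           assign_ct[!is.na(assign_ct)]),
                    target_cell_type = target))
}
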