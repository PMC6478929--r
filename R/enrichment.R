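#' Construct an expression table
#'
#' Per-gene log2 fold-enrichment (FE) values over one or more cell types
#' for one species. FE is expression in a cell type relative to all other
#' cells.
#'
#' @param gene_id unique, stable gene identifiers.
#' @param fe data frame or matrix of log2 FE values, one column per cell
#'   type.
#' @param species species tag.
#' @return object of class \code{expression_table}.
#' @export
expression_table <- function(gene_id, fe, species = "worm") {
  fe <- as.data.frame(fe)
  stopifnot(length(gene_id) == nrow(fe))
  if (anyDuplicated(gene_id)) stop("gene ids must be unique within species")
  if (!all(vapply(fe, is.numeric, logical(1))))
    stop("FE columns must be numeric")
  if (!all(vapply(fe, function(x) all(is.finite(x)), logical(1))))
    stop("FE values must be finite")
  structure(cbind(data.frame(gene_id = as.character(gene_id),
                             stringsAsFactors = FALSE), fe),
            class = c("expression_table", "data.frame"), species = species)
}

fe_columns <- function(table) setdiff(names(table), "gene_id")

#' Construct an ortholog map
#'
#' Cross-species gene pairs; many-to-many relations are allowed.
#'
#' @param worm_gene,mouse_gene paired identifiers.
#' @return object of class \code{ortholog_map} (two-column data frame).
#' @export
ortholog_map <- function(worm_gene, mouse_gene) {
  stopifnot(length(worm_gene) == length(mouse_gene))
  out <- unique(data.frame(worm_gene = as.character(worm_gene),
                           mouse_gene = as.character(mouse_gene),
                           stringsAsFactors = FALSE))
  structure(out, class = c("ortholog_map", "data.frame"))
}

#' Rank-transform fold-enrichment values
#'
#' Converts each cell type's FE column to rank order: the highest FE gets
#' rank 1; ties share the average rank. Ranks are invariant to any
#' strictly monotone transform of FE.
#'
#' @param table an \code{expression_table}.
#' @return data frame with \code{gene_id} and one rank column per cell
#'   type.
#' @export
rank_transform <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  ranks <- lapply(table[fe_columns(table)], function(x)
    rank(-x, ties.method = "average"))
  cbind(data.frame(gene_id = table$gene_id, stringsAsFactors = FALSE),
        as.data.frame(ranks))
}

#' Uniquely enriched gene sets per cell type
#'
#' At a given log2 FE cutoff, a gene belongs to a cell type's set iff its
#' FE meets the cutoff in that cell type and in no other — genes enriched
#' in several cell types are excluded from all of them, enforcing
#' cell-type specificity.
#'
#' @param table an \code{expression_table} with >= 2 cell types.
#' @param cutoff log2 FE cutoff.
#' @return named list of gene-id character vectors, one per cell type.
#' @export
unique_enriched_sets <- function(table, cutoff) {
  stopifnot(inherits(table, "expression_table"))
  cols <- fe_columns(table)
  above <- vapply(table[cols], function(x) x >= cutoff,
                  logical(nrow(table)))
  if (is.null(dim(above))) above <- matrix(above, nrow = 1L)
  n_above <- rowSums(above)
  sets <- lapply(seq_along(cols), function(j)
    table$gene_id[above[, j] & n_above == 1L])
  names(sets) <- cols
  sets
}

#' Cross-species ortholog enrichment score
#'
#' Compares the frequency of worm-set genes having an ortholog on a mouse
#' cell-type-enriched list with the same frequency over the whole worm
#' gene universe, each normalized by the number of genes with any mouse
#' ortholog:
#' \deqn{score = \frac{\#\{worm set genes with an enriched mouse
#'   ortholog\} / \#\{worm set genes with a mouse ortholog\}}
#'   {\#\{universe genes with an enriched mouse ortholog\} /
#'   \#\{universe genes with a mouse ortholog\}}}
#' A worm gene counts as related to the mouse set if \emph{any} of its
#' orthologs is on the list. Genes without a mouse ortholog drop out of
#' both proportions.
#'
#' @param worm_set character vector of worm gene ids (the enriched set).
#' @param mouse_set character vector of mouse gene ids (the cell type's
#'   uniquely enriched list).
#' @param map an \code{ortholog_map}.
#' @param worm_universe all worm gene ids under consideration.
#' @return list with \code{score} (NA with \code{defined = FALSE} when no
#'   set gene has a mouse ortholog) and the four counts entering the two
#'   proportions.
#' @export
enrichment_score <- function(worm_set, mouse_set, map, worm_universe) {
  stopifnot(inherits(map, "ortholog_map"))
  hits <- split(map$mouse_gene, map$worm_gene)
  mapped <- names(hits)
  related <- names(hits)[vapply(hits, function(m)
    any(m %in% mouse_set), logical(1))]
  set_mapped <- sum(worm_set %in% mapped)
  set_related <- sum(worm_set %in% related)
  uni_mapped <- sum(worm_universe %in% mapped)
  uni_related <- sum(worm_universe %in% related)
  if (set_mapped == 0L || uni_mapped == 0L || uni_related == 0L) {
    return(list(score = NA_real_, defined = FALSE,
                set_related = set_related, set_mapped = set_mapped,
                universe_related = uni_related,
                universe_mapped = uni_mapped))
  }
  list(score = (set_related / set_mapped) / (uni_related / uni_mapped),
       defined = TRUE,
       set_related = set_related, set_mapped = set_mapped,
       universe_related = uni_related, universe_mapped = uni_mapped)
}

#' Enrichment scores over the fold-enrichment cutoff grid
#'
#' Evaluates the enrichment score for every combination of worm cutoff
#' (default log2 FE 1, 1.5, 2, 2.5), mouse cutoff (default 1-4 in steps of
#' 0.5) and mouse cell type. The worm enriched set at a cutoff is every
#' gene whose (single-column) FE meets it; mouse sets are the uniquely
#' enriched sets of [unique_enriched_sets()].
#'
#' @param worm_table single-cell-type \code{expression_table} (the glial
#'   FE column).
#' @param mouse_table multi-cell-type \code{expression_table}.
#' @param map an \code{ortholog_map}.
#' @param worm_cutoffs,mouse_cutoffs increasing log2 FE cutoff vectors.
#' @return data frame with columns \code{worm_cutoff}, \code{mouse_cutoff},
#'   \code{cell_type}, \code{score} and the underlying counts.
#' @export
enrichment_grid <- function(worm_table, mouse_table, map,
                            worm_cutoffs = c(1, 1.5, 2, 2.5),
                            mouse_cutoffs = c(1, 1.5, 2, 2.5, 3, 3.5, 4)) {
  stopifnot(inherits(worm_table, "expression_table"),
            inherits(mouse_table, "expression_table"),
            !is.unsorted(worm_cutoffs, strictly = TRUE),
            !is.unsorted(mouse_cutoffs, strictly = TRUE))
  wcol <- fe_columns(worm_table)
  if (length(wcol) != 1L)
    stop("worm table must carry exactly one FE column")
  universe <- worm_table$gene_id
  rows <- list()
  for (mc in mouse_cutoffs) {
    msets <- unique_enriched_sets(mouse_table, mc)
    for (wc in worm_cutoffs) {
      wset <- worm_table$gene_id[worm_table[[wcol]] >= wc]
      for (ct in names(msets)) {
        es <- enrichment_score(wset, msets[[ct]], map, universe)
        rows[[length(rows) + 1L]] <-
          data.frame(worm_cutoff = wc, mouse_cutoff = mc, cell_type = ct,
                     score = es$score, set_related = es$set_related,
                     set_mapped = es$set_mapped,
                     universe_related = es$universe_related,
                     universe_mapped = es$universe_mapped,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Association score per cell type
#'
#' Corrects the raw enrichment scores for ortholog-mapping bias with an
#' observed/expected contingency construction: at each cutoff pair the
#' expected score under no cell-type specificity is the mean score across
#' cell types, and the association is observed/expected (set
#' \code{invert = TRUE} for the reciprocal). Cell-type summaries are the
#' mean association over all cutoff pairs where the score is defined.
#'
#' @param grid output of [enrichment_grid()].
#' @param invert report expected/observed instead.
#' @return list with \code{per_pair} (the grid plus \code{expected} and
#'   \code{association} columns) and \code{per_cell_type} (named summary
#'   vector, higher = more associated under the default direction).
#' @export
association_score <- function(grid, invert = FALSE) {
  stopifnot(is.data.frame(grid),
            all(c("worm_cutoff", "mouse_cutoff", "cell_type", "score")
                %in% names(grid)))
  if (length(unique(grid$cell_type)) < 2L)
    stop("association requires at least two cell types")
  key <- interaction(grid$worm_cutoff, grid$mouse_cutoff, drop = TRUE)
  expected <- stats::ave(grid$score, key,
                         FUN = function(x) mean(x, na.rm = TRUE))
  assoc <- grid$score / expected
  if (invert) assoc <- 1 / assoc
  grid$expected <- expected
  grid$association <- assoc
  per_ct <- tapply(assoc, grid$cell_type,
                   function(x) mean(x, na.rm = TRUE))
  list(per_pair = grid,
       per_cell_type = setNames(as.numeric(per_ct), names(per_ct)))
}
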