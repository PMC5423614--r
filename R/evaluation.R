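# ---- classical differential-expression baseline -----------------------------

#' Select differentially expressed genes by fold-change and p-value cutoffs
#'
#' Classical threshold selection: a gene is kept when its absolute log2
#' fold change is at least `fc_cut` and `-log10(p)` is at least `p_cut`.
#' The result is intersected with the universe (genes belonging to at least
#' one pathway), mirroring the restriction applied before pathway analysis.
#'
#' @param stats Per-gene statistics data frame (`gene_id`, `log2fc`,
#'   `p_value`).
#' @param fc_cut Threshold on `abs(log2fc)`.
#' @param p_cut Threshold on `-log10(p_value)`.
#' @param universe Character vector of genes in at least one pathway.
#' @return Character vector of selected gene ids.
#' @export
select_de_genes <- function(stats, fc_cut, p_cut, universe) {
  neglogp <- -log10(pmax(stats$p_value, .Machine$double.xmin))
  sel <- abs(stats$log2fc) >= fc_cut & neglogp >= p_cut
  intersect(stats$gene_id[sel], universe)
}

#' Subgraph of the global graph induced by a gene list
#'
#' Returns the interactions connecting any pair of genes in the list.
#' Input genes with no internal interaction are retained as singleton
#' components (disconnected genes are still part of the reported network).
#'
#' @param graph A `global_graph`.
#' @param genes Character vector of gene ids.
#' @return A `mechanism` object whose `nodes` are all input genes present
#'   in the call (including singletons).
#' @export
induced_subgraph <- function(graph, genes) {
  genes <- unique(as.character(genes))
  ed <- graph$edges
  keep <- ed$gene_a %in% genes & ed$gene_b %in% genes
  selected <- ed[keep, , drop = FALSE]
  rownames(selected) <- NULL
  nodes <- sort(genes)
  if (length(nodes)) {
    g <- as_igraph(NULL, edges = selected, vertices = nodes)
    comp <- igraph::components(g)
    membership <- comp$membership[nodes]
    n_comp <- comp$no
  } else {
    membership <- stats::setNames(integer(0), character(0))
    n_comp <- 0L
  }
  structure(list(edges = selected, nodes = nodes, components = membership,
                 n_components = n_comp,
                 cutoff_score = NA_real_, safety_fraction = NA_real_),
            class = "mechanism")
}

# ---- over-representation analysis -------------------------------------------

#' Over-representation analysis of a gene list against pathways
#'
#' One-sided hypergeometric upper-tail test per pathway: the p-value is
#' `P(X >= overlap)` for the overlap between the gene list and the pathway,
#' drawing `length(gene_list)` genes from the universe. Pathway gene sets
#' are intersected with the universe before testing; pathways with no
#' universe gene are not tested. False discovery rates are
#' Benjamini-Hochberg across all tested pathways.
#'
#' @param gene_list Character vector of genes (intersected with the
#'   universe).
#' @param pathways A `pathway_collection`.
#' @param universe Character vector: all measured genes belonging to at
#'   least one pathway.
#' @param alpha Significance level on the FDR, default 0.1.
#' @return Data frame (`ora_result`) with columns `pathway_id`, `overlap`,
#'   `pathway_size`, `list_size`, `universe_size`, `p_value`, `fdr`,
#'   `significant`.
#' @export
ora <- function(gene_list, pathways, universe, alpha = 0.1) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_list <- intersect(unique(as.character(gene_list)), universe)
  k <- length(gene_list)
  N <- length(universe)
  sets <- lapply(unclass(pathways), intersect, y = universe)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets))
    return(data.frame(pathway_id = character(0), overlap = integer(0),
                      pathway_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  m <- lengths(sets)
  x <- vapply(sets, function(s) length(intersect(s, gene_list)), integer(1))
  # upper tail inclusive: P(X >= x)
  p <- stats::phyper(x - 1L, m, N - m, k, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pathway_id = names(sets), overlap = x,
                    pathway_size = m, list_size = k, universe_size = N,
                    p_value = p, fdr = fdr, significant = fdr < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$pathway_id), ]
}

# ---- knockout-based evaluation ----------------------------------------------

#' Evaluate pathway calls against knockout ground truth
#'
#' In a knockout experiment the pathways containing the KO gene are the
#' true positives; every other tested pathway is a negative. TPR is the
#' fraction of positive pathways called significant (FDR < `alpha`), FPR
#' the fraction of negative pathways called significant, and the positive
#' likelihood ratio is `tpr / fpr` (`Inf` when `fpr = 0` and `tpr > 0`; 0
#' when both are 0).
#'
#' @param ora_results Data frame with columns `pathway_id` and `fdr` (from
#'   [ora()] or an external method via [read_pathway_pvalues()]).
#' @param ko_gene The knocked-out gene id.
#' @param pathways A `pathway_collection` defining membership.
#' @param alpha FDR significance level, default 0.1.
#' @param gene_list_size Optional size of the gene list that produced the
#'   results (metadata).
#' @param threshold_descriptor Optional label of the thresholds used
#'   (metadata).
#' @return A one-row data frame (`eval_result`) with `tpr`, `fpr`,
#'   `positive_lr`, `n_positive_pathways`, `n_negative_pathways`,
#'   `gene_list_size`, `threshold_descriptor`.
#' @export
evaluate_ko <- function(ora_results, ko_gene, pathways, alpha = 0.1,
                        gene_list_size = NA_integer_,
                        threshold_descriptor = NA_character_) {
  contains_ko <- vapply(unclass(pathways), function(g) ko_gene %in% g,
                        logical(1))
  if (!any(contains_ko))
    stop("no ground-truth positives: KO gene '", ko_gene,
         "' is in no pathway", call. = FALSE)
  is_pos <- ora_results$pathway_id %in% names(pathways)[contains_ko]
  sig <- ora_results$fdr < alpha
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L)
    stop("no positive pathway was tested (KO-containing pathways absent ",
         "from results)", call. = FALSE)
  tpr <- sum(sig & is_pos) / n_pos
  fpr <- if (n_neg > 0L) sum(sig & !is_pos) / n_neg else 0
  lr <- if (fpr > 0) tpr / fpr else if (tpr > 0) Inf else 0
  data.frame(tpr = tpr, fpr = fpr, positive_lr = lr,
             n_positive_pathways = n_pos, n_negative_pathways = n_neg,
             gene_list_size = gene_list_size,
             threshold_descriptor = threshold_descriptor,
             stringsAsFactors = FALSE)
}

#' Read an externally computed pathway p-value table
#'
#' Adapter for evaluating other pathway-ranking methods with
#' [evaluate_ko()]: accepts a table with columns `pathway_id` and either
#' `fdr` or `p_value` (the latter is BH-adjusted here).
#'
#' @param path TSV/CSV path or data frame.
#' @return Data frame with `pathway_id` and `fdr`.
#' @export
read_pathway_pvalues <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"pathway_id" %in% names(tab))
    stop("pathway p-value table needs a 'pathway_id' column", call. = FALSE)
  if (!"fdr" %in% names(tab)) {
    if (!"p_value" %in% names(tab))
      stop("pathway p-value table needs an 'fdr' or 'p_value' column",
           call. = FALSE)
    tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  }
  tab[, intersect(c("pathway_id", "p_value", "fdr"), names(tab)),
      drop = FALSE]
}

# ---- threshold sweeps --------------------------------------------------------

#' Sweep the classical fold-change / p-value threshold grid
#'
#' Evaluates the classical approach over a grid of cutoffs: for each
#' `(fc_cut, p_cut)` pair the DE gene list is formed, tested by ORA and
#' scored against the KO ground truth. The default grid spans `log2|FC|`
#' from 0.5 to the maximum observed value in steps of 0.25 and `-log10(p)`
#' from 0.5 to 5 in steps of 0.5 (least to most stringent). Cells with no
#' DE genes are recorded with `tpr = fpr = 0`. The best cell maximizes the
#' positive likelihood ratio, ties broken by higher TPR, then by more
#' stringent cuts.
#'
#' @param stats Per-gene statistics data frame.
#' @param graph A `global_graph` (unused by selection itself, accepted for
#'   interface symmetry; the induced subgraph per cell is not materialised).
#' @param pathways A `pathway_collection`.
#' @param ko_gene Knocked-out gene id.
#' @param fc_grid,p_grid Numeric grids of cutoffs; defaults as above.
#' @param alpha FDR significance level, default 0.1.
#' @param universe Optional universe; default: measured genes in at least
#'   one pathway.
#' @return Data frame with one row per grid cell (`fc_cut`, `p_cut`,
#'   `n_genes`, `tpr`, `fpr`, `positive_lr`); the best row index is
#'   attached as attribute `"best"`.
#' @export
classical_sweep <- function(stats, graph, pathways, ko_gene,
                            fc_grid = NULL, p_grid = NULL, alpha = 0.1,
                            universe = NULL) {
  if (is.null(universe))
    universe <- intersect(stats$gene_id, pathway_universe(pathways))
  if (is.null(fc_grid)) {
    fc_max <- max(abs(stats$log2fc))
    fc_grid <- seq(0.5, max(0.5, fc_max), by = 0.25)
  }
  if (is.null(p_grid)) p_grid <- seq(0.5, 5, by = 0.5)
  if (!length(fc_grid) || !length(p_grid))
    stop("threshold grids must be non-empty", call. = FALSE)
  cells <- expand.grid(fc_cut = fc_grid, p_cut = p_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    fc <- cells$fc_cut[i]; pc <- cells$p_cut[i]
    genes <- select_de_genes(stats, fc, pc, universe)
    if (!length(genes)) {
      return(data.frame(fc_cut = fc, p_cut = pc, n_genes = 0L, tpr = 0,
                        fpr = 0, positive_lr = 0))
    }
    res <- ora(genes, pathways, universe, alpha = alpha)
    ev <- evaluate_ko(res, ko_gene, pathways, alpha = alpha,
                      gene_list_size = length(genes))
    data.frame(fc_cut = fc, p_cut = pc, n_genes = length(genes),
               tpr = ev$tpr, fpr = ev$fpr, positive_lr = ev$positive_lr)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$positive_lr, -out$tpr, -out$fc_cut, -out$p_cut)
  attr(out, "best") <- ord[1]
  out
}

#' Sweep edge-score cutoffs for the high-edge-score method
#'
#' Evaluates the method over a grid of edge-score cutoffs spanning the
#' change-point threshold to the maximum observed score. For each cutoff
#' the gene list is the set of endpoints of edges scoring at or above the
#' cutoff, tested by ORA and scored against the KO ground truth. The
#' default change-point + safety-margin selection is evaluated as well and
#' attached as attribute `"default"`.
#'
#' @param scored A `scored_edges` data frame from [score_graph()].
#' @param pathways A `pathway_collection`.
#' @param ko_gene Knocked-out gene id.
#' @param threshold_grid Numeric vector of score cutoffs; default
#'   `n_points` evenly spaced values from the change-point threshold to the
#'   maximum score.
#' @param changepoint Optional precomputed `changepoint_result`.
#' @param n_points Number of default grid points, default 20.
#' @param safety_fraction Safety margin for the default selection, 0.75.
#' @param alpha FDR significance level, default 0.1.
#' @param universe Optional universe; default: measured genes (endpoints
#'   and stats genes) in at least one pathway.
#' @param measured_genes Optional character vector of all measured genes
#'   used to build the universe (defaults to the scored-edge endpoints).
#' @return Data frame with one row per cutoff (`cutoff`, `n_genes`, `tpr`,
#'   `fpr`, `positive_lr`), plus attribute `"default"` holding the
#'   evaluation of the change-point + safety-margin selection.
#' @export
highedges_sweep <- function(scored, pathways, ko_gene,
                            threshold_grid = NULL, changepoint = NULL,
                            n_points = 20L, safety_fraction = 0.75,
                            alpha = 0.1, universe = NULL,
                            measured_genes = NULL) {
  if (is.null(measured_genes))
    measured_genes <- unique(c(scored$gene_a, scored$gene_b))
  if (is.null(universe))
    universe <- intersect(measured_genes, pathway_universe(pathways))
  if (is.null(changepoint)) changepoint <- detect_changepoint(scored$score)
  if (is.null(threshold_grid))
    threshold_grid <- seq(changepoint$threshold_score, max(scored$score),
                          length.out = n_points)
  eval_cutoff <- function(genes, label) {
    genes <- intersect(genes, universe)
    if (!length(genes))
      return(data.frame(n_genes = 0L, tpr = 0, fpr = 0, positive_lr = 0))
    res <- ora(genes, pathways, universe, alpha = alpha)
    ev <- evaluate_ko(res, ko_gene, pathways, alpha = alpha,
                      gene_list_size = length(genes),
                      threshold_descriptor = label)
    data.frame(n_genes = length(genes), tpr = ev$tpr, fpr = ev$fpr,
               positive_lr = ev$positive_lr)
  }
  rows <- lapply(threshold_grid, function(cut) {
    keep <- scored$score >= cut
    genes <- unique(c(scored$gene_a[keep], scored$gene_b[keep]))
    cbind(cutoff = cut, eval_cutoff(genes, sprintf("score>=%.4g", cut)))
  })
  out <- do.call(rbind, rows)
  sel <- apply_safety_margin(scored, changepoint,
                             safety_fraction = safety_fraction)
  def <- cbind(cutoff = if (nrow(sel)) min(sel$score) else NA_real_,
               eval_cutoff(unique(c(sel$gene_a, sel$gene_b)),
                           "changepoint+margin"))
  attr(out, "default") <- def
  attr(out, "changepoint") <- changepoint
  out
}

#' Write a sweep result table as CSV
#' @param sweep Data frame from [classical_sweep()] or [highedges_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
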