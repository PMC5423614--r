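# ---- edge scores ------------------------------------------------------------

#' Score one interaction edge from its endpoint statistics
#'
#' The score of the edge between genes A and B is
#' `FC'_A * (1 - p_A) + FC'_B * (1 - p_B)`, where `FC'` is the absolute
#' log2 fold change under the default `"absolute_log2"` transform (so an
#' up- and a down-regulated endpoint reinforce rather than cancel), or the
#' signed log2 fold change under `"signed_log2"` (kept for sensitivity
#' analysis). Vectorized over all four statistic arguments.
#'
#' @param fc_a,fc_b Log2 fold changes of the two endpoints.
#' @param p_a,p_b Two-sided p-values of the endpoints, in `[0, 1]`.
#' @param fc_transform `"absolute_log2"` (default) or `"signed_log2"`.
#' @return Numeric vector of edge scores.
#' @export
score_edge <- function(fc_a, p_a, fc_b, p_b,
                       fc_transform = c("absolute_log2", "signed_log2")) {
  fc_transform <- match.arg(fc_transform)
  p_a <- as.numeric(p_a); p_b <- as.numeric(p_b)
  if (anyNA(p_a) || anyNA(p_b) || any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  fa <- if (fc_transform == "absolute_log2") abs(fc_a) else fc_a
  fb <- if (fc_transform == "absolute_log2") abs(fc_b) else fc_b
  fa * (1 - p_a) + fb * (1 - p_b)
}

#' Score every edge of the global graph
#'
#' Assigns the edge score to each interaction whose two endpoints have
#' measured statistics; edges with at least one unmeasured endpoint are
#' dropped and counted (imputing a fold change of 0 would silently halve
#' scores and bias the selection). The result is ordered deterministically:
#' descending score, ties broken by the lexicographic gene pair.
#'
#' @param graph A `global_graph`.
#' @param stats Per-gene statistics data frame (`gene_id`, `log2fc`,
#'   `p_value`), e.g. from [moderated_t_test()].
#' @param fc_transform Passed to [score_edge()].
#' @return A `scored_edges` data frame with columns `gene_a`, `gene_b`,
#'   `fc_a`, `p_a`, `fc_b`, `p_b`, `score`, `interaction_type`,
#'   `source_pathways`; the number of dropped edges is attached as
#'   attribute `"n_dropped"`.
#' @export
score_graph <- function(graph, stats,
                        fc_transform = c("absolute_log2", "signed_log2")) {
  fc_transform <- match.arg(fc_transform)
  stopifnot(inherits(graph, "global_graph"))
  ed <- graph$edges
  ia <- match(ed$gene_a, stats$gene_id)
  ib <- match(ed$gene_b, stats$gene_id)
  measured <- !is.na(ia) & !is.na(ib)
  if (!any(measured))
    stop("no scorable edges: graph genes and measured genes do not overlap",
         call. = FALSE)
  ed <- ed[measured, , drop = FALSE]
  ia <- ia[measured]; ib <- ib[measured]
  out <- data.frame(
    gene_a = ed$gene_a, gene_b = ed$gene_b,
    fc_a = stats$log2fc[ia], p_a = stats$p_value[ia],
    fc_b = stats$log2fc[ib], p_b = stats$p_value[ib],
    interaction_type = ed$interaction_type,
    source_pathways = ed$source_pathways,
    stringsAsFactors = FALSE
  )
  out$score <- score_edge(out$fc_a, out$p_a, out$fc_b, out$p_b, fc_transform)
  out <- out[order(-out$score, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!measured)
  attr(out, "fc_transform") <- fc_transform
  class(out) <- c("scored_edges", "data.frame")
  out
}

#' Write scored edges as TSV
#' @param scored A `scored_edges` data frame from [score_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scored_edges <- function(scored, path) {
  cols <- c("gene_a", "gene_b", "fc_a", "p_a", "fc_b", "p_b", "score",
            "source_pathways")
  utils::write.table(scored[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
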