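# ---- change-point threshold selection --------------------------------------

#' Detect the critical edge-score threshold by change-point analysis
#'
#' The edge-score distribution of a real comparison has a large mass of
#' low, noise-level scores and a sparse tail of high scores carrying the
#' signal. The threshold is found as the single change point in mean of the
#' scores sorted in descending order: the split index minimizing the
#' two-segment residual sum of squares (least-squares / AMOC criterion).
#' The reported `threshold_score` is the midpoint between the last score of
#' the high segment and the first score of the low segment, so it falls
#' inside the gap whenever the two regimes are separated. The fit is exact
#' and deterministic for a fixed input.
#'
#' A histogram of the scores (Freedman-Diaconis bin width with a floor of
#' 30 bins, or `n_bins` if given) is returned for diagnostics; it is the
#' usual way to visualise where the distribution becomes flat.
#'
#' @param scores Numeric vector of edge scores (at least 20 values with at
#'   least 2 distinct values).
#' @param n_bins Optional number of diagnostic histogram bins.
#' @return A `changepoint_result`: list with `threshold_score`,
#'   `changepoint_index` (size of the high segment), `segment_means`,
#'   `n_edges_above` (scores at or above the threshold), `bin_edges`,
#'   `bin_counts` and `method`.
#' @export
detect_changepoint <- function(scores, n_bins = NULL) {
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  if (length(scores) < 20L)
    stop("need at least 20 scores for change-point detection; with fewer ",
         "edges select a percentile cutoff directly", call. = FALSE)
  if (length(unique(scores)) < 2L)
    stop("no change point: all scores are identical", call. = FALSE)

  s <- sort(scores, decreasing = TRUE)
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  tau <- seq_len(n - 1L)
  rss <- (cs2[tau] - cs[tau]^2 / tau) +
    ((cs2[n] - cs2[tau]) - (cs[n] - cs[tau])^2 / (n - tau))
  k <- which.min(rss)  # first minimum: smallest high segment on exact ties
  threshold <- (s[k] + s[k + 1L]) / 2

  if (is.null(n_bins)) {
    iqr <- stats::IQR(scores)
    width <- 2 * iqr / length(scores)^(1 / 3)
    span <- diff(range(scores))
    n_bins <- if (width > 0) max(30L, ceiling(span / width)) else 30L
  }
  breaks <- seq(min(scores), max(scores), length.out = n_bins + 1L)
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE)

  structure(list(
    threshold_score = threshold,
    changepoint_index = k,
    segment_means = c(high = cs[k] / k, low = (cs[n] - cs[k]) / (n - k)),
    n_edges_above = sum(scores >= threshold),
    bin_edges = h$breaks,
    bin_counts = h$counts,
    method = "least-squares single mean-shift on descending sorted scores"
  ), class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat("changepoint_result: threshold", format(x$threshold_score),
      "|", x$n_edges_above, "edges above",
      "| segment means", format(x$segment_means["high"]), "/",
      format(x$segment_means["low"]), "\n")
  invisible(x)
}

#' Write change-point diagnostics as TSV
#'
#' One row per histogram bin (`bin_low`, `bin_high`, `count`) plus the
#' chosen threshold in a comment header line.
#'
#' @param changepoint A `changepoint_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_changepoint_tsv <- function(changepoint, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold_score=%.10g n_edges_above=%d",
                     changepoint$threshold_score,
                     changepoint$n_edges_above), con)
  nb <- length(changepoint$bin_counts)
  utils::write.table(
    data.frame(bin_low = changepoint$bin_edges[seq_len(nb)],
               bin_high = changepoint$bin_edges[-1L],
               count = changepoint$bin_counts),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- safety margin ----------------------------------------------------------

#' Apply the safety margin to the edges above the change point
#'
#' Of the `K` edges scoring at or above the change-point threshold, only
#' the top `ceiling(safety_fraction * K)` are kept (default 75%), leaving a
#' safety margin against borderline false positives. Edges tied with the
#' last kept score are included, so the selection does not depend on input
#' ordering. The result is always a prefix of the descending-sorted edge
#' list.
#'
#' @param scored_edges A `scored_edges` data frame sorted by descending
#'   score (as returned by [score_graph()]).
#' @param changepoint A `changepoint_result` (or a single numeric threshold).
#' @param safety_fraction Fraction of above-threshold edges to keep, in
#'   `(0, 1]`. Default 0.75.
#' @return The selected rows of `scored_edges`.
#' @export
apply_safety_margin <- function(scored_edges, changepoint,
                                safety_fraction = 0.75) {
  if (!is.numeric(safety_fraction) || safety_fraction <= 0 ||
      safety_fraction > 1)
    stop("safety_fraction must be in (0, 1]", call. = FALSE)
  threshold <- if (inherits(changepoint, "changepoint_result"))
    changepoint$threshold_score else as.numeric(changepoint)
  sc <- scored_edges$score
  if (is.unsorted(rev(sc)))
    stop("scored_edges must be sorted by descending score", call. = FALSE)
  K <- sum(sc >= threshold)
  if (K == 0L) {
    warning("no edges at or above the change-point threshold; ",
            "empty selection", call. = FALSE)
    return(scored_edges[0L, , drop = FALSE])
  }
  # round() guards against binary representation error in f * K
  k <- ceiling(round(safety_fraction * K, 9))
  k <- sum(sc >= sc[k])  # extend across ties at the boundary score
  scored_edges[seq_len(k), , drop = FALSE]
}

# ---- mechanism extraction ---------------------------------------------------

#' Extract the putative mechanism subgraph from selected edges
#'
#' The mechanism is the subgraph induced by the selected high-score edges:
#' its genes are exactly the endpoints of those edges, partitioned into
#' connected components. Original interaction type and pathway provenance
#' are preserved for rendering.
#'
#' @param graph The `global_graph` the edges came from (used only for
#'   validation; may be `NULL`).
#' @param selected Data frame of selected scored edges (e.g. from
#'   [apply_safety_margin()]).
#' @param safety_fraction Fraction recorded in the result (metadata).
#' @return A `mechanism` object: list with `edges`, `nodes`, `components`
#'   (named integer membership vector), `n_components`, `cutoff_score` (the
#'   minimum selected score, `NA` when empty) and `safety_fraction`.
#' @export
extract_mechanism <- function(graph, selected, safety_fraction = NA_real_) {
  if (!is.null(graph) && nrow(selected)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    if (!all(key(selected$gene_a, selected$gene_b) %in%
             key(graph$edges$gene_a, graph$edges$gene_b)))
      stop("selected edges are not a subset of the graph's edges",
           call. = FALSE)
  }
  nodes <- sort(unique(c(selected$gene_a, selected$gene_b)))
  if (length(nodes)) {
    g <- as_igraph(NULL, edges = selected, vertices = nodes)
    comp <- igraph::components(g)
    membership <- comp$membership[nodes]
    n_comp <- comp$no
  } else {
    membership <- stats::setNames(integer(0), character(0))
    n_comp <- 0L
  }
  structure(list(
    edges = selected,
    nodes = nodes,
    components = membership,
    n_components = n_comp,
    cutoff_score = if (nrow(selected)) min(selected$score) else NA_real_,
    safety_fraction = safety_fraction
  ), class = "mechanism")
}

#' @export
print.mechanism <- function(x, ...) {
  cat("mechanism:", nrow(x$edges), "edges,", length(x$nodes), "genes,",
      x$n_components, "connected component(s)")
  if (!is.na(x$cutoff_score))
    cat("; cutoff score", format(x$cutoff_score))
  cat("\n")
  invisible(x)
}

#' Write the selected mechanism edges as a flat TSV
#' @param mechanism A `mechanism` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mechanism_tsv <- function(mechanism, path) {
  ed <- mechanism$edges
  cols <- intersect(c("gene_a", "gene_b", "fc_a", "p_a", "fc_b", "p_b",
                      "score", "interaction_type", "source_pathways"),
                    names(ed))
  utils::write.table(ed[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- end-to-end pipeline ----------------------------------------------------

#' Run the full high-edge-score mechanism pipeline
#'
#' Convenience wrapper: scores the global graph from per-gene statistics,
#' detects the change-point threshold, applies the safety margin and
#' extracts the mechanism subgraph.
#'
#' @param stats Per-gene statistics (data frame with `gene_id`, `log2fc`,
#'   `p_value`) or an `expression_dataset` (then [moderated_t_test()] is run
#'   first).
#' @param graph A `global_graph`.
#' @param safety_fraction Safety-margin fraction, default 0.75.
#' @param fc_transform Passed to [score_graph()].
#' @param n_bins Passed to [detect_changepoint()].
#' @return A `highedges_result`: list with `stats`, `scored`, `changepoint`
#'   and `mechanism`.
#' @export
run_highedges <- function(stats, graph, safety_fraction = 0.75,
                          fc_transform = "absolute_log2", n_bins = NULL) {
  if (inherits(stats, "expression_dataset")) stats <- moderated_t_test(stats)
  scored <- score_graph(graph, stats, fc_transform = fc_transform)
  cp <- detect_changepoint(scored$score, n_bins = n_bins)
  selected <- apply_safety_margin(scored, cp,
                                  safety_fraction = safety_fraction)
  mech <- extract_mechanism(graph, selected,
                            safety_fraction = safety_fraction)
  structure(list(stats = stats, scored = scored, changepoint = cp,
                 mechanism = mech), class = "highedges_result")
}

#' @export
print.highedges_result <- function(x, ...) {
  print(x$changepoint)
  print(x$mechanism)
  invisible(x)
}
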