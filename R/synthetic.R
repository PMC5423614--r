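# ---- synthetic knockout experiment ------------------------------------------

#' Generate a synthetic multi-pathway interaction database
#'
#' Builds `n_pathways` sparse connected interaction graphs emulating
#' signaling pathways. Each pathway graph is a random recursive spanning
#' tree over its gene set plus extra random edges up to the target density,
#' so connectivity is guaranteed. A fraction of each pathway's genes
#' (after the first) is shared with previously generated pathways; the
#' shared genes are drawn as a *connected module* (a degree-weighted walk
#' around a seed gene of the accumulated graph), because curated databases
#' duplicate whole signaling cores across pathways rather than isolated
#' genes. Shared genes are wired first in the new pathway's tree, so
#' re-used genes are well connected wherever they appear. Deterministic
#' for a fixed seed.
#'
#' @param n_pathways Number of pathways, default 10.
#' @param genes_per_pathway Genes per pathway, default 30.
#' @param edge_density Fraction of possible gene pairs wired per pathway,
#'   default 0.11 (average degree about 3.2, matching curated signaling maps).
#' @param overlap_fraction Fraction of each pathway's genes shared with
#'   earlier pathways, in `[0, 1)`; default 0.18.
#' @param seed Random seed.
#' @return List with `edges` (interaction edge data frame) and `pathways`
#'   (a `pathway_collection`).
#' @export
generate_pathway_db <- function(n_pathways = 10, genes_per_pathway = 30,
                                edge_density = 0.11, overlap_fraction = 0.18,
                                seed = 1) {
  stopifnot(n_pathways >= 1, genes_per_pathway >= 2,
            edge_density > 0, overlap_fraction >= 0, overlap_fraction < 1)
  set.seed(seed)
  degree_total <- numeric(0)  # named: gene -> accumulated degree
  gene_counter <- 0L
  edge_rows <- vector("list", n_pathways)
  sets <- vector("list", n_pathways)
  npp <- genes_per_pathway
  for (i in seq_len(n_pathways)) {
    n_shared <- if (i == 1L) 0L else
      min(round(overlap_fraction * npp), length(degree_total))
    shared <- character(0)
    if (n_shared > 0L) {
      # re-used genes form a connected module: databases duplicate whole
      # signaling cores across pathways, not isolated genes
      prev <- do.call(rbind, edge_rows[seq_len(i - 1L)])
      seed_gene <- sample(names(degree_total), 1L, prob = degree_total)
      module <- seed_gene
      while (length(module) < n_shared) {
        nb <- setdiff(c(prev$gene_b[prev$gene_a %in% module],
                        prev$gene_a[prev$gene_b %in% module]), module)
        if (!length(nb)) break
        w <- degree_total[nb]
        module <- c(module, if (length(nb) == 1L) nb else
          sample(nb, 1L, prob = w))
      }
      shared <- module
    }
    n_new <- npp - length(shared)
    new_genes <- sprintf("g%04d", gene_counter + seq_len(n_new))
    gene_counter <- gene_counter + n_new
    # shared genes are wired first, so re-used genes sit near the root of
    # this pathway's tree and stay well connected
    genes <- c(sample(shared), sample(new_genes))

    # random recursive spanning tree guarantees connectivity
    deg <- numeric(npp)
    parent <- integer(npp - 1L)
    for (j in 2:npp) {
      parent[j - 1L] <- sample.int(j - 1L, 1L)
      deg[j] <- deg[j] + 1
      deg[parent[j - 1L]] <- deg[parent[j - 1L]] + 1
    }
    tree <- cbind(genes[parent], genes[2:npp])
    m_target <- max(npp - 1L, round(edge_density * npp * (npp - 1L) / 2))
    n_extra <- m_target - (npp - 1L)
    extra <- NULL
    if (n_extra > 0L) {
      pairs <- utils::combn(seq_len(npp), 2L)
      key <- paste(pmin(parent, 2:npp), pmax(parent, 2:npp))
      all_key <- paste(pairs[1, ], pairs[2, ])
      avail <- which(!(all_key %in% key))
      take <- sample(avail, min(n_extra, length(avail)))
      extra <- cbind(genes[pairs[1, take]], genes[pairs[2, take]])
    }
    pw_edges <- rbind(tree, extra)
    for (g in c(pw_edges[, 1], pw_edges[, 2]))
      degree_total[g] <- if (g %in% names(degree_total))
        degree_total[g] + 1 else 1
    edge_rows[[i]] <- data.frame(
      gene_a = pw_edges[, 1], gene_b = pw_edges[, 2], directed = TRUE,
      interaction_type = sample(c("activation", "inhibition"),
                                nrow(pw_edges), replace = TRUE),
      pathway_id = sprintf("path%02d", i), stringsAsFactors = FALSE)
    sets[[i]] <- genes
  }
  names(sets) <- sprintf("path%02d", seq_len(n_pathways))
  edges <- do.call(rbind, edge_rows)
  rownames(edges) <- NULL
  list(edges = edges,
       pathways = pathway_collection(
         sets, stats::setNames(sprintf("synthetic pathway %d",
                                       seq_len(n_pathways)), names(sets))))
}

#' Plant a knockout mechanism in a synthetic interaction database
#'
#' Picks a knockout (KO) gene (requiring degree >= 2 in the global graph
#' and membership in at least one pathway; by default the eligible gene
#' whose pathway multiplicity is closest to `ko_pathway_target`) and plants
#' the true mechanism as the breadth-first propagation front rooted at the
#' KO gene up to `cascade_depth` hops: every interaction connecting a gene
#' at depth `d - 1` to a gene at depth `d` carries the knockout signal and
#' is part of the planted mechanism (on paths and stars this is exactly the
#' breadth-first tree). Each affected gene's expression shift is inherited
#' through its primary parent (deterministically the lexicographically
#' smallest neighbour one hop closer to the KO gene), with per-edge signs
#' alternating randomly to emulate activating and inhibiting interactions.
#'
#' @param edges Interaction edge data frame (as from
#'   [generate_pathway_db()]).
#' @param pathways A `pathway_collection`.
#' @param seed Random seed.
#' @param cascade_depth Number of hops the KO effect propagates, >= 1;
#'   default 2.
#' @param ko_gene Optional explicit KO gene id (must have degree >= 2 and
#'   belong to a pathway unless `require_degree` is lowered).
#' @param ko_effect Log2 expression shift of the KO gene in cases,
#'   default -3 (knockdown, not zero expression, keeping variances finite).
#' @param decay Per-hop attenuation of the downstream effect, in (0, 1);
#'   default 0.6.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale,
#'   default 0.4.
#' @param require_degree Minimum KO-gene degree, default 2.
#' @param ko_pathway_target When `ko_gene` is not given, the KO gene is
#'   chosen among eligible genes whose pathway multiplicity is closest to
#'   this target (default 3, the emulated study condition of a KO gene
#'   shared by a handful of pathways).
#' @return A `synthetic_truth` object: list with `ko_gene`,
#'   `planted_edges` (data frame `gene_a`, `gene_b`, `depth`, `sign`,
#'   `primary`; primary rows form the breadth-first tree),
#'   `node_effects` (named log2 shifts of all affected genes),
#'   `positive_pathways`, `genes` (all database genes), `ko_effect`,
#'   `decay`, `noise_sd`, `cascade_depth`.
#' @export
plant_mechanism <- function(edges, pathways, seed = 1, cascade_depth = 2,
                            ko_gene = NULL, ko_effect = -3, decay = 0.6,
                            noise_sd = 0.4, require_degree = 2,
                            ko_pathway_target = 3) {
  stopifnot(cascade_depth >= 1, decay > 0, decay < 1, noise_sd >= 0)
  set.seed(seed)
  graph <- build_global_graph(edges)
  g <- as_igraph(graph)
  deg <- igraph::degree(g)
  in_pw <- pathway_universe(pathways)
  multiplicity <- vapply(graph$nodes, function(gn)
    sum(vapply(unclass(pathways), function(s) gn %in% s, logical(1))),
    integer(1))
  if (is.null(ko_gene)) {
    eligible <- graph$nodes[deg[graph$nodes] >= require_degree &
                              graph$nodes %in% in_pw]
    if (!length(eligible))
      stop("no eligible KO gene (degree >= ", require_degree,
           " and in a pathway)", call. = FALSE)
    gap <- abs(multiplicity[eligible] - ko_pathway_target)
    best <- eligible[gap == min(gap)]
    if (length(best) > 1L) {
      # a knocked-out master regulator is well wired in each of its
      # pathways: maximize the minimum within-pathway degree
      pw_ids <- unique(edges$pathway_id)
      wdeg <- sapply(pw_ids, function(p) {
        e <- edges[edges$pathway_id == p, ]
        tab <- table(c(e$gene_a, e$gene_b))
        cnt <- stats::setNames(as.integer(tab)[match(best, names(tab))], best)
        member <- vapply(best, function(gn)
          gn %in% pathways[[p]], logical(1))
        ifelse(member, ifelse(is.na(cnt), 0L, cnt), NA_integer_)
      })
      min_wdeg <- apply(matrix(wdeg, nrow = length(best)), 1,
                        function(x) min(x, na.rm = TRUE))
      best <- best[min_wdeg == max(min_wdeg)]
      ko_gene <- if (length(best) > 1L) sample(best, 1L) else best
    } else ko_gene <- best
  } else {
    if (!ko_gene %in% graph$nodes || deg[ko_gene] < require_degree ||
        !ko_gene %in% in_pw)
      stop("requested KO gene is not eligible", call. = FALSE)
  }

  d <- igraph::distances(g, v = ko_gene)[1, ]
  planted <- list()
  node_effects <- stats::setNames(ko_effect, ko_gene)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  names(adj) <- igraph::V(g)$name
  for (depth in seq_len(cascade_depth)) {
    at_depth <- sort(names(d)[is.finite(d) & d == depth])
    if (!length(at_depth)) break
    for (v in at_depth) {
      nb <- sort(names(adj[[v]]))
      parents <- nb[d[nb] == depth - 1]  # every depth-increasing edge
      sgn <- sample(c(-1, 1), 1L)
      planted[[length(planted) + 1L]] <- data.frame(
        gene_a = parents, gene_b = v, depth = depth, sign = sgn,
        primary = parents == parents[1L], stringsAsFactors = FALSE)
      # the expression shift is inherited through the primary parent
      node_effects[v] <- node_effects[parents[1L]] * decay * sgn
    }
  }
  planted <- do.call(rbind, planted)
  contains_ko <- vapply(unclass(pathways), function(s) ko_gene %in% s,
                        logical(1))
  structure(list(
    ko_gene = ko_gene, planted_edges = planted, node_effects = node_effects,
    positive_pathways = names(pathways)[contains_ko],
    genes = graph$nodes, ko_effect = ko_effect, decay = decay,
    noise_sd = noise_sd, cascade_depth = cascade_depth
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: KO gene", x$ko_gene, "in",
      length(x$positive_pathways), "pathway(s);",
      nrow(x$planted_edges), "planted edges to depth", x$cascade_depth, "\n")
  invisible(x)
}

#' Generate a two-group expression matrix with a planted KO mechanism
#'
#' Control samples are drawn per gene from
#' `Normal(baseline_g, noise_sd^2)`; case samples additionally shift the KO
#' gene by `ko_effect` and every gene at depth `d` of the planted cascade
#' by `ko_effect * decay^d` (with the planted per-edge signs), so a gene at
#' depth 2 with `ko_effect = -3`, `decay = 0.5` has expected log2 fold
#' change of magnitude 0.75. All other genes, and `n_background_genes`
#' extra genes belonging to no pathway, share the control distribution.
#' Values emulate log2-scale normalized microarray intensities;
#' deterministic for a fixed seed.
#'
#' @param truth A `synthetic_truth` from [plant_mechanism()].
#' @param n_case,n_control Samples per group (>= 3 recommended), default 5.
#' @param n_background_genes Extra pathway-free measured genes, default 200.
#' @param seed Random seed.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log2 intensities, default Normal(7, 1).
#' @return An `expression_dataset`.
#' @export
generate_expression <- function(truth, n_case = 5, n_control = 5,
                                n_background_genes = 200, seed = 1,
                                baseline_mean = 7, baseline_sd = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), n_case >= 2, n_control >= 2)
  set.seed(seed)
  genes <- c(truth$genes,
             if (n_background_genes > 0)
               sprintf("bg%04d", seq_len(n_background_genes)))
  n_genes <- length(genes)
  n_samples <- n_case + n_control
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  mat <- matrix(stats::rnorm(n_genes * n_samples, sd = truth$noise_sd),
                nrow = n_genes) + baseline
  effects <- stats::setNames(numeric(n_genes), genes)
  effects[names(truth$node_effects)] <- truth$node_effects
  case_cols <- seq_len(n_case)
  mat[, case_cols] <- mat[, case_cols] + effects
  rownames(mat) <- genes
  colnames(mat) <- c(sprintf("case_%02d", seq_len(n_case)),
                     sprintf("control_%02d", seq_len(n_control)))
  expression_dataset(mat, c(rep("case", n_case), rep("control", n_control)))
}

#' Simulate a complete synthetic knockout experiment
#'
#' Chains [generate_pathway_db()], [plant_mechanism()] and
#' [generate_expression()] with derived sub-seeds, returning everything a
#' pipeline run needs.
#'
#' @param seed Master seed; sub-seeds are derived deterministically.
#' @param ... Passed through to the generators (`n_pathways`,
#'   `genes_per_pathway`, `edge_density`, `overlap_fraction`,
#'   `cascade_depth`, `ko_gene`, `ko_effect`, `decay`, `noise_sd`,
#'   `n_case`, `n_control`, `n_background_genes`).
#' @return List with `edges`, `pathways`, `graph` (the built
#'   `global_graph`), `truth` and `dataset`.
#' @export
simulate_ko_experiment <- function(seed = 1, n_pathways = 10,
                                   genes_per_pathway = 30,
                                   edge_density = 0.11,
                                   overlap_fraction = 0.18,
                                   cascade_depth = 2, ko_gene = NULL,
                                   ko_effect = -3, decay = 0.6,
                                   noise_sd = 0.4, n_case = 5,
                                   n_control = 5, n_background_genes = 200) {
  db <- generate_pathway_db(n_pathways = n_pathways,
                            genes_per_pathway = genes_per_pathway,
                            edge_density = edge_density,
                            overlap_fraction = overlap_fraction,
                            seed = seed)
  truth <- plant_mechanism(db$edges, db$pathways, seed = seed + 1L,
                           cascade_depth = cascade_depth, ko_gene = ko_gene,
                           ko_effect = ko_effect, decay = decay,
                           noise_sd = noise_sd)
  dataset <- generate_expression(truth, n_case = n_case,
                                 n_control = n_control,
                                 n_background_genes = n_background_genes,
                                 seed = seed + 2L)
  list(edges = db$edges, pathways = db$pathways,
       graph = build_global_graph(db$edges), truth = truth,
       dataset = dataset)
}

#' Write all synthetic inputs in the formats the pipeline reads
#'
#' Writes the expression matrix + group file, the interaction edge list,
#' the pathway GMT and a truth JSON (KO gene, planted edges, parameters)
#' into a directory.
#'
#' @param sim Result of [simulate_ko_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(sim$dataset, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))
  write_edge_table(sim$edges, file.path(dir, "interactions.tsv"))
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  truth <- sim$truth
  jsonlite::write_json(
    list(ko_gene = truth$ko_gene,
         planted_edges = truth$planted_edges,
         positive_pathways = truth$positive_pathways,
         ko_effect = truth$ko_effect, decay = truth$decay,
         noise_sd = truth$noise_sd, cascade_depth = truth$cascade_depth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
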