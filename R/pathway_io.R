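# ---- pathway interaction input ---------------------------------------------

#' Parse a KGML pathway document into interaction edges
#'
#' Reads a single KEGG KGML (pathway XML) file and returns the gene-level
#' interaction edges it describes, together with the pathway's gene
#' membership. Gene entries may carry several gene identifiers (space
#' separated in the `name` attribute); group entries are expanded to their
#' member genes, so a relation pointing at a group yields one edge per member.
#' Relations whose endpoints cannot be mapped to genes (compounds, maps,
#' unknown entry ids) are skipped with a warning.
#'
#' Metabolic `reaction` elements are ignored by default because the method
#' operates on signaling interactions; set `include_reactions = TRUE` to add
#' an edge of type `"reaction"` between gene entries catalyzing reactions
#' that share a compound (the product of one is a substrate of the other).
#'
#' @param path Path to a KGML file (or a literal XML string).
#' @param include_reactions Logical; also derive gene-gene edges from
#'   metabolic reaction elements. Default `FALSE`.
#' @return A list with components `edges` (a data frame with columns
#'   `gene_a`, `gene_b`, `directed`, `interaction_type`, `pathway_id`) and
#'   `pathway` (a list with `id`, `name` and the character vector `genes`).
#' @export
parse_kgml <- function(path, include_reactions = FALSE) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed KGML document '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document (no <pathway> root): ", path,
                        call. = FALSE)
  pathway_id <- xml2::xml_attr(root, "name")
  if (is.na(pathway_id)) pathway_id <- "unknown_pathway"
  pathway_id <- sub("^path:", "", pathway_id)
  pathway_name <- xml2::xml_attr(root, "title")
  if (is.na(pathway_name)) pathway_name <- pathway_id

  entries <- xml2::xml_find_all(doc, "//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")
  entry_reaction <- xml2::xml_attr(entries, "reaction")

  # genes carried by each entry; groups expand through their components
  genes_of <- vector("list", length(entries))
  names(genes_of) <- entry_id
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      genes_of[[i]] <- strsplit(trimws(entry_name[i]), "\\s+")[[1]]
    } else {
      genes_of[[i]] <- character(0)
    }
  }
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "./component"),
                             "id")
      genes_of[[i]] <- unique(unlist(genes_of[comp], use.names = FALSE))
    }
  }

  rows <- list()
  add_pairs <- function(ga, gb, type) {
    grid <- expand.grid(gene_a = ga, gene_b = gb,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    grid$directed <- TRUE
    grid$interaction_type <- type
    grid$pathway_id <- pathway_id
    grid
  }

  relations <- xml2::xml_find_all(doc, "//relation")
  for (rel in relations) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    if (!(e1 %in% entry_id) || !(e2 %in% entry_id)) {
      warning("relation references unknown entry id (", e1, ", ", e2,
              ") in pathway ", pathway_id, "; edge skipped", call. = FALSE)
      next
    }
    ga <- genes_of[[e1]]
    gb <- genes_of[[e2]]
    if (length(ga) == 0L || length(gb) == 0L) {
      warning("relation ", e1, "->", e2, " in pathway ", pathway_id,
              " has no gene mapping (compound/map endpoint); edge skipped",
              call. = FALSE)
      next
    }
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    type <- if (length(subtypes)) paste(subtypes, collapse = ";") else
      xml2::xml_attr(rel, "type")
    rows[[length(rows) + 1L]] <- add_pairs(ga, gb, type)
  }

  if (isTRUE(include_reactions)) {
    reactions <- xml2::xml_find_all(doc, "//reaction")
    if (length(reactions)) {
      rx_name <- xml2::xml_attr(reactions, "name")
      subs <- lapply(reactions, function(r)
        xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "name"))
      prods <- lapply(reactions, function(r)
        xml2::xml_attr(xml2::xml_find_all(r, "./product"), "name"))
      # gene entries annotated with each reaction
      rx_genes <- lapply(rx_name, function(nm) {
        hit <- !is.na(entry_reaction) &
          vapply(strsplit(entry_reaction, "\\s+"),
                 function(x) nm %in% x, logical(1))
        unique(unlist(genes_of[hit], use.names = FALSE))
      })
      for (i in seq_along(reactions)) {
        for (j in seq_along(reactions)) {
          if (i == j) next
          if (length(intersect(prods[[i]], subs[[j]])) &&
              length(rx_genes[[i]]) && length(rx_genes[[j]])) {
            rows[[length(rows) + 1L]] <-
              add_pairs(rx_genes[[i]], rx_genes[[j]], "reaction")
          }
        }
      }
    }
  }

  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               directed = logical(0), interaction_type = character(0),
               pathway_id = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  genes <- unique(unlist(genes_of[entry_type == "gene"], use.names = FALSE))
  list(edges = edges,
       pathway = list(id = pathway_id, name = pathway_name, genes = genes))
}

#' Read a generic interaction edge-list table
#'
#' Generic alternative to KGML input: a tab-separated table with header
#' columns `gene_a`, `gene_b`, `directed`, `interaction_type`, `pathway_id`.
#' Self-loop rows (`gene_a == gene_b`) are dropped and counted; duplicate
#' rows are kept (deduplication happens in [build_global_graph()]).
#'
#' @param path Path to a TSV file, or a data frame with the same columns.
#' @return A data frame of interaction edges; the number of dropped
#'   self-loops is attached as attribute `"n_self_loops_dropped"`.
#' @export
read_edge_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("gene_a", "gene_b", "directed", "interaction_type",
                "pathway_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("edge table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- tab[required]
  tab$gene_a <- as.character(tab$gene_a)
  tab$gene_b <- as.character(tab$gene_b)
  blank <- !nzchar(trimws(tab$gene_a)) | !nzchar(trimws(tab$gene_b)) |
    is.na(tab$gene_a) | is.na(tab$gene_b)
  if (any(blank))
    stop("edge table has ", sum(blank), " row(s) with a blank gene id",
         call. = FALSE)
  tab$directed <- as.logical(tab$directed)
  self <- tab$gene_a == tab$gene_b
  out <- tab[!self, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_loops_dropped") <- sum(self)
  out
}

#' Write an interaction edge list as TSV
#' @param edges Edge data frame (as from [read_edge_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- pathway membership (GMT) ----------------------------------------------

#' Read pathway membership from a GMT file
#'
#' Each GMT line is `pathway_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed; duplicate pathway ids are an
#' error.
#'
#' @param path Path to a GMT file.
#' @return A `pathway_collection`: a named list of unique gene identifier
#'   vectors with pathway descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(pathway_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id in GMT: ",
         ids[duplicated(ids)][1], call. = FALSE)
  descriptions <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  names(descriptions) <- ids
  pathway_collection(sets, descriptions)
}

#' Construct a pathway collection
#'
#' @param sets Named list of gene identifier vectors (names are pathway ids).
#' @param descriptions Optional named character vector of pathway names.
#' @return A `pathway_collection` object.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every pathway must have an id", call. = FALSE)
    if (anyDuplicated(names(sets)))
      stop("pathway ids must be unique", call. = FALSE)
    if (any(lengths(sets) == 0L))
      stop("every pathway gene set must be non-empty", call. = FALSE)
    sets <- lapply(sets, function(g) unique(as.character(g)))
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "pathway_collection")
}

#' Union of all genes annotated to at least one pathway
#' @param pathways A `pathway_collection`.
#' @return Character vector of gene identifiers.
#' @export
pathway_universe <- function(pathways) {
  unique(unlist(unclass(pathways), use.names = FALSE))
}

#' Write a pathway collection as GMT
#' @param pathways A `pathway_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "descriptions")
  lines <- vapply(names(pathways), function(id)
    paste(c(id, desc[[id]], pathways[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x), "pathways,",
      length(pathway_universe(x)), "genes\n")
  invisible(x)
}

# ---- global graph ----------------------------------------------------------

#' Build the global interaction graph
#'
#' Merges interaction edge records from all pathways into a single graph.
#' Edges are deduplicated by unordered gene pair; the merged edge keeps the
#' union of source pathways and interaction types as metadata. Self-loops
#' are excluded (the edge score of a self-loop is degenerate). Scoring treats
#' the graph as undirected; original direction is retained only as metadata.
#'
#' @param edges Edge data frame with columns `gene_a`, `gene_b`,
#'   `interaction_type`, `pathway_id` (and optionally `directed`).
#' @param gene_map Optional two-column data frame (`from`, `to`) applied to
#'   both endpoint columns before merging (e.g. probe-to-gene mapping).
#' @return A `global_graph` object: list with `nodes` (character vector) and
#'   `edges` (data frame with canonical `gene_a < gene_b`, collapsed
#'   `interaction_type` and `source_pathways`, and record count `n_records`).
#' @export
build_global_graph <- function(edges, gene_map = NULL) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      interaction_type = character(0),
                      source_pathways = character(0),
                      n_records = integer(0), stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L)
    return(structure(list(nodes = character(0), edges = empty,
                          n_input_records = 0L), class = "global_graph"))
  ga <- as.character(edges$gene_a)
  gb <- as.character(edges$gene_b)
  if (!is.null(gene_map)) {
    map <- stats::setNames(as.character(gene_map[[2]]),
                           as.character(gene_map[[1]]))
    ga <- ifelse(ga %in% names(map), map[ga], ga)
    gb <- ifelse(gb %in% names(map), map[gb], gb)
  }
  type <- if ("interaction_type" %in% names(edges))
    as.character(edges$interaction_type) else NA_character_
  pw <- if ("pathway_id" %in% names(edges))
    as.character(edges$pathway_id) else NA_character_

  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]
  type <- rep_len(type, length(keep))[keep]
  pw <- rep_len(pw, length(keep))[keep]
  if (!length(ga))
    return(structure(list(nodes = character(0), edges = empty,
                          n_input_records = nrow(edges)),
                     class = "global_graph"))

  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  key <- paste(lo, hi, sep = "\r")
  collapse <- function(x) paste(sort(unique(x[!is.na(x)])), collapse = ";")
  idx <- split(seq_along(key), key)
  merged <- data.frame(
    gene_a = vapply(idx, function(i) lo[i[1]], character(1)),
    gene_b = vapply(idx, function(i) hi[i[1]], character(1)),
    interaction_type = vapply(idx, function(i) collapse(type[i]),
                              character(1)),
    source_pathways = vapply(idx, function(i) collapse(pw[i]), character(1)),
    n_records = vapply(idx, length, integer(1)),
    stringsAsFactors = FALSE
  )
  merged <- merged[order(merged$gene_a, merged$gene_b), , drop = FALSE]
  rownames(merged) <- NULL
  structure(list(nodes = sort(unique(c(lo, hi))), edges = merged,
                 n_input_records = nrow(edges)), class = "global_graph")
}

#' @export
print.global_graph <- function(x, ...) {
  cat("global_graph:", length(x$nodes), "genes,", nrow(x$edges),
      "interactions (from", x$n_input_records, "records)\n")
  invisible(x)
}

#' Convert a global graph (or an edge selection) to an igraph object
#'
#' @param graph A `global_graph`.
#' @param edges Optional data frame of edges (subset) to use instead of the
#'   full edge set; must contain `gene_a`/`gene_b`.
#' @param vertices Optional character vector of vertices to force into the
#'   graph (isolated genes are kept as singletons).
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(graph, edges = NULL, vertices = NULL) {
  ed <- if (is.null(edges)) graph$edges else edges
  verts <- unique(c(ed$gene_a, ed$gene_b, vertices))
  igraph::graph_from_data_frame(
    ed[, c("gene_a", "gene_b",
           intersect(names(ed), c("interaction_type", "source_pathways",
                                  "score"))), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = verts))
}

#' Write a graph in GraphML format
#'
#' Nodes can be annotated with per-gene statistics (log2 fold change and
#' p-value) when a statistics table is supplied.
#'
#' @param graph A `global_graph` or `mechanism` object.
#' @param path Output file path.
#' @param stats Optional per-gene statistics data frame (columns `gene_id`,
#'   `log2fc`, `p_value`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, stats = NULL) {
  g <- if (inherits(graph, "mechanism"))
    as_igraph(NULL, edges = graph$edges, vertices = graph$nodes)
  else as_igraph(graph)
  if (!is.null(stats)) {
    m <- match(igraph::V(g)$name, stats$gene_id)
    igraph::V(g)$log2fc <- stats$log2fc[m]
    igraph::V(g)$p_value <- stats$p_value[m]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a graph in SIF (simple interaction format)
#'
#' One line per edge: `gene_a <interaction_type> gene_b`; isolated nodes are
#' written as bare names.
#'
#' @param graph A `global_graph` or `mechanism` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  ed <- if (inherits(graph, "mechanism")) graph$edges else graph$edges
  nodes <- if (inherits(graph, "mechanism")) graph$nodes else graph$nodes
  type <- if ("interaction_type" %in% names(ed) && nrow(ed))
    ifelse(nzchar(ed$interaction_type), ed$interaction_type, "interacts")
  else rep("interacts", nrow(ed))
  lines <- if (nrow(ed)) paste(ed$gene_a, type, ed$gene_b) else character(0)
  isolated <- setdiff(nodes, c(ed$gene_a, ed$gene_b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}
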