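test_that("parse_kgml extracts gene-level relations", {
  doc <- make_kgml(
    entries = list(`1` = list(type = "gene", name = "tst:A"),
                   `2` = list(type = "gene", name = "tst:B")),
    relations = list(list(entry1 = "1", entry2 = "2",
                          subtype = "activation")))
  out <- parse_kgml(doc)
  expect_equal(nrow(out$edges), 1L)
  expect_equal(out$edges$gene_a, "tst:A")
  expect_equal(out$edges$gene_b, "tst:B")
  expect_equal(out$edges$interaction_type, "activation")
  expect_equal(out$edges$pathway_id, "test01")
  expect_setequal(out$pathway$genes, c("tst:A", "tst:B"))
})

test_that("parse_kgml expands group entries to member genes", {
  doc <- make_kgml(
    entries = list(`1` = list(type = "gene", name = "tst:A"),
                   `2` = list(type = "gene", name = "tst:B"),
                   `3` = list(type = "gene", name = "tst:C"),
                   `4` = list(type = "group", name = "undefined",
                              component = c("2", "3"))),
    relations = list(list(entry1 = "1", entry2 = "4",
                          subtype = "activation")))
  out <- parse_kgml(doc)
  # oracle: one edge per (source gene) x (group member)
  expect_setequal(paste(out$edges$gene_a, out$edges$gene_b),
                  c("tst:A tst:B", "tst:A tst:C"))
})

test_that("parse_kgml skips unmappable or dangling relations with warnings", {
  doc <- make_kgml(
    entries = list(`1` = list(type = "gene", name = "tst:A"),
                   `2` = list(type = "compound", name = "cpd:C00001")),
    relations = list(list(entry1 = "1", entry2 = "2", type = "PCrel")))
  expect_warning(out <- parse_kgml(doc), "no gene mapping")
  expect_equal(nrow(out$edges), 0L)

  doc2 <- make_kgml(
    entries = list(`1` = list(type = "gene", name = "tst:A")),
    relations = list(list(entry1 = "1", entry2 = "99")))
  expect_warning(out2 <- parse_kgml(doc2), "unknown entry")
  expect_equal(nrow(out2$edges), 0L)
})

test_that("parse_kgml rejects malformed XML with the file named", {
  bad <- file.path(tempdir(), "broken.xml")
  writeLines("<pathway><entry", bad)
  expect_error(parse_kgml(bad), "broken.xml")
})

test_that("parse_kgml derives reaction edges only on request", {
  doc <- make_kgml(
    entries = list(`1` = list(type = "gene", name = "tst:E1",
                              reaction = "rn:R1"),
                   `2` = list(type = "gene", name = "tst:E2",
                              reaction = "rn:R2")),
    relations = list(),
    reactions = list(
      list(id = "1", name = "rn:R1", substrate = "cpd:C1",
           product = "cpd:C2"),
      list(id = "2", name = "rn:R2", substrate = "cpd:C2",
           product = "cpd:C3")))
  expect_equal(nrow(parse_kgml(doc)$edges), 0L)
  out <- parse_kgml(doc, include_reactions = TRUE)
  expect_equal(nrow(out$edges), 1L)
  expect_equal(out$edges$interaction_type, "reaction")
  expect_setequal(c(out$edges$gene_a, out$edges$gene_b),
                  c("tst:E1", "tst:E2"))
})

test_that("read_edge_table validates columns and drops self-loops", {
  path <- file.path(tempdir(), "edges.tsv")
  write_edge_table(rbind(edge_df("A", "B"), edge_df("B", "B"),
                         edge_df("B", "C")), path)
  out <- read_edge_table(path)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_self_loops_dropped"), 1L)

  # duplicates are preserved; dedup is the graph builder's job
  dup <- read_edge_table(rbind(edge_df("A", "B"), edge_df("A", "B")))
  expect_equal(nrow(dup), 2L)

  expect_error(read_edge_table(data.frame(gene_a = "A", gene_b = "B")),
               "missing required column")
  expect_error(read_edge_table(edge_df("A", "")), "blank gene")
})

test_that("read_gmt parses, collapses duplicates and enforces uniqueness", {
  path <- file.path(tempdir(), "sets.gmt")
  writeLines(c("P1\tdesc one\tA\tB\tA", "P2\tdesc two\tB\tC"), path)
  pc <- read_gmt(path)
  expect_setequal(pc[["P1"]], c("A", "B"))
  expect_equal(length(pc), 2L)
  expect_setequal(pathway_universe(pc), c("A", "B", "C"))

  writeLines(c("P1\td\tA", "P1\td\tB"), path)
  expect_error(read_gmt(path), "duplicate pathway id")
  writeLines("P1\tonly-two-fields", path)
  expect_error(read_gmt(path), "line 1")
  writeLines(character(0), path)
  expect_equal(length(read_gmt(path)), 0L)
})

test_that("GMT writing round-trips a pathway collection", {
  pc <- pathway_collection(list(P1 = c("A", "B"), P2 = c("B", "C", "D")),
                           c(P1 = "first", P2 = "second"))
  path <- file.path(tempdir(), "roundtrip.gmt")
  write_gmt(pc, path)
  back <- read_gmt(path)
  expect_equal(unclass(back)[order(names(back))],
               unclass(pc)[order(names(pc))],
               ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions")[["P2"]], "second")
})

test_that("build_global_graph merges unordered pairs with metadata unions", {
  edges <- rbind(edge_df("A", "B", "P1"), edge_df("B", "A", "P2"))
  g <- build_global_graph(edges)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$source_pathways, "P1;P2")
  expect_setequal(g$nodes, c("A", "B"))

  g2 <- build_global_graph(rbind(edge_df("A", "B"), edge_df("B", "C"),
                                 edge_df("A", "B")))
  expect_equal(length(g2$nodes), 3L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(g2$edges$n_records, c(2L, 1L))
})

test_that("global graph construction is idempotent and order-invariant", {
  set.seed(42)
  genes <- sprintf("g%02d", 1:12)
  edges <- edge_df(sample(genes, 40, TRUE), sample(genes, 40, TRUE),
                   pathway = sample(c("P1", "P2", "P3"), 40, TRUE))
  g1 <- build_global_graph(edges)
  # brute-force pair dedup oracle
  keep <- edges$gene_a != edges$gene_b
  expect_equal(nrow(g1$edges),
               length(unique(pair_key(edges$gene_a[keep],
                                      edges$gene_b[keep]))))
  # rebuilding from the merged edges yields the same graph
  g2 <- build_global_graph(g1$edges)
  expect_equal(g2$edges[c("gene_a", "gene_b")],
               g1$edges[c("gene_a", "gene_b")])
  # permuting the input records changes nothing
  g3 <- build_global_graph(edges[sample(nrow(edges)), ])
  expect_equal(g3$edges, g1$edges)
  expect_lte(nrow(g1$edges), nrow(edges))
  # empty input is a valid empty graph
  expect_equal(length(build_global_graph(NULL)$nodes), 0L)
})

test_that("gene_map hook remaps endpoints before merging", {
  g <- build_global_graph(rbind(edge_df("probe1", "probe2"),
                                edge_df("GENE1", "probe2")),
                          gene_map = data.frame(from = c("probe1", "probe2"),
                                                to = c("GENE1", "GENE2")))
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(g$nodes, c("GENE1", "GENE2"))
})

test_that("GraphML and SIF writers produce readable files", {
  g <- build_global_graph(rbind(edge_df("A", "B"), edge_df("B", "C")))
  stats <- data.frame(gene_id = c("A", "B", "C"), log2fc = c(1, -2, 0.5),
                      p_value = c(0.01, 0.2, 0.6))
  gml <- file.path(tempdir(), "g.graphml")
  write_graphml(g, gml, stats = stats)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), 3)
  expect_equal(igraph::gsize(back), 2)
  expect_equal(sort(igraph::V(back)$log2fc), c(-2, 0.5, 1))

  sif <- file.path(tempdir(), "g.sif")
  mech <- induced_subgraph(g, c("A", "B", "D"))
  write_sif(mech, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), 2L)  # one edge, one isolated node
  expect_true("D" %in% lines)
})
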