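# shared fixture builders (everything is generated in code)

# minimal KGML document; entries: named list id -> list(type, name, component)
make_kgml <- function(entries, relations, pathway = "test01",
                      title = "test pathway", reactions = NULL) {
  ent <- vapply(names(entries), function(id) {
    e <- entries[[id]]
    comp <- if (!is.null(e$component))
      paste(sprintf('<component id="%s"/>', e$component), collapse = "")
    else ""
    rx <- if (!is.null(e$reaction))
      sprintf(' reaction="%s"', e$reaction) else ""
    sprintf('<entry id="%s" name="%s" type="%s"%s>%s</entry>',
            id, e$name, e$type, rx, comp)
  }, character(1))
  rel <- vapply(relations, function(r) {
    sub <- if (!is.null(r$subtype))
      sprintf('<subtype name="%s" value="--&gt;"/>', r$subtype) else ""
    sprintf('<relation entry1="%s" entry2="%s" type="%s">%s</relation>',
            r$entry1, r$entry2, if (is.null(r$type)) "PPrel" else r$type, sub)
  }, character(1))
  rx <- if (!is.null(reactions)) vapply(reactions, function(r) {
    sprintf(paste0('<reaction id="%s" name="%s" type="irreversible">',
                   '<substrate id="0" name="%s"/>',
                   '<product id="0" name="%s"/></reaction>'),
            r$id, r$name, r$substrate, r$product)
  }, character(1)) else character(0)
  paste0('<?xml version="1.0"?>\n<pathway name="path:', pathway,
         '" org="tst" number="1" title="', title, '">\n',
         paste(ent, collapse = "\n"), "\n",
         paste(rel, collapse = "\n"), "\n",
         paste(rx, collapse = "\n"),
         "\n</pathway>")
}

# edge data frame shorthand
edge_df <- function(a, b, pathway = "P1", type = "activation",
                    directed = TRUE) {
  data.frame(gene_a = a, gene_b = b, directed = directed,
             interaction_type = type, pathway_id = pathway,
             stringsAsFactors = FALSE)
}

# a small expression dataset with known per-gene values
make_dataset <- function(n_genes = 50, n_case = 3, n_control = 3, seed = 1,
                         sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_case + n_control), mean = 7, sd = sd),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              c(sprintf("ca%d", seq_len(n_case)),
                                sprintf("co%d", seq_len(n_control)))))
  expression_dataset(m, c(rep("case", n_case), rep("control", n_control)))
}

# canonical unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# brute-force two-segment least-squares change point on sorted scores
brute_changepoint <- function(scores) {
  s <- sort(scores, decreasing = TRUE)
  n <- length(s)
  rss <- vapply(seq_len(n - 1), function(k) {
    sum((s[1:k] - mean(s[1:k]))^2) +
      sum((s[(k + 1):n] - mean(s[(k + 1):n]))^2)
  }, numeric(1))
  k <- which.min(rss)
  list(k = k, threshold = (s[k] + s[k + 1]) / 2)
}
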