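# ---- expression data container ---------------------------------------------

#' Construct a two-group expression dataset
#'
#' Wraps a genes-by-samples matrix of log-scale normalized expression values
#' with per-sample group labels. Exactly two groups are supported: `"case"`
#' and `"control"`, each with at least two samples.
#'
#' @param matrix Numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns.
#' @param groups Character vector (length = number of samples) of labels in
#'   `c("case", "control")`.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(matrix, groups) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("expression matrix must be numeric",
                                call. = FALSE)
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("gene ids (rownames) must be present and unique", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix))
    stop("one group label per sample is required", call. = FALSE)
  if (anyNA(groups) || !all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control' with no missing values",
         call. = FALSE)
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  structure(list(matrix = matrix, gene_ids = rownames(matrix),
                 groups = groups), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$matrix), "genes;",
      sum(x$groups == "case"), "case vs", sum(x$groups == "control"),
      "control samples\n")
  invisible(x)
}

#' Read an expression matrix and sample groups from disk
#'
#' The matrix file is TSV/CSV with gene ids in the first column and sample
#' ids in the header; the groups file is a two-column table
#' (`sample`, `group`).
#'
#' @param matrix_path Path to the expression table.
#' @param groups_path Path to the sample-to-group table.
#' @param sep Field separator (default tab).
#' @return An `expression_dataset`.
#' @export
read_expression <- function(matrix_path, groups_path, sep = "\t") {
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  grp <- utils::read.table(groups_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(grp)))
    stop("groups file needs columns 'sample' and 'group'", call. = FALSE)
  m <- match(colnames(tab), grp$sample)
  if (anyNA(m)) stop("samples missing from groups file: ",
                     paste(colnames(tab)[is.na(m)], collapse = ", "),
                     call. = FALSE)
  expression_dataset(as.matrix(tab), grp$group[m])
}

#' Write an expression dataset (matrix + groups) to disk
#' @param data An `expression_dataset`.
#' @param matrix_path,groups_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(data, matrix_path, groups_path) {
  out <- data.frame(gene_id = data$gene_ids, data$matrix,
                    check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(data$matrix), group = data$groups),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

# ---- per-gene statistics ----------------------------------------------------

#' Per-gene group means, pooled variance and residual degrees of freedom
#'
#' @param data An `expression_dataset`.
#' @return Data frame with columns `gene_id`, `mean_case`, `mean_control`,
#'   `pooled_var`, `df` (residual degrees of freedom,
#'   `n_case + n_control - 2`).
#' @export
group_stats <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  case <- data$matrix[, data$groups == "case", drop = FALSE]
  ctrl <- data$matrix[, data$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  ss1 <- rowSums((case - m1)^2)
  ss2 <- rowSums((ctrl - m2)^2)
  df <- n1 + n2 - 2L
  data.frame(gene_id = data$gene_ids, mean_case = m1, mean_control = m2,
             pooled_var = (ss1 + ss2) / df, df = df,
             n_case = n1, n_control = n2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq` of
#' the scaled inverse-chi-squared prior on per-gene variances by the
#' method-of-moments fit on log variances (the same estimator used for
#' variance shrinkage in moderated t-tests; delegated to
#' [limma::fitFDist()]). `d0 = Inf` (complete shrinkage) is returned when
#' the spread of log variances is at or below its sampling floor.
#'
#' @param variances Numeric vector of per-gene pooled variances.
#' @param df Residual degrees of freedom (scalar or per-gene vector).
#' @return List with elements `d0` and `s0_sq`.
#' @export
fit_prior <- function(variances, df) {
  variances <- as.numeric(variances)
  if (all(variances <= 0))
    stop("all variances are zero; add a variance floor before fitting ",
         "the prior", call. = FALSE)
  pos <- variances > 0
  if (sum(pos) < 2L)
    stop("at least 2 genes with positive variance are required",
         call. = FALSE)
  df <- rep_len(df, length(variances))
  fit <- limma::fitFDist(variances[pos], df1 = df[pos])
  if (is.null(fit$df2) || is.na(fit$scale))
    stop("variance prior estimation failed", call. = FALSE)
  list(d0 = fit$df2, s0_sq = fit$scale)
}

#' Moderated two-sample t-test
#'
#' Computes, for every gene, the log2 fold change (case mean minus control
#' mean, on the log2 scale), the moderated t-statistic using the
#' empirical-Bayes posterior variance
#' `(d0 * s0_sq + df * s^2) / (d0 + df)`, and a two-sided p-value from a t
#' distribution with `d0 + df` degrees of freedom (standard normal when
#' `d0` is infinite). With `d0 = 0` this is the ordinary pooled two-sample
#' t-test. Genes with zero pooled variance receive the smallest positive
#' observed variance as a floor before shrinkage; a gene with zero variance
#' and zero mean difference gets `t = 0`, `p = 1`.
#'
#' @param data An `expression_dataset`.
#' @param prior Optional list with `d0` and `s0_sq`; fitted from the data
#'   with [fit_prior()] when `NULL`.
#' @return Data frame with columns `gene_id`, `log2fc`, `t_stat`, `p_value`,
#'   `df_total`; the prior used is attached as attribute `"prior"`.
#' @export
moderated_t_test <- function(data, prior = NULL) {
  gs <- group_stats(data)
  s2 <- gs$pooled_var
  if (any(s2 <= 0)) {
    floor_val <- suppressWarnings(min(s2[s2 > 0]))
    if (!is.finite(floor_val))
      stop("all genes have zero variance; cannot form a variance floor",
           call. = FALSE)
    s2[s2 <= 0] <- floor_val
  }
  if (is.null(prior)) prior <- fit_prior(s2, gs$df)
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    post <- rep_len(s0, length(s2))
    df_total <- rep_len(Inf, length(s2))
  } else if (d0 == 0) {
    post <- s2
    df_total <- gs$df
  } else {
    post <- (d0 * s0 + gs$df * s2) / (d0 + gs$df)
    df_total <- d0 + gs$df
  }
  delta <- gs$mean_case - gs$mean_control
  se <- sqrt(post * (1 / gs$n_case + 1 / gs$n_control))
  t_stat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_stat)),
              2 * stats::pt(-abs(t_stat), df = df_total))
  out <- data.frame(gene_id = gs$gene_id, log2fc = delta, t_stat = t_stat,
                    p_value = pmin(p, 1), df_total = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  out
}

#' Read a precomputed per-gene statistics table
#'
#' Accepts externally computed differential-expression output (columns
#' `gene`/`gene_id`, `log2fc`, `p_value`).
#'
#' @param path Path to a TSV file or a data frame.
#' @return Data frame with columns `gene_id`, `log2fc`, `p_value`.
#' @export
read_stats_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if ("gene" %in% names(tab) && !"gene_id" %in% names(tab))
    names(tab)[names(tab) == "gene"] <- "gene_id"
  required <- c("gene_id", "log2fc", "p_value")
  if (!all(required %in% names(tab)))
    stop("stats table needs columns gene (or gene_id), log2fc, p_value",
         call. = FALSE)
  tab <- tab[required]
  if (nrow(tab)) {
    tab$log2fc <- as.numeric(tab$log2fc)
    tab$p_value <- as.numeric(tab$p_value)
    bad <- is.na(tab$p_value) | tab$p_value < 0 | tab$p_value > 1
    if (any(bad))
      stop("p-value outside [0,1] for gene(s): ",
           paste(tab$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Write a per-gene statistics table as TSV
#' @param stats Data frame from [moderated_t_test()] or [read_stats_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
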