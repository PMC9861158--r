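#' Gene co-dependency and co-expression correlation screening
#'
#' Matrices are plain numeric matrices with genes as rows (rownames =
#' gene ids) and cell lines as columns (colnames = cell-line ids);
#' missing entries are allowed and handled by pairwise-complete deletion.
#' An optional per-column lineage label supports within-lineage screens.
#'
#' @name codependency
NULL

#' Pearson correlation with a t-distribution p-value
#'
#' Drops incomplete pairs, then computes the sample Pearson coefficient r
#' on the remaining n pairs and a two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} against the t distribution with n - 2
#' degrees of freedom. If either vector has zero variance (or n < 3) the
#' result is flagged undefined.
#'
#' @param x,y Paired numeric vectors.
#' @param gene_a,gene_b Identifiers recorded in the result.
#' @return A one-row `data.frame(gene_a, gene_b, r, p, n, defined)`.
#' @export
pearson_with_p <- function(x, y, gene_a = "x", gene_b = "y") {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  undefined <- data.frame(gene_a = gene_a, gene_b = gene_b, r = NA_real_,
                          p = NA_real_, n = n, defined = FALSE,
                          stringsAsFactors = FALSE)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(undefined)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(gene_a = gene_a, gene_b = gene_b, r = unname(ct$estimate),
             p = ct$p.value, n = n, defined = TRUE, stringsAsFactors = FALSE)
}

#' Top co-dependent genes for an anchor gene
#'
#' Correlates the anchor gene's profile against every other gene over the
#' shared (pairwise-complete) cell lines, ranks by |r| descending with
#' ties broken by p-value then gene id, and returns the top k. The anchor
#' itself is excluded.
#'
#' @param dep Numeric matrix, genes x cell lines (rownames = gene ids).
#' @param anchor_gene Row name of the anchor gene.
#' @param k Number of partners to return (default 100; truncated to the
#'   number of other genes).
#' @return A `data.frame` of [pearson_with_p()] rows, ranked.
#' @export
top_codependent <- function(dep, anchor_gene, k = 100L) {
  stopifnot(is.matrix(dep), k >= 1L)
  if (!anchor_gene %in% rownames(dep)) {
    stop(sprintf("anchor gene '%s' not present in the matrix", anchor_gene))
  }
  others <- setdiff(rownames(dep), anchor_gene)
  res <- do.call(rbind, lapply(others, function(g)
    pearson_with_p(dep[anchor_gene, ], dep[g, ], anchor_gene, g)))
  res <- res[order(-abs(res$r), res$p, res$gene_b, na.last = TRUE), ,
             drop = FALSE]
  rownames(res) <- NULL
  head(res, min(k, nrow(res)))
}

#' Correlation screen with |r|, p and sample-size filters
#'
#' Correlates every gene row of `mat` against a single profile `b`
#' (e.g. the expression or methylation of one gene across cell lines),
#' optionally within lineage groups, and flags results passing the
#' screen: |r| > `r_cut` AND p < `p_cut` AND n > `min_n` (all strict).
#' Groups with fewer than 3 complete pairs are skipped with a message.
#'
#' A Benjamini-Hochberg adjusted p-value can be requested
#' (`adjust = "BH"`); by default raw p-values are filtered.
#'
#' @param mat Numeric matrix, genes x cell lines.
#' @param b Named numeric vector (names = cell-line ids) to screen against.
#' @param b_id Identifier for `b` in the output.
#' @param r_cut,p_cut,min_n Filter thresholds (defaults 0.4, 0.05, 10).
#' @param group_by Optional per-column lineage labels (named by cell-line
#'   id, or in column order of `mat`); when set, correlations are
#'   evaluated within each lineage.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `data.frame` with one row per gene (x lineage), columns
#'   gene_a, gene_b, r, p, n, lineage, passes_filter.
#' @export
screen_correlations <- function(mat, b, b_id = "b", r_cut = 0.4,
                                p_cut = 0.05, min_n = 10L, group_by = NULL,
                                adjust = c("none", "BH")) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)), !is.null(names(b)))
  adjust <- match.arg(adjust)
  shared <- intersect(colnames(mat), names(b))
  if (!length(shared)) stop("no shared cell lines between matrix and profile")
  groups <- if (is.null(group_by)) {
    list("all" = shared)
  } else {
    gb <- if (!is.null(names(group_by))) group_by[shared] else
      setNames(group_by, colnames(mat))[shared]
    split(shared, gb)
  }
  out <- list()
  for (lin in names(groups)) {
    cols <- groups[[lin]]
    if (sum(complete.cases(b[cols])) < 3L) {
      message(sprintf("lineage '%s' skipped: fewer than 3 samples", lin))
      next
    }
    res <- do.call(rbind, lapply(rownames(mat), function(g)
      pearson_with_p(mat[g, cols], b[cols], g, b_id)))
    res$lineage <- lin
    out[[lin]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  p_eff <- if (adjust == "BH") stats::p.adjust(res$p, method = "BH") else res$p
  res$passes_filter <- res$defined & abs(res$r) > r_cut & p_eff < p_cut &
    res$n > min_n
  res$passes_filter[is.na(res$passes_filter)] <- FALSE
  res
}

#' Read / write a genes-by-cell-lines CSV matrix
#'
#' Wide layout: first column gene ids, header row of cell-line ids —
#' the layout used by dependency-portal exports.
#'
#' @param path CSV path.
#' @param mat Numeric matrix with row and column names.
#' @return `read_matrix_csv()` returns a numeric matrix;
#'   `write_matrix_csv()` returns `path` invisibly.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
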