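# Expression normalization and miRNA-coexpressed gene groups.

#' Normalize an expression matrix
#'
#' Three normalizations are offered: `zscore` (per-entity mean 0, sd 1 with
#' the n-1 denominator; zero-variance entities are excluded with a warning
#' and recorded in attribute `excluded`), `quantile` (identical per-condition
#' sorted distributions, via limma), and `control_gene` (each condition
#' divided by an internal control's value in that condition, e.g. Actin).
#'
#' @param mat numeric matrix, rows = entities, columns = conditions.
#' @param method `"zscore"`, `"quantile"` or `"control_gene"`.
#' @param controlId row name of the control entity (required for
#'   `control_gene`; its values must all be positive).
#' @return the normalized matrix.
#' @export
normalizeExpression <- function(mat, method = c("zscore", "quantile",
                                                "control_gene"),
                                controlId = NULL) {
  method <- match.arg(method)
  if (method == "zscore") {
    sds <- apply(mat, 1, stats::sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad)) {
      warning("excluding ", length(bad),
              " zero-variance entities under zscore: ",
              paste(head(names(bad), 5), collapse = ", "))
      mat <- mat[-bad, , drop = FALSE]
      sds <- sds[-bad]
    }
    out <- (mat - rowMeans(mat)) / sds
    attr(out, "excluded") <- names(bad)
    out
  } else if (method == "quantile") {
    out <- limma::normalizeQuantiles(mat)
    dimnames(out) <- dimnames(mat)
    out
  } else {
    if (is.null(controlId) || !controlId %in% rownames(mat))
      stop("'control_gene' normalization needs a 'controlId' present in the matrix")
    ctrl <- mat[controlId, ]
    if (any(ctrl <= 0)) stop("control entity must have all-positive values")
    sweep(mat, 2, ctrl, "/")
  }
}

.checkSeries <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 conditions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant series")
}

#' Pearson's correlation coefficient
#'
#' @param x,y numeric series of equal length >= 3, both non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  .checkSeries(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @inheritParams pcc
#' @return correlation in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  .checkSeries(x, y)
  stats::cor(x, y, method = "spearman")
}

#' Genes coexpressed with a miRNA
#'
#' Correlates the miRNA's expression profile with every annotated gene and
#' returns the genes with `|correlation| >= threshold`, sorted by decreasing
#' absolute correlation (sign retained). When fewer than `minGenes` genes
#' pass, the group is relaxed to the top `minGenes` by absolute correlation
#' and flagged (`attr(., "relaxed")`). miRNAs absent from the expression
#' matrix are skipped with a warning (`NULL` return).
#'
#' @param mirnaId miRNA identifier (row of `mirnaExpr`).
#' @param mirnaExpr miRNA expression matrix (rows = miRNAs).
#' @param geneExpr gene expression matrix (rows = genes); condition columns
#'   must match `mirnaExpr` exactly.
#' @param method `"pcc"` or `"spearman"`.
#' @param threshold absolute-correlation cutoff in `(0, 1]` (default 0.9).
#' @param minGenes minimum group size before the top-k relaxation (default
#'   10).
#' @return `data.frame` with columns `gene`, `correlation`, attributes
#'   `mirna`, `method`, `threshold`, `relaxed`; or `NULL` when the miRNA has
#'   no expression record.
#' @export
coexpressedGroup <- function(mirnaId, mirnaExpr, geneExpr,
                             method = c("pcc", "spearman"), threshold = 0.9,
                             minGenes = 10L) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  if (!identical(colnames(mirnaExpr), colnames(geneExpr))) {
    d1 <- setdiff(colnames(mirnaExpr), colnames(geneExpr))
    d2 <- setdiff(colnames(geneExpr), colnames(mirnaExpr))
    stop("condition labels differ between matrices: ",
         paste(c(d1, d2), collapse = ", "))
  }
  if (!mirnaId %in% rownames(mirnaExpr)) {
    warning("miRNA ", mirnaId, " has no expression record; skipped")
    return(NULL)
  }
  prof <- mirnaExpr[mirnaId, ]
  corMethod <- if (method == "pcc") "pearson" else "spearman"
  cors <- suppressWarnings(
    stats::cor(t(geneExpr), prof, method = corMethod)[, 1])
  cors <- cors[is.finite(cors)]
  keep <- cors[abs(cors) >= threshold]
  relaxed <- FALSE
  if (length(keep) < minGenes && length(cors) >= 1L) {
    keep <- cors[order(-abs(cors))][seq_len(min(minGenes, length(cors)))]
    relaxed <- TRUE
  }
  if (length(keep) == 0L)
    warning("empty coexpression group for ", mirnaId)
  keep <- keep[order(-abs(keep))]
  out <- data.frame(gene = names(keep), correlation = unname(keep),
                    stringsAsFactors = FALSE)
  attr(out, "mirna") <- mirnaId
  attr(out, "method") <- method
  attr(out, "threshold") <- threshold
  attr(out, "relaxed") <- relaxed
  out
}
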