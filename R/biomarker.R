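## Expression-biomarker correlation with compound sensitivity.

#' Correlate gene expression with compound sensitivity across cell lines
#'
#' For every gene, correlates its expression with a per-line sensitivity
#' metric (AAC by default in the pipeline; any numeric per-line vector works)
#' over the cell lines shared between the expression matrix and the
#' sensitivity vector. Genes with constant expression across the shared
#' lines are reported with a missing coefficient and excluded from the BH
#' adjustment.
#'
#' @param expr Numeric matrix, genes x cell lines (log2 scale), with row and
#'   column names.
#' @param sensitivity Named numeric vector (cell line -> sensitivity).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_n Minimal number of shared cell lines.
#' @return Data frame: `gene`, `corr`, `p`, `q`, `n`, sorted by decreasing
#'   `corr`.
#' @export
biomarker_correlation <- function(expr, sensitivity,
                                  method = c("pearson", "spearman"),
                                  min_n = 10L) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)),
            !is.null(names(sensitivity)))
  shared <- intersect(colnames(expr), names(sensitivity)[is.finite(sensitivity)])
  if (length(shared) < min_n) {
    stop(sprintf("only %d cell lines shared between expression and sensitivity (need >= %d)",
                 length(shared), min_n), call. = FALSE)
  }
  x <- sensitivity[shared]
  m <- expr[, shared, drop = FALSE]
  n <- length(shared)

  corr <- p <- rep(NA_real_, nrow(m))
  constant <- apply(m, 1L, function(g) stats::sd(g) == 0 || !all(is.finite(g)))
  for (i in which(!constant)) {
    ct <- stats::cor.test(m[i, ], x, method = method, exact = FALSE)
    corr[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  if (any(constant)) {
    ss_log("INFO", "%d constant or non-finite genes excluded from correlation",
           sum(constant))
  }
  q <- rep(NA_real_, nrow(m))
  q[!constant] <- stats::p.adjust(p[!constant], method = "BH")
  res <- data.frame(gene = rownames(m), corr = corr, p = p, q = q, n = n,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$corr, na.last = TRUE), ]
  rownames(res) <- NULL
  res
}
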