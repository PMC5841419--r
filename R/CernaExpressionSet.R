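#' Construct a CernaExpressionSet
#'
#' @param expr numeric matrix of log2 expression values, genes in rows
#'   (rownames required), samples in columns (colnames required).
#' @param geneClass character vector (\code{"mRNA"}/\code{"lncRNA"}), one per
#'   gene, or a named vector covering all genes.
#' @param group binary 0/1 sample labels, one per column.
#'
#' @return a [CernaExpressionSet-class]
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "l1"), paste0("s", 1:4)))
#' es <- CernaExpressionSet(m, c("mRNA", "mRNA", "lncRNA"), c(0, 0, 1, 1))
#' exprMatrix(es)
#' @export
CernaExpressionSet <- function(expr, geneClass, group) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs row (gene) and column (sample) names")
  if (!is.null(names(geneClass)))
    geneClass <- geneClass[rownames(expr)]
  if (length(geneClass) != nrow(expr))
    stop("geneClass must supply one label per gene")
  if (length(group) != ncol(expr))
    stop("group must supply one label per sample")
  group <- as.integer(group)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = expr),
    rowData = S4Vectors::DataFrame(geneClass = as.character(geneClass),
                                   row.names = rownames(expr)),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = colnames(expr))
  )
  methods::new("CernaExpressionSet", se)
}

#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "CernaExpressionSet", function(x) {
  SummarizedExperiment::assay(x, "log2expr")
})

#' @rdname geneClass
#' @export
setMethod("geneClass", "CernaExpressionSet", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$geneClass, rownames(x))
})

#' @rdname sampleGroup
#' @export
setMethod("sampleGroup", "CernaExpressionSet", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$group, colnames(x))
})

setMethod("show", "CernaExpressionSet", function(object) {
  gc <- geneClass(object)
  gr <- sampleGroup(object)
  cat("CernaExpressionSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  mRNAs:", sum(gc == "mRNA"), " lncRNAs:", sum(gc == "lncRNA"), "\n")
  cat("  groups: 0 (n=", sum(gr == 0L), ") / 1 (n=", sum(gr == 1L), ")\n",
      sep = "")
})

#' Subset an expression set to one gene class
#'
#' @param x a [CernaExpressionSet-class]
#' @param class \code{"mRNA"} or \code{"lncRNA"}
#' @return a [CernaExpressionSet-class] holding only that class
#' @export
subsetByClass <- function(x, class = c("mRNA", "lncRNA")) {
  class <- match.arg(class)
  x[geneClass(x) == class, ]
}
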