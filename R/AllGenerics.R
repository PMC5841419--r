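#' Extract the log2 expression matrix
#' @param x a [CernaExpressionSet-class]
#' @return numeric matrix, genes in rows, samples in columns
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' Gene class labels
#' @param x a [CernaExpressionSet-class]
#' @return named character vector, values \code{"mRNA"} / \code{"lncRNA"}
#' @export
setGeneric("geneClass", function(x) standardGeneric("geneClass"))

#' Binary sample group labels
#' @param x a [CernaExpressionSet-class]
#' @return named integer vector of 0/1 labels
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))

#' miRNA universe size ("Total" of the shared-miRNA test)
#' @param x an [InteractionUniverse-class]
#' @return integer scalar
#' @export
setGeneric("mirnaTotal", function(x) standardGeneric("mirnaTotal"))

#' miRNA regulator set of one gene
#' @param x an [InteractionUniverse-class]
#' @param id gene id
#' @param class \code{"mRNA"} or \code{"lncRNA"}
#' @return character vector of miRNA ids (clipped to the universe; empty for
#'   genes absent from the interaction tables)
#' @export
setGeneric("targetSet", function(x, id, class) standardGeneric("targetSet"))

#' Retained competing pairs
#' @param x a [CompetingPairResult-class]
#' @return data.frame of pairs flagged as retained
#' @export
setGeneric("retainedPairs", function(x) standardGeneric("retainedPairs"))

#' Network edges
#' @param x a [CeRNANetwork-class]
#' @return data.frame with columns \code{lncrna}, \code{mrna}
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Node degrees
#' @param x a [CeRNANetwork-class]
#' @return named integer vector of node degrees
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' Panel features
#' @param x a [PanelResult-class]
#' @return character vector of feature ids
#' @export
setGeneric("panelFeatures", function(x) standardGeneric("panelFeatures"))
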