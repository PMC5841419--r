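#' @import methods
NULL

#' Expression set for ceRNA analysis
#'
#' A \linkS4class{SummarizedExperiment} specialised for two-group lncRNA/mRNA
#' ceRNA analysis. The single assay \code{"log2expr"} holds log2-scale
#' expression values; \code{rowData()$geneClass} labels every gene as
#' \code{"mRNA"} or \code{"lncRNA"}; \code{colData()$group} carries the binary
#' sample label (0 = reference group, 1 = case group).
#'
#' @seealso [CernaExpressionSet()] for the constructor, [exprMatrix()],
#'   [geneClass()], [sampleGroup()] for accessors.
#' @export
setClass("CernaExpressionSet", contains = "SummarizedExperiment")

setValidity("CernaExpressionSet", function(object) {
  msg <- character()
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2expr' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"geneClass" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'geneClass' is required")
  } else if (!all(rd$geneClass %in% c("mRNA", "lncRNA"))) {
    msg <- c(msg, "geneClass values must be 'mRNA' or 'lncRNA'")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData column 'group' is required")
  } else if (!all(cd$group %in% c(0L, 1L))) {
    msg <- c(msg, "group labels must be 0 or 1")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene ids")
  if (length(msg)) msg else TRUE
})

#' miRNA-target interaction universe
#'
#' Holds the miRNA regulator set of every mRNA and lncRNA, restricted to the
#' common miRNA universe: the intersection of the miRNAs appearing in the
#' miRNA-mRNA table and those appearing in the miRNA-lncRNA table. The size of
#' that intersection is the "Total" of the shared-miRNA hypergeometric test.
#'
#' @slot mrnaTargets named list; per-mRNA character vectors of miRNA ids
#'   (clipped to the universe).
#' @slot lncTargets named list; per-lncRNA character vectors of miRNA ids
#'   (clipped to the universe).
#' @slot universe character vector of miRNA ids common to both tables.
#'
#' @seealso [buildUniverse()], [sharedMirnaTest()]
#' @export
setClass("InteractionUniverse",
  representation(
    mrnaTargets = "list",
    lncTargets = "list",
    universe = "character"
  )
)

setValidity("InteractionUniverse", function(object) {
  msg <- character()
  if (length(object@universe) == 0L)
    msg <- c(msg, "miRNA universe is empty")
  bad <- vapply(c(object@mrnaTargets, object@lncTargets),
                function(s) !all(s %in% object@universe), logical(1))
  if (any(bad))
    msg <- c(msg, "target sets contain miRNAs outside the universe")
  if (is.null(names(object@mrnaTargets)) || is.null(names(object@lncTargets)))
    msg <- c(msg, "target lists must be named by gene id")
  if (length(msg)) msg else TRUE
})

#' Result of competing-pair identification
#'
#' @slot pairs data.frame with one row per step-1 candidate pair: columns
#'   \code{lncrna}, \code{mrna}, \code{overlap} (shared miRNA count),
#'   \code{hyper_p}, \code{pcc}, \code{retained}.
#' @slot pccThreshold realized Pearson-correlation threshold (the requested
#'   percentile of the reference correlation distribution).
#' @slot nCandidates number of candidate pairs surviving the hypergeometric
#'   step.
#' @slot pccReference which correlation distribution defined the percentile:
#'   \code{"all"} (all SDE lncRNA x mRNA pairs) or \code{"candidates"}.
#'
#' @seealso [identifyCompetingPairs()]
#' @export
setClass("CompetingPairResult",
  representation(
    pairs = "data.frame",
    pccThreshold = "numeric",
    nCandidates = "integer",
    pccReference = "character"
  )
)

#' Bipartite dysregulated lncRNA-mRNA network
#'
#' Strictly bipartite graph whose edges join one lncRNA to one mRNA; no
#' duplicate edges, no isolated nodes.
#'
#' @slot edges data.frame with character columns \code{lncrna} and
#'   \code{mrna}; one row per unique edge.
#' @slot nodeClass named character vector mapping every node id to
#'   \code{"mRNA"} or \code{"lncRNA"}.
#'
#' @seealso [buildNetwork()], [degreeStats()], [selectHubs()]
#' @export
setClass("CeRNANetwork",
  representation(
    edges = "data.frame",
    nodeClass = "character"
  )
)

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("lncrna", "mrna") %in% colnames(e)))
    msg <- c(msg, "edges must have columns 'lncrna' and 'mrna'")
  if (nrow(e)) {
    if (anyDuplicated(paste(e$lncrna, e$mrna, sep = "\r")))
      msg <- c(msg, "duplicate edges")
    if (length(intersect(e$lncrna, e$mrna)))
      msg <- c(msg, "network is not bipartite")
    nodes <- unique(c(e$lncrna, e$mrna))
    if (!all(nodes %in% names(object@nodeClass)))
      msg <- c(msg, "every node needs a class label")
    if (!all(object@nodeClass[e$lncrna] == "lncRNA") ||
        !all(object@nodeClass[e$mrna] == "mRNA"))
      msg <- c(msg, "edge endpoints disagree with node classes")
  }
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes moderated-t fit
#'
#' Hyperparameters and per-gene statistics of the moderated two-sample
#' t-test: the per-gene pooled residual variances s_g^2 (with d_g = n0+n1-2
#' degrees of freedom each) are modelled as scaled chi-square draws around a
#' prior variance s0^2 with d0 prior degrees of freedom, estimated by moment
#' matching on log s_g^2.
#'
#' @slot d0 prior degrees of freedom (may be \code{Inf}).
#' @slot s0sq prior variance.
#' @slot dg residual degrees of freedom per gene (scalar, n0+n1-2).
#' @slot sgsq named per-gene pooled residual variances.
#' @slot meanDiff named per-gene group1 - group0 mean differences.
#' @slot n0,n1 group sample sizes.
#'
#' @seealso [fitEBayes()], [moderatedTTest()]
#' @export
setClass("EBayesFit",
  representation(
    d0 = "numeric",
    s0sq = "numeric",
    dg = "numeric",
    sgsq = "numeric",
    meanDiff = "numeric",
    n0 = "integer",
    n1 = "integer"
  )
)

#' Biomarker panel evaluated under leave-one-out cross-validation
#'
#' @slot features lncRNA ids in the panel.
#' @slot accuracy held-out classification accuracy in [0, 1].
#' @slot auc area under the ROC curve of the held-out decision values.
#' @slot scores named per-sample held-out decision values (higher = more
#'   case-like).
#' @slot predicted named per-sample held-out predicted class labels.
#' @slot confusion 2x2 confusion matrix (truth in rows).
#' @slot degenerateFolds ids of held-out samples whose training fold contained
#'   a single class (predicted by majority vote).
#'
#' @seealso [loocvSvm()], [selectOptimalPanel()]
#' @export
setClass("PanelResult",
  representation(
    features = "character",
    accuracy = "numeric",
    auc = "numeric",
    scores = "numeric",
    predicted = "character",
    confusion = "matrix",
    degenerateFolds = "character"
  )
)

setValidity("PanelResult", function(object) {
  msg <- character()
  if (length(object@accuracy) != 1L || object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must be a single value in [0, 1]")
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must be a single value in [0, 1]")
  if (length(object@scores) != length(object@predicted))
    msg <- c(msg, "scores and predictions must align")
  if (length(msg)) msg else TRUE
})
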