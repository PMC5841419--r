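#' Incidence matrix of a bipartite ceRNA network
#'
#' @param net a [CeRNANetwork-class].
#' @return binary matrix, lncRNAs in rows and mRNAs in columns, both in
#'   ascending id order; 0x0 for an empty network. Row and column sums equal
#'   node degrees.
#' @export
incidenceMatrix <- function(net) {
  e <- networkEdges(net)
  if (!nrow(e))
    return(matrix(0L, 0, 0))
  rows <- sort(unique(e$lncrna))
  cols <- sort(unique(e$mrna))
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(e$lncrna, e$mrna)] <- 1L
  m
}

#' Hierarchical clustering of incidence profiles
#'
#' Agglomerative clustering with city-block (Manhattan) distance and, by
#' default, complete linkage — the combination used for ceRNA module
#' detection on the network incidence matrix.
#'
#' @param m numeric matrix.
#' @param axis cluster the \code{"rows"} or the \code{"cols"}.
#' @param metric distance metric; \code{"cityblock"} or \code{"euclidean"}.
#' @param linkage \code{"complete"}, \code{"average"} or \code{"single"}.
#' @return an \code{\link[stats]{hclust}} dendrogram.
#' @export
hierarchicalCluster <- function(m, axis = c("rows", "cols"),
                                metric = "cityblock", linkage = "complete") {
  axis <- match.arg(axis)
  if (!metric %in% c("cityblock", "euclidean"))
    stop("unsupported metric: ", metric)
  if (!linkage %in% c("complete", "average", "single"))
    stop("unsupported linkage: ", linkage)
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2L) stop("need at least 2 vectors to cluster")
  d <- stats::dist(m, method = if (metric == "cityblock") "manhattan"
                               else "euclidean")
  stats::hclust(d, method = linkage)
}

#' Extract ceRNA modules from an lncRNA dendrogram
#'
#' Cuts the lncRNA dendrogram into k clusters and assigns every mRNA to the
#' lncRNA cluster holding the majority of its edges; ties go to the cluster
#' of its highest-degree lncRNA partner, then to the lowest cluster id in
#' partner-id order.
#'
#' @param net a [CeRNANetwork-class].
#' @param rowDendrogram \code{hclust} of the incidence-matrix rows (lncRNAs),
#'   from [hierarchicalCluster()]. Ignored when the network has a single
#'   lncRNA (k must then be 1).
#' @param k number of modules, between 1 and the number of lncRNAs.
#' @return list of modules; each has \code{moduleId}, \code{lncrnas},
#'   \code{mrnas} and \code{internalEdges} (edge count inside the module).
#'   Modules without mRNAs are reported with an empty mRNA set.
#' @export
extractModules <- function(net, rowDendrogram, k) {
  e <- networkEdges(net)
  lncs <- sort(unique(e$lncrna))
  if (k < 1L || k > length(lncs))
    stop("k must lie between 1 and the number of lncRNAs")
  if (length(lncs) == 1L) {
    cl <- stats::setNames(1L, lncs)
  } else {
    cl <- stats::cutree(rowDendrogram, k = k)
    if (!all(lncs %in% names(cl)))
      stop("dendrogram labels do not cover the network's lncRNAs")
    cl <- cl[lncs]
  }
  deg <- nodeDegrees(net)
  mrnas <- sort(unique(e$mrna))
  mAssign <- vapply(mrnas, function(m) {
    partners <- e$lncrna[e$mrna == m]
    votes <- table(cl[partners])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(as.integer(top))
    # tie: cluster of the highest-degree partner, then partner id order
    partners <- partners[order(-deg[partners], partners)]
    as.integer(cl[partners[1L]])
  }, integer(1))
  lapply(sort(unique(cl)), function(b) {
    ml <- names(cl)[cl == b]
    mm <- mrnas[mAssign == b]
    list(moduleId = b,
         lncrnas = ml,
         mrnas = mm,
         internalEdges = sum(e$lncrna %in% ml & e$mrna %in% mm))
  })
}

#' Detect ceRNA modules in one call
#'
#' Convenience wrapper: incidence matrix, row clustering (city-block,
#' complete linkage) and k-cut module extraction.
#'
#' @param net a [CeRNANetwork-class].
#' @param k number of modules (default 3).
#' @return as [extractModules()].
#' @export
detectModules <- function(net, k = 3L) {
  m <- incidenceMatrix(net)
  dend <- if (nrow(m) >= 2L) hierarchicalCluster(m, "rows") else NULL
  extractModules(net, dend, k)
}
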