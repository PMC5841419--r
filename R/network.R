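#' Build the dysregulated lncRNA-mRNA network
#'
#' Merges retained competing pairs into a strictly bipartite graph: nodes are
#' the pair endpoints (classed lncRNA / mRNA), edges the unique pairs.
#'
#' @param pairs a [CompetingPairResult-class] (its retained pairs are used)
#'   or a data.frame with character columns \code{lncrna} and \code{mrna}.
#' @return a [CeRNANetwork-class]; an empty pair list gives a valid empty
#'   network.
#' @export
buildNetwork <- function(pairs) {
  if (methods::is(pairs, "CompetingPairResult")) pairs <- retainedPairs(pairs)
  if (!all(c("lncrna", "mrna") %in% colnames(pairs)))
    stop("pairs need columns 'lncrna' and 'mrna'")
  e <- unique(data.frame(lncrna = as.character(pairs$lncrna),
                         mrna = as.character(pairs$mrna),
                         stringsAsFactors = FALSE))
  if (nrow(e) && length(intersect(e$lncrna, e$mrna)))
    stop("bipartiteness violated: some ids occur as both lncRNA and mRNA")
  nodeClass <- c(
    stats::setNames(rep("lncRNA", length(unique(e$lncrna))), unique(e$lncrna)),
    stats::setNames(rep("mRNA", length(unique(e$mrna))), unique(e$mrna))
  )
  methods::new("CeRNANetwork", edges = e, nodeClass = nodeClass)
}

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "CeRNANetwork", function(x) x@edges)

#' @rdname nodeDegrees
#' @export
setMethod("nodeDegrees", "CeRNANetwork", function(x) {
  if (!nrow(x@edges)) return(stats::setNames(integer(0), character(0)))
  tab <- table(c(x@edges$lncrna, x@edges$mrna))
  stats::setNames(as.integer(tab), names(tab))
})

#' Node class labels of a network
#' @param x a [CeRNANetwork-class]
#' @return named character vector (\code{"mRNA"} / \code{"lncRNA"})
#' @export
networkNodeClass <- function(x) {
  stopifnot(methods::is(x, "CeRNANetwork"))
  x@nodeClass
}

setMethod("show", "CeRNANetwork", function(object) {
  cat("CeRNANetwork:", sum(object@nodeClass == "lncRNA"), "lncRNAs,",
      sum(object@nodeClass == "mRNA"), "mRNAs,", nrow(object@edges),
      "edges\n")
})

sampleSkewness <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x)
  m3 <- mean((x - m)^3)
  m2 <- mean((x - m)^2)
  m3 / m2^1.5
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration for small tie-free samples (combined n <= 20), normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return the two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Degree statistics of a ceRNA network
#'
#' Per-node degrees, per-class mean/min/max, a two-sided Wilcoxon rank-sum
#' test of lncRNA vs mRNA degrees, and the sample skewness of the pooled
#' degree distribution (right-skew operationalised as skewness > 0).
#'
#' @param net a non-empty [CeRNANetwork-class].
#' @return list of class \code{"DegreeSummary"}: \code{degrees} (named),
#'   \code{byClass} (data.frame: class, mean, min, max, n), \code{wilcoxonP},
#'   \code{skewness}.
#' @export
degreeStats <- function(net) {
  deg <- nodeDegrees(net)
  if (!length(deg)) stop("network is empty")
  cls <- networkNodeClass(net)[names(deg)]
  byClass <- do.call(rbind, lapply(c("lncRNA", "mRNA"), function(cl) {
    d <- deg[cls == cl]
    data.frame(class = cl, mean = mean(d), min = min(d), max = max(d),
               n = length(d), stringsAsFactors = FALSE)
  }))
  out <- list(
    degrees = deg,
    byClass = byClass,
    wilcoxonP = wilcoxonRankSum(deg[cls == "lncRNA"], deg[cls == "mRNA"]),
    skewness = sampleSkewness(as.numeric(deg))
  )
  class(out) <- "DegreeSummary"
  out
}

#' @export
print.DegreeSummary <- function(x, ...) {
  cat("Degree summary (", length(x$degrees), " nodes)\n", sep = "")
  df <- x$byClass
  df$mean <- round(df$mean, 2)
  print(df, row.names = FALSE)
  cat("lncRNA vs mRNA Wilcoxon p =", signif(x$wilcoxonP, 3),
      "; skewness =", signif(x$skewness, 3), "\n")
  invisible(x)
}

#' Select hub nodes
#'
#' Ranks nodes by degree (descending, ties broken by id for a deterministic
#' order), takes k = ceiling(fraction x node count), and returns every node
#' whose degree reaches the k-th ranked degree — ties at the cutoff are
#' included.
#'
#' @param net a non-empty [CeRNANetwork-class].
#' @param fraction top fraction of nodes, in (0, 1].
#' @return data.frame with columns \code{id}, \code{class}, \code{degree},
#'   ordered by (degree desc, id asc).
#' @export
selectHubs <- function(net, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  deg <- nodeDegrees(net)
  if (!length(deg)) stop("network is empty")
  ord <- order(-deg, names(deg))
  deg <- deg[ord]
  k <- ceiling(fraction * length(deg))
  cutoff <- deg[k]
  keep <- deg >= cutoff
  data.frame(id = names(deg)[keep],
             class = unname(networkNodeClass(net)[names(deg)[keep]]),
             degree = unname(deg[keep]), stringsAsFactors = FALSE)
}
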