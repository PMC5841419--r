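#' Build the shared-miRNA interaction universe
#'
#' The miRNA universe ("Total" of the shared-miRNA test) is the intersection
#' of the miRNAs occurring in the miRNA-mRNA table and those occurring in the
#' miRNA-lncRNA table; every per-gene regulator set is clipped to it. Genes
#' whose clipped set is empty are retained with an empty set (their pair
#' tests yield overlap 0, p = 1).
#'
#' @param mirnaMrna,mirnaLncrna two-column data.frames; first column miRNA
#'   id, second column target gene id. Duplicated rows are ignored.
#' @return an [InteractionUniverse-class].
#' @export
buildUniverse <- function(mirnaMrna, mirnaLncrna) {
  asPairs <- function(tab, what) {
    if (ncol(tab) < 2L || !nrow(tab))
      stop("the ", what, " table must be a non-empty 2-column table")
    data.frame(mirna = as.character(tab[[1]]),
               target = as.character(tab[[2]]), stringsAsFactors = FALSE)
  }
  tm <- unique(asPairs(mirnaMrna, "miRNA-mRNA"))
  tl <- unique(asPairs(mirnaLncrna, "miRNA-lncRNA"))
  universe <- intersect(unique(tm$mirna), unique(tl$mirna))
  if (!length(universe))
    stop("the two interaction tables share no miRNAs; the test is undefined")
  clip <- function(tab) {
    tab <- tab[tab$mirna %in% universe, , drop = FALSE]
    sets <- split(tab$mirna, tab$target)
    lapply(sets, unique)
  }
  mSets <- clip(tm)
  lSets <- clip(tl)
  # genes emptied by clipping are kept with N = 0
  allM <- unique(tm$target); allL <- unique(tl$target)
  mSets[setdiff(allM, names(mSets))] <- list(character(0))
  lSets[setdiff(allL, names(lSets))] <- list(character(0))
  methods::new("InteractionUniverse", mrnaTargets = mSets, lncTargets = lSets,
               universe = universe)
}

#' @rdname mirnaTotal
#' @export
setMethod("mirnaTotal", "InteractionUniverse", function(x) length(x@universe))

#' @rdname targetSet
#' @export
setMethod("targetSet", "InteractionUniverse", function(x, id, class) {
  sets <- switch(class, mRNA = x@mrnaTargets, lncRNA = x@lncTargets,
                 stop("class must be 'mRNA' or 'lncRNA'"))
  if (id %in% names(sets)) sets[[id]] else character(0)
})

setMethod("show", "InteractionUniverse", function(object) {
  cat("InteractionUniverse: Total =", length(object@universe), "miRNAs\n")
  cat("  mRNAs:", length(object@mrnaTargets),
      " lncRNAs:", length(object@lncTargets), "\n")
})

#' Cumulative hypergeometric test for shared miRNA regulators
#'
#' Tests whether an mRNA and an lncRNA share more miRNA regulators than
#' expected by chance within the common universe: with N_mRNA and N_lnc the
#' clipped regulator-set sizes and Total the universe size, the p-value sums
#' C(N_mRNA, i) C(Total - N_mRNA, N_lnc - i) / C(Total, N_lnc) from the
#' observed overlap up to min(N_mRNA, N_lnc), in log space.
#'
#' @param mrnaId,lncrnaId gene ids (genes absent from the tables have empty
#'   sets and give overlap 0, p = 1).
#' @param universe an [InteractionUniverse-class].
#' @return list with \code{overlap} and \code{p}.
#' @export
sharedMirnaTest <- function(mrnaId, lncrnaId, universe) {
  sm <- targetSet(universe, mrnaId, "mRNA")
  sl <- targetSet(universe, lncrnaId, "lncRNA")
  ov <- length(intersect(sm, sl))
  p <- hyperUpperTail(ov, length(sm), length(sl), mirnaTotal(universe))
  list(overlap = ov, p = p)
}

#' Pearson correlation of two expression vectors
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the product-moment correlation.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("at least 3 samples are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant vector")
  stats::cor(x, y)
}

#' Identify dysregulated lncRNA-mRNA competing pairs
#'
#' Two-step screen over all SDE lncRNA x SDE mRNA pairs. Step 1 keeps
#' candidate pairs whose shared-miRNA hypergeometric p-value is below
#' \code{hyperAlpha}. Step 2 computes Pearson correlations across all samples
#' of the contrast, takes the \code{pccPercentile}-th percentile of the
#' reference correlation distribution as the threshold, and retains candidate
#' pairs that are positively correlated above it (strictly). The reference
#' distribution is, by default, the correlations of all SDE lncRNA x mRNA
#' pairs (\code{pccReference = "all"}); \code{"candidates"} restricts it to
#' the step-1 survivors.
#'
#' @param sdeMrnas,sdeLncrnas character vectors of SDE gene ids.
#' @param universe an [InteractionUniverse-class].
#' @param expr a [CernaExpressionSet-class] (or numeric matrix) containing
#'   all SDE genes.
#' @param hyperAlpha step-1 significance level.
#' @param pccPercentile percentile (0-100) defining the correlation
#'   threshold; computed with linear interpolation between order statistics.
#' @param pccReference \code{"all"} or \code{"candidates"}; see above.
#' @return a [CompetingPairResult-class]. If no pair survives step 1 the
#'   result is empty, with a warning.
#' @export
identifyCompetingPairs <- function(sdeMrnas, sdeLncrnas, universe, expr,
                                   hyperAlpha = 0.05, pccPercentile = 95,
                                   pccReference = c("all", "candidates")) {
  pccReference <- match.arg(pccReference)
  if (!length(sdeMrnas) || !length(sdeLncrnas))
    stop("both SDE lists must be non-empty")
  mat <- if (methods::is(expr, "CernaExpressionSet")) exprMatrix(expr)
         else as.matrix(expr)
  missing <- setdiff(c(sdeMrnas, sdeLncrnas), rownames(mat))
  if (length(missing))
    stop("expression matrix lacks SDE genes: ",
         paste(utils::head(missing, 5), collapse = ", "))

  total <- mirnaTotal(universe)
  mSets <- lapply(sdeMrnas, targetSet, x = universe, class = "mRNA")
  lSets <- lapply(sdeLncrnas, targetSet, x = universe, class = "lncRNA")
  # overlap counts for every pair via 0/1 membership matrices
  memb <- function(sets) {
    m <- matrix(0L, length(sets), total,
                dimnames = list(NULL, universe@universe))
    for (i in seq_along(sets))
      if (length(sets[[i]])) m[i, sets[[i]]] <- 1L
    m
  }
  Mm <- memb(mSets); Ml <- memb(lSets)
  ov <- Ml %*% t(Mm) # lnc x mrna
  nM <- lengths(mSets); nL <- lengths(lSets)

  grid <- expand.grid(li = seq_along(sdeLncrnas), mi = seq_along(sdeMrnas))
  pv <- hyperUpperTailVec(ov[cbind(grid$li, grid$mi)], nL[grid$li],
                          nM[grid$mi], total)
  pcc <- stats::cor(t(mat[sdeLncrnas, , drop = FALSE]),
                    t(mat[sdeMrnas, , drop = FALSE]))
  allPcc <- pcc[cbind(grid$li, grid$mi)]

  isCand <- pv < hyperAlpha
  refPcc <- if (pccReference == "all") allPcc else allPcc[isCand]
  threshold <- if (length(refPcc))
    unname(stats::quantile(refPcc, pccPercentile / 100, type = 7))
  else NA_real_

  cand <- data.frame(
    lncrna = sdeLncrnas[grid$li[isCand]],
    mrna = sdeMrnas[grid$mi[isCand]],
    overlap = as.integer(ov[cbind(grid$li, grid$mi)][isCand]),
    hyper_p = pv[isCand],
    pcc = allPcc[isCand],
    stringsAsFactors = FALSE
  )
  if (!nrow(cand)) {
    warning("no candidate pair survived the hypergeometric step")
    cand$retained <- logical(0)
  } else {
    cand$retained <- cand$pcc > max(threshold, 0)
  }
  methods::new("CompetingPairResult", pairs = cand,
               pccThreshold = as.numeric(threshold),
               nCandidates = nrow(cand), pccReference = pccReference)
}

#' @rdname retainedPairs
#' @export
setMethod("retainedPairs", "CompetingPairResult", function(x) {
  x@pairs[x@pairs$retained, , drop = FALSE]
})

#' Realized correlation threshold of a pair screen
#' @param x a [CompetingPairResult-class]
#' @return numeric scalar (NA when no reference correlations existed)
#' @export
pccThreshold <- function(x) {
  stopifnot(methods::is(x, "CompetingPairResult"))
  x@pccThreshold
}

setMethod("show", "CompetingPairResult", function(object) {
  cat("CompetingPairResult:", object@nCandidates, "candidates,",
      sum(object@pairs$retained), "retained\n")
  cat("  PCC threshold:", signif(object@pccThreshold, 4),
      "(reference:", object@pccReference, ")\n")
})
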