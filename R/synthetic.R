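#' Configuration for the synthetic ceRNA study generator
#'
#' Defines a two-group expression study with planted ceRNA structure: a set
#' of lncRNA-mRNA pairs that share exactly \code{sharedK} miRNA regulators by
#' construction and whose expression profiles are driven by a shared latent
#' factor with target correlation \code{rho}. Planted pairs are grouped into
#' \code{nModules} blocks; pairs within a block share the same miRNA set and
#' the same latent factor, giving block-level module ground truth. Block miRNA
#' sets are mutually disjoint, so pairs straddling two blocks behave as null
#' pairs under the shared-miRNA test.
#'
#' @param nMirna number of miRNAs in the universe.
#' @param nMrna,nLncrna gene counts per class.
#' @param perGeneTargets mean miRNA-set size per gene (set sizes are drawn
#'   Poisson around this mean, truncated to at least 1).
#' @param nPlantedPairs number of planted lncRNA-mRNA pairs (0 = pure null).
#' @param sharedK shared-miRNA count per planted pair.
#' @param nModules number of planted blocks the pairs are grouped into.
#' @param nGroup0,nGroup1 sample counts per class.
#' @param effectSize mean log2 shift of differentially expressed genes in
#'   group 1.
#' @param rho target within-pair expression correlation, in [0, 1).
#' @param noiseSd residual standard deviation (log2 units).
#' @param deFrac fraction of non-planted genes that receive the differential
#'   effect (random sign); planted genes always receive it (one sign per
#'   block).
#' @param seed RNG seed (integer).
#'
#' @return a validated list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(nMirna = 100, nMrna = 50, nLncrna = 20,
#'                        nPlantedPairs = 4, sharedK = 10, seed = 1)
#' @export
syntheticConfig <- function(nMirna = 200L, nMrna = 300L, nLncrna = 60L,
                            perGeneTargets = 15L, nPlantedPairs = 12L,
                            sharedK = 10L, nModules = 1L,
                            nGroup0 = 25L, nGroup1 = 25L,
                            effectSize = 2, rho = 0.9, noiseSd = 1,
                            deFrac = 0.35, seed = 1L) {
  cfg <- list(nMirna = as.integer(nMirna), nMrna = as.integer(nMrna),
              nLncrna = as.integer(nLncrna),
              perGeneTargets = perGeneTargets,
              nPlantedPairs = as.integer(nPlantedPairs),
              sharedK = as.integer(sharedK), nModules = as.integer(nModules),
              nGroup0 = as.integer(nGroup0), nGroup1 = as.integer(nGroup1),
              effectSize = effectSize, rho = rho, noiseSd = noiseSd,
              deFrac = deFrac, seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  with(cfg, {
    if (any(c(nMirna, nMrna, nLncrna, nGroup0, nGroup1, nModules) <= 0L))
      stop("invalid config: all counts must be positive")
    if (nPlantedPairs < 0L)
      stop("invalid config: nPlantedPairs must be >= 0")
    if (sharedK > nMirna)
      stop("invalid config: sharedK exceeds the miRNA universe size")
    if (sharedK > perGeneTargets)
      stop("invalid config: sharedK exceeds perGeneTargets")
    if (rho < 0 || rho >= 1)
      stop("invalid config: rho must be in [0, 1)")
    if (noiseSd <= 0)
      stop("invalid config: noiseSd must be positive")
    if (deFrac < 0 || deFrac > 1)
      stop("invalid config: deFrac must be in [0, 1]")
    if (nPlantedPairs > 0L) {
      if (nPlantedPairs > min(nMrna, nLncrna))
        stop("invalid config: more planted pairs than genes of a class")
      if (nModules > nPlantedPairs)
        stop("invalid config: more modules than planted pairs")
      if (nModules * sharedK > nMirna)
        stop("invalid config: disjoint block miRNA sets do not fit the universe")
    }
    invisible(TRUE)
  })
}

mirnaIds <- function(n) sprintf("miR-%04d", seq_len(n))
mrnaIds <- function(n) sprintf("M%04d", seq_len(n))
lncIds <- function(n) sprintf("L%04d", seq_len(n))

# Poisson set size, truncated to [1, nMirna]
drawSetSizes <- function(n, mean, nMirna) {
  pmin(pmax(stats::rpois(n, mean), 1L), nMirna)
}

#' Generate miRNA-target interaction tables with planted shared structure
#'
#' Every gene receives a miRNA regulator set drawn uniformly at random with
#' Poisson(\code{perGeneTargets}) size. The two genes of a planted pair both
#' receive their block's \code{sharedK}-miRNA set plus random filler miRNAs
#' drawn from outside all block sets, so planted pairs share exactly
#' \code{sharedK} miRNAs by construction (up to rare coincidental filler
#' overlap) and cross-block pairs share none through the planted sets.
#'
#' @param cfg a [syntheticConfig()] object.
#' @return a list with \code{mirnaMrna} and \code{mirnaLncrna} two-column
#'   data.frames (\code{mirna}, \code{target}), and \code{truth}, a
#'   \code{"PlantedTruth"} list holding \code{pairs} (lncrna, mrna, block,
#'   shared miRNA ids), \code{deGenes} (gene, sign) and \code{blockGenes}
#'   (planted gene to block map).
#' @export
generateInteractions <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  validateSyntheticConfig(cfg)
  set.seed(cfg$seed)
  mirnas <- mirnaIds(cfg$nMirna)
  mrnas <- mrnaIds(cfg$nMrna)
  lncs <- lncIds(cfg$nLncrna)

  nP <- cfg$nPlantedPairs
  plantedL <- character(0); plantedM <- character(0); blockOf <- integer(0)
  blockSets <- list()
  fillerPool <- mirnas
  if (nP > 0L) {
    plantedL <- sample(lncs, nP)
    plantedM <- sample(mrnas, nP)
    blockOf <- rep_len(seq_len(cfg$nModules), nP)
    shuffled <- sample(mirnas)
    for (b in seq_len(cfg$nModules))
      blockSets[[b]] <- shuffled[((b - 1L) * cfg$sharedK + 1L):(b * cfg$sharedK)]
    fillerPool <- setdiff(mirnas, unlist(blockSets))
  }

  geneSet <- function(planted, block) {
    size <- drawSetSizes(1L, cfg$perGeneTargets, cfg$nMirna)
    if (!planted) return(sample(mirnas, size))
    extra <- max(0L, size - cfg$sharedK)
    extra <- min(extra, length(fillerPool))
    c(blockSets[[block]],
      if (extra > 0L) sample(fillerPool, extra) else character(0))
  }

  mrnaSets <- vector("list", cfg$nMrna); names(mrnaSets) <- mrnas
  lncSets <- vector("list", cfg$nLncrna); names(lncSets) <- lncs
  mBlock <- stats::setNames(rep(NA_integer_, cfg$nMrna), mrnas)
  lBlock <- stats::setNames(rep(NA_integer_, cfg$nLncrna), lncs)
  mBlock[plantedM] <- blockOf
  lBlock[plantedL] <- blockOf
  for (g in mrnas) mrnaSets[[g]] <- geneSet(!is.na(mBlock[[g]]), mBlock[[g]])
  for (g in lncs) lncSets[[g]] <- geneSet(!is.na(lBlock[[g]]), lBlock[[g]])

  # differential-expression ground truth: planted genes always shifted (one
  # sign per block); a deFrac fraction of the rest shifted with random sign
  blockSign <- if (nP > 0L) sample(c(-1, 1), cfg$nModules, replace = TRUE)
               else numeric(0)
  deGene <- character(0); deSign <- numeric(0)
  if (nP > 0L) {
    deGene <- c(plantedM, plantedL)
    deSign <- c(blockSign[blockOf], blockSign[blockOf])
  }
  others <- setdiff(c(mrnas, lncs), deGene)
  pick <- others[stats::runif(length(others)) < cfg$deFrac]
  deGene <- c(deGene, pick)
  deSign <- c(deSign, sample(c(-1, 1), length(pick), replace = TRUE))

  truth <- list(
    pairs = if (nP > 0L)
      data.frame(lncrna = plantedL, mrna = plantedM, block = blockOf,
                 shared = I(blockSets[blockOf]), stringsAsFactors = FALSE)
    else data.frame(lncrna = character(0), mrna = character(0),
                    block = integer(0)),
    deGenes = data.frame(gene = deGene, sign = deSign,
                         stringsAsFactors = FALSE),
    blockGenes = if (nP > 0L)
      data.frame(gene = c(plantedL, plantedM),
                 class = rep(c("lncRNA", "mRNA"), each = nP),
                 block = c(blockOf, blockOf), stringsAsFactors = FALSE)
    else data.frame(gene = character(0), class = character(0),
                    block = integer(0)),
    blockSets = blockSets,
    config = cfg
  )
  class(truth) <- "PlantedTruth"

  toTable <- function(sets) {
    data.frame(
      mirna = unlist(sets, use.names = FALSE),
      target = rep(names(sets), lengths(sets)),
      stringsAsFactors = FALSE
    )
  }
  list(mirnaMrna = unique(toTable(mrnaSets)),
       mirnaLncrna = unique(toTable(lncSets)),
       truth = truth)
}

#' Generate a two-group expression matrix with planted correlation structure
#'
#' Non-planted genes are independent Gaussian noise around a constant
#' baseline. Genes of planted block b are generated from the block's latent
#' factor z_b as x = sqrt(rho) z_b + sqrt(1 - rho) eps (scaled by
#' \code{noiseSd}), so within-block pairs have expected Pearson correlation
#' \code{rho}. Differentially expressed genes have their group-1 mean shifted
#' by the signed \code{effectSize}.
#'
#' @param cfg a [syntheticConfig()] object.
#' @param truth the \code{"PlantedTruth"} produced under the same config.
#' @return a [CernaExpressionSet-class]; group labels are in
#'   \code{sampleGroup()}.
#' @export
generateExpression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SyntheticConfig"), inherits(truth, "PlantedTruth"))
  mrnas <- mrnaIds(cfg$nMrna)
  lncs <- lncIds(cfg$nLncrna)
  genes <- c(mrnas, lncs)
  if (!all(truth$blockGenes$gene %in% genes) ||
      !all(truth$deGenes$gene %in% genes))
    stop("truth references genes outside the configured dimensions")

  set.seed(cfg$seed + 1L)
  n <- cfg$nGroup0 + cfg$nGroup1
  samples <- sprintf("S%03d", seq_len(n))
  group <- c(rep(0L, cfg$nGroup0), rep(1L, cfg$nGroup1))

  eps <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, samples))
  x <- eps
  nBlocks <- length(truth$blockSets)
  if (nBlocks > 0L) {
    z <- matrix(stats::rnorm(nBlocks * n), nBlocks, n)
    bg <- truth$blockGenes
    for (i in seq_len(nrow(bg))) {
      g <- bg$gene[i]; b <- bg$block[i]
      x[g, ] <- sqrt(cfg$rho) * z[b, ] + sqrt(1 - cfg$rho) * eps[g, ]
    }
  }
  x <- 7 + cfg$noiseSd * x
  if (nrow(truth$deGenes)) {
    shift <- cfg$effectSize * truth$deGenes$sign
    x[truth$deGenes$gene, group == 1L] <-
      x[truth$deGenes$gene, group == 1L, drop = FALSE] + shift
  }
  classes <- c(rep("mRNA", cfg$nMrna), rep("lncRNA", cfg$nLncrna))
  CernaExpressionSet(x, classes, group)
}

#' Run the whole synthetic generator
#'
#' @param cfg a [syntheticConfig()] object.
#' @return list with \code{expr} ([CernaExpressionSet-class]),
#'   \code{mirnaMrna}, \code{mirnaLncrna} interaction tables and \code{truth}.
#' @export
simulateCeRNAStudy <- function(cfg) {
  ia <- generateInteractions(cfg)
  expr <- generateExpression(cfg, ia$truth)
  list(expr = expr, mirnaMrna = ia$mirnaMrna, mirnaLncrna = ia$mirnaLncrna,
       truth = ia$truth)
}
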