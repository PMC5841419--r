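#' Pipeline configuration
#'
#' Collects the file paths and thresholds of a full occurrence- or
#' recurrence-style run. Occurrence vs recurrence differ only in the labels
#' file and the DE threshold (0.01 vs 0.05 in the motivating study design);
#' there is a single code path.
#'
#' @param expression,labels,geneClasses,mirnaMrna,mirnaLncrna input TSV
#'   paths (see [readExpression()], [readLabels()], [readGeneClasses()],
#'   [readInteractions()]).
#' @param gmt optional GMT path for the enrichment stage.
#' @param outDir output directory.
#' @param deP raw-p DE threshold.
#' @param hyperAlpha,pccPercentile,pccReference pair-screen settings
#'   (see [identifyCompetingPairs()]).
#' @param hubFraction top-degree fraction for hub selection.
#' @param moduleK number of ceRNA modules to extract.
#' @param targetK random-forest elimination stop size.
#' @param seed RNG seed for the stochastic biomarker stage.
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(expression, labels, geneClasses, mirnaMrna,
                           mirnaLncrna, gmt = NULL, outDir = "cerna_out",
                           deP = 0.01, hyperAlpha = 0.05, pccPercentile = 95,
                           pccReference = "all", hubFraction = 0.05,
                           moduleK = 3L, targetK = 7L, seed = 1L) {
  cfg <- list(expression = expression, labels = labels,
              geneClasses = geneClasses, mirnaMrna = mirnaMrna,
              mirnaLncrna = mirnaLncrna, gmt = gmt, outDir = outDir,
              deP = deP, hyperAlpha = hyperAlpha,
              pccPercentile = pccPercentile, pccReference = pccReference,
              hubFraction = hubFraction, moduleK = as.integer(moduleK),
              targetK = as.integer(targetK), seed = as.integer(seed))
  if (deP <= 0 || deP >= 1 || hyperAlpha <= 0 || hyperAlpha >= 1)
    stop("p-value thresholds must lie in (0, 1)")
  if (pccPercentile <= 0 || pccPercentile >= 100)
    stop("pccPercentile must lie in (0, 100)")
  if (hubFraction <= 0 || hubFraction > 1)
    stop("hubFraction must lie in (0, 1]")
  for (f in c("expression", "labels", "geneClasses", "mirnaMrna",
              "mirnaLncrna"))
    if (!file.exists(cfg[[f]])) stop("missing input file for ", f, ": ",
                                     cfg[[f]])
  if (!is.null(gmt) && !file.exists(gmt)) stop("missing GMT file: ", gmt)
  class(cfg) <- "PipelineConfig"
  cfg
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full ceRNA-network pipeline
#'
#' Stages, in order: differential expression (moderated t), competing-pair
#' identification (shared-miRNA test + correlation screen), network
#' construction and degree/hub analysis, ceRNA module extraction, optional
#' gene-set overrepresentation of the network mRNAs, and lncRNA biomarker
#' panel selection. Every stage's tables are written under \code{outDir};
#' a JSON manifest records thresholds, seeds, input checksums and stage
#' summaries. A stage failure aborts with the stage name after writing the
#' partial manifest.
#'
#' @param cfg a [pipelineConfig()].
#' @return the manifest, invisibly a list (also written to
#'   \code{outDir/manifest.json}).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(cfg$expression, cfg$labels, cfg$geneClasses, cfg$mirnaMrna,
              cfg$mirnaLncrna, cfg$gmt)
  manifest <- list(
    package = as.character(utils::packageVersion("ceRNAnet")),
    seed = cfg$seed,
    thresholds = cfg[c("deP", "hyperAlpha", "pccPercentile", "pccReference",
                       "hubFraction", "moduleK", "targetK")],
    inputChecksums = as.list(tools::md5sum(inputs)),
    stages = list()
  )
  finish <- function() {
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$error <<- paste0("stage '", name, "' failed: ",
                                conditionMessage(e))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- res$summary
    res$value
  }

  expr <- readExpression(cfg$expression)
  labels <- readLabels(cfg$labels)
  classes <- readGeneClasses(cfg$geneClasses)
  if (!setequal(colnames(expr), names(labels)))
    stop("expression samples and label samples do not match")
  if (!all(rownames(expr) %in% names(classes)))
    stop("gene classes missing for some expression genes")
  labels <- labels[colnames(expr)]
  es <- CernaExpressionSet(expr, classes[rownames(expr)], labels)
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (min(n0, n1) < 10L)
    manifest$imbalanceCaveat <-
      paste0("small/imbalanced groups (", n0, " vs ", n1,
             "): cross-validated accuracy concentrates near the ",
             "majority-class rate under the null")

  de <- stage("diffexpr", function() {
    res <- moderatedTTest(es)
    res$class <- unname(geneClass(es)[res$gene_id])
    sel <- selectSDE(res, cfg$deP)
    writeTsv(res, file.path(cfg$outDir, "de_table.tsv"))
    writeTsv(sel$sde, file.path(cfg$outDir, "sde_genes.tsv"))
    list(value = sel,
         summary = list(nSDE = sel$n, nUp = sel$nUp, nDown = sel$nDown,
                        nSDEmRNA = sum(sel$sde$class == "mRNA"),
                        nSDElncRNA = sum(sel$sde$class == "lncRNA")))
  })

  pairs <- stage("cerna_pairs", function() {
    u <- buildUniverse(readInteractions(cfg$mirnaMrna),
                       readInteractions(cfg$mirnaLncrna))
    sdeM <- de$sde$gene_id[de$sde$class == "mRNA"]
    sdeL <- de$sde$gene_id[de$sde$class == "lncRNA"]
    cp <- identifyCompetingPairs(sdeM, sdeL, u, es,
                                 hyperAlpha = cfg$hyperAlpha,
                                 pccPercentile = cfg$pccPercentile,
                                 pccReference = cfg$pccReference)
    writeTsv(cp@pairs, file.path(cfg$outDir, "competing_pairs.tsv"))
    list(value = cp,
         summary = list(total = mirnaTotal(u), nCandidates = cp@nCandidates,
                        nRetained = sum(cp@pairs$retained),
                        pccThreshold = cp@pccThreshold))
  })

  net <- stage("network", function() {
    nw <- buildNetwork(pairs)
    if (!nrow(networkEdges(nw)))
      return(list(value = nw, summary = list(nNodes = 0L, nEdges = 0L)))
    ds <- degreeStats(nw)
    hubs <- selectHubs(nw, cfg$hubFraction)
    deg <- nodeDegrees(nw)
    nodeTab <- data.frame(id = names(deg),
                          class = unname(networkNodeClass(nw)[names(deg)]),
                          degree = unname(deg),
                          is_hub = names(deg) %in% hubs$id,
                          stringsAsFactors = FALSE)
    writeTsv(networkEdges(nw), file.path(cfg$outDir, "edges.tsv"))
    writeTsv(nodeTab, file.path(cfg$outDir, "nodes.tsv"))
    list(value = nw,
         summary = list(nNodes = length(deg),
                        nEdges = nrow(networkEdges(nw)),
                        meanDegree = as.list(stats::setNames(
                          ds$byClass$mean, ds$byClass$class)),
                        wilcoxonP = ds$wilcoxonP,
                        skewness = ds$skewness,
                        hubs = hubs$id))
  })

  mods <- stage("modules", function() {
    e <- networkEdges(net)
    nL <- length(unique(e$lncrna))
    if (nL < 1L)
      return(list(value = list(), summary = list(nModules = 0L)))
    k <- min(cfg$moduleK, nL)
    ml <- detectModules(net, k = k)
    memb <- do.call(rbind, lapply(ml, function(m)
      data.frame(module = m$moduleId,
                 id = c(m$lncrnas, m$mrnas),
                 class = c(rep("lncRNA", length(m$lncrnas)),
                           rep("mRNA", length(m$mrnas))),
                 stringsAsFactors = FALSE)))
    writeTsv(memb, file.path(cfg$outDir, "modules.tsv"))
    list(value = ml,
         summary = list(nModules = length(ml), k = k,
                        sizes = vapply(ml, function(m)
                          length(m$lncrnas) + length(m$mrnas), integer(1))))
  })

  if (!is.null(cfg$gmt)) {
    stage("enrichment", function() {
      sets <- readGmt(cfg$gmt)
      uni <- rownames(expr)[classes[rownames(expr)] == "mRNA"]
      coll <- suppressWarnings(geneSetCollection(sets, uni))
      query <- unique(networkEdges(net)$mrna)
      tab <- enrich(query, coll)
      writeTsv(tab, file.path(cfg$outDir, "enrichment.tsv"))
      list(value = tab,
           summary = list(nSets = nrow(tab),
                          nSignificant = sum(tab$significant)))
    })
  }

  stage("biomarkers", function() {
    lncs <- unique(networkEdges(net)$lncrna)
    if (length(lncs) < 2L)
      return(list(value = NULL,
                  summary = list(skipped = "fewer than 2 network lncRNAs")))
    xl <- exprMatrix(es)[lncs, , drop = FALSE]
    panel <- selectOptimalPanel(xl, labels, targetK = cfg$targetK,
                                seed = cfg$seed)
    writeTsv(panel$table, file.path(cfg$outDir, "panel_ranking.tsv"))
    writeTsv(data.frame(sample = names(panel$best@scores),
                        score = unname(panel$best@scores),
                        predicted = unname(panel$best@predicted),
                        truth = unname(labels[names(panel$best@scores)])),
             file.path(cfg$outDir, "panel_scores.tsv"))
    jsonlite::write_json(
      list(features = panel$best@features,
           accuracy = panel$best@accuracy, auc = panel$best@auc),
      file.path(cfg$outDir, "best_panel.json"), auto_unbox = TRUE,
      digits = NA)
    list(value = panel,
         summary = list(nInput = length(lncs),
                        nRetained = length(panel$trace$finalFeatures),
                        nSubsets = nrow(panel$table),
                        bestFeatures = panel$best@features,
                        accuracy = panel$best@accuracy,
                        auc = panel$best@auc))
  })

  finish()
  invisible(manifest)
}
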