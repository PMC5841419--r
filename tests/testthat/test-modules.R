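test_that("incidence matrix is deterministic with degree marginals", {
  pairs <- data.frame(lncrna = c("L1", "L1", "L2"),
                      mrna = c("M1", "M2", "M3"))
  net <- buildNetwork(pairs)
  m <- incidenceMatrix(net)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(rowSums(m)), c(2, 1))
  expect_equal(rownames(m), c("L1", "L2"))
  deg <- nodeDegrees(net)
  expect_equal(rowSums(m), deg[rownames(m)])
  expect_equal(colSums(m), deg[colnames(m)])
  # complete bipartite K(2,3): all ones
  k23 <- buildNetwork(expand.grid(lncrna = c("L1", "L2"),
                                  mrna = c("M1", "M2", "M3"),
                                  stringsAsFactors = FALSE))
  expect_true(all(incidenceMatrix(k23) == 1L))
  # empty network: 0 x 0
  empty <- buildNetwork(data.frame(lncrna = character(0),
                                   mrna = character(0)))
  expect_equal(dim(incidenceMatrix(empty)), c(0L, 0L))
})

test_that("city-block complete-linkage merges at the expected heights", {
  m <- rbind(a = c(1, 0, 1), b = c(0, 0, 1))
  h <- hierarchicalCluster(m)
  expect_equal(h$height, 1)
  m2 <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
  expect_equal(hierarchicalCluster(m2)$height, 0)
  expect_error(hierarchicalCluster(m, metric = "cosine"), "metric")
  expect_error(hierarchicalCluster(m, linkage = "ward"), "linkage")
  expect_error(hierarchicalCluster(m[1, , drop = FALSE]), "at least 2")
})

test_that("a planted 2-block binary matrix is recovered exactly at k = 2", {
  m <- rbind(matrix(rep(c(rep(1, 5), rep(0, 5)), 5), 5, 10, byrow = TRUE),
             matrix(rep(c(rep(0, 5), rep(1, 5)), 5), 5, 10, byrow = TRUE))
  rownames(m) <- paste0("r", 1:10)
  cl <- cutree(hierarchicalCluster(m), k = 2)
  expect_length(unique(cl[1:5]), 1L)
  expect_length(unique(cl[6:10]), 1L)
  expect_false(cl[1] == cl[6])
})

test_that("module extraction partitions the network", {
  # two disjoint bicliques: k = 2 recovers the components
  e <- rbind(expand.grid(lncrna = c("L1", "L2"), mrna = c("M1", "M2"),
                         stringsAsFactors = FALSE),
             expand.grid(lncrna = c("L3", "L4"), mrna = c("M3", "M4"),
                         stringsAsFactors = FALSE))
  net <- buildNetwork(e)
  mods <- detectModules(net, k = 2)
  expect_length(mods, 2L)
  got <- vapply(mods, function(m) paste(sort(c(m$lncrnas, m$mrnas)),
                                        collapse = ","), character(1))
  expect_setequal(got, c("L1,L2,M1,M2", "L3,L4,M3,M4"))
  # lncRNAs partitioned, each mRNA in exactly one module
  allL <- sort(unlist(lapply(mods, `[[`, "lncrnas")))
  allM <- sort(unlist(lapply(mods, `[[`, "mrnas")))
  expect_equal(allL, c("L1", "L2", "L3", "L4"))
  expect_equal(allM, c("M1", "M2", "M3", "M4"))
  # internal edges sum to total (no between-module edges here)
  expect_equal(sum(vapply(mods, `[[`, integer(1), "internalEdges")),
               nrow(networkEdges(net)))
  # k = 1: one module holding everything
  m1 <- detectModules(net, k = 1)
  expect_length(m1, 1L)
  expect_equal(m1[[1]]$internalEdges, nrow(networkEdges(net)))
  expect_error(detectModules(net, k = 5), "between 1")
})

test_that("mRNA tie-breaking follows majority then partner degree", {
  # M3 has one edge into each biclique: tie broken toward the
  # higher-degree partner L1 (degree 3)
  e <- rbind(expand.grid(lncrna = c("L1", "L2"), mrna = c("M1", "M2"),
                         stringsAsFactors = FALSE),
             data.frame(lncrna = c("L3", "L1", "L3"),
                        mrna = c("M4", "M3", "M3")))
  net <- buildNetwork(e)
  mods <- detectModules(net, k = 2)
  holder <- Filter(function(m) "M3" %in% m$mrnas, mods)[[1]]
  expect_true("L1" %in% holder$lncrnas)
})

test_that("planted module blocks are recovered through the full pipeline", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    cfg <- syntheticConfig(nPlantedPairs = 12, nModules = 3, seed = seed)
    sim <- simulateCeRNAStudy(cfg)
    de <- moderatedTTest(sim$expr)
    de$class <- unname(geneClass(sim$expr)[de$gene_id])
    sel <- selectSDE(de, 0.01)$sde
    u <- buildUniverse(sim$mirnaMrna, sim$mirnaLncrna)
    cp <- identifyCompetingPairs(sel$gene_id[sel$class == "mRNA"],
                                 sel$gene_id[sel$class == "lncRNA"],
                                 u, sim$expr)
    net <- buildNetwork(cp)
    mods <- detectModules(net, k = 3)
    bg <- sim$truth$blockGenes
    assign <- rep(NA_integer_, nrow(bg)); names(assign) <- bg$gene
    for (m in mods) {
      members <- c(m$lncrnas, m$mrnas)
      assign[members[members %in% bg$gene]] <- m$moduleId
    }
    tab <- table(factor(bg$block), factor(assign, levels = 1:3))
    hits <- hits + sum(apply(tab, 1, max))
    total <- total + nrow(bg)
  }
  expect_gte(hits / total, 0.95)
})
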