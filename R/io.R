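#' Read a gene x sample expression TSV
#'
#' First column = gene id, header row = sample ids, numeric cells.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames; duplicate gene ids or
#'   non-numeric cells raise errors naming the offending rows.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column and samples")
  genes <- as.character(df[[1]])
  dup <- which(duplicated(genes))
  if (length(dup))
    stop("duplicated gene ids at rows: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badCol <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    stop("non-numeric expression values in column ", colnames(df)[badCol])
  }
  rownames(m) <- genes
  m
}

#' Read a 2-column sample label TSV (sample id, 0/1 class)
#' @param path TSV file path.
#' @return named integer vector of 0/1 labels.
#' @export
readLabels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels table needs (sample, class) columns")
  cls <- suppressWarnings(as.integer(df[[2]]))
  if (any(is.na(cls)) || !all(cls %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  stats::setNames(cls, as.character(df[[1]]))
}

#' Read a 2-column gene class TSV (gene id, mRNA|lncRNA)
#' @param path TSV file path.
#' @return named character vector of gene classes.
#' @export
readGeneClasses <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene class table needs (gene, class) columns")
  cls <- as.character(df[[2]])
  if (!all(cls %in% c("mRNA", "lncRNA")))
    stop("gene classes must be 'mRNA' or 'lncRNA'")
  stats::setNames(cls, as.character(df[[1]]))
}

#' Read a 2-column miRNA-target interaction TSV
#' @param path TSV file path.
#' @return data.frame with columns \code{mirna}, \code{target}.
#' @export
readInteractions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("interaction table needs (miRNA, target) columns")
  data.frame(mirna = as.character(df[[1]]), target = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a synthetic study to disk
#'
#' Writes the expression TSV (first column gene id, header = sample ids), a
#' sample-labels TSV, a gene-classes TSV, the two interaction TSVs and the
#' planted-truth JSON.
#'
#' @param sim output of [simulateCeRNAStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(expression = file.path(dir, "expression.tsv"),
         labels = file.path(dir, "labels.tsv"),
         geneClasses = file.path(dir, "gene_classes.tsv"),
         mirnaMrna = file.path(dir, "mirna_mrna.tsv"),
         mirnaLncrna = file.path(dir, "mirna_lncrna.tsv"),
         truth = file.path(dir, "truth.json"))
  m <- exprMatrix(sim$expr)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     p["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gr <- sampleGroup(sim$expr)
  utils::write.table(data.frame(sample = names(gr), class = unname(gr)),
                     p["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gc <- geneClass(sim$expr)
  utils::write.table(data.frame(gene = names(gc), class = unname(gc)),
                     p["geneClasses"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$mirnaMrna, p["mirnaMrna"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$mirnaLncrna, p["mirnaLncrna"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(pairs = data.frame(lncrna = truth$pairs$lncrna,
                            mrna = truth$pairs$mrna,
                            block = truth$pairs$block),
         deGenes = truth$deGenes,
         blockGenes = truth$blockGenes,
         blockSets = truth$blockSets,
         config = unclass(truth$config)),
    p["truth"], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
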