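#' Read probe alignments from BED6
#'
#' @param path BED file with at least 6 columns (name = probe id, strand).
#' @return a \code{GRanges} with a \code{name} column; zero-width or
#'   malformed records raise an error naming the probe.
#' @export
readProbeBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop("BED probes need names (column 4)")
  bad <- which(GenomicRanges::width(gr) < 1L)
  if (length(bad))
    stop("malformed probe interval(s): ",
         paste(gr$name[utils::head(bad, 5)], collapse = ", "))
  gr
}

#' Read gene annotation from GTF
#'
#' Keeps \code{gene} feature lines; \code{gene_id} is required,
#' \code{gene_type} (falling back to \code{gene_biotype}) is carried as the
#' biotype when present.
#'
#' @param path GTF file path.
#' @param biotypes optional character vector; keep only these biotypes.
#' @return a \code{GRanges} with \code{gene_id} and \code{biotype} columns.
#' @export
readGeneGtf <- function(path, biotypes = NULL) {
  gr <- rtracklayer::import(path, format = "GTF")
  if ("type" %in% colnames(S4Vectors::mcols(gr)))
    gr <- gr[gr$type == "gene"]
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes")
  bt <- if (!is.null(gr$gene_type)) gr$gene_type
        else if (!is.null(gr$gene_biotype)) gr$gene_biotype
        else rep(NA_character_, length(gr))
  S4Vectors::mcols(gr)$biotype <- bt
  if (!is.null(biotypes)) gr <- gr[gr$biotype %in% biotypes]
  gr
}

#' Match probes to genes by genomic-interval overlap
#'
#' A probe is assigned to a gene when their intervals overlap by at least
#' \code{minOverlap} bases on the same chromosome (and the same strand under
#' \code{strandMode = "strict"}). Probes overlapping no gene, or more than
#' one gene, are excluded — uniqueness of the genomic assignment is required
#' — and counted.
#'
#' @param probes \code{GRanges} of probe alignments (with \code{name}).
#' @param genes \code{GRanges} of gene annotation (with \code{gene_id}).
#' @param strandMode \code{"strict"} (default; strand must agree) or
#'   \code{"ignore"}.
#' @param minOverlap minimum overlap in bases (default 1).
#' @return list of class \code{"ProbeGeneMap"}: \code{map} (data.frame
#'   probe_id, gene_id), \code{droppedAmbiguous}, \code{droppedUnmatched}.
#' @export
matchProbesToGenes <- function(probes, genes,
                               strandMode = c("strict", "ignore"),
                               minOverlap = 1L) {
  strandMode <- match.arg(strandMode)
  hits <- GenomicRanges::findOverlaps(
    probes, genes, minoverlap = minOverlap,
    ignore.strand = (strandMode == "ignore")
  )
  nHits <- tabulate(S4Vectors::queryHits(hits), nbins = length(probes))
  unique1 <- which(nHits == 1L)
  keep <- S4Vectors::queryHits(hits) %in% unique1
  map <- data.frame(
    probe_id = probes$name[S4Vectors::queryHits(hits)[keep]],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)[keep]],
    stringsAsFactors = FALSE
  )
  out <- list(map = map,
              droppedAmbiguous = sum(nHits > 1L),
              droppedUnmatched = sum(nHits == 0L))
  class(out) <- "ProbeGeneMap"
  out
}

#' @export
print.ProbeGeneMap <- function(x, ...) {
  cat("ProbeGeneMap:", nrow(x$map), "probes assigned;",
      x$droppedAmbiguous, "ambiguous and", x$droppedUnmatched,
      "unmatched probes dropped\n")
  invisible(x)
}

#' Collapse probe-level expression to gene level
#'
#' Each gene's expression row is the arithmetic mean of its probes' rows,
#' sample by sample.
#'
#' @param probeExpr numeric matrix, probes in rows and samples in columns.
#' @param mapping a \code{"ProbeGeneMap"} (or a data.frame with
#'   \code{probe_id} and \code{gene_id} columns).
#' @return numeric matrix keyed by gene id; sample set unchanged.
#' @export
collapseProbes <- function(probeExpr, mapping) {
  if (inherits(mapping, "ProbeGeneMap")) mapping <- mapping$map
  missing <- setdiff(mapping$probe_id, rownames(probeExpr))
  if (length(missing))
    stop("probes in the mapping are absent from the matrix: ",
         paste(missing, collapse = ", "))
  sub <- probeExpr[mapping$probe_id, , drop = FALSE]
  sums <- rowsum(sub, group = mapping$gene_id)
  counts <- as.integer(table(mapping$gene_id)[rownames(sums)])
  sums / counts
}
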