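# Independent oracles and small programmatic fixtures shared by the suite.

# Exhaustive upper-tail hypergeometric probability by subset enumeration:
# fix set A = first nA items of the universe, enumerate every nB-subset B and
# count those with |A intersect B| >= k. Feasible for total <= 12.
enumHyperTail <- function(k, nA, nB, total) {
  if (k <= 0) return(1)
  items <- seq_len(total)
  a <- items[seq_len(nA)]
  combos <- utils::combn(items, nB)
  hits <- apply(combos, 2, function(b) sum(b %in% a))
  mean(hits >= k)
}

# A deterministic simple bipartite graph with given node counts and edges:
# edge i joins lncRNA (i mod nL) and mRNA (i mod nM); pairs are unique while
# nEdges <= lcm(nL, nM).
makeBipartiteEdges <- function(nL, nM, nEdges) {
  i <- seq_len(nEdges) - 1L
  data.frame(lncrna = sprintf("L%03d", (i %% nL) + 1L),
             mrna = sprintf("M%03d", (i %% nM) + 1L),
             stringsAsFactors = FALSE)
}

# Tiny two-group expression fixture with named genes/samples.
makeExprFixture <- function(nGenes = 10, n0 = 4, n1 = 4, seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  m <- matrix(rnorm(nGenes * n), nGenes, n,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n))))
  list(expr = m, labels = c(rep(0L, n0), rep(1L, n1)))
}

# Exact per-pair null rejection probability of the discrete shared-miRNA
# test at level alpha, given the two clipped set sizes and the universe size:
# the attained size of the most extreme rejection region below alpha.
exactNullRejectRate <- function(nA, nB, total, alpha = 0.05) {
  hi <- min(nA, nB)
  if (hi == 0) return(0)
  pv <- vapply(1:hi, hyperUpperTail, numeric(1), nA = nA, nB = nB,
               total = total)
  ok <- which(pv < alpha)
  if (!length(ok)) 0 else pv[ok[1]]
}

# GTF line for a 'gene' feature (1-based inclusive coordinates).
gtfGeneLine <- function(chrom, start, end, strand, geneId, biotype) {
  sprintf(
    '%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
    chrom, start, end, strand, geneId, biotype
  )
}

# BED6 line (0-based half-open).
bedLine <- function(chrom, start, end, name, strand) {
  sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, start, end, name, strand)
}
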