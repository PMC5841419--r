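#' Upper-tail cumulative hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric with \code{nA} "special" items among
#' \code{total}, drawing \code{nB}. Summed in log space for numerical
#' stability; this is the kernel of both the shared-miRNA pair test and
#' gene-set overrepresentation.
#'
#' @param k observed overlap (summation start).
#' @param nA size of the first set (number of special items).
#' @param nB size of the second set (number of draws).
#' @param total universe size.
#' @return the tail probability, a value in [0, 1]; \code{k <= 0} gives 1.
#' @examples
#' hyperUpperTail(3, 4, 5, 10)  # 66/252
#' @export
hyperUpperTail <- function(k, nA, nB, total) {
  stopifnot(length(k) == 1L, length(nA) == 1L, length(nB) == 1L,
            length(total) == 1L)
  if (nA > total || nB > total)
    stop("set sizes exceed the universe size")
  if (k <= 0) return(1)
  hi <- min(nA, nB)
  if (k > hi) return(0)
  i <- k:hi
  lt <- lchoose(nA, i) + lchoose(total - nA, nB - i) - lchoose(total, nB)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(0)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

# Vectorised version over equal-length k/nA/nB (scalar total).
hyperUpperTailVec <- function(k, nA, nB, total) {
  n <- length(k)
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- hyperUpperTail(k[j], nA[j], nB[j], total)
  out
}
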