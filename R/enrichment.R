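#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, then gene ids.
#'
#' @param path file path.
#' @return named list of character vectors (set name -> gene ids).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has no genes (name and description only)")
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Gene-set collection with explicit background universe
#'
#' @param sets named list of gene-id vectors (e.g. from [readGmt()]).
#' @param universe character vector of background gene ids; sets are clipped
#'   to it.
#' @return list of class \code{"GeneSetCollection"} with clipped \code{sets}
#'   and \code{universe}.
#' @export
geneSetCollection <- function(sets, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  if (any(lengths(sets) == 0L))
    warning("some sets are empty after clipping to the universe")
  out <- list(sets = sets, universe = universe)
  class(out) <- "GeneSetCollection"
  out
}

#' Upper-tail hypergeometric overrepresentation test for one gene set
#'
#' @param query character vector of query gene ids.
#' @param geneSet character vector of set gene ids.
#' @param universe character vector of background gene ids; query and set are
#'   clipped to it.
#' @param setName optional label for the output row.
#' @return one-row data.frame: \code{set_name}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size},
#'   \code{p_value}.
#' @export
oraTest <- function(query, geneSet, universe, setName = "set") {
  if (!length(universe)) stop("universe must be non-empty")
  universe <- unique(as.character(universe))
  q <- intersect(unique(query), universe)
  s <- intersect(unique(geneSet), universe)
  if (!length(q)) {
    warning("query is empty after clipping to the universe")
    return(data.frame(set_name = setName, overlap = 0L,
                      set_size = length(s), query_size = 0L,
                      universe_size = length(universe), p_value = 1,
                      stringsAsFactors = FALSE))
  }
  ov <- length(intersect(q, s))
  p <- hyperUpperTail(ov, length(s), length(q), length(universe))
  data.frame(set_name = setName, overlap = ov, set_size = length(s),
             query_size = length(q), universe_size = length(universe),
             p_value = p, stringsAsFactors = FALSE)
}

#' Overrepresentation analysis across a gene-set collection
#'
#' One upper-tail hypergeometric test per set; rows sorted by p-value, with a
#' raw-p significance flag at \code{alpha} and Benjamini-Hochberg q-values
#' reported additionally.
#'
#' @param query character vector of query gene ids.
#' @param collection a [geneSetCollection()].
#' @param alpha raw-p significance level.
#' @return data.frame, one row per set, plus columns \code{q_value} and
#'   \code{significant}.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  rows <- lapply(names(collection$sets), function(nm) {
    oraTest(query, collection$sets[[nm]], collection$universe, setName = nm)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$set_name), , drop = FALSE]
}
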