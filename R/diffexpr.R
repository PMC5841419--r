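#' Invert the trigamma function
#'
#' Newton iteration on the monotone decreasing trigamma, used when moment
#' matching the prior degrees of freedom of the variance model.
#'
#' @param x positive value; the target trigamma(y).
#' @return y with trigamma(y) = x.
#' @keywords internal
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

groupIndices <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  list(i0 = which(labels == 0L), i1 = which(labels == 1L))
}

#' Moment-matching estimator of the variance prior
#'
#' Given per-gene variances s_g^2 with dg degrees of freedom each, estimates
#' the scaled-F prior (d0, s0^2) from the mean and variance of
#' e_g = log s_g^2 - digamma(dg/2) + log(dg/2).
#'
#' @param sgsq per-gene variances (floored away from zero by the caller).
#' @param dg residual degrees of freedom (scalar).
#' @return list with \code{d0} (possibly \code{Inf}) and \code{s0sq}.
#' @keywords internal
fitFDistMoments <- function(sgsq, dg) {
  e <- log(sgsq) - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0sq = exp(ebar))
  } else {
    d0 <- 2 * trigammaInverse(evar)
    list(d0 = d0, s0sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Fit the empirical-Bayes variance model for the moderated t-test
#'
#' Pools the two within-group residual variances into per-gene s_g^2 with
#' d_g = n0 + n1 - 2 degrees of freedom, then estimates the prior
#' (d0, s0^2) by moment matching on log s_g^2: the mean and variance of
#' e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2) are matched to their
#' digamma/trigamma expressions under the scaled-chi-square model, inverting
#' the trigamma numerically. If the empirical variance of e_g does not exceed
#' its expected sampling variance trigamma(d_g/2), the genes show no excess
#' dispersion: d0 = Inf and s0^2 is the geometric-mean-based pooled variance.
#'
#' @param expr a [CernaExpressionSet-class] or a numeric matrix (genes x
#'   samples).
#' @param labels binary 0/1 sample labels; defaults to the set's own groups.
#' @return an [EBayesFit-class].
#' @seealso [moderatedTTest()]
#' @export
fitEBayes <- function(expr, labels = NULL) {
  if (methods::is(expr, "CernaExpressionSet")) {
    if (is.null(labels)) labels <- sampleGroup(expr)
    expr <- exprMatrix(expr)
  }
  if (is.null(labels)) stop("labels are required for a plain matrix")
  g <- groupIndices(labels)
  n0 <- length(g$i0); n1 <- length(g$i1)
  if (n0 < 2L || n1 < 2L) stop("each group needs at least 2 samples")
  dg <- n0 + n1 - 2L

  m0 <- rowMeans(expr[, g$i0, drop = FALSE])
  m1 <- rowMeans(expr[, g$i1, drop = FALSE])
  ss0 <- rowSums((expr[, g$i0, drop = FALSE] - m0)^2)
  ss1 <- rowSums((expr[, g$i1, drop = FALSE] - m1)^2)
  sgsq <- pmax((ss0 + ss1) / dg, 1e-12)

  mm <- fitFDistMoments(sgsq, dg)
  methods::new("EBayesFit", d0 = mm$d0, s0sq = mm$s0sq, dg = as.numeric(dg),
               sgsq = sgsq, meanDiff = m1 - m0,
               n0 = n0, n1 = n1)
}

setMethod("show", "EBayesFit", function(object) {
  cat("EBayesFit:", length(object@sgsq), "genes, dg =", object@dg, "\n")
  cat("  d0 =", object@d0, " s0^2 =", signif(object@s0sq, 4), "\n")
})

#' Moderated two-sample t-test
#'
#' Shrinks each gene's pooled variance toward the prior,
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), and tests the group mean
#' difference with t = meanDiff / (s~_g sqrt(1/n0 + 1/n1)) on d0 + d_g
#' degrees of freedom (standard normal when d0 is infinite). With d0 = 0 this
#' is exactly the ordinary pooled two-sample t-test.
#'
#' @param expr a [CernaExpressionSet-class] or numeric matrix.
#' @param labels binary 0/1 sample labels (defaults to the set's groups).
#' @param fit an [EBayesFit-class]; fitted from \code{expr} when \code{NULL}.
#' @param d0 optional override of the prior degrees of freedom (e.g. 0 for
#'   the ordinary t-test).
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{mean_diff}, \code{s_g_sq}, \code{t_mod}, \code{df_total},
#'   \code{p_value}, \code{q_value} (Benjamini-Hochberg, reported for
#'   transparency, not used for selection) and \code{direction}.
#' @export
moderatedTTest <- function(expr, labels = NULL, fit = NULL, d0 = NULL) {
  if (is.null(fit)) fit <- fitEBayes(expr, labels)
  if (is.null(d0)) d0 <- fit@d0
  dg <- fit@dg
  stsq <- if (is.infinite(d0)) rep(fit@s0sq, length(fit@sgsq))
          else if (d0 == 0) fit@sgsq
          else (d0 * fit@s0sq + dg * fit@sgsq) / (d0 + dg)
  se <- sqrt(stsq * (1 / fit@n0 + 1 / fit@n1))
  t <- fit@meanDiff / se
  df <- d0 + dg
  p <- 2 * stats::pt(-abs(t), df = df)
  data.frame(
    gene_id = names(fit@sgsq),
    mean_diff = unname(fit@meanDiff),
    s_g_sq = unname(fit@sgsq),
    t_mod = unname(t),
    df_total = df,
    p_value = unname(p),
    q_value = unname(stats::p.adjust(p, method = "BH")),
    direction = ifelse(fit@meanDiff > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' Select significantly differentially expressed genes
#'
#' Thresholds the raw moderated-t p-values (the selection rule is a raw-p
#' cutoff; the BH q-values in the table are informational only).
#'
#' @param results data.frame from [moderatedTTest()].
#' @param pThreshold raw p-value cutoff in (0, 1).
#' @return list with \code{sde} (the selected rows), \code{nUp}, \code{nDown}
#'   and \code{n}.
#' @export
selectSDE <- function(results, pThreshold = 0.01) {
  if (!nrow(results)) stop("empty results")
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0, 1)")
  sde <- results[results$p_value < pThreshold, , drop = FALSE]
  list(sde = sde,
       nUp = sum(sde$direction == "up"),
       nDown = sum(sde$direction == "down"),
       n = nrow(sde))
}
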