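#' Iterative random-forest feature elimination
#'
#' Repeatedly fits a random forest on the current feature set, scores each
#' feature by out-of-bag permutation importance (mean decrease in accuracy,
#' unscaled) and discards the max(1, floor(k/3)) least important features,
#' until at most \code{targetK} remain.
#'
#' @param x numeric matrix, features in rows and samples in columns.
#' @param labels binary 0/1 sample labels.
#' @param targetK stop once at most this many features remain.
#' @param seed RNG seed (forest fitting is stochastic).
#' @param ntree trees per forest.
#' @return list of class \code{"RFSelectionTrace"}: \code{iterations} (each
#'   with \code{retained}, \code{importance}, \code{discarded}),
#'   \code{finalFeatures}, \code{seed}. If \code{targetK} is already met, a
#'   single trivial iteration returns all features.
#' @export
rfIterativeSelection <- function(x, labels, targetK, seed = 1L,
                                 ntree = 500L) {
  if (nrow(x) < 2L) stop("need at least 2 features")
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  set.seed(seed)
  feats <- rownames(x)
  if (is.null(feats)) stop("feature matrix needs rownames")
  iterations <- list()
  if (length(feats) <= targetK) {
    iterations[[1]] <- list(retained = feats,
                            importance = stats::setNames(rep(NA_real_,
                                                             length(feats)),
                                                         feats),
                            discarded = character(0))
  } else {
    while (length(feats) > targetK) {
      rf <- randomForest::randomForest(t(x[feats, , drop = FALSE]), y,
                                       ntree = ntree, importance = TRUE)
      imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
      nDrop <- max(1L, floor(length(feats) / 3))
      dropped <- names(sort(imp))[seq_len(nDrop)]
      kept <- setdiff(feats, dropped)
      iterations[[length(iterations) + 1L]] <-
        list(retained = kept, importance = imp, discarded = dropped)
      feats <- kept
    }
  }
  out <- list(iterations = iterations, finalFeatures = feats, seed = seed)
  class(out) <- "RFSelectionTrace"
  out
}

#' All non-empty subsets of a feature list
#'
#' @param features character vector, at most 20 long (combinatorial guard).
#' @return list of 2^k - 1 character vectors, ordered by size then
#'   lexicographically within size.
#' @export
enumerateSubsets <- function(features) {
  k <- length(features)
  if (k < 1L) stop("need at least one feature")
  if (k > 20L) stop("refusing to enumerate subsets of more than 20 features")
  features <- as.character(features)
  out <- list()
  for (size in seq_len(k)) {
    combos <- utils::combn(sort(features), size, simplify = FALSE)
    ord <- order(vapply(combos, paste, character(1), collapse = "\r"))
    out <- c(out, combos[ord])
  }
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: AUC = U / (n1 n0), with tied scores given half
#' credit — the probability that a random positive outranks a random
#' negative.
#'
#' @param scores numeric decision values, higher = more positive-class-like.
#' @param labels binary 0/1 labels (1 = positive class).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

svmDecisionScore <- function(model, newdata, posClass) {
  pr <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cn <- colnames(dv)[1]
  parts <- strsplit(cn, "/", fixed = TRUE)[[1]]
  score <- as.numeric(dv[, 1])
  # libsvm decision values are positive toward the first-listed class
  if (parts[1] != posClass) score <- -score
  list(pred = as.character(pr), score = score)
}

#' Leave-one-out cross-validated SVM evaluation of a feature subset
#'
#' For every sample, an SVM (RBF kernel by default) is trained on the other
#' n - 1 samples and the held-out sample's predicted class and decision value
#' are recorded. Features are standardized with training-fold statistics only
#' (no leakage). Accuracy and AUC are computed from the pooled held-out
#' results; decision values are oriented so that higher means class 1.
#'
#' @param x numeric matrix, features in rows and samples in columns.
#' @param labels binary 0/1 sample labels.
#' @param kernel,cost,gamma SVM hyperparameters; \code{gamma} defaults to
#'   1 / n_features.
#' @return a [PanelResult-class]. Training folds containing a single class
#'   predict the majority class; such held-out samples are flagged in
#'   \code{degenerateFolds}.
#' @export
loocvSvm <- function(x, labels, kernel = "radial", cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 4L) stop("need at least 4 samples")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%03d", seq_len(n))
  if (is.null(gamma)) gamma <- 1 / nrow(x)
  y <- factor(labels, levels = c(0L, 1L))
  scores <- numeric(n); pred <- character(n); degen <- character(0)
  for (i in seq_len(n)) {
    xt <- t(x[, -i, drop = FALSE])
    yt <- y[-i]
    mu <- colMeans(xt)
    sdv <- apply(xt, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xt <- scale(xt, center = mu, scale = sdv)
    xh <- (x[, i] - mu) / sdv
    if (nlevels(droplevels(yt)) < 2L) {
      maj <- names(which.max(table(yt)))
      pred[i] <- maj
      scores[i] <- mean(yt == "1") - 0.5
      degen <- c(degen, colnames(x)[i])
      next
    }
    fit <- e1071::svm(xt, yt, kernel = kernel, cost = cost, gamma = gamma,
                      scale = FALSE)
    res <- svmDecisionScore(fit, matrix(xh, 1,
                                        dimnames = list(NULL, colnames(xt))),
                            posClass = "1")
    pred[i] <- res$pred
    scores[i] <- res$score
  }
  names(scores) <- colnames(x); names(pred) <- colnames(x)
  conf <- table(truth = factor(labels, levels = c(0L, 1L)),
                predicted = factor(pred, levels = c("0", "1")))
  methods::new("PanelResult",
               features = rownames(x),
               accuracy = mean(pred == as.character(labels)),
               auc = rocAuc(scores, labels),
               scores = scores,
               predicted = pred,
               confusion = unclass(conf),
               degenerateFolds = degen)
}

#' @rdname panelFeatures
#' @export
setMethod("panelFeatures", "PanelResult", function(x) x@features)

setMethod("show", "PanelResult", function(object) {
  cat("PanelResult:", length(object@features), "features (",
      paste(object@features, collapse = ", "), ")\n")
  cat("  LOOCV accuracy =", round(object@accuracy, 3),
      " AUC =", round(object@auc, 3), "\n")
  if (length(object@degenerateFolds))
    cat("  degenerate folds:", length(object@degenerateFolds), "\n")
})

#' Select the optimal biomarker panel
#'
#' Runs [rfIterativeSelection()] down to \code{targetK} features, enumerates
#' every non-empty subset of the retained set, evaluates each with
#' [loocvSvm()] and returns the subset with the highest held-out accuracy
#' (ties broken by higher AUC, fewer features, then lexicographic order).
#'
#' @inheritParams rfIterativeSelection
#' @param kernel,cost,gamma forwarded to [loocvSvm()].
#' @return list with \code{best} (a [PanelResult-class]), \code{table}
#'   (data.frame: subset, size, accuracy, auc, ranked best-first) and
#'   \code{trace} (the selection trace).
#' @export
selectOptimalPanel <- function(x, labels, targetK = 7L, seed = 1L,
                               ntree = 500L, kernel = "radial", cost = 1,
                               gamma = NULL) {
  trace <- rfIterativeSelection(x, labels, targetK, seed = seed,
                                ntree = ntree)
  subsets <- enumerateSubsets(trace$finalFeatures)
  results <- lapply(subsets, function(s) {
    loocvSvm(x[s, , drop = FALSE], labels, kernel = kernel, cost = cost,
             gamma = gamma)
  })
  tab <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = ","),
    size = lengths(subsets),
    accuracy = vapply(results, function(r) r@accuracy, numeric(1)),
    auc = vapply(results, function(r) r@auc, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$accuracy, -tab$auc, tab$size, tab$subset)
  list(best = results[[ord[1]]], table = tab[ord, , drop = FALSE],
       trace = trace)
}
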