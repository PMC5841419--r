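makeSeparableFixture <- function(nNoise = 3, n0 = 10, n1 = 10, gap = 10,
                                 seed = 33) {
  set.seed(seed)
  n <- n0 + n1
  x <- matrix(rnorm(nNoise * n), nNoise, n)
  sep <- c(rnorm(n0), rnorm(n1) + gap)
  x <- rbind(sep = sep, x)
  rownames(x) <- c("sep", paste0("noise", seq_len(nNoise)))
  colnames(x) <- sprintf("s%02d", seq_len(n))
  list(x = x, labels = c(rep(0L, n0), rep(1L, n1)))
}

test_that("subset enumeration is exact, ordered and guarded", {
  expect_length(enumerateSubsets(letters[1:7]), 127L)
  expect_length(enumerateSubsets(letters[1:6]), 63L)
  expect_equal(enumerateSubsets("a"), list("a"))
  s <- enumerateSubsets(c("b", "a", "c"))
  expect_equal(s[[1]], "a")
  expect_equal(lengths(s), c(1, 1, 1, 2, 2, 2, 3))
  expect_error(enumerateSubsets(letters), "20")
  # cardinality is exactly 2^k - 1
  for (k in c(2, 5, 10))
    expect_length(enumerateSubsets(paste0("f", 1:k)), 2^k - 1)
})

test_that("AUC matches its pairwise-comparison definition", {
  labels <- c(0, 0, 1, 1)
  expect_equal(rocAuc(c(0, 0, 1, 1), labels), 1)
  expect_equal(rocAuc(c(1, 1, 0, 0), labels), 0)
  expect_equal(rocAuc(c(2, 2, 2, 2), labels), 0.5)
  set.seed(8)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  pos <- sc[lb == 1]; neg <- sc[lb == 0]
  brute <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(rocAuc(sc, lb), brute, tolerance = 1e-12)
  expect_error(rocAuc(sc, rep(1, 60)), "both classes")
})

test_that("random-forest elimination follows the discard arithmetic", {
  set.seed(1)
  x <- matrix(rnorm(16 * 24), 16, 24,
              dimnames = list(paste0("f", 1:16), paste0("s", 1:24)))
  labels <- rep(c(0L, 1L), each = 12)
  tr <- rfIterativeSelection(x, labels, targetK = 7, seed = 4, ntree = 100)
  sizes <- c(16L, vapply(tr$iterations, function(it)
    length(it$retained), integer(1)))
  expect_equal(sizes, c(16L, 11L, 8L, 6L))
  expect_lte(length(tr$finalFeatures), 7L)
  # retained sets strictly nested
  for (i in seq_along(tr$iterations)[-1])
    expect_true(all(tr$iterations[[i]]$retained %in%
                      tr$iterations[[i - 1]]$retained))
  # 9 features, one step: 6 remain
  tr9 <- rfIterativeSelection(x[1:9, ], labels, targetK = 6, seed = 4,
                              ntree = 100)
  expect_length(tr9$iterations[[1]]$retained, 6L)
  # target already met: single trivial iteration
  tr0 <- rfIterativeSelection(x[1:3, ], labels, targetK = 5, seed = 4)
  expect_length(tr0$iterations, 1L)
  expect_equal(tr0$finalFeatures, paste0("f", 1:3))
})

test_that("an informative feature survives elimination", {
  kept <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    x <- matrix(rnorm(16 * n), 16, n,
                dimnames = list(c("signal", paste0("noise", 1:15)),
                                sprintf("s%02d", 1:n)))
    labels <- rep(c(0L, 1L), each = 15)
    x["signal", labels == 1L] <- x["signal", labels == 1L] + 3
    tr <- rfIterativeSelection(x, labels, targetK = 5, seed = seed,
                               ntree = 200)
    kept <- kept + ("signal" %in% tr$finalFeatures)
  }
  expect_gte(kept / 10, 0.95)
})

test_that("LOOCV SVM is perfect on a separable fixture and deterministic", {
  f <- makeSeparableFixture()
  res <- loocvSvm(f$x["sep", , drop = FALSE], f$labels)
  expect_equal(res@accuracy, 1)
  expect_equal(res@auc, 1)
  res2 <- loocvSvm(f$x["sep", , drop = FALSE], f$labels)
  expect_identical(res@scores, res2@scores)
  # invariant to sample order
  set.seed(19)
  perm <- sample(ncol(f$x))
  res3 <- loocvSvm(f$x["sep", perm, drop = FALSE], f$labels[perm])
  expect_equal(res3@accuracy, res@accuracy)
  expect_equal(res3@auc, res@auc)
  # the SMO solver is order-sensitive at its numeric tolerance, so decision
  # values agree only approximately across sample permutations
  expect_equal(res3@scores[names(res@scores)], res@scores, tolerance = 1e-2)
})

test_that("LOOCV SVM hovers near chance on pure noise", {
  accs <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(3 * 30), 3, 30,
                dimnames = list(paste0("f", 1:3), sprintf("s%02d", 1:30)))
    loocvSvm(x, rep(c(0L, 1L), 15))@accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("degenerate single-class training folds are flagged", {
  set.seed(2)
  x <- matrix(rnorm(2 * 8), 2, 8,
              dimnames = list(c("f1", "f2"), paste0("s", 1:8)))
  labels <- c(rep(0L, 7), 1L)
  res <- loocvSvm(x, labels)
  expect_equal(res@degenerateFolds, "s8")
  expect_equal(unname(res@predicted["s8"]), "0")
})

test_that("held-out AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  f <- makeSeparableFixture(gap = 1.5, seed = 40)
  res <- loocvSvm(f$x, f$labels)
  want <- as.numeric(pROC::auc(pROC::roc(f$labels, res@scores,
                                         direction = "<", quiet = TRUE)))
  expect_equal(res@auc, want, tolerance = 1e-12)
})

test_that("optimal panel search finds the separating feature", {
  f <- makeSeparableFixture(nNoise = 3)
  panel <- selectOptimalPanel(f$x, f$labels, targetK = 4, seed = 6,
                              ntree = 150)
  expect_equal(nrow(panel$table), 15L) # 2^4 - 1 subsets of 4 retained
  expect_true("sep" %in% panelFeatures(panel$best))
  expect_equal(panel$best@accuracy, 1)
  expect_equal(panel$best@auc, 1)
  # ranked table is best-first on accuracy
  expect_true(all(diff(panel$table$accuracy) <= 1e-12))
})

test_that("imbalanced null (5 vs 22) concentrates near the majority rate", {
  set.seed(14)
  x <- matrix(rnorm(3 * 27), 3, 27,
              dimnames = list(paste0("f", 1:3), sprintf("s%02d", 1:27)))
  labels <- c(rep(1L, 5), rep(0L, 22))
  accs <- vapply(1:10, function(i) {
    loocvSvm(x, sample(labels))@accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.6)   # dominated by the majority class
  expect_lt(mean(accs), 0.95)  # but no real signal
})
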