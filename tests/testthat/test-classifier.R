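blobData <- function(seed = 1, nPos = 20, nNeg = 100, sep = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(nPos * 4, sep), nPos, 4),
             matrix(rnorm(nNeg * 4, 0), nNeg, 4))
  list(X = X, y = c(rep("native", nPos), rep("non_native", nNeg)))
}

test_that("the SVM separates seeded blobs and calibrates their probabilities", {
  b <- blobData()
  m <- trainInterfaceSvm(b$X, b$y, seed = 2)
  p <- predictProbability(m, b$X)
  expect_equal(mean((p >= 0.5) == (b$y == "native")), 1)  # 100% training acc
  expect_gt(min(p[1:20]), 0.9)   # deep native points score confidently
  expect_lt(max(p[21:120]), 0.5)
})

test_that("degenerate duplicated rows with opposite labels give indifferent probabilities", {
  X <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  y <- rep(c("native", "non_native"), 4)
  m <- trainInterfaceSvm(X, y, seed = 1)
  p <- predictProbability(m, X[1, ])
  expect_gte(p, 0.3)
  expect_lte(p, 0.7)
})

test_that("training and prediction are reproducible from the seed", {
  b <- blobData(3)
  m1 <- trainInterfaceSvm(b$X, b$y, seed = 9)
  m2 <- trainInterfaceSvm(b$X, b$y, seed = 9)
  expect_identical(predictProbability(m1, b$X), predictProbability(m2, b$X))
  expect_error(trainInterfaceSvm(b$X, rep("native", 120)), "class")
})

test_that("schema-version mismatches are refused at prediction time", {
  b <- blobData(4)
  m <- trainInterfaceSvm(b$X, b$y)
  bad <- new("LabeledSet",
             features = b$X,
             labels = factor(b$y, levels = c("non_native", "native")),
             meta = data.frame(id = seq_along(b$y)),
             schemaVersion = "other/9")
  expect_error(predictProbability(m, bad), "schema")
  expect_error(predictProbability(m, b$X[, 1:2]), "feature count")
})

test_that("confusion metrics implement the standard definitions and conventions", {
  m <- confusionMetrics(TP = 10, TN = 50, FP = 0, FN = 0)
  expect_equal(unlist(m[c("TPR", "TNR", "NPV", "precision", "F1", "MCC")]),
               c(TPR = 1, TNR = 1, NPV = 1, precision = 1, F1 = 1, MCC = 1))
  expect_equal(m$accuracy, 100)
  # 0/0 convention
  z <- confusionMetrics(TP = 0, TN = 5, FP = 0, FN = 5)
  expect_equal(z$precision, 0)
  expect_equal(z$F1, 0)
  expect_error(confusionMetrics(TP = -1, TN = 1, FP = 1, FN = 1), "negative")
  # fractional counts (trial averages) are fine and internally consistent
  set.seed(17)
  for (rep in 1:20) {
    cnt <- as.list(setNames(runif(4, 0, 100), c("TP", "TN", "FP", "FN")))
    mm <- confusionMetrics(cnt)
    expect_gte(mm$MCC, -1); expect_lte(mm$MCC, 1)
    expect_gte(mm$F1, 0); expect_lte(mm$F1, 1)
    for (r in c("TPR", "TNR", "NPV", "precision")) {
      expect_gte(mm[[r]], 0); expect_lte(mm[[r]], 1)
    }
    expect_equal(mm$accuracy,
                 100 * (cnt$TP + cnt$TN) / Reduce(`+`, cnt), tolerance = 1e-9)
  }
})

test_that("ROC/AUC handles perfect, reversed and tied rankings", {
  lab <- c(rep("native", 4), rep("non_native", 6))
  expect_equal(rocAuc(c(4, 3.5, 3, 2.9, 2, 1, 0.5, 0.4, 0.2, 0.1), lab)$auc, 1)
  expect_equal(rocAuc(c(0.1, 0.2, 0.3, 0.35, 2, 3, 4, 5, 6, 7), lab)$auc, 0)
  # ties: AUC must equal the Mann-Whitney U / (n1 n2) identity
  scores <- c(0.9, 0.8, 0.8, 0.5, 0.8, 0.5, 0.4, 0.3)
  labs <- c("native", "native", "native", "native",
            "non_native", "non_native", "non_native", "non_native")
  r <- rank(scores)
  U <- sum(r[labs == "native"]) - 4 * 5 / 2
  expect_equal(rocAuc(scores, labs)$auc, U / 16, tolerance = 1e-12)
  expect_error(rocAuc(1:3, rep("native", 3)), "both classes")
})

test_that("AUC of negated scores complements the original", {
  set.seed(23)
  for (rep in 1:5) {
    sc <- round(runif(30), 2)  # rounding forces ties
    lab <- sample(c("native", "non_native"), 30, replace = TRUE,
                  prob = c(0.3, 0.7))
    if (length(unique(lab)) < 2) next
    expect_equal(rocAuc(sc, lab)$auc + rocAuc(-sc, lab)$auc, 1,
                 tolerance = 1e-12)
  }
})

test_that("the threshold sweep matches a direct recount at every cutoff", {
  set.seed(29)
  sc <- runif(40)
  lab <- sample(c("native", "non_native"), 40, replace = TRUE)
  sw <- thresholdSweep(sc, lab)
  expect_equal(sw$threshold, seq(0.5, 0.95, 0.05))
  for (i in seq_len(nrow(sw))) {
    t <- sw$threshold[i]
    expect_equal(sw$TP[i], sum(sc >= t & lab == "native"))
    expect_equal(sw$TN[i], sum(sc < t & lab == "non_native"))
    expect_equal(sw$FP[i], sum(sc >= t & lab == "non_native"))
    expect_equal(sw$FN[i], sum(sc < t & lab == "native"))
  }
  expect_true(all(diff(sw$TP) <= 0))  # raising the cutoff never adds TPs
  allNative <- thresholdSweep(rep(1, 5), rep("native", 5))
  expect_true(all(allNative$TP == 5 & allNative$FP == 0))
})

test_that("cross-validation is reproducible and near-perfect on separable data", {
  b <- blobData(5, nPos = 16, nNeg = 80)
  cv1 <- crossValidate(b$X, b$y, nTrials = 20, seed = 7)
  cv2 <- crossValidate(b$X, b$y, nTrials = 20, seed = 7)
  expect_identical(cv1$trials, cv2$trials)
  expect_gte(cv1$summary$meanAccuracy, 95)
  expect_gte(cv1$summary$meanAuc, 0.95)
  # the averaged sweep row reproduces its own confusion metrics
  row <- cv1$sweep[1, ]
  mm <- confusionMetrics(as.list(row[c("TP", "TN", "FP", "FN")]))
  expect_equal(row$MCC, mm$MCC, tolerance = 1e-12)
  expect_equal(row$accuracy, mm$accuracy, tolerance = 1e-12)
})

test_that("shuffled labels fall back to the majority-class baseline", {
  set.seed(31)
  X <- matrix(rnorm(96 * 12), 96, 12)
  y <- sample(c(rep("native", 16), rep("non_native", 80)))
  cv <- crossValidate(X, y, nTrials = 25, seed = 11)
  # with calibrated probabilities and a 1:5 prior, an uninformative model
  # predicts non-native: accuracy near 100 * 10/12
  expect_lt(abs(cv$summary$meanAccuracy - 100 * 10 / 12), 3)
})

test_that("models persist and restore through the archive format", {
  b <- blobData(6)
  m <- trainInterfaceSvm(b$X, b$y, seed = 2)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_equal(predictProbability(m2, b$X), predictProbability(m, b$X),
               tolerance = 1e-12)
  expect_error(loadModel(system.file("extdata", "vdw_radii.tsv",
                                     package = "dockiface")))
})
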