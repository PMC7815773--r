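svmDecision <- function(fit, X, orientation = 1) {
  p <- stats::predict(fit, X, decision.values = TRUE)
  orientation * as.numeric(attr(p, "decision.values"))
}

# Platt sigmoid: p = 1 / (1 + exp(a*f + b)), fitted by minimizing the
# cross-entropy against the regularized targets t+ = (N+ + 1)/(N+ + 2),
# t- = 1/(N- + 2).
plattFit <- function(f, isPos) {
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  t <- ifelse(isPos, (nPos + 1) / (nPos + 2), 1 / (nNeg + 2))
  nll <- function(ab) {
    z <- ab[1] * f + ab[2]
    # p = 1/(1+exp(z)); NLL = sum(log(1+exp(z)) - (1-t) z), stable form
    log1pexp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(log1pexp - (1 - t) * z)
  }
  fit <- stats::optim(c(a = -1, b = log((nNeg + 1) / (nPos + 1))), nll,
                      method = "BFGS", control = list(maxit = 200))
  fit$par
}

plattProb <- function(f, ab) 1 / (1 + exp(ab[1] * f + ab[2]))

fitRbfSvm <- function(X, y, cost, gamma) {
  w <- length(y) / (2 * table(y))
  fit <- e1071::svm(X, y, kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = w, scale = FALSE, probability = FALSE)
  d <- svmDecision(fit, X)
  # libsvm's decision sign depends on label order in the data; orient it so
  # larger values mean more native-like
  orientation <- if (mean(d[y == "native"]) >= mean(d[y != "native"])) 1 else -1
  list(fit = fit, orientation = orientation)
}

#' Train an RBF-SVM interface classifier
#'
#' Features are standardized with statistics estimated on the training data
#' only (constant features get scale 1); an RBF-kernel SVM is fitted with
#' class weights inverse to class frequency (mirroring the fixed 1:5
#' native:non-native design without oversampling); probabilities come from a
#' Platt sigmoid fitted to out-of-fold decision values from a seeded 3-fold
#' split of the training data, so calibration never sees its own training
#' predictions and the whole fit is reproducible from the seed.
#'
#' @param X numeric feature matrix (rows = poses, schema columns) or a
#'   [LabeledSet-class] (then \code{y} is taken from it).
#' @param y factor/character labels (\code{native} / \code{non_native});
#'   both classes must be present with >= 2 samples each.
#' @param cost SVM penalty C (default 10).
#' @param gamma RBF width (default 1/n_features).
#' @param seed seed for the calibration folds.
#' @return an [SvmModel-class].
#' @seealso [predictProbability()], [crossValidate()]
#' @export
trainInterfaceSvm <- function(X, y = NULL, cost = 10, gamma = NULL,
                              seed = 1L) {
  schemaVersion <- FEATURE_SCHEMA_VERSION
  if (is(X, "LabeledSet")) {
    y <- setLabels(X)
    schemaVersion <- X@schemaVersion
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("non_native", "native"))
  if (any(table(y) < 2L)) stop("need at least 2 samples in each class")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  # out-of-fold decision values for calibration
  nFold <- min(3L, min(table(y)))
  folds <- withSeed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(nFold), length(idx)))
    }
    f
  })
  dec <- numeric(length(y))
  for (fold in seq_len(nFold)) {
    tr <- folds != fold
    if (length(unique(y[tr])) < 2L) { dec[!tr] <- 0; next }
    m <- fitRbfSvm(Xs[tr, , drop = FALSE], y[tr], cost, gamma)
    dec[!tr] <- svmDecision(m$fit, Xs[!tr, , drop = FALSE], m$orientation)
  }
  ab <- plattFit(dec, y == "native")
  final <- fitRbfSvm(Xs, y, cost, gamma)
  new("SvmModel", fit = final$fit, center = center, scale = scale,
      platt = ab, orientation = final$orientation,
      schemaVersion = schemaVersion, cost = cost, gamma = gamma)
}

#' Probability that poses are native-like
#'
#' Standardizes with the model's stored training statistics, evaluates the
#' SVM decision function and maps it through the model's Platt sigmoid.
#' Classification at threshold t is native iff p >= t.
#'
#' @param model an [SvmModel-class].
#' @param x feature vector, matrix, or [LabeledSet-class]; the schema
#'   version must match the model's.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictProbability <- function(model, x) {
  if (is(x, "LabeledSet")) {
    if (!identical(x@schemaVersion, model@schemaVersion))
      stop("feature schema version mismatch: model ", model@schemaVersion,
           ", data ", x@schemaVersion)
    x <- featureMatrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  if (ncol(x) != length(model@center)) stop("feature count mismatch")
  Xs <- sweep(sweep(as.matrix(x), 2, model@center), 2, model@scale, "/")
  plattProb(svmDecision(model@fit, Xs, model@orientation), model@platt)
}

#' Confusion-matrix performance metrics
#'
#' \code{accuracy = 100 (TP+TN)/(TP+TN+FP+FN)}; \code{TPR = TP/(TP+FN)}
#' (sensitivity); \code{TNR = TN/(TN+FP)} (specificity);
#' \code{NPV = TN/(TN+FN)}; \code{precision = TP/(TP+FP)};
#' \code{F1 = 2 prec TPR/(prec+TPR)};
#' \code{MCC = (TP TN - FP FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}.
#' Counts may be non-negative reals (averages over trials). Any 0/0 is 0 by
#' convention.
#'
#' @param TP,TN,FP,FN confusion counts; alternatively pass a single list or
#'   data.frame row with those names as \code{TP}.
#' @return named list: accuracy (percent), TPR, TNR, NPV, precision, F1,
#'   MCC.
#' @examples
#' confusionMetrics(TP = 10, TN = 50, FP = 0, FN = 0)  # all 1
#' @export
confusionMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP)) { x <- TP; TP <- x$TP; TN <- x$TN; FP <- x$FP; FN <- x$FN }
  if (any(c(TP, TN, FP, FN) < 0)) stop("negative counts")
  div <- function(a, b) if (b == 0) 0 else a / b
  tpr <- div(TP, TP + FN)
  tnr <- div(TN, TN + FP)
  npv <- div(TN, TN + FN)
  prec <- div(TP, TP + FP)
  f1 <- div(2 * prec * tpr, prec + tpr)
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mccDen == 0) 0 else (TP * TN - FP * FN) / mccDen
  list(accuracy = 100 * div(TP + TN, TP + TN + FP + FN),
       TPR = tpr, TNR = tnr, NPV = npv, precision = prec, F1 = f1, MCC = mcc)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the unique scores as thresholds (ties grouped), computes
#' (FPR, TPR) points and the trapezoidal area under the curve. Perfectly
#' ranked scores give AUC 1, perfectly reversed 0.
#'
#' @param scores numeric scores (higher = more native-like).
#' @param labels logical/character/factor; \code{TRUE}/\code{"native"} is
#'   the positive class. Both classes must be present.
#' @return list with \code{auc} and a data.frame \code{points} (threshold,
#'   fpr, tpr).
#' @export
rocAuc <- function(scores, labels) {
  pos <- labels == "native" | labels == TRUE
  if (!any(pos) || all(pos)) stop("both classes required")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  fprAll <- c(0, fpr, 1)
  tprAll <- c(0, tpr, 1)
  auc <- sum(diff(fprAll) * (utils::head(tprAll, -1) + utils::tail(tprAll, -1)) / 2)
  list(auc = auc,
       points = data.frame(threshold = c(Inf, thr, -Inf), fpr = fprAll,
                           tpr = tprAll))
}

#' Confusion counts and metrics across probability thresholds
#'
#' One row per threshold (default 0.50 to 0.95 in steps of 0.05): TP, TN,
#' FP, FN at \code{predicted native iff p >= threshold}, followed by the
#' [confusionMetrics()] columns.
#'
#' @inheritParams rocAuc
#' @param thresholds probability cutoffs.
#' @return data.frame with columns threshold, TP, TN, FP, FN, accuracy,
#'   TPR, TNR, NPV, precision, F1, MCC.
#' @export
thresholdSweep <- function(scores, labels, thresholds = seq(0.5, 0.95, 0.05)) {
  pos <- labels == "native" | labels == TRUE
  rows <- lapply(thresholds, function(t) {
    pred <- scores >= t
    counts <- list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                   FP = sum(pred & !pos), FN = sum(!pred & pos))
    c(list(threshold = t), counts, confusionMetrics(counts))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Repeated 80/20 cross-validation of the interface classifier
#'
#' The evaluation protocol: \code{nTrials} times (default 100), a seeded
#' stratified random 80/20 split is drawn, the SVM is trained on the 80%
#' and evaluated on the held-out 20%; performance is summarized as the mean
#' and SD over trials. Stratification keeps both classes in every split
#' (with the 1:5 design, unstratified splits are occasionally single-class);
#' if a test split still ends up single-class it is resampled (logged via a
#' message). Per-trial confusion counts are recorded at each probability
#' threshold 0.50--0.95 and averaged into a benchmark-style table.
#'
#' @param dataset a [LabeledSet-class] (or feature matrix with \code{y}).
#' @param y labels when \code{dataset} is a matrix.
#' @param nTrials number of random trials.
#' @param trainFrac training fraction (0.8).
#' @param seed master seed; trial j uses seed + j.
#' @param cost,gamma SVM hyperparameters (see [trainInterfaceSvm()]).
#' @param thresholds probability cutoffs for the sweep table.
#' @return list with \code{trials} (data.frame: trial, accuracy (percent,
#'   at p >= 0.5), auc), \code{summary} (meanAccuracy, sdAccuracy, meanAuc,
#'   sdAuc), and \code{sweep} (mean confusion counts per threshold with
#'   metrics recomputed from the mean counts).
#' @export
crossValidate <- function(dataset, y = NULL, nTrials = 100L, trainFrac = 0.8,
                          seed = 1L, cost = 10, gamma = NULL,
                          thresholds = seq(0.5, 0.95, 0.05)) {
  if (is(dataset, "LabeledSet")) {
    y <- setLabels(dataset)
    X <- featureMatrix(dataset)
  } else X <- as.matrix(dataset)
  y <- factor(as.character(y), levels = c("non_native", "native"))
  if (any(table(y) < 3L))
    stop("cross-validation needs >= 3 samples per class; pool more references")
  trials <- data.frame(trial = seq_len(nTrials), accuracy = NA_real_,
                       auc = NA_real_)
  countSum <- matrix(0, length(thresholds), 4,
                     dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  for (j in seq_len(nTrials)) {
    trialSeed <- seed + j
    split <- withSeed(trialSeed, {
      for (attempt in 1:10) {
        tr <- unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          # leave at least one of each class in the test fold and keep at
          # least two in training
          nTr <- min(length(idx) - 1L, max(2L, round(trainFrac * length(idx))))
          sample(idx, nTr)
        }))
        te <- setdiff(seq_along(y), tr)
        if (length(unique(y[te])) == 2L && length(unique(y[tr])) == 2L)
          break
        message("resampling single-class split (trial ", j, ")")
      }
      list(train = tr, test = te)
    })
    model <- trainInterfaceSvm(X[split$train, , drop = FALSE], y[split$train],
                               cost = cost, gamma = gamma, seed = trialSeed)
    p <- predictProbability(model, X[split$test, , drop = FALSE])
    yTest <- y[split$test]
    trials$accuracy[j] <- 100 * mean((p >= 0.5) == (yTest == "native"))
    trials$auc[j] <- rocAuc(p, yTest)$auc
    sw <- thresholdSweep(p, yTest, thresholds)
    countSum <- countSum + as.matrix(sw[, c("TP", "TN", "FP", "FN")])
  }
  meanCounts <- countSum / nTrials
  sweep <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    counts <- as.list(meanCounts[i, ])
    as.data.frame(c(list(threshold = thresholds[i]), counts,
                    confusionMetrics(counts)))
  }))
  list(trials = trials,
       summary = list(meanAccuracy = mean(trials$accuracy),
                      sdAccuracy = stats::sd(trials$accuracy),
                      meanAuc = mean(trials$auc),
                      sdAuc = stats::sd(trials$auc)),
       sweep = sweep)
}

#' Persist / restore a fitted classifier
#'
#' The model is stored as a single self-describing archive (an RDS file
#' holding the schema version, scaling statistics, Platt coefficients and
#' the fitted SVM).
#'
#' @param model an [SvmModel-class].
#' @param file path of the archive.
#' @return \code{loadModel} returns the [SvmModel-class].
#' @export
saveModel <- function(model, file) {
  saveRDS(list(format = "dockiface-svm/1", schemaVersion = model@schemaVersion,
               center = model@center, scale = model@scale,
               platt = model@platt, orientation = model@orientation,
               cost = model@cost, gamma = model@gamma, fit = model@fit),
          file)
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  x <- readRDS(file)
  if (!identical(x$format, "dockiface-svm/1")) stop("not a model archive")
  new("SvmModel", fit = x$fit, center = x$center, scale = x$scale,
      platt = x$platt, orientation = x$orientation,
      schemaVersion = x$schemaVersion, cost = x$cost, gamma = x$gamma)
}
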