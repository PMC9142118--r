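#' Clustering-coefficient feature series for one subject
#'
#' Binarizes every snapshot at the given density and computes the global
#' clustering coefficient of each, concatenating in-snapshot features first
#' and out-snapshot features after, so a 140-volume subject with horizon 70
#' yields a 210-dimensional feature vector. Either sequence may be empty
#' (in-only / out-only ablations).
#'
#' @param inSnaps,outSnaps [SnapshotSequence-class] objects (either may have
#'   length 0, not both).
#' @param density binarization density.
#' @return numeric feature vector with entries in [0, 1].
#' @export
extractFeatures <- function(inSnaps, outSnaps = NULL, density = 0.15) {
  mats <- c(if (!is.null(inSnaps)) inSnaps@matrices else list(),
            if (!is.null(outSnaps)) outSnaps@matrices else list())
  if (length(mats) == 0L) stop("no snapshots to extract features from")
  vapply(mats, function(M) globalClustering(binarizeSnapshot(M, density)),
         numeric(1))
}

#' Assemble a feature table
#'
#' @param features named list (subject_id -> feature vector, all equal
#'   length).
#' @param groups named character vector (subject_id -> group label).
#' @return data.frame with subject_id, group and f_1 ... f_K columns.
#' @export
buildFeatureTable <- function(features, groups) {
  stopifnot(length(features) > 0, !is.null(names(features)))
  lens <- lengths(features)
  if (length(unique(lens)) != 1L)
    stop("feature vectors have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  ids <- names(features)
  if (!all(ids %in% names(groups))) stop("missing group label for some subjects")
  mat <- do.call(rbind, features)
  colnames(mat) <- paste0("f_", seq_len(ncol(mat)))
  data.frame(subject_id = ids, group = unname(groups[ids]), mat,
             row.names = NULL, check.names = FALSE)
}

.stratifiedFolds <- function(labels, nFolds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
  })
}

.foldScores <- function(trainX, trainY, testX, classifier) {
  # standardize with training-fold statistics only
  mu <- colMeans(trainX)
  sdv <- apply(trainX, 2, sd)
  sdv[sdv == 0] <- 1
  trS <- scale(trainX, mu, sdv)
  teS <- scale(testX, mu, sdv)
  if (classifier == "svm") {
    fit <- e1071::svm(trS, trainY, kernel = "radial", probability = FALSE,
                      scale = FALSE)
    pr <- predict(fit, teS, decision.values = TRUE)
    score <- as.numeric(attr(pr, "decision.values"))
    # orient decision values toward the first factor level
    dvName <- colnames(attr(pr, "decision.values"))[1]
    if (!identical(dvName, paste(levels(trainY), collapse = "/")))
      score <- -score
    list(pred = pr, score = score)
  } else if (classifier == "knn") {
    pr <- class::knn(trS, teS, trainY, k = 5, prob = TRUE)
    p <- attr(pr, "prob")
    score <- ifelse(pr == levels(trainY)[1], p, 1 - p)
    list(pred = pr, score = score)
  } else if (classifier == "nb") {
    fit <- e1071::naiveBayes(as.data.frame(trS), trainY)
    raw <- predict(fit, as.data.frame(teS), type = "raw")
    pred <- factor(levels(trainY)[max.col(raw)], levels = levels(trainY))
    list(pred = pred, score = raw[, levels(trainY)[1]])
  } else stop("unknown classifier: ", classifier)
}

#' Cross-validated binary classification of two groups
#'
#' Stratified k-fold cross-validation of \code{groupA} (treated as the
#' disease / positive class: sensitivity) versus \code{groupB} (control:
#' specificity). Features are standardized inside each training fold only —
#' test folds are transformed with training-fold statistics, so no
#' information leaks. AUC is computed from pooled decision scores.
#'
#' @param table feature table from [buildFeatureTable()].
#' @param groupA,groupB group labels to contrast (A = positive class).
#' @param classifier "svm" (radial kernel), "knn" (k = 5) or "nb"
#'   (Gaussian naive Bayes).
#' @param nFolds folds (must not exceed the smaller group).
#' @param seed seed controlling the fold assignment.
#' @return list with accuracy, sensitivity, specificity (percent), auc,
#'   foldDetails (per-fold accuracy), and the resolved settings.
#' @export
classifyGroups <- function(table, groupA, groupB, classifier = "svm",
                           nFolds = 5L, seed = 1L) {
  stopifnot(is.data.frame(table))
  for (g in c(groupA, groupB))
    if (!g %in% table$group) stop("group not present in table: ", g)
  sub <- table[table$group %in% c(groupA, groupB), , drop = FALSE]
  y <- factor(sub$group, levels = c(groupA, groupB))
  X <- as.matrix(sub[, grep("^f_", names(sub)), drop = FALSE])
  if (min(table(y)) < nFolds)
    stop("nFolds (", nFolds, ") exceeds the smaller group size (",
         min(table(y)), ")")
  fold <- .stratifiedFolds(as.character(y), nFolds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  score <- numeric(length(y))
  foldAcc <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    fs <- .foldScores(X[tr, , drop = FALSE], droplevels(y[tr]),
                      X[te, , drop = FALSE], classifier)
    pred[te] <- as.character(fs$pred)
    score[te] <- fs$score
    foldAcc[f] <- mean(fs$pred == y[te])
  }
  tp <- sum(pred == groupA & y == groupA)
  tn <- sum(pred == groupB & y == groupB)
  auc <- tryCatch(
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                   levels = c(groupB, groupA),
                                   direction = "<", quiet = TRUE))),
    error = function(e) NA_real_)
  list(classifier = classifier,
       accuracy = 100 * mean(pred == y),
       sensitivity = 100 * tp / sum(y == groupA),
       specificity = 100 * tn / sum(y == groupB),
       auc = auc,
       foldDetails = data.frame(fold = seq_len(nFolds), accuracy = 100 * foldAcc),
       config = list(groupA = groupA, groupB = groupB, nFolds = nFolds,
                     seed = seed, kernel = if (classifier == "svm") "radial" else NA,
                     k = if (classifier == "knn") 5L else NA))
}

#' In / out / combined feature ablation
#'
#' Runs [classifyGroups()] on the in-only, out-only and combined feature
#' tables with identical fold assignments (same seed), producing a
#' side-by-side comparison of what each snapshot segment contributes.
#'
#' @param tableIn,tableOut,tableBoth feature tables over the same subjects.
#' @param groupA,groupB,classifier,nFolds,seed as in [classifyGroups()].
#' @return data.frame with one row per feature set.
#' @export
featureAblation <- function(tableIn, tableOut, tableBoth, groupA, groupB,
                            classifier = "svm", nFolds = 5L, seed = 1L) {
  ids <- tableIn$subject_id
  if (!identical(sort(ids), sort(tableOut$subject_id)) ||
      !identical(sort(ids), sort(tableBoth$subject_id)))
    stop("feature tables cover different subjects")
  sets <- list(`in` = tableIn, out = tableOut, both = tableBoth)
  rows <- lapply(names(sets), function(nm) {
    r <- classifyGroups(sets[[nm]], groupA, groupB, classifier, nFolds, seed)
    data.frame(features = nm, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               auc = r$auc)
  })
  do.call(rbind, rows)
}
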