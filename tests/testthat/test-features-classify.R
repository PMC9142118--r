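denseSeq <- function(n, m = 5) {
  M <- matrix(0.9, m, m); diag(M) <- 1
  SnapshotSequence(rep(list(M), n), times = seq_len(n) - 1, provenance = "in")
}

test_that("feature series concatenate in- then out-snapshot clustering values", {
  ins <- denseSeq(4)
  outs <- denseSeq(3)
  f <- extractFeatures(ins, outs, density = 1)
  expect_length(f, 7)
  expect_equal(f, rep(1, 7))               # dense graphs are fully clustered
  expect_length(extractFeatures(ins, NULL, density = 1), 4)
  expect_error(extractFeatures(NULL, NULL), "no snapshots")
})

test_that("clustering features are invariant under node relabeling", {
  withr::with_seed(23, {
    M <- symm(matrix(runif(64), 8, 8)); diag(M) <- 1
    perm <- sample(8)
  })
  s1 <- SnapshotSequence(list(M), times = 0, provenance = "in")
  s2 <- SnapshotSequence(list(M[perm, perm]), times = 0, provenance = "in")
  expect_equal(extractFeatures(s1, density = 0.3),
               extractFeatures(s2, density = 0.3))
})

test_that("feature tables enforce consistent dimensions and labels", {
  feats <- list(a = c(0.1, 0.2), b = c(0.3, 0.4))
  tab <- buildFeatureTable(feats, c(a = "NC", b = "AD"))
  expect_equal(names(tab), c("subject_id", "group", "f_1", "f_2"))
  expect_error(buildFeatureTable(list(a = 1:2, b = 1:3),
                                 c(a = "NC", b = "AD")), "unequal")
  expect_error(buildFeatureTable(feats, c(a = "NC")), "missing group")
})

makeTable <- function(nPer, sep, seed, K = 10) {
  withr::with_seed(seed, {
    feats <- c(
      lapply(seq_len(nPer), function(i) 0.5 + sep / 2 + rnorm(K, sd = 0.05)),
      lapply(seq_len(nPer), function(i) 0.5 - sep / 2 + rnorm(K, sd = 0.05)))
  })
  names(feats) <- c(sprintf("d%02d", seq_len(nPer)), sprintf("c%02d", seq_len(nPer)))
  groups <- setNames(rep(c("AD", "NC"), each = nPer), names(feats))
  buildFeatureTable(feats, groups)
}

test_that("widely separated groups classify perfectly with every classifier", {
  tab <- makeTable(10, sep = 0.4, seed = 1)
  for (cl in c("svm", "knn", "nb")) {
    r <- classifyGroups(tab, "AD", "NC", cl, nFolds = 5, seed = 2)
    expect_equal(r$accuracy, 100, info = cl)
    expect_equal(r$sensitivity, 100, info = cl)
    expect_equal(r$specificity, 100, info = cl)
    expect_gt(r$auc, 0.99)
    expect_equal(mean(r$foldDetails$accuracy), r$accuracy)
  }
})

test_that("label permutation collapses accuracy to chance", {
  tab <- makeTable(10, sep = 0.4, seed = 1)
  accs <- vapply(1:20, function(p) {
    ptab <- tab
    ptab$group <- withr::with_seed(100 + p, sample(tab$group))
    classifyGroups(ptab, "AD", "NC", "svm", nFolds = 5, seed = 2)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 30)
  expect_lt(mean(accs), 70)
})

test_that("classification is deterministic given the seed", {
  tab <- makeTable(8, sep = 0.1, seed = 3)
  r1 <- classifyGroups(tab, "AD", "NC", "svm", nFolds = 4, seed = 9)
  r2 <- classifyGroups(tab, "AD", "NC", "svm", nFolds = 4, seed = 9)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$auc, r2$auc)
})

test_that("invalid contrasts and fold counts are rejected", {
  tab <- makeTable(4, sep = 0.2, seed = 5)
  expect_error(classifyGroups(tab, "AD", "EMCI"), "not present")
  expect_error(classifyGroups(tab, "AD", "NC", nFolds = 5), "exceeds")
})

test_that("test-fold statistics never enter the feature standardization", {
  withr::with_seed(29, {
    trainX <- matrix(rnorm(40), 10, 4)
    trainY <- factor(rep(c("AD", "NC"), each = 5))
    testX <- matrix(rnorm(12), 3, 4)
  })
  testOutlier <- testX
  testOutlier[3, ] <- 1e6
  for (cl in c("svm", "knn", "nb")) {
    f1 <- braindynet:::.foldScores(trainX, trainY, testX, cl)
    f2 <- braindynet:::.foldScores(trainX, trainY, testOutlier, cl)
    # the transform of rows 1-2 is a fixed function of training statistics,
    # so an extreme outlier elsewhere in the test fold cannot move them
    expect_identical(as.character(f1$pred[1:2]), as.character(f2$pred[1:2]),
                     info = cl)
    expect_equal(f1$score[1:2], f2$score[1:2], info = cl)
  }
})

test_that("the ablation report compares in/out/both under identical folds", {
  tab <- makeTable(6, sep = 0.3, seed = 13)
  rep <- featureAblation(tab, tab, tab, "AD", "NC", nFolds = 3, seed = 4)
  expect_equal(rep$features, c("in", "out", "both"))
  expect_equal(rep$accuracy[1], rep$accuracy[2])
  expect_equal(rep$accuracy[1], rep$accuracy[3])
  tabOther <- makeTable(5, sep = 0.3, seed = 14)
  expect_error(featureAblation(tab, tabOther, tab, "AD", "NC"),
               "different subjects")
})
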