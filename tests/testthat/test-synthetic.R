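test_that("generation is bit-reproducible under a fixed seed", {
  s1 <- generateSubject(syntheticSpec(m = 10, T = 50, seed = 42))
  s2 <- generateSubject(syntheticSpec(m = 10, T = 50, seed = 42))
  s3 <- generateSubject(syntheticSpec(m = 10, T = 50, seed = 43))
  expect_identical(boldMatrix(s1), boldMatrix(s2))
  expect_false(identical(boldMatrix(s1), boldMatrix(s3)))
})

test_that("long static series recover the specified block correlations", {
  spec <- syntheticSpec(m = 12, T = 2000, nModules = 3, withinCorr = 0.6,
                        betweenCorr = 0.1, noiseSd = 0, seed = 2)
  s <- generateSubject(spec)
  R <- cor(t(boldMatrix(s)))
  blocks <- rep(1:3, each = 4)
  within <- mean(R[outer(blocks, blocks, "==") & upper.tri(R)])
  between <- mean(R[outer(blocks, blocks, "!=") & upper.tri(R)])
  expect_lt(abs(within - 0.6), 0.05)
  expect_lt(abs(between - 0.1), 0.05)
})

test_that("correlation estimation error shrinks as the series lengthens", {
  blocks <- rep(1:3, each = 4)
  target <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.6, 0.1))
  err <- vapply(c(150L, 3000L), function(T) {
    s <- generateSubject(syntheticSpec(m = 12, T = T, noiseSd = 0, seed = 6))
    R <- cor(t(boldMatrix(s)))
    mean(abs((R - target)[upper.tri(R)]))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("observation noise attenuates correlations as 1/(1 + noiseSd^2)", {
  s <- generateSubject(syntheticSpec(m = 12, T = 2000, noiseSd = 0.5, seed = 3))
  R <- cor(t(boldMatrix(s)))
  blocks <- rep(1:3, each = 4)
  within <- mean(R[outer(blocks, blocks, "==") & upper.tri(R)])
  expect_lt(abs(within - 0.6 / 1.25), 0.05)
})

test_that("an acquisition-scale subject has the expected shape", {
  s <- generateSubject(syntheticSpec(m = 264, T = 140, seed = 1))
  expect_equal(dim(boldMatrix(s)), c(264, 140))
})

test_that("infeasible correlation structures are rejected at generation", {
  expect_error(syntheticSpec(withinCorr = 1.2), "in \\(-1, 1\\)")
  expect_error(generateSubject(syntheticSpec(m = 12, nModules = 2,
                                             withinCorr = -0.5)),
               "positive semi-definite")
})

test_that("drifting covariance models generate and stay within range", {
  for (dm in c("linear_mixing", "oscillatory")) {
    s <- generateSubject(syntheticSpec(m = 12, T = 60, driftModel = dm,
                                       seed = 4))
    expect_true(all(is.finite(boldMatrix(s))))
  }
})

test_that("cohort generation writes a valid, reproducible manifest tree", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- syntheticSpec(m = 8, T = 30, seed = 10)
  mp1 <- generateCohort(spec, nPerGroup = 1L, groups = c(NC = 0, AD = -0.2),
                        dir = d1)
  mp2 <- generateCohort(spec, nPerGroup = 1L, groups = c(NC = 0, AD = -0.2),
                        dir = d2)
  man <- readManifest(mp1)
  expect_equal(nrow(man), 2)
  expect_setequal(man$group, c("NC", "AD"))
  for (f in basename(man$path))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("group effects shift within-module correlation as specified", {
  base <- syntheticSpec(m = 12, T = 2000, withinCorr = 0.7, noiseSd = 0,
                        seed = 5)
  hi <- generateSubject(base)
  lo <- generateSubject(syntheticSpec(m = 12, T = 2000, withinCorr = 0.7,
                                      groupEffect = -0.3, noiseSd = 0,
                                      seed = 5))
  blocks <- rep(1:3, each = 4)
  wcor <- function(s) {
    R <- cor(t(boldMatrix(s)))
    mean(R[outer(blocks, blocks, "==") & upper.tri(R)])
  }
  expect_lt(abs(wcor(hi) - 0.7), 0.05)
  expect_lt(abs(wcor(lo) - 0.4), 0.05)
})

test_that("the dynamics truth generator is self-consistent and exact", {
  tr0 <- generateDynamicsTruth(4, 6, seed = 9, noiseSd = 0)
  # noiseless emitted snapshots equal the evaluator bit for bit
  for (k in seq_along(tr0$sequence@matrices))
    expect_identical(tr0$sequence@matrices[[k]],
                     tr0$exact(tr0$sequence@times[k]))
  # zero generator: constant trajectory
  trz <- generateDynamicsTruth(4, 5, seed = 9, beta = 0, noiseSd = 0)
  for (M in snapshotMatrices(trz$sequence))
    expect_equal(M, snapshotMatrices(trz$sequence)[[1]])
})

test_that("two-node diffusion matches the scalar closed form", {
  tr <- generateDynamicsTruth(2, 5, seed = 3, beta = 0.4, noiseSd = 0)
  # L on a single edge has eigenvalues {0, 2}; with X(t) = E X0 E and
  # E = exp(-beta L t / 2), averages are conserved and differences decay
  # like exp(-beta * 2 * t / 2) on each side
  X0 <- tr$exact(0)
  f <- exp(-0.4 * 1.5)        # per-side decay factor at t = 1.5
  E <- matrix(c(1 + f, 1 - f, 1 - f, 1 + f) / 2, 2, 2)
  expect_equal(tr$exact(1.5), E %*% X0 %*% E, tolerance = 1e-12)
})

test_that("truth sequences carry seeded observation noise by default", {
  trA <- generateDynamicsTruth(4, 6, seed = 9)
  trB <- generateDynamicsTruth(4, 6, seed = 9)
  expect_identical(snapshotMatrices(trA$sequence),
                   snapshotMatrices(trB$sequence))
  resid <- snapshotMatrices(trA$sequence)[[2]] - trA$exact(1)
  expect_gt(sd(as.numeric(resid)), 0.005)
  expect_lt(sd(as.numeric(resid)), 0.05)
})
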