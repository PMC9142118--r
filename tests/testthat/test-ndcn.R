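test_that("coupling graph reduces to the thresholded snapshot for trivial sequences", {
  M <- matrix(c(1, .8, .2, .8, 1, .5, .2, .5, 1), 3, 3)
  seq1 <- SnapshotSequence(list(M), times = 0)
  cg1 <- buildCouplingGraph(seq1, density = 1 / 3)   # keep 1 of 3 pairs
  expect_equal(cg1@adjacency[1, 2], 0.8)
  expect_equal(sum(cg1@adjacency > 0), 2)            # symmetric single edge

  seq2 <- SnapshotSequence(list(M, M), times = 0:1)  # mean is idempotent
  cg2 <- buildCouplingGraph(seq2, density = 1 / 3)
  expect_equal(cg2@adjacency, cg1@adjacency)
  expect_error(buildCouplingGraph(SnapshotSequence(list(), numeric())), "empty")
})

test_that("the normalized operator matches hand arithmetic and is contractive", {
  M <- matrix(c(1, .6, .3, .6, 1, .2, .3, .2, 1), 3, 3)
  cg <- buildCouplingGraph(SnapshotSequence(list(M), times = 0), density = 1)
  A <- matrix(c(0, .6, .3, .6, 0, .2, .3, .2, 0), 3, 3)
  Ahat <- A + diag(3)
  D <- rowSums(Ahat)
  expect_equal(cg@operator, Ahat * outer(1 / sqrt(D), 1 / sqrt(D)))
  expect_lte(max(abs(eigen(cg@operator, symmetric = TRUE)$values)), 1 + 1e-12)
})

test_that("the dynamics right-hand side matches explicit dense arithmetic", {
  m <- 4; d <- 3
  mdl <- analyticModel(m, d, diag(m), matrix(0, d, d))
  expect_equal(ndcnRhs(mdl, matrix(1, m, d)), matrix(0, m, d))  # zero weights, linear

  mdlNeg <- analyticModel(m, d, diag(m), -diag(d))
  H <- matrix(rnorm(m * d), m, d)
  expect_equal(ndcnRhs(mdlNeg, H), -H)

  withr::with_seed(5, {
    P <- symm(matrix(rnorm(16), 4, 4))
    Wh <- matrix(rnorm(9), 3, 3)
    bh <- rnorm(3)
  })
  mdlT <- analyticModel(4, 3, P, Wh, activation = "tanh")
  mdlT@weights$bh <- bh
  expect_equal(ndcnRhs(mdlT, H),
               tanh(P %*% H %*% Wh + matrix(bh, 4, 3, byrow = TRUE)))
  expect_error(ndcnRhs(mdlT, matrix(0, 2, 2)), "shape")
})

test_that("integration reproduces closed forms", {
  # zero dynamics, identity codec: exact identity at every time
  mdl0 <- analyticModel(3, 3, diag(3), matrix(0, 3, 3))
  X0 <- matrix(rnorm(9), 3, 3)
  out <- ndcnIntegrate(mdl0, X0, times = c(0, 0.3, 1.7, 4))
  for (X in out) expect_equal(X, X0)

  # dx/dt = -x: P = I, Wh = -I
  mdl1 <- analyticModel(2, 2, diag(2), -diag(2))
  X1 <- ndcnIntegrate(mdl1, diag(2), times = 1)[[1]]
  expect_equal(X1[1, 1], exp(-1), tolerance = 1e-3)

  # graph diffusion on one edge: dX/dt = -L X
  L <- matrix(c(1, -1, -1, 1), 2, 2)
  mdl2 <- analyticModel(2, 2, L, -diag(2))
  for (tt in c(0.5, 1, 2)) {
    X <- ndcnIntegrate(mdl2, diag(2), times = tt)[[1]]
    expect_equal(X[1, 1], (1 + exp(-2 * tt)) / 2, tolerance = 1e-3)
    expect_equal(X[2, 1], (1 - exp(-2 * tt)) / 2, tolerance = 1e-3)
  }
  expect_equal(ndcnIntegrate(mdl2, diag(2), times = numeric()), list())
})

test_that("Euler error halves as the step halves (first-order convergence)", {
  errAt <- function(h) {
    mdl <- analyticModel(2, 2, diag(2), -diag(2), solver = "euler", h = h)
    abs(ndcnIntegrate(mdl, diag(2), times = 1)[[1]][1, 1] - exp(-1))
  }
  errs <- vapply(c(0.1, 0.05, 0.025, 0.0125), errAt, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 1.8 & ratios < 2.2))
})

test_that("reverse-mode gradients agree with finite differences", {
  withr::with_seed(12, {
    obsM <- lapply(1:3, function(i) symm(matrix(rnorm(16), 4, 4)))
  })
  obsT <- c(0, 0.9, 2)
  P <- diag(4)
  for (act in c("tanh", "linear")) for (ln in c("l2")) {
    w <- braindynet:::.initWeights(4, 3, 1)
    w$Wh <- matrix(0.1, 3, 3)
    lg <- braindynet:::.lossGrad(w, P, obsM[[1]], obsT, obsM, "rk4", 0.25, ln, act)
    for (nm in names(w)) {
      i <- 2L
      w2 <- w; w2[[nm]][i] <- w2[[nm]][i] + 1e-6
      num <- (braindynet:::.lossGrad(w2, P, obsM[[1]], obsT, obsM, "rk4",
                                     0.25, ln, act, wantGrad = FALSE)$loss -
              lg$loss) / 1e-6
      expect_equal(lg$grad[[nm]][i], num, tolerance = 1e-4,
                   info = paste(act, nm))
    }
  }
})

test_that("a stationary snapshot sequence is fitted to near-zero loss", {
  M <- matrix(0.3, 4, 4); diag(M) <- 1
  seq0 <- SnapshotSequence(rep(list(M), 5), times = 0:4)
  mod <- fitNdcn(seq0, config = ndcnConfig(epochs = 150))
  expect_lt(mod@finalLoss, 0.05)
  preds <- predictInSnapshots(mod, times = c(0.5, 2.5, 4.5))
  for (X in snapshotMatrices(preds)) expect_lt(mean(abs(X - M)), 0.1)
  outs <- predictOutSnapshots(mod, horizon = 3)
  expect_length(outs, 3)
  for (X in snapshotMatrices(outs)) expect_lt(mean(abs(X - M)), 0.15)
})

test_that("training is deterministic given the seed and insensitive across seeds", {
  tr <- generateDynamicsTruth(4, 6, seed = 3)
  cfg <- ndcnConfig(epochs = 80, seed = 7L)
  m1 <- fitNdcn(tr$sequence, config = cfg)
  m2 <- fitNdcn(tr$sequence, config = cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@finalLoss, m2@finalLoss)
  m3 <- fitNdcn(tr$sequence, config = ndcnConfig(epochs = 80, seed = 8L))
  expect_lt(abs(m3@finalLoss - m1@finalLoss), 0.05)
})

test_that("the trajectory at training times reproduces the final training loss", {
  tr <- generateDynamicsTruth(4, 6, seed = 2)
  mod <- fitNdcn(tr$sequence, config = ndcnConfig(epochs = 60))
  preds <- ndcnIntegrate(mod, times = mod@trainTimes)
  obs <- snapshotMatrices(tr$sequence)
  l1 <- mean(vapply(seq_along(obs), function(i)
    mean(abs(preds[[i]] - obs[[i]])), numeric(1)))
  expect_equal(l1, mod@finalLoss, tolerance = 1e-10)
})

test_that("prediction contracts: counts, spans and edge cases", {
  tr <- generateDynamicsTruth(4, 8, seed = 5)
  mod <- fitNdcn(tr$sequence, config = ndcnConfig(epochs = 40))
  ins <- predictInSnapshots(mod)
  expect_length(ins, 8)                       # one per volume index
  expect_equal(provenance(ins), rep("in", 8))
  for (X in snapshotMatrices(ins)) expect_equal(X, t(X))
  expect_length(predictInSnapshots(mod, times = numeric()), 0)
  expect_error(predictInSnapshots(mod, times = 9), "extrapolation")
  outs <- predictOutSnapshots(mod, 5)
  expect_length(outs, 5)
  expect_equal(snapshotTimes(outs), 8:12)
  expect_equal(provenance(outs), rep("out", 5))
  expect_true(all(vapply(snapshotMatrices(outs),
                         function(X) all(X >= -1 & X <= 1), logical(1))))
  expect_length(predictOutSnapshots(mod, 0), 0)
})

test_that("model archives round-trip and reject foreign schemas", {
  tr <- generateDynamicsTruth(4, 6, seed = 6)
  mod <- fitNdcn(tr$sequence, config = ndcnConfig(epochs = 30))
  f <- withr::local_tempfile(fileext = ".json")
  saveNdcnModel(mod, f)
  back <- loadNdcnModel(f)
  expect_equal(back@weights, mod@weights, tolerance = 1e-12)
  p1 <- ndcnIntegrate(mod, times = c(1.5, 4.2))
  p2 <- ndcnIntegrate(back, times = c(1.5, 4.2))
  expect_equal(p1, p2, tolerance = 1e-12)
  obj <- jsonlite::read_json(f)
  obj$schema <- "something-else"
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(loadNdcnModel(f), "schema")
})
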