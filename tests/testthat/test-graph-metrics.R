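test_that("proportional thresholding keeps the strongest pairs deterministically", {
  full <- binarizeSnapshot(matrix(1, 4, 4), density = 1)
  expect_equal(nrow(full@edges), 6)                     # K4

  M <- matrix(0.1, 3, 3); diag(M) <- 1; M[1, 3] <- M[3, 1] <- 0.9
  g1 <- binarizeSnapshot(M, density = 1 / 3)            # keep 1 of 3
  expect_equal(g1@edges, matrix(c(1L, 3L), 1, 2))

  tied <- matrix(0.5, 4, 4); diag(tied) <- 1            # all-equal weights
  a <- binarizeSnapshot(tied, density = 0.5)
  b <- binarizeSnapshot(tied, density = 0.5)
  expect_identical(a@edges, b@edges)
  expect_equal(nrow(a@edges), 3)

  expect_error(binarizeSnapshot(tied, density = 0.01), "zero edges")
})

test_that("clustering and path length match brute-force enumeration", {
  withr::with_seed(44, {
    for (i in 1:30) {
      m <- sample(4:12, 1)
      p <- runif(1, 0.25, 0.8)
      A <- matrix(0, m, m)
      A[upper.tri(A)] <- runif(m * (m - 1) / 2) < p
      e <- which(A == 1, arr.ind = TRUE)
      if (nrow(e) < 2) next
      g <- makeGraph(m, e)
      expect_equal(globalClustering(g), bruteClustering(g),
                   info = sprintf("clustering m=%d rep=%d", m, i))
      expect_equal(charPathLength(g), brutePathLength(g),
                   info = sprintf("path m=%d rep=%d", m, i))
    }
  })
})

test_that("clustering and path length reproduce textbook values", {
  k4 <- binarizeSnapshot(matrix(1, 4, 4), density = 1)
  expect_equal(globalClustering(k4), 1)
  expect_equal(charPathLength(k4), 1)

  path4 <- makeGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(globalClustering(path4), 0)

  triPendant <- makeGraph(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
  expect_equal(globalClustering(triPendant), 0.6)

  path3 <- makeGraph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(charPathLength(path3), 4 / 3)

  twoEdges <- makeGraph(4, rbind(c(1, 2), c(3, 4)))   # disconnected
  expect_equal(charPathLength(twoEdges), 1)

  expect_error(charPathLength(makeGraph(3, matrix(integer(), 0, 2))),
               "edgeless")
})

test_that("rewired references preserve the degree multiset and vary by seed", {
  withr::with_seed(3, {
    A <- matrix(0, 20, 20)
    A[upper.tri(A)] <- runif(190) < 0.25
    g <- makeGraph(20, which(A == 1, arr.ind = TRUE))
  })
  deg <- function(x) sort(tabulate(x@edges, nbins = x@nNodes))
  r1 <- randomReference(g, seed = 1)
  r2 <- randomReference(g, seed = 2)
  r1b <- randomReference(g, seed = 1)
  expect_equal(deg(r1), deg(g))
  expect_equal(deg(r2), deg(g))
  expect_identical(r1@edges, r1b@edges)            # seeded determinism
  expect_false(identical(r1@edges, r2@edges))

  star <- makeGraph(5, cbind(1L, 2:5))
  expect_warning(rs <- randomReference(star, seed = 1), "no rewiring")
  expect_identical(rs@edges, star@edges)
})

test_that("small-world indices separate lattice-like from random graphs", {
  ring <- withr::with_seed(7, igraphToGraph(igraph::sample_smallworld(1, 30, 2, 0.1)))
  recRing <- smallWorld(ring, nRandom = 10, seed = 3)
  expect_gt(recRing$sigma, 1)
  expect_gt(recRing$gamma, 1.5)

  er <- withr::with_seed(9, igraphToGraph(igraph::sample_gnp(30, 0.4)))
  recEr <- smallWorld(er, nRandom = 10, seed = 3)
  expect_gt(recEr$sigma, 0.8)
  expect_lt(recEr$sigma, 1.2)

  expect_equal(recRing$sigma, recRing$gamma / recRing$lambda)
  expect_equal(recRing$gamma, recRing$C / recRing$C_R)
  expect_equal(recRing$lambda, recRing$L / recRing$L_R)
})

test_that("rewiring cannot change a complete graph, so sigma is exactly 1", {
  k6 <- binarizeSnapshot(matrix(1, 6, 6), density = 1)
  rec <- smallWorld(k6, nRandom = 5, seed = 1)
  expect_identical(rec$gamma, 1)
  expect_identical(rec$lambda, 1)
  expect_identical(rec$sigma, 1)
})

test_that("triangle-free references make gamma undefined, not infinite", {
  p4 <- makeGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  rec <- smallWorld(p4, nRandom = 3, seed = 1)
  expect_true(is.na(rec$sigma))
})

test_that("the small-world fraction counts snapshots with sigma above 1", {
  M <- matrix(0.05, 12, 12)
  M[1:4, 1:4] <- M[5:8, 5:8] <- M[9:12, 9:12] <- 0.8   # modular: high clustering
  diag(M) <- 1
  seq1 <- SnapshotSequence(rep(list(M), 3), times = 0:2)
  res <- smallWorldFraction(seq1, density = 0.25, nRandom = 8, seed = 2)
  expect_equal(res$total, 3)
  expect_equal(res$fraction, 1)
  expect_match(res$label, "^100.0%\\(3/3\\)$")
  expect_equal(nrow(res$table), 3)

  single <- smallWorldFraction(seq1[1], density = 0.25, nRandom = 4, seed = 2)
  expect_equal(single$total, 1)
})
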