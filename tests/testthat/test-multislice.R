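## planted two-block graphs for multislice tests
plantedBlocks <- function(n = 20, pIn = 0.8, pOut = 0.05, seed = 1,
                          blocks = rep(1:2, each = n / 2)) {
  set.seed(seed)
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) pIn else pOut
    a[i, j] <- rbinom(1, 1, p)
  }
  a <- a | t(a)
  ## guarantee no empty slice pathology
  if (sum(a) == 0) a[1, 2] <- a[2, 1] <- TRUE
  a
}

test_that("multislice quality beats trivial partitions and the optimizer is deterministic", {
  slices <- array(0, c(20, 20, 4))
  for (s in 1:4) slices[, , s] <- plantedBlocks(seed = s)
  m <- multislicePartition(slices, gamma = 1.5, omega = 0.1, seed = 7)
  expect_equal(dim(m), c(20, 4))
  q <- attr(m, "quality")
  qSingle <- multisliceQuality(slices, matrix(seq_len(80), 20, 4), 1.5, 0.1)
  qAll <- multisliceQuality(slices, matrix(1L, 20, 4), 1.5, 0.1)
  expect_gt(q, qSingle)
  expect_gt(q, qAll)
  expect_equal(q, multisliceQuality(slices, m, 1.5, 0.1), tolerance = 1e-9)
  m2 <- multislicePartition(slices, gamma = 1.5, omega = 0.1, seed = 7)
  expect_identical(unclass(m), unclass(m2))
})

test_that("single slice reduces to single-graph Louvain quality at the same resolution", {
  adj <- plantedBlocks(seed = 11)
  m <- multislicePartition(adj, gamma = 1, omega = 0, seed = 3)
  g <- igraph::graph_from_adjacency_matrix(adj * 1, "undirected")
  set.seed(3)
  ref <- igraph::cluster_louvain(g)
  qOur <- multisliceQuality(adj, m, gamma = 1, omega = 0)
  ## normalize our unnormalized quality to modularity units: Q = q / (2m),
  ## and sum(adj) over the symmetric matrix is exactly 2m
  qOurNorm <- qOur / sum(adj)
  expect_equal(qOurNorm, igraph::modularity(g, igraph::membership(ref)),
               tolerance = 0.02)
  ## planted blocks are recovered
  expect_equal(length(unique(m[, 1])), 2)
})

test_that("strong coupling aligns labels across slices; zero coupling decouples them", {
  slices <- array(0, c(20, 20, 3))
  for (s in 1:3) slices[, , s] <- plantedBlocks(seed = 20 + s)
  mStrong <- multislicePartition(slices, gamma = 1.5, omega = 100, seed = 5)
  expect_true(all(mStrong[, 1] == mStrong[, 2] & mStrong[, 2] == mStrong[, 3]))
  ## omega = 0: total quality equals the sum of per-slice qualities
  m0 <- multislicePartition(slices, gamma = 1.5, omega = 0, seed = 5)
  qTotal <- multisliceQuality(slices, m0, gamma = 1.5, omega = 0)
  qSum <- sum(vapply(1:3, function(s)
    multisliceQuality(slices[, , s, drop = FALSE],
                      m0[, s, drop = FALSE], gamma = 1.5, omega = 0),
    numeric(1)))
  expect_equal(qTotal, qSum, tolerance = 1e-9)
})

test_that("agreement matrices track planted block structure", {
  slices <- array(0, c(20, 20, 8))
  for (s in 1:8) slices[, , s] <- plantedBlocks(seed = 30 + s)
  am <- agreementMatrix(slices, nReps = 8, seed = 2)
  expect_equal(diag(am), rep(1, 20))
  expect_true(all(am >= 0 & am <= 1))
  expect_equal(am, t(am), tolerance = 1e-12)
  blocks <- rep(1:2, each = 10)
  within <- am[outer(blocks, blocks, "==") & upper.tri(am)]
  between <- am[outer(blocks, blocks, "!=") & upper.tri(am)]
  expect_gt(mean(within), 0.9)
  expect_lt(mean(between), 0.1)
  ## subsampling keeps the estimator stable on homogeneous groups
  amSub <- agreementMatrix(slices, nSubsample = 6, nReps = 20, seed = 3)
  expect_lt(sqrt(mean((amSub - am)^2)), 0.1)
})

test_that("difference matrix and nodal reorganization behave under group swap", {
  slices <- array(0, c(20, 20, 6))
  for (s in 1:6) slices[, , s] <- plantedBlocks(seed = 40 + s)
  amA <- agreementMatrix(slices, nReps = 5, seed = 1)
  ## group B: nodes 5 and 15 switch blocks
  blocksB <- rep(1:2, each = 10); blocksB[c(5, 15)] <- c(2, 1)
  slicesB <- array(0, c(20, 20, 6))
  for (s in 1:6) slicesB[, , s] <- plantedBlocks(seed = 50 + s, blocks = blocksB)
  amB <- agreementMatrix(slicesB, nReps = 5, seed = 1)
  dr <- differenceAndReorg(amB, amA)
  expect_equal(dr$diff, -differenceAndReorg(amA, amB)$diff, tolerance = 1e-12)
  expect_equal(dr$reorg$reorg, differenceAndReorg(amA, amB)$reorg$reorg,
               tolerance = 1e-12)
  expect_equal(dr$reorg$reorg, dr$reorg$positive + abs(dr$reorg$negative),
               tolerance = 1e-12)
  ## switched nodes attain the largest reorganization scores
  top <- order(dr$reorg$reorg, decreasing = TRUE)[1:2]
  expect_setequal(top, c(5, 15))
  ## identical groups: near-zero reorganization
  dr0 <- differenceAndReorg(amA, amA)
  expect_equal(max(abs(dr0$diff)), 0)
  expect_error(differenceAndReorg(amA[1:10, 1:10], amB), "shape")
})

test_that("permutation null separates planted reorganization from an exchangeable null", {
  ## planted: two nodes switch blocks in the patient group; they must carry
  ## the smallest permutation p (other nodes also shift somewhat, since
  ## their agreement WITH the switched nodes genuinely changes)
  blocksB <- rep(1:2, each = 10); blocksB[c(3, 17)] <- c(2, 1)
  nP <- 8; nC <- 8
  adjP <- array(0, c(20, 20, nP)); adjC <- array(0, c(20, 20, nC))
  for (s in 1:nP) adjP[, , s] <- plantedBlocks(seed = 60 + s, blocks = blocksB)
  for (s in 1:nC) adjC[, , s] <- plantedBlocks(seed = 80 + s)
  res <- reorgPermutationNull(adjP, adjC, nPerm = 199, nReps = 2,
                              seed = 4, alpha = 0.05)
  expect_equal(nrow(res$observed), 20)
  expect_true(all(res$observed$perm_p >= 1 / 200))
  expect_true(all(res$observed$perm_p[c(3, 17)] <= 0.05))
  expect_setequal(order(res$observed$reorg, decreasing = TRUE)[1:2], c(3, 17))
  ## exchangeable null: both groups drawn from the same block structure
  adjP0 <- array(0, c(20, 20, nP)); adjC0 <- array(0, c(20, 20, nC))
  for (s in 1:nP) adjP0[, , s] <- plantedBlocks(seed = 160 + s)
  for (s in 1:nC) adjC0[, , s] <- plantedBlocks(seed = 180 + s)
  res0 <- reorgPermutationNull(adjP0, adjC0, nPerm = 199, nReps = 2,
                               seed = 4, alpha = 0.05)
  expect_lt(mean(res0$observed$perm_p <= 0.05), 0.25)
  expect_error(reorgPermutationNull(adjP, adjC, nPerm = 50), "99")
})
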