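test_that("propagation finds one cluster per well-separated clique", {
  sim <- makeBlobs(400, c(a = 0.5, b = 0.5), separation = 20, dim = 5,
                   seed = 4)
  idx <- buildKnn(sim$embedding, 20)
  q <- allQ(idx, 6)
  asg <- propagateLabels(idx, q)
  expect_true(asg@converged)
  # no cluster straddles the two blobs
  tab <- table(asg@labels, sim$labels)
  expect_true(all(rowSums(tab > 0) == 1))
  # fixed point: every cell carries its waypoint's label
  expect_true(all(asg@labels %in% asg@waypoints))
})

test_that("a cell whose Q tops its neighborhood is a waypoint", {
  # regular octagons at k = 5: each neighborhood is the symmetric
  # self +/- 2 arc, so Q is identical for every cell and strict
  # adoption never fires
  emb <- cliqueEmbedding(nCliques = 2, size = 8)
  idx <- buildKnn(emb, kParam = 8)
  q <- allQ(idx, 5)
  expect_equal(length(unique(qValues(q))), 1L)
  asg <- propagateLabels(idx, q, RareQParams(k = 5L, kParam = 8L))
  expect_equal(sort(asg@waypoints), 1:16)
  expect_equal(asg@labels, 1:16)
})

test_that("identical Q everywhere yields all-singleton clusters", {
  # evenly spaced ring at k = 3 (the symmetric self +/- 1 arc):
  # perfect symmetry forces equal Q
  n <- 12
  ang <- 2 * pi * seq_len(n) / n
  emb <- cbind(cos(ang), sin(ang))
  idx <- buildKnn(emb, kParam = 6)
  q <- allQ(idx, 3)
  expect_equal(length(unique(qValues(q))), 1L)
  expect_equal(unname(qValues(q)[1]), 7 / 9)
  asg <- propagateLabels(idx, q, RareQParams(k = 3L, kParam = 6L))
  expect_equal(asg@labels, seq_len(n))
})

test_that("voting flips an isolated dissenter and leaves a tie alone", {
  sim <- makeBlobs(300, c(a = 0.5, b = 0.5), separation = 20, dim = 5,
                   seed = 9)
  idx <- buildKnn(sim$embedding, 20)
  lab <- as.integer(factor(sim$labels))
  dissent <- lab
  dissent[1] <- 2L # cell 1 sits deep in blob a
  out <- voteRefine(idx, asAssignment(dissent, "propagated"))
  expect_equal(out@labels, lab)
  # perfectly separated labels are a voting fixed point
  out2 <- voteRefine(idx, asAssignment(lab, "propagated"))
  expect_equal(out2@labels, lab)
  # symmetric two-cell world: 1 vote each under voteK = 2 -> keep current
  emb <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, 10), d = c(0.5, 10.5))
  idx2 <- buildKnn(emb, kParam = 2)
  mixed <- c(1L, 2L, 3L, 4L)
  out3 <- voteRefine(idx2, asAssignment(mixed, "propagated"),
                     RareQParams(k = 2L, kParam = 2L))
  expect_equal(out3@labels, mixed)
})

test_that("retention keeps clusters strictly above the Q threshold", {
  st <- data.frame(cluster = 1:4, meanQ = c(0.9, 0.61, 0.6, 0.3))
  expect_equal(retainRare(st, 0.6), c(1L, 2L))
  expect_equal(retainRare(st[0, ], 0.6), integer())
  st$meanQ <- 1
  expect_equal(retainRare(st, 0.6), 1:4)
})

test_that("an artificially bisected blob re-merges into one cluster", {
  set.seed(14)
  emb <- matrix(rnorm(1000 * 5), 1000, 5)
  idx <- buildKnn(emb, 20)
  split <- rep(1:2, each = 500) # arbitrary index cut through one blob
  out <- mergeClusters(idx, asAssignment(split), integer())
  expect_equal(length(unique(out@labels)), 1L)
  # merged id is that of the larger constituent (tie -> smaller id)
  expect_equal(unique(out@labels), 1L)
})

test_that("clusters without cross edges never merge", {
  sim <- makeBlobs(400, c(a = 0.5, b = 0.5), separation = 50, dim = 5,
                   seed = 21)
  idx <- buildKnn(sim$embedding, 20)
  lab <- as.integer(factor(sim$labels))
  out <- mergeClusters(idx, asAssignment(lab), integer())
  expect_equal(out@labels, lab)
})

test_that("a singleton cluster survives strict merging but not minClusterSize", {
  set.seed(26)
  emb <- matrix(rnorm(300 * 4), 300, 4)
  idx <- buildKnn(emb, 20)
  lab <- rep(1L, 300)
  lab[7] <- 2L # singleton: Qc = 1 makes Qc(union) > 1 unsatisfiable
  out <- mergeClusters(idx, asAssignment(lab), integer())
  expect_equal(sort(unique(out@labels)), c(1L, 2L))
  forced <- mergeClusters(idx, asAssignment(lab), integer(),
                          RareQParams(minClusterSize = 2L))
  expect_equal(unique(forced@labels), 1L)
})

test_that("retained rare clusters are frozen during merging", {
  set.seed(61)
  emb <- rbind(cliqueEmbedding(nCliques = 1, size = 6, r = 0.1),
               matrix(rnorm(400 * 2, mean = 30), 400, 2))
  rownames(emb) <- paste0("c", seq_len(nrow(emb)))
  idx <- buildKnn(emb, 20)
  lab <- c(rep(99L, 6), rep(1:2, 200))
  out <- mergeClusters(idx, asAssignment(lab), rareIds = 99L)
  expect_equal(which(out@labels == 99L), 1:6)
  expect_error(mergeClusters(idx, asAssignment(lab), rareIds = 55L),
               "invalid rare set")
})

test_that("the full pipeline recovers a planted 1% rare blob perfectly", {
  sim <- makeBlobs(2000, c(major = 0.99, rare = 0.01), separation = 10,
                   dim = 10, seed = 1)
  res <- runRareQ(sim$embedding)
  expect_length(rareClusterIds(res), 1L)
  expect_equal(which(isRareCell(res)), which(sim$labels == "rare"),
               ignore_attr = TRUE)
  ev <- evaluateClustering(clusterLabels(res), sim$labels,
                           rareTypes = "rare")
  expect_equal(ev@perType$f1, 1)
  expect_equal(ev@perType$jaccard, 1)
  # every retained rare cluster clears the mean-Q threshold
  st <- clusterStats(res)
  expect_true(all(st$meanQ[st$isRare] > 0.6))
  # final ids are contiguous from 0
  expect_equal(sort(unique(clusterLabels(res))), 0:(nrow(st) - 1))
})

test_that("the pipeline is deterministic and permutation-consistent", {
  sim <- makeBlobs(600, c(major = 0.98, rare = 0.02), separation = 10,
                   dim = 8, seed = 17)
  r1 <- runRareQ(sim$embedding)
  r2 <- runRareQ(sim$embedding)
  expect_identical(clusterLabels(r1), clusterLabels(r2))
  expect_identical(qValues(r1), qValues(r2))
  # Q scores are permutation-covariant whenever distances are tie-free
  set.seed(99)
  perm <- sample(nrow(sim$embedding))
  qp <- qValues(allQ(buildKnn(sim$embedding[perm, ], 20), 6))
  expect_identical(unname(qp), unname(qValues(r1)[perm]))
  # the rare-population call against truth does not depend on cell order
  # (equal-Q tie-breaks may shift diffuse fragment boundaries, but never
  # the planted rare group)
  ev0 <- evaluateClustering(clusterLabels(r1), sim$labels,
                            rareTypes = "rare")@perType
  rp <- runRareQ(sim$embedding[perm, ])
  evp <- evaluateClustering(clusterLabels(rp), sim$labels[perm],
                            rareTypes = "rare")@perType
  expect_identical(evp$f1, ev0$f1)
  expect_identical(evp$jaccard, ev0$jaccard)
})

test_that("degenerate inputs are rejected before any work", {
  emb <- lineEmbedding(4)
  expect_error(runRareQ(emb), "insufficient cells")
  expect_error(RareQParams(qThreshold = 1.2), "0, 1")
})
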