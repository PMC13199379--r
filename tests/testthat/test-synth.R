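test_that("blob counts follow largest-remainder allocation and seeds reproduce", {
  sim <- makeBlobs(2000, c(major = 0.99, rare = 0.01), separation = 10,
                   dim = 10, seed = 5)
  expect_equal(unname(table(sim$labels)[c("major", "rare")]),
               c(1980L, 20L), ignore_attr = TRUE)
  expect_equal(dim(sim$embedding), c(2000L, 10L))
  sim2 <- makeBlobs(2000, c(major = 0.99, rare = 0.01), separation = 10,
                    dim = 10, seed = 5)
  expect_identical(sim$embedding, sim2$embedding)
  # separation 0 collapses to one mixed cloud but labels persist
  mixed <- makeBlobs(500, c(a = 0.5, b = 0.5), separation = 0, seed = 5)
  expect_lt(max(abs(colMeans(mixed$embedding[mixed$labels == "a", ]) -
                    colMeans(mixed$embedding[mixed$labels == "b", ]))), 0.5)
  expect_error(makeBlobs(50, c(0.99, 0.01)), "rare type too small")
})

test_that("generators never disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(makeBlobs(100, c(0.5, 0.5), seed = 7))
  invisible(simulateCounts(nGenes = 50, batchCells = 40, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("count simulation has the documented shape and group structure", {
  sim <- simulateCounts(nGenes = 5000, groupProb = c(0.99, 0.01),
                        batchCells = 1500, seed = 2024)
  expect_equal(dim(sim$counts), c(1500L, 5000L))
  nRare <- sum(sim$labels == "group2")
  # minority size fluctuates binomially around 15
  expect_true(nRare >= 4 && nRare <= 30)
  expect_true(all(sim$counts >= 0))
  # forced group sizes are exact
  forced <- simulateCounts(nGenes = 100, batchCells = 200,
                           groupSizes = c(190, 10), seed = 1)
  expect_equal(unname(table(forced$labels)), c(190L, 10L),
               ignore_attr = TRUE)
  expect_error(simulateCounts(groupProb = c(0.7, 0.7), seed = 1),
               "invalid params")
  expect_error(simulateCounts(outProb = 0.05, seed = 1), "not implemented")
})

test_that("a null simulation carries no group signal, a DE one does", {
  # deProb = 0: both groups share every gene mean
  null <- simulateCounts(nGenes = 300, batchCells = 400, deProb = 0,
                         seed = 3)
  expect_true(all(null$deFactors == 1))
  # with DE, group means differ for DE genes and match for the rest:
  # average over 20 seeds
  deltaDE <- deltaNull <- numeric()
  for (s in 1:20) {
    sim <- simulateCounts(nGenes = 200, batchCells = 300,
                          groupProb = c(0.5, 0.5), deProb = 0.4,
                          deFacLoc = 1, deFacScale = 0.2, seed = s)
    g1 <- sim$labels == "group1"
    norm <- logNormalize(sim$counts)
    d <- abs(colMeans(norm[g1, ]) - colMeans(norm[!g1, ]))
    isDe <- sim$deFactors[, 1] != 1 | sim$deFactors[, 2] != 1
    deltaDE <- c(deltaDE, mean(d[isDe]))
    deltaNull <- c(deltaNull, mean(d[!isDe]))
  }
  expect_gt(mean(deltaDE), 3 * mean(deltaNull))
})

test_that("empirical gene means track the drawn gamma means", {
  sim <- simulateCounts(nGenes = 800, batchCells = 1500, deProb = 0,
                        seed = 10)
  expect_gt(cor(colMeans(sim$counts), sim$geneMeans, method = "spearman"),
            0.9)
})

test_that("down-sampling hits rare quotas exactly and majors proportionally", {
  set.seed(55)
  src <- sample(rep(c("A", "B", "C", "D", "rare"),
                    c(4000, 3000, 2000, 1000, 200)))
  idx <- downsampleByType(src, c("A", "B", "C", "D"), "rare",
                          total = 5000, rareCount = 50, seed = 8)
  got <- table(src[idx])
  expect_equal(got[["rare"]], 50L)
  expect_equal(sum(got), 5000L)
  # majors in source proportion via largest remainder of 4950
  expect_equal(unname(got[c("A", "B", "C", "D")]),
               largestRemainder(4950, c(4000, 3000, 2000, 1000)),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(idx) > 0)
  # proportional mode covers every listed type by frequency
  idx2 <- downsampleByType(src, c("A", "B"), c("rare"), total = 1000,
                           rareCount = NULL, seed = 8)
  expect_equal(unname(table(src[idx2])[c("A", "B", "rare")]),
               largestRemainder(1000, c(4000, 3000, 200)),
               ignore_attr = TRUE)
  # all available rare cells is a valid quota
  idx3 <- downsampleByType(src, "A", "rare", total = 400, rareCount = 200,
                           seed = 8)
  expect_equal(sum(src[idx3] == "rare"), 200L)
  expect_error(downsampleByType(src, "A", "rare", 300, rareCount = 500,
                                seed = 1), "cannot satisfy quota")
})

test_that("DEG titration replaces genes reproducibly with nested sets", {
  null <- simulateCounts(nGenes = 120, batchCells = 60, deProb = 0,
                         seed = 4)$counts
  pool <- simulateCounts(nGenes = 30, batchCells = 60, deProb = 0.5,
                         seed = 5)$counts
  colnames(pool) <- paste0("P", 1:30)
  expect_identical(degTitration(null, pool, 0, seed = 9), null)
  t10 <- degTitration(null, pool, 10, seed = 9)
  t20 <- degTitration(null, pool, 20, seed = 9)
  ch10 <- which(colSums(t10 != null) > 0)
  ch20 <- which(colSums(t20 != null) > 0)
  expect_length(setdiff(ch10, ch20), 0) # nested sampling
  expect_lte(length(ch10), 10)
  # the full pool lands exactly once
  tAll <- degTitration(null, pool, 30, seed = 9)
  expect_equal(sum(grepl("^deg_P", colnames(tAll))), 30)
  expect_error(degTitration(null, pool, 31, seed = 9),
               "titration exceeds pool")
})

test_that("fold-change perturbation touches only target cells and genes", {
  counts <- matrix(4, 10, 20, dimnames = list(paste0("c", 1:10),
                                              paste0("g", 1:20)))
  out <- perturbUpregulate(counts, targetCells = 1:3, nGenes = 5, fold = 3,
                           seed = 2)
  changed <- which(colSums(out != counts) > 0)
  expect_length(changed, 5)
  expect_true(all(out[1:3, changed] == 12))
  expect_identical(out[4:10, ], counts[4:10, ])
  expect_identical(perturbUpregulate(counts, 1:3, 5, fold = 1, seed = 2),
                   counts)
  expect_error(perturbUpregulate(counts, integer(), 5, seed = 2),
               "no target cells")
})

test_that("the multi-scale series forces exact rare counts per scale", {
  series <- multiscaleSeries(scales = c(200, 500), rareN = 10, seed = 6,
                             nGenes = 100)
  expect_length(series, 2)
  expect_equal(vapply(series, function(d) sum(d$labels == "group2"),
                      integer(1)), c(n200 = 10L, n500 = 10L))
  series2 <- multiscaleSeries(scales = c(200, 500), rareN = 10, seed = 6,
                              nGenes = 100)
  expect_identical(series$n200$counts, series2$n200$counts)
  expect_error(multiscaleSeries(scales = c(10, 200), rareN = 10, seed = 1),
               "invalid scale")
})
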