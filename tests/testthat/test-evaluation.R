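test_that("majority annotation takes the modal type, ties alphabetical", {
  pred <- rep(c("x", "y", "z"), c(10, 10, 4))
  truth <- c(rep("A", 9), "B", rep("A", 5), rep("B", 5), rep("C", 4))
  ann <- annotateClusters(pred, truth)
  expect_equal(ann[["x"]], "A")
  expect_equal(ann[["y"]], "A") # 5 A vs 5 B -> alphabetically first
  expect_equal(ann[["z"]], "C")
})

test_that("precision, recall, F1 and Jaccard match their closed forms", {
  # one cluster annotated rare with TP=8, FP=2; FN=2 rare cells elsewhere
  truth <- rep(c("rare", "maj"), c(10, 40))
  pred <- c(rep("p", 8), "q", "q", rep("p", 2), rep("q", 38))
  prf <- rarePRF(pred, truth, "rare")
  expect_equal(unname(prf), c(0.8, 0.8, 0.8))
  # Jaccard 5/10
  truth2 <- rep(c("rare", "maj"), c(7, 20))
  pred2 <- c(rep("a", 5), "b", "b", rep("a", 3), rep("b", 17))
  expect_equal(jaccardIndex(pred2, truth2, "rare"), 0.5)
  # perfect single-cluster recovery
  expect_equal(unname(rarePRF(rep(1:2, c(5, 20)), rep(c("r", "m"), c(5, 20)),
                              "r")), c(1, 1, 1))
  expect_equal(jaccardIndex(rep(1:2, c(5, 20)), rep(c("r", "m"), c(5, 20)),
                            "r"), 1)
  # no cluster annotated to the rare type
  truth3 <- rep(c("rare", "maj"), c(2, 48))
  pred3 <- rep("all", 50)
  expect_equal(unname(rarePRF(pred3, truth3, "rare")), c(0, 0, 0))
  expect_error(rarePRF(pred3, truth3, "ghost"), "type not in truth")
})

test_that("F1 equals the harmonic mean identity on random partitions", {
  set.seed(41)
  for (trial in 1:50) {
    n <- sample(20:200, 1)
    truth <- sample(c("r", "m1", "m2"), n, replace = TRUE,
                    prob = c(0.15, 0.5, 0.35))
    if (!"r" %in% truth) next
    pred <- sample(1:5, n, replace = TRUE)
    prf <- rarePRF(pred, truth, "r")
    if (prf[["precision"]] + prf[["recall"]] > 0)
      expect_equal(prf[["f1"]],
                   2 * prf[["precision"]] * prf[["recall"]] /
                     (prf[["precision"]] + prf[["recall"]]))
    # brute-force set comparison oracle
    ann <- annotateClusters(pred, truth)
    S <- which(pred %in% as.integer(names(ann)[ann == "r"]))
    T_ <- which(truth == "r")
    expect_equal(prf[["precision"]],
                 if (length(S)) length(intersect(S, T_)) / length(S) else 0)
    expect_equal(prf[["recall"]], length(intersect(S, T_)) / length(T_))
    expect_equal(jaccardIndex(pred, truth, "r"),
                 if (length(union(S, T_)))
                   length(intersect(S, T_)) / length(union(S, T_)) else 0)
  }
})

test_that("metrics are invariant to cluster relabeling", {
  set.seed(43)
  truth <- sample(c("r", "m"), 100, replace = TRUE, prob = c(0.2, 0.8))
  pred <- sample(1:4, 100, replace = TRUE)
  relab <- c(9L, 7L, 5L, 3L)[pred]
  expect_equal(rarePRF(pred, truth, "r"), rarePRF(relab, truth, "r"))
  expect_equal(nmi(pred, truth), nmi(relab, truth))
})

test_that("NMI honors its conventions and matches an independent oracle", {
  expect_equal(nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # zero-entropy conventions
  expect_equal(nmi(rep(1, 6), rep("a", 6)), 1)
  expect_equal(nmi(rep(1, 6), c("a", "a", "a", "b", "b", "b")), 0)
  # near-zero dependence for independent labelings at n = 10,000
  set.seed(47)
  a <- sample(1:4, 10000, replace = TRUE)
  b <- sample(1:4, 10000, replace = TRUE)
  expect_lt(nmi(a, b), 0.01)
  # igraph's Danon et al. NMI (mean-entropy normalization) as oracle
  skip_if_not_installed("igraph")
  for (trial in 1:10) {
    x <- sample(1:5, 300, replace = TRUE)
    y <- sample(1:3, 300, replace = TRUE)
    expect_equal(nmi(x, y), igraph::compare(x, y, method = "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("evaluateClustering derives rare types from the <1% rule", {
  truth <- rep(c("big", "mid", "tiny"), c(800, 195, 5))
  pred <- rep(c(1, 2, 3), c(800, 195, 5))
  rep_ <- evaluateClustering(pred, truth)
  expect_equal(rep_@rareTypes, "tiny")
  expect_equal(rep_@perType$f1, 1)
  expect_equal(rep_@nmi, 1)
  # explicit override
  rep2 <- evaluateClustering(pred, truth, rareTypes = c("mid", "tiny"))
  expect_equal(rep2@perType$type, c("mid", "tiny"))
})
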