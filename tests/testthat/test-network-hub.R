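starGraph <- function() {
  g <- igraph::make_star(5, mode = "undirected")
  igraph::V(g)$name <- c("c", "l1", "l2", "l3", "l4")
  g
}

test_that("centralities are exact on hand-checkable graphs", {
  ct <- computeCentralities(starGraph())
  ctr <- ct[ct$node == "c", ]
  expect_equal(ctr$degree, 4)
  expect_equal(ctr$betweenness, 6)           # all C(4,2) leaf pairs
  expect_equal(ctr$closeness, 4)             # four distance-1 neighbours
  expect_equal(ct$closeness[ct$node == "l1"], 1 + 3 / 2)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  ck <- computeCentralities(k4)
  expect_true(all(ck$betweenness == 0))
  expect_true(all(ck$degree == 3))
  path <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c"), c("b", "c", "d")), directed = FALSE)
  cp <- computeCentralities(path)
  expect_equal(cp$betweenness[cp$node == "b"], 2)
  expect_equal(cp$betweenness[cp$node == "c"], 2)
})

test_that("centralities match brute-force enumeration on random graphs", {
  for (s in 1:30) {
    rg <- randomGraph(s, nNodes = sample(4:8, 1))
    got <- computeCentralities(rg$graph)
    want <- bruteCentralities(rg$edges, rg$nodes)
    want <- want[order(want$node), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
  }
})

test_that("maximal-clique scores follow the (|S|-1)! statistic", {
  tri <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c"), c("b", "c", "a")), directed = FALSE)
  expect_true(all(mccScores(tri) == 2))              # single 3-clique
  pend <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c", "c"), c("b", "c", "a", "d")),
    directed = FALSE)
  sc <- mccScores(pend)
  expect_equal(unname(sc["d"]), 1)                   # clique {c,d}
  expect_equal(unname(sc["c"]), 3)                   # 2! + 1!
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("x", "y", "z")
  expect_true(all(mccScores(lone) == 1))             # singleton cliques
  expect_error(mccScores(tri, cliqueBudget = 0), "budget")
})

test_that("maximal-clique scores match subset-grown enumeration", {
  for (s in 31:60) {
    rg <- randomGraph(s, nNodes = sample(5:10, 1), p = 0.4)
    got <- mccScores(rg$graph)
    want <- bruteMCC(rg$edges, rg$nodes)
    expect_equal(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("hub selection is the top-k triple intersection", {
  g <- simulateNetwork(30, "scale_free_like", plantedHub = "g3",
                       seed = 5)
  ct <- computeCentralities(g)
  hubs <- selectHubGenes(ct, k = 5)
  expect_true("g3" %in% hubs)
  # independent sort-and-slice oracle
  top <- function(col) {
    o <- order(-ct[[col]], ct$node)
    ct$node[o][1:5]
  }
  expect_setequal(hubs, Reduce(intersect, lapply(
    c("degree", "closeness", "betweenness"), top)))
  expect_warning(selectHubGenes(ct, k = 50), "fewer nodes")
})

test_that("core-gene ranking is deterministic with named ties broken", {
  g <- simulateNetwork(25, "scale_free_like", seed = 9)
  cores <- scoreCoreGenes(g, top = 5)
  expect_equal(nrow(cores), 5)
  expect_true(all(diff(cores$clique_score) <= 0))
  sc <- mccScores(g)
  expect_equal(cores$clique_score, unname(sort(sc, decreasing = TRUE)[1:5]),
               tolerance = 1e-12)
})

test_that("AUC is the Mann-Whitney statistic over case-control pairs", {
  expect_equal(aucRank(c(5, 6, 7), c(4, 5, 6)), 7 / 9)
  expect_equal(aucRank(10:12, 1:3), 1.0)      # perfect separation
  expect_equal(aucRank(rep(3, 4), rep(3, 4)), 0.5)   # all ties
  expect_equal(aucRank(1:3, 10:12), 0)        # fixed orientation, no flip
  for (s in 1:20) {
    withr::with_seed(s, {
      x <- rnorm(7); y <- rnorm(5)
      u <- wilcox.test(x, y, exact = FALSE)$statistic
      expect_equal(aucRank(x, y), unname(u) / 35, tolerance = 1e-12)
      expect_equal(aucRank(x, y), bruteAUC(x, y), tolerance = 1e-12)
    })
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    x <- rnorm(10, 1); y <- rnorm(8)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), c(10, 8)), predictor = c(x, y),
      direction = "<", quiet = TRUE)))
    expect_equal(aucRank(x, y), ref, tolerance = 1e-12)
  })
})

test_that("biomarker screen flags candidates above the AUC bar", {
  se <- simulateExpression(100, 8, 20, 4, 0.5, seed = 2)
  spiked <- rownames(se)[SummarizedExperiment::rowData(se)$spiked &
    SummarizedExperiment::rowData(se)$trueLog2FC > 0]
  out <- suppressWarnings(rocAucBiomarker(se, c(spiked[1:3], "MISSING")))
  expect_equal(nrow(out), 3)
  expect_true(all(out$auc > 0.7))
  expect_true(all(out$candidate))
  expect_warning(rocAucBiomarker(se, "MISSING"), "absent")
})
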