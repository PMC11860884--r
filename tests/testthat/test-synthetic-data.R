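test_that("cohort generator recovers the printed marker quantiles", {
  co <- simulateCohort(nPatients = 10000, seed = 11)
  specs <- markerSpecs()
  for (m in specs$name) {
    s <- specs[specs$name == m, ]
    med <- median(co[[paste0(m, "_pre")]])
    expect_lt(abs(med / s$pre_median - 1), 0.02)
  }
  # the log-normal solved from median + IQR also recovers both quartile
  # endpoints where the printed quartiles are log-symmetric (FBG)
  s <- specs[specs$name == "FBG", ]
  q <- quantile(co[["FBG_pre"]], c(0.25, 0.75))
  expect_lt(abs(q[1] / s$pre_q1 - 1), 0.05)
  expect_lt(abs(q[2] / s$pre_q3 - 1), 0.05)
})

test_that("cohort generator honours the conditional effect map exactly at zero noise", {
  em <- defaultEffectMap()
  co <- simulateCohort(nPatients = 10000, treatedFraction = 0.5,
                       effectMap = em, noiseCV = 0, seed = 5)
  tr <- co$treated
  frac <- mean(co[["Hs-CRP_post"]][tr] < co[["Hs-CRP_pre"]][tr])
  expect_lt(abs(frac - 0.8), 0.03)
  fracU <- mean(co[["Hs-CRP_post"]][!tr] < co[["Hs-CRP_pre"]][!tr])
  expect_lt(abs(fracU - 0.5), 0.03)
})

test_that("cohort edge cases: empty cohort, bad quantiles, determinism", {
  co0 <- simulateCohort(nPatients = 0, seed = 1)
  expect_equal(nrow(co0), 0)
  expect_true(all(c("patient_id", "treated", "FBG_pre", "FBG_post")
                  %in% names(co0)))
  bad <- markerSpecs()
  bad$pre_q1[bad$name == "ESR"] <- bad$pre_q3[bad$name == "ESR"]
  expect_error(simulateCohort(bad, nPatients = 5), "ESR")
  expect_identical(simulateCohort(nPatients = 100, seed = 9),
                   simulateCohort(nPatients = 100, seed = 9))
})

test_that("improvement sequences match their contracts", {
  expect_equal(simulateImprovementSequence(5, "constant"), rep(1, 5))
  x <- simulateImprovementSequence(10000, "iid", p = 0.5, seed = 2)
  expect_true(all(x %in% c(-1, 1)))
  expect_lt(abs(mean(x)), 0.03)
  expect_identical(simulateImprovementSequence(500, "iid", seed = 4),
                   simulateImprovementSequence(500, "iid", seed = 4))
  expect_error(simulateImprovementSequence(10, "drifted", p = 0.5),
               "p != 0.5")
  xi <- simulateImprovementSequence(100, "integrated", seed = 3)
  expect_true(all(diff(xi) %in% c(-1, 1)))  # increments of a ±1 walk
  expect_error(simulateImprovementSequence(10, "weird"))
})

test_that("expression generator plants recoverable spikes", {
  se <- simulateExpression(nGenes = 500, nPerGroup = 10, nSpiked = 0,
                           seed = 1)
  expect_false(any(SummarizedExperiment::rowData(se)$spiked))
  hit <- sapply(1:5, function(s) {
    se <- simulateExpression(2000, 10, 50, 3, 1, seed = s)
    vals <- SummarizedExperiment::assay(se)
    grp <- SummarizedExperiment::colData(se)$group
    lfc <- rowMeans(vals[, grp == "case"]) -
      rowMeans(vals[, grp == "control"])
    mean(abs(lfc[SummarizedExperiment::rowData(se)$spiked]) > 2)
  })
  expect_gte(mean(hit), 0.90)
})

test_that("network generator yields simple undirected graphs with planted hubs", {
  for (s in 1:10) {
    g <- simulateNetwork(40, model = "scale_free_like", seed = s)
    expect_true(igraph::is_simple(g))
    expect_false(igraph::is_directed(g))
  }
  g1 <- simulateNetwork(1, seed = 1)
  expect_equal(igraph::ecount(g1), 0)
  g <- simulateNetwork(50, "erdos_like", plantedHub = "g7",
                       edgeProb = 0.3, seed = 6)
  deg <- igraph::degree(g)
  expect_equal(names(which.max(deg)), "g7")
  expect_equal(sum(deg == max(deg)), 1)   # strictly dominant
  expect_error(simulateNetwork(10, plantedHub = "g99"), "outside")
  # Erdos mean edge count ~ p * C(n,2)
  ec <- sapply(1:50, function(s)
    igraph::ecount(simulateNetwork(100, "erdos_like", edgeProb = 0.1,
                                   seed = 100 + s)))
  expect_lt(abs(mean(ec) / (0.1 * choose(100, 2)) - 1), 0.10)
})

test_that("gene-set generator respects sizes and planted sets", {
  uni <- sprintf("G%03d", 1:200)
  gsc <- simulateGeneSets(uni, nSets = 0, seed = 1)
  expect_equal(length(gsc), 0)
  planted <- sample(uni, 20)
  gsc <- suppressMessages(
    simulateGeneSets(uni, nSets = 5, setSizeRange = c(10, 10),
                     plantedSet = planted, seed = 2))
  expect_setequal(geneSets(gsc)$planted_set, toupper(planted))
  expect_true(all(lengths(geneSets(gsc)[names(geneSets(gsc)) !=
                                          "planted_set"]) == 10))
  expect_error(simulateGeneSets(character(0)), "non-empty")
  expect_error(simulateGeneSets(uni[1:5], setSizeRange = c(10, 10)),
               "universe")
})
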