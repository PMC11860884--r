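makeCohortRow <- function(marker, pre, post, treated = TRUE) {
  df <- data.frame(patient_id = "P1", treated = treated)
  df[[paste0(marker, "_pre")]] <- pre
  df[[paste0(marker, "_post")]] <- post
  df
}

test_that("improvement coding uses strict beneficial movement", {
  tt <- codeImprovements(makeCohortRow("FBG", 5.0, 4.5))
  expect_equal(unname(transactionMatrix(tt)[1, "FBG_improved"]), 1L)
  expect_equal(unname(transactionMatrix(tt)[1, "XFC"]), 1L)
  tt <- codeImprovements(makeCohortRow("FBG", 4.5, 4.5))     # tie
  expect_equal(unname(transactionMatrix(tt)[1, "FBG_improved"]), 0L)
  tt <- codeImprovements(makeCohortRow("Hs-CRP", 36, 4))
  expect_equal(unname(transactionMatrix(tt)[1, "Hs-CRP_improved"]), 1L)
  # tolerance dead-band
  tt <- codeImprovements(makeCohortRow("FBG", 5.0, 4.8), tolerance = 0.05)
  expect_equal(unname(transactionMatrix(tt)[1, "FBG_improved"]), 0L)
  # missing pair keeps the record in N but emits no item
  tt <- codeImprovements(makeCohortRow("FBG", NA, 4.5))
  expect_equal(nRecords(tt), 1L)
  expect_equal(unname(transactionMatrix(tt)[1, "FBG_improved"]), 0L)
})

test_that("improvement coding rejects unknown markers and bad values", {
  expect_error(codeImprovements(makeCohortRow("NOTAMARKER", 2, 1)),
               "NOTAMARKER")
  expect_error(codeImprovements(makeCohortRow("FBG", -1, 1)), "FBG")
})

test_that("saturated table mines all itemsets at support 1", {
  tt <- TransactionTable(matrix(1L, 4, 2,
    dimnames = list(NULL, c("A", "B"))))
  fi <- mineFrequentItemsets(tt, 0.5)
  expect_equal(fi$label, c("A", "B", "A,B"))
  expect_equal(fi$support, c(1, 1, 1))
  fi1 <- mineFrequentItemsets(tt, 1.0)
  expect_equal(nrow(fi1), 3)   # all contained in every record
})

test_that("apriori equals exhaustive power-set enumeration on random tables", {
  for (s in 1:25) {
    tt <- randomTable(s, nRec = 10, nItem = 5)
    for (ms in c(0.2, 0.3, 0.5)) {
      mined <- mineFrequentItemsets(tt, ms)
      oracle <- bruteItemsets(tt, ms)
      expect_identical(sort(mined$label),
                   sort(as.character(names(oracle))))
      expect_equal(mined$support,
                   as.numeric(unlist(oracle[mined$label])),
                   tolerance = 1e-12)
    }
  }
})

test_that("raising min_support never adds an itemset", {
  tt <- randomTable(99, nRec = 12, nItem = 6)
  lo <- mineFrequentItemsets(tt, 0.2)$label
  hi <- mineFrequentItemsets(tt, 0.4)$label
  expect_true(all(hi %in% lo))
})

test_that("rule metrics follow the support/confidence/lift formulas", {
  # constructed table: N=10, sigma(X)=4, sigma(X∪Y)=3, sigma(Y)=5
  m <- matrix(0L, 10, 2, dimnames = list(NULL, c("X", "Y")))
  m[1:4, "X"] <- 1L
  m[c(1:3, 5:6), "Y"] <- 1L
  tt <- TransactionTable(m)
  r <- deriveRules(tt, antecedents = "X", consequents = "Y")
  expect_equal(r$support, 0.30)
  expect_equal(r$confidence, 0.75)
  expect_equal(r$lift, 1.50)
  # consequent in every record: confidence 1, lift 1
  m2 <- cbind(X = c(1L, 1L, 0L), Y = c(1L, 1L, 1L))
  r2 <- deriveRules(TransactionTable(m2), "X", "Y")
  expect_equal(r2$confidence, 1)
  expect_equal(r2$lift, 1)
  # forced overlap rejected
  expect_error(deriveRules(tt, "X", "X"), "overlap")
})

test_that("rule metrics match brute-force counting on random tables", {
  for (s in 26:50) {
    tt <- randomTable(s, nRec = 12, nItem = 6, p = 0.5)
    rules <- deriveRules(tt, antecedents = as.list(itemLabels(tt)),
                         consequents = as.list(itemLabels(tt)),
                         minSupport = 0, minConfidence = 0)
    for (i in seq_len(nrow(rules))) {
      o <- bruteRule(tt, rules$antecedent[i], rules$consequent[i])
      expect_equal(rules$support[i], unname(o["support"]),
                   tolerance = 1e-12)
      expect_equal(rules$confidence[i], unname(o["confidence"]),
                   tolerance = 1e-12)
      expect_equal(rules$lift[i], unname(o["lift"]), tolerance = 1e-12)
    }
  }
})

test_that("metric identities hold on every mined rule", {
  tt <- randomTable(7, nRec = 12, nItem = 6, p = 0.5)
  rules <- deriveRules(tt, antecedents = as.list(itemLabels(tt)),
                       consequents = as.list(itemLabels(tt)),
                       minSupport = 0)
  N <- nRecords(tt)
  for (i in seq_len(nrow(rules))) {
    supY <- supportCount(tt, rules$consequent[i]) / N
    expect_lte(rules$support[i], rules$confidence[i] + 1e-12)
    expect_lte(rules$confidence[i], 1)
    expect_equal(rules$lift[i] * supY, rules$confidence[i],
                 tolerance = 1e-12)
    # dropping records without X leaves confidence unchanged
    keep <- transactionMatrix(tt)[, rules$antecedent[i]] == 1L
    sub <- TransactionTable(transactionMatrix(tt)[keep, , drop = FALSE])
    expect_equal(supportCount(sub, c(rules$antecedent[i],
                                     rules$consequent[i])) / sum(keep),
                 rules$confidence[i], tolerance = 1e-12)
  }
})

test_that("rule strength classification applies the confidence/lift bars", {
  expect_equal(classifyRuleStrength(0.65, 1.27), "strong")
  expect_equal(classifyRuleStrength(0.65, 1.00), "weak")  # lift not > 1
  expect_equal(classifyRuleStrength(0.39, 1.123), "moderate")
  expect_equal(classifyRuleStrength(0.39, 0.901), "weak")
  expect_equal(classifyRuleStrength(c(0.7, 0.5), c(1.2, 0.9)),
               c("strong", "weak"))
})
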