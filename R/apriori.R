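#' Mine frequent itemsets by level-wise Apriori
#'
#' From-scratch level-wise search with downward-closure pruning: level-1
#' candidates are single items, level-k candidates are joins of frequent
#' (k-1)-itemsets sharing their first k-2 items, pruned when any (k-1)
#' subset is infrequent, then counted against the table. Returns exactly
#' the itemsets whose support `sigma(X)/N` reaches `minSupport`.
#'
#' @param table a \linkS4class{TransactionTable}.
#' @param minSupport minimum support fraction in \[0, 1\].
#' @return data.frame with columns `items` (list of character vectors,
#'   lexicographically sorted), `label` (collapsed string), `size`,
#'   `support`; rows ordered by (size, label).
#' @examples
#' tt <- TransactionTable(matrix(1L, 4, 2, dimnames = list(NULL, c("A", "B"))))
#' mineFrequentItemsets(tt, 0.5)
#' @export
mineFrequentItemsets <- function(table, minSupport = 0.01) {
  stopifnot(is(table, "TransactionTable"))
  .assertProb(minSupport, "minSupport")
  N <- nRecords(table)
  empty <- data.frame(items = I(list()), label = character(),
                      size = integer(), support = numeric())
  if (N == 0L || length(itemLabels(table)) == 0L) return(empty)

  rec <- table@records
  counts <- colSums(rec)
  items <- sort(itemLabels(table))
  frequent <- list()   # per level: named list itemset -> support
  lev <- lapply(items, identity)
  sup1 <- counts[items] / N
  keep <- sup1 >= minSupport
  levSets <- lev[keep]
  levSup <- sup1[keep]
  k <- 1L
  while (length(levSets)) {
    frequent[[k]] <- list(sets = levSets, support = unname(levSup))
    # candidate generation: join sets sharing the first k-1 items
    keys <- vapply(levSets, function(s) paste(s, collapse = "\r"),
                   character(1))
    prev <- new.env(parent = emptyenv())
    for (key in keys) assign(key, TRUE, envir = prev)
    cand <- list()
    if (length(levSets) >= 2L) {
      for (i in seq_len(length(levSets) - 1L)) {
        for (j in seq(i + 1L, length(levSets))) {
          a <- levSets[[i]]; b <- levSets[[j]]
          if (k == 1L || identical(a[seq_len(k - 1L)],
                                   b[seq_len(k - 1L)])) {
            u <- sort(union(a, b))
            if (length(u) != k + 1L) next
            # downward closure: all k-subsets must be frequent
            ok <- all(vapply(seq_along(u), function(d)
              exists(paste(u[-d], collapse = "\r"), envir = prev,
                     inherits = FALSE), logical(1)))
            if (ok) cand[[paste(u, collapse = "\r")]] <- u
          }
        }
      }
    }
    if (!length(cand)) break
    cand <- cand[order(names(cand))]
    sup <- vapply(cand, function(s)
      sum(rowSums(rec[, s, drop = FALSE]) == length(s)) / N, numeric(1))
    keep <- sup >= minSupport
    levSets <- unname(cand[keep])
    levSup <- sup[keep]
    k <- k + 1L
  }
  if (!length(frequent)) return(empty)
  allSets <- do.call(c, lapply(frequent, `[[`, "sets"))
  allSup <- do.call(c, lapply(frequent, `[[`, "support"))
  lab <- vapply(allSets, paste, character(1), collapse = ",")
  sz <- lengths(allSets)
  o <- order(sz, lab)
  data.frame(items = I(allSets[o]), label = lab[o], size = sz[o],
             support = allSup[o])
}

#' Derive association rules with support, confidence and lift
#'
#' Evaluates rules X -> Y under the standard transaction metrics:
#' `support = sigma(X u Y) / N`, `confidence = sigma(X u Y) / sigma(X)`,
#' `lift = confidence / support(Y)`. By default the search is restricted
#' to a single-item antecedent (the treatment-exposure item) against every
#' single-item consequent — the only rule family the clinical question
#' needs; `expand = TRUE` instead pairs all frequent itemsets. Rules whose
#' antecedent never occurs are not emitted.
#'
#' @param table a \linkS4class{TransactionTable}.
#' @param antecedents,consequents character vectors of items (each item
#'   taken as a singleton set) or lists of character itemsets.
#' @param minSupport,minConfidence reporting thresholds in \[0, 1\].
#' @param expand if TRUE, mine all frequent itemsets at `minSupport` and
#'   emit every disjoint antecedent/consequent pair.
#' @return data.frame: `antecedent`, `consequent` (comma-joined labels),
#'   `support`, `confidence`, `lift`, `strength` (see
#'   [classifyRuleStrength()]).
#' @export
deriveRules <- function(table, antecedents = "XFC",
                        consequents = NULL, minSupport = 0.01,
                        minConfidence = 0, expand = FALSE) {
  stopifnot(is(table, "TransactionTable"))
  .assertProb(minSupport, "minSupport")
  .assertProb(minConfidence, "minConfidence")
  N <- nRecords(table)
  if (N == 0L) stop("empty transaction table")
  asSets <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) lapply(x, function(s) sort(as.character(s)))
    else lapply(as.character(x), identity)
  }
  if (expand) {
    fi <- mineFrequentItemsets(table, minSupport)
    ante <- fi$items
    cons <- fi$items
  } else {
    ante <- asSets(antecedents)
    cons <- asSets(consequents)
    if (is.null(cons))
      cons <- lapply(setdiff(itemLabels(table), unlist(ante)), identity)
  }
  if (!length(ante) || !length(cons))
    stop("antecedent and consequent filters must be non-empty")
  if (!expand) {
    forced <- all(vapply(ante, function(a) all(vapply(cons,
      function(b) length(intersect(a, b)) > 0, logical(1))), logical(1)))
    if (forced)
      stop("antecedent/consequent filters force overlapping rules")
  }
  rows <- list()
  for (a in ante) {
    sX <- supportCount(table, a)
    if (sX == 0L) next
    for (b in cons) {
      if (length(intersect(a, b))) next
      sXY <- supportCount(table, union(a, b))
      sY <- supportCount(table, b)
      support <- sXY / N
      confidence <- sXY / sX
      lift <- if (sY > 0) confidence / (sY / N) else NA_real_
      if (support >= minSupport && confidence >= minConfidence)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(a, collapse = ","),
          consequent = paste(b, collapse = ","),
          support = support, confidence = confidence, lift = lift,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), strength = character()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$confidence, out$antecedent, out$consequent), ]
  rownames(out) <- NULL
  out$strength <- classifyRuleStrength(out$confidence, out$lift)
  out
}

#' Classify rule strength
#'
#' A rule is `"strong"` when confidence exceeds 60% and lift exceeds 1
#' (the positive-association bar used for the treatment/marker rules);
#' `"moderate"` when lift exceeds 1 but confidence does not clear 60%; and
#' `"weak"` otherwise (lift <= 1 indicates no positive association
#' regardless of confidence). The moderate band is this package's explicit
#' decision; the source analysis never defines its criterion.
#'
#' @param confidence,lift numeric vectors (recycled to common length).
#' @return character vector in \{"strong", "moderate", "weak"\}.
#' @examples
#' classifyRuleStrength(c(0.65, 0.65, 0.39), c(1.27, 1.00, 1.123))
#' @export
classifyRuleStrength <- function(confidence, lift) {
  n <- max(length(confidence), length(lift))
  confidence <- rep_len(confidence, n)
  lift <- rep_len(lift, n)
  ifelse(confidence > 0.60 & lift > 1, "strong",
         ifelse(lift > 1, "moderate", "weak"))
}
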