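#' Construct a GeneSetCollection
#'
#' Symbols are normalized (trimmed, upper-cased); set members outside the
#' universe are dropped with a logged count.
#'
#' @param sets named list of member symbol vectors.
#' @param universe background symbols.
#' @param category per-set tags (BP/CC/MF/pathway); recycled, default
#'   "pathway".
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, universe, category = "pathway") {
  universe <- unique(.normSymbols(universe))
  if (!length(universe)) stop("universe must be non-empty")
  sets <- lapply(sets, function(s) unique(.normSymbols(s)))
  dropped <- sum(vapply(sets, function(s) sum(!s %in% universe),
                        integer(1)))
  if (dropped > 0)
    message(dropped, " set member(s) outside the universe dropped")
  sets <- lapply(sets, function(s) s[s %in% universe])
  category <- rep_len(as.character(category), length(sets))
  names(category) <- names(sets)
  new("GeneSetCollection", universe = universe, sets = sets,
      category = category)
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setCategories", "GeneSetCollection", function(x) x@category)

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over a universe of",
      length(object@universe), "genes\n")
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, the one-sided upper-tail probability
#' `P(X >= k)` of drawing at least the observed overlap `k` when `n` query
#' genes are sampled without replacement from a universe of `N` genes of
#' which `K` belong to the set. Query genes outside the universe are
#' dropped with a logged count. Sets with zero overlap are hidden by
#' default (tool convention); BH q-values are computed across the emitted
#' batch.
#'
#' @param query symbol vector of genes of interest.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param reportZero include zero-overlap sets (their p is 1 at k = 0).
#' @param mode `"raw"` flags `p_value < alpha` (the selection rule of the
#'   source workflow); `"bh"` flags `q_value < alpha`.
#' @param alpha significance level.
#' @return data.frame ordered by p: `term`, `category`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, `significant`.
#' @export
hypergeomEnrich <- function(query, collection, reportZero = FALSE,
                            mode = c("raw", "bh"), alpha = 0.05) {
  stopifnot(is(collection, "GeneSetCollection"))
  mode <- match.arg(mode)
  .assertProb(alpha, "alpha")
  uni <- geneUniverse(collection)
  query <- unique(.normSymbols(query))
  out <- query[!query %in% uni]
  if (length(out))
    message(length(out), " query gene(s) outside the universe dropped")
  query <- query[query %in% uni]
  if (!length(query)) stop("no query genes inside the universe")
  N <- length(uni); n <- length(query)
  sets <- geneSets(collection)
  rows <- data.frame(
    term = names(sets),
    category = unname(setCategories(collection)),
    k = vapply(sets, function(s) length(intersect(s, query)), integer(1)),
    K = lengths(sets), n = n, N = N,
    stringsAsFactors = FALSE)
  rows$p_value <- stats::phyper(rows$k - 1, rows$K, N - rows$K, n,
                                lower.tail = FALSE)
  if (!reportZero) rows <- rows[rows$k > 0, , drop = FALSE]
  rows <- adjustEnrichment(rows, alpha = alpha, mode = mode)
  rows <- rows[order(rows$p_value, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Benjamini-Hochberg adjustment and significance flags
#'
#' Adds step-up q-values over the batch of rows and flags significance
#' either on raw p (`mode = "raw"`, mirroring the source selection rule)
#' or on q (`mode = "bh"`). q-values are invariant to row order.
#'
#' @param rows data.frame with a `p_value` column.
#' @param alpha significance level.
#' @param mode `"raw"` or `"bh"`.
#' @return the rows with `q_value` and `significant` columns set.
#' @export
adjustEnrichment <- function(rows, alpha = 0.05,
                             mode = c("raw", "bh")) {
  mode <- match.arg(mode)
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- if (mode == "raw") rows$p_value < alpha
                      else rows$q_value < alpha
  rows
}

#' Rank enrichment terms for display
#'
#' Deterministic ordering with an alphabetical term tie-break. `by = "p"`
#' ranks by ascending p (equivalently descending -log10 p, the GO display
#' order); `by = "count"` ranks by descending overlap k (the pathway
#' display order); `by = "fold"` by descending fold enrichment
#' `(k/n) / (K/N)`.
#'
#' @param rows enrichment table from [hypergeomEnrich()].
#' @param by ranking key.
#' @param top number of rows to keep (default all).
#' @return the ordered subset.
#' @export
rankTerms <- function(rows, by = c("p", "fold", "count"), top = Inf) {
  by <- match.arg(by)
  if (!nrow(rows)) stop("no enrichment rows to rank")
  key <- switch(by,
    p = rows$p_value,
    count = -rows$k,
    fold = -(rows$k / rows$n) / (rows$K / rows$N))
  o <- order(key, rows$term)
  rows <- rows[o, , drop = FALSE]
  utils::head(rows, top)
}
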