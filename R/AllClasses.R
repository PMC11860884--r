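#' @import methods
NULL

#' Binary improvement-transaction table
#'
#' Container for the 0/1 item-by-record matrix that association-rule mining
#' operates on. Rows are patient records, columns are items such as the
#' treatment-exposure flag (\code{"XFC"}) or \code{"<marker>_improved"}.
#' The record count \code{N} is the denominator of the support formula, so
#' records carrying no item at all still count.
#'
#' @slot items character vector of unique item labels (column order).
#' @slot records integer matrix of 0/1 memberships, one row per record.
#'
#' @seealso [codeImprovements()], [mineFrequentItemsets()], [deriveRules()]
#' @exportClass TransactionTable
setClass("TransactionTable",
  representation(items = "character", records = "matrix"))

setValidity("TransactionTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@items))
    msg <- c(msg, "item labels must be unique")
  if (ncol(object@records) != length(object@items))
    msg <- c(msg, "record matrix must have one column per item")
  if (nrow(object@records) > 0 && !all(object@records %in% c(0L, 1L)))
    msg <- c(msg, "record entries must be strictly binary (0/1)")
  if (length(msg)) msg else TRUE
})

#' Cumulative treatment-outcome walk
#'
#' A per-record outcome series in admission order. Walks built from
#' transactions have increments in \{+1, -1\} (improvement vs no
#' improvement); the class also admits general numeric increments so that
#' super-diffusive test processes (increments that are themselves cumulative
#' sums) can be analysed with the same fluctuation machinery.
#'
#' @slot increments numeric vector of per-record outcomes.
#'
#' @seealso [buildWalk()], [fluctuationFunction()]
#' @exportClass EfficacyWalk
setClass("EfficacyWalk", representation(increments = "numeric"))

setValidity("EfficacyWalk", function(object) {
  if (length(object@increments) < 1L)
    return("walk must contain at least one increment")
  if (!all(is.finite(object@increments)))
    return("increments must be finite")
  TRUE
})

#' Fluctuation-analysis result
#'
#' Holds the fluctuation function F2(l) of a walk, the fitted scaling
#' exponent of F(l) = sqrt(F2(l)) against l, and (after the permutation
#' test) the verdict against the memoryless null alpha = 1/2.
#'
#' @slot lags numeric, strictly increasing window lengths l.
#' @slot F2 numeric, variance of l-step displacements, one per lag.
#' @slot alphaHat fitted exponent (NA until [fitScalingExponent()] is run).
#' @slot alphaSE regression standard error of the exponent.
#' @slot nullRejected logical verdict of the permutation test (NA before).
#' @slot nShuffles number of permutations used.
#' @slot nullAlphas exponents refitted on shuffled increments.
#'
#' @exportClass FluctuationResult
setClass("FluctuationResult",
  representation(lags = "numeric", F2 = "numeric",
    alphaHat = "numeric", alphaSE = "numeric",
    nullRejected = "logical", nShuffles = "integer",
    nullAlphas = "numeric"),
  prototype(alphaHat = NA_real_, alphaSE = NA_real_,
    nullRejected = NA, nShuffles = 0L, nullAlphas = numeric()))

setValidity("FluctuationResult", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@F2))
    msg <- c(msg, "lags and F2 must have equal length")
  if (is.unsorted(object@lags, strictly = TRUE))
    msg <- c(msg, "lags must be strictly increasing")
  if (any(object@F2 < 0))
    msg <- c(msg, "F2 must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Gene-set collection for over-representation analysis
#'
#' Named gene sets with a category tag (BP/CC/MF/pathway) against a
#' background universe. Members outside the universe are dropped at
#' construction with a logged count.
#'
#' @slot universe background gene symbols (normalized, unique).
#' @slot sets named list of member vectors (normalized, restricted to the
#'   universe).
#' @slot category named character, one tag per set.
#'
#' @seealso [hypergeomEnrich()], [readGMT()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(universe = "character", sets = "list",
    category = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe symbols must be unique")
  if (length(object@sets) != length(object@category))
    msg <- c(msg, "one category tag per set required")
  if (length(object@sets) && is.null(names(object@sets)))
    msg <- c(msg, "sets must be named")
  bad <- vapply(object@sets,
    function(s) any(!s %in% object@universe), logical(1))
  if (any(bad))
    msg <- c(msg, "set members must lie inside the universe")
  if (length(msg)) msg else TRUE
})
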