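#' Build a cumulative treatment-outcome walk
#'
#' Each record contributes a step: +1 if it contains `outcomeItem`
#' (improvement observed), -1 otherwise. Records are taken in the supplied
#' order; file order stands in for admission sequence when no ordering
#' column is available.
#'
#' @param table a \linkS4class{TransactionTable}.
#' @param outcomeItem item label coding the beneficial outcome.
#' @param order optional permutation of record indices.
#' @return an \linkS4class{EfficacyWalk}.
#' @export
buildWalk <- function(table, outcomeItem, order = NULL) {
  stopifnot(is(table, "TransactionTable"))
  if (nRecords(table) == 0L) stop("empty transaction table")
  if (!outcomeItem %in% itemLabels(table))
    stop("outcome item '", outcomeItem, "' not in table")
  hit <- table@records[, outcomeItem]
  if (!is.null(order)) {
    stopifnot(length(order) == length(hit))
    hit <- hit[order]
  }
  EfficacyWalk(ifelse(hit == 1L, 1, -1))
}

#' Construct an EfficacyWalk from raw increments
#'
#' @param increments numeric outcome steps (\[buildWalk()] produces +/-1).
#' @return an \linkS4class{EfficacyWalk}.
#' @export
EfficacyWalk <- function(increments) {
  new("EfficacyWalk", increments = as.numeric(increments))
}

#' @rdname EfficacyWalk-class
#' @export
setMethod("increments", "EfficacyWalk", function(x) x@increments)

#' @describeIn EfficacyWalk-class cumulative path y with y(0) = 0.
#' @export
setMethod("walkPath", "EfficacyWalk",
          function(x) c(0, cumsum(x@increments)))

setMethod("show", "EfficacyWalk", function(object) {
  n <- length(object@increments)
  cat("EfficacyWalk of length", n, "| terminal y(n) =",
      sum(object@increments), "\n")
})

setMethod("length", "EfficacyWalk", function(x) length(x@increments))

# F2 at each lag: population variance of all overlapping l-step
# displacements, computed by the second-raw-moment identity
# F2(l) = mean(dy^2) - mean(dy)^2.
.fluct <- function(y, lags) {
  n <- length(y) - 1L
  vapply(lags, function(l) {
    d <- y[(l + 1L):(n + 1L)] - y[1:(n + 1L - l)]
    mean(d^2) - mean(d)^2
  }, numeric(1))
}

# fast slope of 0.5*log(F2) on log(l); zero-F2 lags dropped; NA if < 3 left
.alphaFast <- function(lags, F2) {
  keep <- F2 > 0
  if (sum(keep) < 3L) return(NA_real_)
  xx <- log(lags[keep]); yy <- 0.5 * log(F2[keep])
  xc <- xx - mean(xx)
  sum(xc * yy) / sum(xc^2)
}

#' Default log-spaced lag grid
#'
#' Up to 12 approximately log-spaced window lengths between 4 and n/4,
#' avoiding small-lag discreteness and large-lag noise.
#'
#' @param n walk length.
#' @return integer vector of lags.
#' @export
defaultLags <- function(n) {
  hi <- max(4, floor(n / 4))
  unique(round(exp(seq(log(4), log(hi), length.out = 12))))
}

#' Fluctuation function of a walk
#'
#' For each window length l, the displacement `dy(l) = y(l0 + l) - y(l0)`
#' is taken over every overlapping start point `l0 in 0..(n-l)`, and F2(l)
#' is the variance of these displacements (second raw moment minus squared
#' mean). For memoryless +/-1 steps F2(l) grows like l, so
#' F(l) = sqrt(F2(l)) ~ l^(1/2); persistent outcome streaks push the
#' exponent above 1/2.
#'
#' @param walk an \linkS4class{EfficacyWalk}.
#' @param lags increasing window lengths; all must satisfy
#'   `1 <= l <= n/2` (longer windows average too few displacements).
#'   Default: [defaultLags()].
#' @return a \linkS4class{FluctuationResult} with `lags` and `F2` filled.
#' @export
fluctuationFunction <- function(walk, lags = NULL) {
  stopifnot(is(walk, "EfficacyWalk"))
  n <- length(increments(walk))
  if (is.null(lags)) lags <- defaultLags(n)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be >= 1")
  if (max(lags) > n / 2)
    stop("lag ", max(lags), " exceeds n/2 = ", n / 2,
         " (unstable averaging)")
  F2 <- .fluct(walkPath(walk), lags)
  new("FluctuationResult", lags = as.numeric(lags), F2 = pmax(F2, 0))
}

#' Fit the fluctuation scaling exponent
#'
#' Least-squares slope of `log F(l) = 0.5 * log F2(l)` against `log l`.
#' The exponent is defined on F (not F2) so that the memoryless null is
#' alpha = 1/2: independent outcomes give F2 proportional to l, hence
#' F proportional to l^(1/2).
#'
#' @param result a \linkS4class{FluctuationResult} from
#'   [fluctuationFunction()].
#' @param fitRange optional subset of lag values to fit over.
#' @return the result with `alphaHat` and `alphaSE` filled.
#' @export
fitScalingExponent <- function(result, fitRange = NULL) {
  stopifnot(is(result, "FluctuationResult"))
  keep <- rep(TRUE, length(result@lags))
  if (!is.null(fitRange)) keep <- result@lags %in% fitRange
  lags <- result@lags[keep]
  F2 <- result@F2[keep]
  zero <- F2 <= 0
  if (any(zero)) {
    warning(sum(zero), " lag(s) with F2 = 0 dropped from the fit")
    lags <- lags[!zero]; F2 <- F2[!zero]
  }
  if (length(lags) < 3L)
    stop("need at least 3 lags with positive F2 to fit an exponent")
  xx <- log(lags); yy <- 0.5 * log(F2)
  xc <- xx - mean(xx)
  slope <- sum(xc * yy) / sum(xc^2)
  resid <- yy - mean(yy) - slope * xc
  result@alphaHat <- slope
  result@alphaSE <- sqrt(sum(resid^2) / (length(xx) - 2) / sum(xc^2))
  result
}

#' Permutation test of the memoryless null
#'
#' Recomputes the scaling exponent on `nShuffles` independent permutations
#' of the increments. Permutation destroys any serial structure while
#' preserving the step marginal, so the shuffled exponents form the null
#' distribution of alpha-hat under memoryless outcomes; the observed
#' exponent is flagged when it falls outside the empirical
#' (level/2, 1 - level/2) quantiles. This is preferred to the regression
#' confidence interval, which is anti-conservative because F2 values at
#' overlapping lags are strongly dependent.
#'
#' @param walk an \linkS4class{EfficacyWalk}; must not be degenerate
#'   (all steps equal gives F2 identically 0 under every shuffle).
#' @param nShuffles number of permutations (>= 99).
#' @param level two-sided test level in (0, 1).
#' @param lags optional lag grid (default [defaultLags()]).
#' @param seed optional seed for the permutation stream.
#' @return a \linkS4class{FluctuationResult} with `alphaHat`, `alphaSE`,
#'   `nullRejected`, `nShuffles` and `nullAlphas` filled.
#' @export
testAlphaNull <- function(walk, nShuffles = 199, level = 0.05,
                          lags = NULL, seed = NULL) {
  stopifnot(is(walk, "EfficacyWalk"))
  nShuffles <- .assertCount(nShuffles, "nShuffles", 99L)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x <- increments(walk)
  if (length(unique(x)) == 1L)
    stop("degenerate walk: all increments equal, F2 is identically 0")
  res <- fitScalingExponent(fluctuationFunction(walk, lags))
  lagv <- res@lags
  nullAlphas <- .withSeed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      xs <- sample(x)
      .alphaFast(lagv, .fluct(c(0, cumsum(xs)), lagv))
    }, numeric(1))
  })
  q <- stats::quantile(nullAlphas, c(level / 2, 1 - level / 2),
                       na.rm = TRUE, names = FALSE)
  res@nullAlphas <- nullAlphas
  res@nShuffles <- nShuffles
  res@nullRejected <- res@alphaHat < q[1] || res@alphaHat > q[2]
  res
}

#' @rdname FluctuationResult-class
#' @export
setMethod("fluctuations", "FluctuationResult", function(x)
  data.frame(lag = x@lags, F2 = x@F2))

#' @rdname FluctuationResult-class
#' @export
setMethod("scalingExponent", "FluctuationResult", function(x)
  c(alpha = x@alphaHat, se = x@alphaSE))

#' @rdname FluctuationResult-class
#' @export
setMethod("nullRejected", "FluctuationResult", function(x)
  x@nullRejected)

setMethod("show", "FluctuationResult", function(object) {
  cat("FluctuationResult over", length(object@lags), "lags\n")
  if (!is.na(object@alphaHat))
    cat(sprintf("  alpha-hat = %.4f (se %.4f)\n",
                object@alphaHat, object@alphaSE))
  if (!is.na(object@nullRejected))
    cat("  memoryless null (alpha = 1/2)",
        if (object@nullRejected) "REJECTED" else "not rejected",
        "by", object@nShuffles, "permutations\n")
})
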