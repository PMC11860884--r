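#' Laboratory-marker specifications
#'
#' Returns the packaged specification table for the eight coagulation and
#' immune-inflammatory markers tracked in active rheumatoid arthritis:
#' fibrinogen (FBG), platelet count (PLT), erythrocyte sedimentation rate
#' (ESR), high-sensitivity C-reactive protein (Hs-CRP), immunoglobulins
#' A/G/M and rheumatoid factor (RF). Each row carries the reference range,
#' the pre-treatment median and quartiles of an active-disease inpatient
#' cohort (the distribution targets of [simulateCohort()]), and the
#' direction of benefit. All eight markers are elevated in active disease,
#' so every direction is `"high-is-bad"`; for IgM the pre/post shift in the
#' source cohort was non-significant, which the default effect map encodes
#' as a null treatment effect (see [defaultEffectMap()]).
#'
#' @param path optional path to a CSV with the same columns, to substitute
#'   user-supplied specifications.
#' @return data.frame with columns `name`, `normal_low`, `normal_high`,
#'   `pre_median`, `pre_q1`, `pre_q3`, `direction`, `unit`.
#' @examples
#' markerSpecs()
#' @export
markerSpecs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "marker_specs.csv", package = "xfcnet",
                        mustWork = TRUE)
  specs <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  validateMarkerSpecs(specs)
  specs
}

#' Validate a marker specification table
#'
#' Checks the invariants every generator and coder relies on:
#' `normal_low < normal_high`, `pre_q1 <= pre_median <= pre_q3`, a solvable
#' quantile triple (`pre_q1 < pre_q3`), and a known direction flag.
#'
#' @param specs data.frame as returned by [markerSpecs()].
#' @return the table, invisibly; errors name the offending marker.
#' @export
validateMarkerSpecs <- function(specs) {
  need <- c("name", "normal_low", "normal_high", "pre_median",
            "pre_q1", "pre_q3", "direction")
  miss <- setdiff(need, names(specs))
  if (length(miss))
    stop("marker specs missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(specs$name))
    stop("duplicate marker names in specification table")
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (!s$direction %in% c("high-is-bad", "low-is-bad"))
      stop("marker ", s$name, ": unknown direction '", s$direction, "'")
    if (!(s$normal_low < s$normal_high))
      stop("marker ", s$name, ": normal range bounds out of order")
    if (s$pre_q1 >= s$pre_q3)
      stop("marker ", s$name,
           ": non-solvable quantile triple (q1 >= q3)")
    if (!(s$pre_q1 <= s$pre_median && s$pre_median <= s$pre_q3))
      stop("marker ", s$name, ": median outside (q1, q3)")
    if (s$pre_median <= 0)
      stop("marker ", s$name, ": pre-treatment median must be positive")
  }
  invisible(specs)
}

#' Default conditional-improvement effect map
#'
#' Per-marker probabilities that a patient shows improvement after the
#' observation window, conditional on treatment exposure. The source cohort
#' observes improvements but never models them, so these defaults are the
#' package's own emulation choice: a strongly responsive acute-phase
#' marker (Hs-CRP, 0.80 treated vs 0.50 untreated, the planted-effect demo
#' condition), intermediate responses for ESR/RF, weak responses for the
#' immunoglobulins, platelets and fibrinogen, and a null effect for IgM.
#'
#' @return data.frame with columns `marker`, `p_treated`, `p_untreated`.
#' @export
defaultEffectMap <- function() {
  data.frame(
    marker = c("FBG", "PLT", "ESR", "Hs-CRP", "IgA", "IgG", "IgM", "RF"),
    p_treated = c(0.52, 0.58, 0.72, 0.80, 0.56, 0.56, 0.50, 0.65),
    p_untreated = c(0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50),
    stringsAsFactors = FALSE)
}
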