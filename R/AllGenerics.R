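#' @rdname TransactionTable-class
#' @param object,x a \linkS4class{TransactionTable}.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname TransactionTable-class
#' @export
setGeneric("itemLabels", function(x) standardGeneric("itemLabels"))

#' @rdname TransactionTable-class
#' @param itemset character vector of item labels.
#' @export
setGeneric("supportCount", function(x, itemset)
  standardGeneric("supportCount"))

#' @rdname EfficacyWalk-class
#' @param x an \linkS4class{EfficacyWalk}.
#' @export
setGeneric("increments", function(x) standardGeneric("increments"))

#' @rdname EfficacyWalk-class
#' @export
setGeneric("walkPath", function(x) standardGeneric("walkPath"))

#' @rdname FluctuationResult-class
#' @param x a \linkS4class{FluctuationResult}.
#' @export
setGeneric("fluctuations", function(x) standardGeneric("fluctuations"))

#' @rdname FluctuationResult-class
#' @export
setGeneric("scalingExponent", function(x)
  standardGeneric("scalingExponent"))

#' @rdname FluctuationResult-class
#' @export
setGeneric("nullRejected", function(x) standardGeneric("nullRejected"))

#' @rdname GeneSetCollection-class
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setCategories", function(x) standardGeneric("setCategories"))
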