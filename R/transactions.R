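#' Construct a TransactionTable
#'
#' @param records 0/1 matrix (records x items) or data.frame coercible to
#'   one; column names become item labels unless `items` is given.
#' @param items optional character vector of item labels.
#' @return a \linkS4class{TransactionTable}.
#' @examples
#' tt <- TransactionTable(matrix(c(1, 1, 0, 1), 2, 2,
#'   dimnames = list(NULL, c("XFC", "ESR_improved"))))
#' nRecords(tt)
#' @export
TransactionTable <- function(records, items = NULL) {
  if (is.data.frame(records)) records <- as.matrix(records)
  if (is.null(items)) items <- colnames(records)
  if (is.null(items))
    stop("item labels required (matrix column names or `items`)")
  storage.mode(records) <- "integer"
  colnames(records) <- items
  new("TransactionTable", items = as.character(items), records = records)
}

#' @rdname TransactionTable-class
#' @export
setMethod("nRecords", "TransactionTable", function(x) nrow(x@records))

#' @rdname TransactionTable-class
#' @export
setMethod("itemLabels", "TransactionTable", function(x) x@items)

#' @describeIn TransactionTable-class sigma(X): number of records containing
#'   every item of `itemset`.
#' @export
setMethod("supportCount", "TransactionTable", function(x, itemset) {
  if (length(itemset) == 0L) return(nRecords(x))
  missing <- setdiff(itemset, x@items)
  if (length(missing))
    stop("unknown item(s): ", paste(missing, collapse = ", "))
  m <- x@records[, itemset, drop = FALSE]
  sum(rowSums(m) == length(itemset))
})

setMethod("show", "TransactionTable", function(object) {
  cat("TransactionTable with", nRecords(object), "records and",
      length(object@items), "items\n")
  cat("items:", paste(utils::head(object@items, 8), collapse = ", "),
      if (length(object@items) > 8) "..." else "", "\n")
})

#' Extract the binary membership matrix
#'
#' @param x a \linkS4class{TransactionTable}.
#' @return integer 0/1 matrix, records in rows.
#' @export
transactionMatrix <- function(x) {
  stopifnot(is(x, "TransactionTable"))
  x@records
}

#' Code pre/post marker pairs into improvement transactions
#'
#' Turns a cohort table (one row per patient, `treated` flag plus
#' `<marker>_pre`/`<marker>_post` columns) into the binary transaction
#' table mined for treatment-to-improvement rules. The treatment item
#' (default `"XFC"`) is emitted iff the patient is treated. For a marker
#' whose elevation is pathological (`direction == "high-is-bad"`) the item
#' `<marker>_improved` is emitted iff `post < pre * (1 - tolerance)`;
#' the rule is mirrored for `"low-is-bad"` markers. A tie is never an
#' improvement. Patients with a missing pre or post value contribute no
#' item for that marker but remain counted in the record total N.
#'
#' @param cohort data.frame as written by [simulateCohort()] /
#'   [readCohort()].
#' @param specs marker specification table, see [markerSpecs()].
#' @param tolerance relative dead-band around no-change; 0 (default) means
#'   any strict move in the beneficial direction counts.
#' @param treatmentItem label of the exposure item.
#' @return a \linkS4class{TransactionTable} with one row per patient.
#' @export
codeImprovements <- function(cohort, specs = markerSpecs(),
                             tolerance = 0, treatmentItem = "XFC") {
  stopifnot(is.data.frame(cohort), tolerance >= 0)
  if (!"treated" %in% names(cohort))
    stop("cohort must contain a 'treated' column")
  preCols <- grep("_pre$", names(cohort), value = TRUE)
  markers <- sub("_pre$", "", preCols)
  missing <- setdiff(markers, specs$name)
  if (length(missing))
    stop("marker(s) absent from the specification table: ",
         paste(missing, collapse = ", "))
  n <- nrow(cohort)
  items <- c(treatmentItem, paste0(markers, "_improved"))
  rec <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  rec[, treatmentItem] <- as.integer(as.logical(cohort$treated))
  for (m in markers) {
    pre <- cohort[[paste0(m, "_pre")]]
    post <- cohort[[paste0(m, "_post")]]
    ok <- !is.na(pre) & !is.na(post)
    if (any(ok & (pre <= 0 | post <= 0)))
      stop("non-positive value for marker ", m)
    dir <- specs$direction[specs$name == m]
    imp <- if (dir == "high-is-bad") {
      post < pre * (1 - tolerance)
    } else {
      post > pre * (1 + tolerance)
    }
    rec[, paste0(m, "_improved")] <- as.integer(ok & imp)
  }
  TransactionTable(rec)
}
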