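#' Read / write a cohort table
#'
#' CSV with header `patient_id, treated, <marker>_pre, <marker>_post ...`.
#'
#' @param path file path.
#' @param cohort data.frame as produced by [simulateCohort()].
#' @return `readCohort`: the cohort data.frame.
#' @export
readCohort <- function(path) {
  co <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  co$treated <- as.logical(co$treated)
  co
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write transactions as a 0/1 CSV
#'
#' @param path file path.
#' @param table a \linkS4class{TransactionTable}.
#' @return `readTransactions`: a \linkS4class{TransactionTable}.
#' @export
readTransactions <- function(path) {
  m <- utils::read.csv(path, check.names = FALSE)
  TransactionTable(as.matrix(m))
}

#' @rdname readTransactions
#' @export
writeTransactions <- function(table, path) {
  utils::write.csv(as.data.frame(transactionMatrix(table)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a rule table in percent columns
#'
#' TSV with `LHS, RHS, support_pct, confidence_pct, lift, strength`:
#' fractions are stored internally in \[0, 1\] (keeping the metric
#' identities exact) and multiplied by 100 only here for display.
#'
#' @param rules data.frame from [deriveRules()].
#' @param path file path.
#' @export
writeRules <- function(rules, path) {
  out <- data.frame(LHS = rules$antecedent, RHS = rules$consequent,
                    support_pct = 100 * rules$support,
                    confidence_pct = 100 * rules$confidence,
                    lift = rules$lift, strength = rules$strength)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write an expression matrix with group labels
#'
#' Matrix as TSV, genes in rows (first column symbol), samples in
#' columns; companion two-column group file (sample, group).
#'
#' @param matrixPath,groupPath file paths.
#' @param se a [SummarizedExperiment::SummarizedExperiment].
#' @return `readExpression`: a SummarizedExperiment with assay
#'   `"log2expr"` and `colData()$group`.
#' @export
readExpression <- function(matrixPath, groupPath) {
  m <- utils::read.delim(matrixPath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  genes <- m[[1]]
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- genes
  grp <- utils::read.delim(groupPath, stringsAsFactors = FALSE)
  names(grp)[1:2] <- c("sample", "group")
  vals <- vals[, grp$sample, drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = vals),
    colData = S4Vectors::DataFrame(group = grp$group,
                                   row.names = grp$sample))
}

#' @rdname readExpression
#' @export
writeExpression <- function(se, matrixPath, groupPath) {
  vals <- SummarizedExperiment::assay(se)
  out <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  utils::write.table(out, matrixPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  grp <- data.frame(sample = colnames(vals),
                    group = SummarizedExperiment::colData(se)$group)
  utils::write.table(grp, groupPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(matrixPath)
}

#' Read a network edge list (two-column TSV or SIF)
#'
#' A two-column file is taken as an edge list; three or more columns as
#' SIF (`node relation node ...`, one hub node per line). The result is
#' simplified to an undirected simple graph.
#'
#' @param path file path.
#' @return an [igraph::igraph].
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (length(parts) && length(parts[[1]]) >= 3) {        # SIF
    edges <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) < 3) return(NULL)
      cbind(p[1], p[3:length(p)])
    }))
  } else {
    if (any(tolower(parts[[1]]) %in% c("from", "to", "source", "target",
                                       "node1", "node2")))
      parts <- parts[-1]
    edges <- do.call(rbind, lapply(parts, function(p) cbind(p[1], p[2])))
  }
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

#' Write a network as a two-column TSV edge list
#'
#' @param net an [igraph::igraph].
#' @param path file path.
#' @export
writeEdgeList <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param path file path.
#' @param universe background symbols for the collection; defaults to the
#'   union of all set members.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return `readGMT`: a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  cats <- vapply(parts, function(p)
    if (nzchar(p[2])) p[2] else "pathway", character(1))
  if (is.null(universe)) universe <- unique(unlist(sets))
  GeneSetCollection(sets, universe, category = cats)
}

#' @rdname readGMT
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  cats <- setCategories(collection)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, cats[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
readTargetList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
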