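#' Node centralities and clique score for an interaction network
#'
#' Degree (incident edge count), harmonic closeness (sum of reciprocal
#' shortest-path distances, well-defined on the disconnected subnetworks
#' typical of protein-interaction data), unnormalized betweenness (for
#' each node, the sum over unordered source-target pairs of the fraction
#' of shortest paths through it), and the maximal-clique centrality
#' `score(v) = sum over maximal cliques S containing v of (|S| - 1)!`
#' (isolated nodes score 1 via their singleton maximal clique).
#'
#' @param net an [igraph::igraph]; must be simple and undirected.
#' @param cliqueBudget abort if the graph has more maximal cliques than
#'   this (enumeration is exponential in the worst case).
#' @return data.frame: `node`, `degree`, `closeness`, `betweenness`,
#'   `clique_score`, ordered by node name.
#' @export
computeCentralities <- function(net, cliqueBudget = 1e6) {
  net <- .checkNetwork(net)
  nodes <- igraph::V(net)$name
  data.frame(
    node = nodes,
    degree = as.integer(igraph::degree(net)),
    closeness = unname(igraph::harmonic_centrality(net,
                                                   normalized = FALSE)),
    betweenness = unname(igraph::betweenness(net, directed = FALSE)),
    clique_score = unname(mccScores(net, cliqueBudget)),
    stringsAsFactors = FALSE)[order(nodes), ]
}

.checkNetwork <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) < 1L) stop("network must have at least 1 node")
  if (igraph::is_directed(net)) net <- igraph::as_undirected(net)
  if (!igraph::is_simple(net))
    stop("network must be simple (no self-loops or parallel edges)")
  if (is.null(igraph::V(net)$name))
    igraph::V(net)$name <- paste0("g", seq_len(igraph::vcount(net)))
  net
}

#' Maximal-clique centrality scores
#'
#' @param net simple undirected [igraph::igraph].
#' @param cliqueBudget maximal-clique count limit.
#' @return named numeric vector of scores in node order.
#' @export
mccScores <- function(net, cliqueBudget = 1e6) {
  net <- .checkNetwork(net)
  nCl <- igraph::count_max_cliques(net)
  if (nCl > cliqueBudget)
    stop("graph has ", nCl, " maximal cliques, above the budget of ",
         cliqueBudget, "; raise cliqueBudget or reduce the network first")
  score <- setNames(numeric(igraph::vcount(net)), igraph::V(net)$name)
  for (cl in igraph::max_cliques(net)) {
    members <- igraph::V(net)$name[as.integer(cl)]
    score[members] <- score[members] + factorial(length(members) - 1L)
  }
  score
}

# deterministic top-k selection: score descending, node name ascending
.topK <- function(nodes, score, k) {
  o <- order(-score, nodes)
  nodes[o][seq_len(min(k, length(nodes)))]
}

#' Select hub genes by triple-centrality intersection
#'
#' The hub set is the intersection of the top-k node lists under degree,
#' closeness and betweenness centrality; ties broken by (score
#' descending, symbol ascending) so the selection is deterministic.
#'
#' @param centralities table from [computeCentralities()].
#' @param k list depth per centrality (default 10).
#' @return character vector of hub gene symbols (sorted).
#' @export
selectHubGenes <- function(centralities, k = 10) {
  k <- .assertCount(k, "k", 1L)
  if (nrow(centralities) < k)
    warning("fewer nodes (", nrow(centralities), ") than k = ", k,
            "; every top list contains all nodes")
  tops <- lapply(c("degree", "closeness", "betweenness"), function(col)
    .topK(centralities$node, centralities[[col]], k))
  sort(Reduce(intersect, tops))
}

#' Rank core genes by maximal-clique centrality
#'
#' @param net simple undirected [igraph::igraph].
#' @param top number of core genes to return (default 5).
#' @param cliqueBudget maximal-clique count limit.
#' @return data.frame `node`, `clique_score`, best first; deterministic
#'   tie-break (score descending, symbol ascending).
#' @export
scoreCoreGenes <- function(net, top = 5, cliqueBudget = 1e6) {
  top <- .assertCount(top, "top", 1L)
  score <- mccScores(net, cliqueBudget)
  nodes <- .topK(names(score), unname(score), top)
  data.frame(node = nodes, clique_score = unname(score[nodes]),
             stringsAsFactors = FALSE)
}

#' ROC-AUC biomarker screen
#'
#' For each gene, the area under the ROC curve for separating case from
#' control samples, computed by the rank statistic: concordant
#' case-control pairs plus half the ties, over all n1 * n2 pairs — the
#' Mann-Whitney U divided by n1 * n2. Orientation is fixed as case-high =
#' positive (no auto-flip), so AUC < 0.5 is reportable and visible.
#'
#' @param se expression [SummarizedExperiment::SummarizedExperiment] (or
#'   matrix plus `group`) with groups "case"/"control".
#' @param genes symbols to screen; absent genes are skipped with a
#'   warning.
#' @param aucThreshold candidate bar (default 0.7).
#' @param group group labels when `se` is a matrix.
#' @return data.frame: `gene`, `auc`, `candidate`.
#' @export
rocAucBiomarker <- function(se, genes, aucThreshold = 0.7,
                            group = NULL) {
  if (is(se, "SummarizedExperiment")) {
    vals <- SummarizedExperiment::assay(se)
    group <- as.character(SummarizedExperiment::colData(se)$group)
  } else {
    vals <- as.matrix(se)
    group <- as.character(group)
  }
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case'/'control'")
  n1 <- sum(group == "case"); n2 <- sum(group == "control")
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  absent <- setdiff(genes, rownames(vals))
  if (length(absent))
    warning("gene(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
  genes <- setdiff(genes, absent)
  auc <- vapply(genes, function(g) {
    aucRank(vals[g, group == "case"], vals[g, group == "control"])
  }, numeric(1))
  data.frame(gene = genes, auc = unname(auc),
             candidate = unname(auc > aucThreshold),
             stringsAsFactors = FALSE)
}

#' Rank-statistic AUC for two samples
#'
#' `(concordant pairs + 0.5 * ties) / (n1 * n2)`, computed from midranks;
#' equals the Mann-Whitney U statistic divided by n1 * n2.
#'
#' @param cases,controls numeric vectors.
#' @return AUC in \[0, 1\].
#' @examples
#' aucRank(c(5, 6, 7), c(4, 5, 6))  # 7/9
#' @export
aucRank <- function(cases, controls) {
  n1 <- length(cases); n2 <- length(controls)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
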