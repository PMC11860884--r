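# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# all non-empty itemsets with support >= minSupport, by direct power-set
# enumeration over the table's items
bruteItemsets <- function(tt, minSupport) {
  items <- sort(itemLabels(tt))
  rec <- transactionMatrix(tt)
  N <- nRecords(tt)
  out <- list()
  for (k in seq_along(items)) {
    for (idx in combn(length(items), k, simplify = FALSE)) {
      s <- items[idx]
      sup <- sum(apply(rec[, s, drop = FALSE], 1, function(r)
        all(r == 1))) / N
      if (sup >= minSupport)
        out[[paste(s, collapse = ",")]] <- sup
    }
  }
  out
}

# rule metrics by direct counting
bruteRule <- function(tt, X, Y) {
  rec <- transactionMatrix(tt)
  N <- nRecords(tt)
  has <- function(set) sum(apply(rec[, set, drop = FALSE], 1,
                                 function(r) all(r == 1)))
  sXY <- has(union(X, Y)); sX <- has(X); sY <- has(Y)
  c(support = sXY / N, confidence = sXY / sX,
    lift = (sXY / sX) / (sY / N))
}

# a random small transaction table
randomTable <- function(seed, nRec = 10, nItem = 5, p = 0.45) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(nRec * nItem, 1, p), nRec, nItem,
                dimnames = list(NULL, LETTERS[seq_len(nItem)]))
    TransactionTable(m)
  })
}

# all-pairs shortest paths by BFS plus explicit path enumeration, for
# exact betweenness/closeness on tiny graphs
bruteCentralities <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(v) character()), nodes)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  # enumerate all shortest paths s -> t by BFS layers
  allShortest <- function(s, t) {
    if (s == t) return(list())
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    if (!is.finite(dist[t])) return(NULL)
    paths <- list(t)
    for (d in seq(dist[t], 1)) {
      paths <- unlist(lapply(paths, function(p) {
        pred <- adj[[p[1]]][dist[adj[[p[1]]]] == d - 1]
        lapply(pred, function(u) c(u, p))
      }), recursive = FALSE)
    }
    paths
  }
  deg <- vapply(adj, length, integer(1))
  clo <- setNames(numeric(length(nodes)), nodes)
  btw <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- allShortest(nodes[i], nodes[j])
    if (is.null(paths)) next
    d <- length(paths[[1]]) - 1
    clo[nodes[i]] <- clo[nodes[i]] + 1 / d
    clo[nodes[j]] <- clo[nodes[j]] + 1 / d
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / length(paths)
    }
  }
  data.frame(node = nodes, degree = unname(deg), closeness = unname(clo),
             betweenness = unname(btw))
}

# maximal cliques grown from all subsets (<= 10 nodes)
bruteMaxCliques <- function(edges, nodes) {
  isEdge <- function(a, b) any((edges[, 1] == a & edges[, 2] == b) |
                               (edges[, 1] == b & edges[, 2] == a))
  isClique <- function(s) {
    if (length(s) <= 1) return(TRUE)
    all(combn(s, 2, function(p) isEdge(p[1], p[2])))
  }
  cliques <- list()
  for (k in seq_along(nodes)) {
    for (idx in combn(length(nodes), k, simplify = FALSE)) {
      s <- nodes[idx]
      if (!isClique(s)) next
      ext <- setdiff(nodes, s)
      maximal <- !any(vapply(ext, function(v) isClique(c(s, v)),
                             logical(1)))
      if (maximal) cliques[[length(cliques) + 1]] <- s
    }
  }
  cliques
}

bruteMCC <- function(edges, nodes) {
  score <- setNames(numeric(length(nodes)), nodes)
  for (cl in bruteMaxCliques(edges, nodes))
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  score
}

bruteAUC <- function(cases, controls) {
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

bruteHyper <- function(N, K, n, k) {
  kk <- seq(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

randomGraph <- function(seed, nNodes, p = 0.35) {
  withr::with_seed(seed, {
    pairs <- t(combn(nNodes, 2))
    keep <- runif(nrow(pairs)) < p
    nodes <- paste0("n", seq_len(nNodes))
    edges <- cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
    g <- igraph::make_empty_graph(nNodes, directed = FALSE)
    igraph::V(g)$name <- nodes
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    list(graph = g, edges = edges, nodes = nodes)
  })
}
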