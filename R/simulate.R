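#' Simulate a pre/post treatment cohort
#'
#' Draws a synthetic inpatient cohort with one pre/post laboratory value
#' pair per marker and a treatment-exposure flag. Pre-treatment values come
#' from a log-normal distribution whose parameters are solved from the
#' printed median and quartiles of each marker (`mu = log(median)`,
#' `sigma = log(q3/q1) / (2 * qnorm(0.75))`): markers are positive and
#' right-skewed, which the log-normal captures while reproducing the median
#' exactly and the IQR endpoints to within the asymmetry of the printed
#' quartiles. Post values apply, with the per-marker conditional probability
#' from `effectMap`, a multiplicative shrink toward the midpoint of the
#' normal range ("high-is-bad" markers; mirrored otherwise); non-improving
#' patients drift slightly in the adverse direction. Multiplicative
#' log-normal measurement noise with coefficient of variation `noiseCV` is
#' then applied to the post value.
#'
#' With `noiseCV = 0` the fraction of treated patients with `post < pre`
#' on a marker equals that marker's `p_treated` in expectation.
#'
#' @param specs marker specification table ([markerSpecs()]).
#' @param nPatients cohort size (the source cohort enrolled 1,283).
#' @param treatedFraction probability of treatment exposure; the default
#'   0.17 matches the exposure share implied by the source rule table.
#' @param effectMap data.frame `marker`, `p_treated`, `p_untreated`; see
#'   [defaultEffectMap()].
#' @param noiseCV coefficient of variation of measurement noise.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return data.frame: `patient_id`, `treated`, then `<marker>_pre`,
#'   `<marker>_post` per marker.
#' @examples
#' co <- simulateCohort(nPatients = 50, seed = 1)
#' head(co[, 1:4])
#' @export
simulateCohort <- function(specs = markerSpecs(), nPatients = 1283,
                           treatedFraction = 0.17,
                           effectMap = defaultEffectMap(),
                           noiseCV = 0.05, seed = 1) {
  validateMarkerSpecs(specs)
  nPatients <- .assertCount(nPatients, "nPatients")
  .assertProb(treatedFraction, "treatedFraction")
  .assertProb(effectMap$p_treated, "effect probabilities")
  .assertProb(effectMap$p_untreated, "effect probabilities")
  if (noiseCV < 0) stop("noiseCV must be non-negative")
  miss <- setdiff(specs$name, effectMap$marker)
  if (length(miss))
    stop("effect map lacks marker(s): ", paste(miss, collapse = ", "))

  cols <- c("patient_id", "treated",
            as.vector(rbind(paste0(specs$name, "_pre"),
                            paste0(specs$name, "_post"))))
  if (nPatients == 0L) {
    out <- as.data.frame(setNames(
      rep(list(numeric(0)), length(cols)), cols), check.names = FALSE)
    out$patient_id <- character(0)
    out$treated <- logical(0)
    return(out)
  }

  .withSeed(seed, {
    treated <- stats::runif(nPatients) < treatedFraction
    out <- data.frame(
      patient_id = sprintf("P%05d", seq_len(nPatients)),
      treated = treated, check.names = FALSE,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      mu <- log(s$pre_median)
      sigma <- log(s$pre_q3 / s$pre_q1) / (2 * stats::qnorm(0.75))
      pre <- stats::rlnorm(nPatients, mu, sigma)
      p <- ifelse(treated,
        effectMap$p_treated[effectMap$marker == s$name],
        effectMap$p_untreated[effectMap$marker == s$name])
      improve <- stats::runif(nPatients) < p
      target <- (s$normal_low + s$normal_high) / 2
      post <- pre
      if (s$direction == "high-is-bad") {
        u <- stats::runif(nPatients, 0.25, 0.75)
        above <- improve & pre > target
        post[above] <- pre[above] - u[above] * (pre[above] - target)
        below <- improve & pre <= target
        post[below] <- pre[below] * stats::runif(sum(below), 0.90, 0.99)
        post[!improve] <- pre[!improve] *
          (1 + stats::runif(sum(!improve), 0, 0.06))
      } else {
        u <- stats::runif(nPatients, 0.25, 0.75)
        below <- improve & pre < target
        post[below] <- pre[below] + u[below] * (target - pre[below])
        above <- improve & pre >= target
        post[above] <- pre[above] * stats::runif(sum(above), 1.01, 1.10)
        post[!improve] <- pre[!improve] *
          (1 - stats::runif(sum(!improve), 0, 0.06))
      }
      if (noiseCV > 0) {
        sdlog <- sqrt(log(1 + noiseCV^2))
        post <- post * stats::rlnorm(nPatients, -sdlog^2 / 2, sdlog)
      }
      out[[paste0(s$name, "_pre")]] <- pre
      out[[paste0(s$name, "_post")]] <- post
    }
    out
  })
}

#' Simulate a per-record outcome increment sequence
#'
#' Test-harness generator for the random-walk efficacy model.
#' `kind = "iid"` gives independent +1/-1 steps with success probability
#' `p`; `"drifted"` is the same with `p != 0.5` enforced; `"integrated"`
#' returns increments that are themselves the cumulative sum of iid +/-1
#' steps (a super-diffusive fixture whose fluctuation function scales as
#' l^3, i.e. exponent 1.5 on F); `"constant"` is all +1.
#'
#' @param n sequence length (>= 1).
#' @param kind one of `"iid"`, `"drifted"`, `"integrated"`, `"constant"`.
#' @param p success (+1) probability.
#' @param seed integer seed.
#' @return numeric increment vector of length `n`.
#' @export
simulateImprovementSequence <- function(n, kind = c("iid", "drifted",
                                                    "integrated",
                                                    "constant"),
                                        p = 0.5, seed = 1) {
  n <- .assertCount(n, "n", min = 1L)
  kind <- match.arg(kind)
  .assertProb(p, "p")
  if (kind == "constant") return(rep(1, n))
  if (kind == "drifted" && p == 0.5)
    stop("drifted sequences require p != 0.5")
  .withSeed(seed, {
    steps <- ifelse(stats::runif(n) < p, 1, -1)
    if (kind == "integrated") cumsum(steps) else steps
  })
}

#' Simulate a two-group expression matrix with spiked genes
#'
#' Background genes share their mean between groups; `nSpiked` genes are
#' shifted by `spikeLog2FC` in the case group, on the log2 scale, with iid
#' Gaussian noise of standard deviation `sigma`. Ground truth is carried in
#' `rowData()$spiked` for recovery tests.
#'
#' @param nGenes,nPerGroup,nSpiked dimensions; `nSpiked <= nGenes`.
#' @param spikeLog2FC log2 fold change planted in the case group.
#' @param sigma within-group standard deviation (log2 units), > 0.
#' @param seed integer seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2expr"`, `colData(x)$group` in \{case, control\}, and logical
#'   `rowData(x)$spiked`.
#' @export
simulateExpression <- function(nGenes = 2000, nPerGroup = 10,
                               nSpiked = 50, spikeLog2FC = 3,
                               sigma = 1, seed = 1) {
  nGenes <- .assertCount(nGenes, "nGenes", 1L)
  nPerGroup <- .assertCount(nPerGroup, "nPerGroup", 1L)
  nSpiked <- .assertCount(nSpiked, "nSpiked")
  if (nSpiked > nGenes) stop("nSpiked must not exceed nGenes")
  if (sigma <= 0) stop("sigma must be positive")
  .withSeed(seed, {
    genes <- sprintf("GENE%04d", seq_len(nGenes))
    base <- stats::runif(nGenes, 4, 10)
    spiked <- logical(nGenes)
    spiked[sample.int(nGenes, nSpiked)] <- TRUE
    sign <- ifelse(stats::runif(nGenes) < 0.5, 1, -1)
    muCase <- base + ifelse(spiked, sign * spikeLog2FC, 0)
    nS <- 2L * nPerGroup
    vals <- matrix(stats::rnorm(nGenes * nS, sd = sigma), nGenes, nS)
    vals[, seq_len(nPerGroup)] <- vals[, seq_len(nPerGroup)] + muCase
    vals[, nPerGroup + seq_len(nPerGroup)] <-
      vals[, nPerGroup + seq_len(nPerGroup)] + base
    colnames(vals) <- c(sprintf("case_%02d", seq_len(nPerGroup)),
                        sprintf("control_%02d", seq_len(nPerGroup)))
    rownames(vals) <- genes
    SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = vals),
      colData = S4Vectors::DataFrame(
        group = rep(c("case", "control"), each = nPerGroup),
        row.names = colnames(vals)),
      rowData = S4Vectors::DataFrame(spiked = spiked,
        trueLog2FC = ifelse(spiked, sign * spikeLog2FC, 0),
        row.names = genes))
  })
}

#' Simulate an interaction network
#'
#' Generates a simple undirected gene graph, either by preferential
#' attachment (`"scale_free_like"`, hub-heavy degree distribution as in
#' protein-interaction networks) or as an Erdos-Renyi graph
#' (`"erdos_like"`). When `plantedHub` names a node, that node is wired to
#' every other node and competing full-degree nodes are trimmed so the
#' planted hub's degree strictly exceeds all others.
#'
#' @param nNodes number of nodes (>= 1); nodes are named `g1 ... gN`.
#' @param model generator family.
#' @param plantedHub optional node name to promote to the unique
#'   highest-degree node (requires `nNodes >= 3`).
#' @param edgeProb edge probability for the Erdos-Renyi model.
#' @param mAttach edges added per step for preferential attachment.
#' @param seed integer seed.
#' @return an [igraph::igraph] object, simple and undirected.
#' @export
simulateNetwork <- function(nNodes, model = c("scale_free_like",
                                              "erdos_like"),
                            plantedHub = NULL, edgeProb = 0.1,
                            mAttach = 2, seed = 1) {
  nNodes <- .assertCount(nNodes, "nNodes", 1L)
  model <- match.arg(model)
  nodes <- paste0("g", seq_len(nNodes))
  if (!is.null(plantedHub)) {
    if (!plantedHub %in% nodes)
      stop("plantedHub '", plantedHub, "' outside node range")
    if (nNodes < 3L)
      stop("a strictly dominant hub needs at least 3 nodes")
  }
  g <- .withSeed(seed, {
    g <- if (model == "erdos_like") {
      igraph::sample_gnp(nNodes, p = edgeProb, directed = FALSE)
    } else if (nNodes == 1L) {
      igraph::make_empty_graph(1, directed = FALSE)
    } else {
      igraph::sample_pa(nNodes, m = min(mAttach, nNodes - 1),
                        directed = FALSE)
    }
    igraph::simplify(g)
  })
  igraph::V(g)$name <- nodes
  if (!is.null(plantedHub)) {
    others <- setdiff(nodes, plantedHub)
    want <- cbind(plantedHub, others)
    have <- igraph::as_edgelist(g)
    for (i in seq_len(nrow(want))) {
      if (!igraph::are_adjacent(g, want[i, 1], want[i, 2]))
        g <- igraph::add_edges(g, want[i, ])
    }
    # trim rivals that are also connected to everything
    repeat {
      deg <- igraph::degree(g)
      rivals <- names(deg)[deg == nNodes - 1 & names(deg) != plantedHub]
      if (!length(rivals)) break
      r <- rivals[[1]]
      nb <- setdiff(names(igraph::neighbors(g, r)), plantedHub)
      g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(r, nb[[1]])))
    }
  }
  igraph::simplify(g)
}

#' Simulate a gene-set collection
#'
#' Samples named annotation sets from a background universe, optionally
#' including a user-planted set verbatim (name `"planted_set"`), for
#' over-representation fixtures.
#'
#' @param universe background gene symbols (non-empty).
#' @param nSets number of random sets.
#' @param setSizeRange integer range `c(min, max)` of set sizes; must not
#'   exceed the universe size.
#' @param plantedSet optional character vector included verbatim.
#' @param seed integer seed.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
simulateGeneSets <- function(universe, nSets = 10,
                             setSizeRange = c(10, 50),
                             plantedSet = NULL, seed = 1) {
  universe <- .normSymbols(universe)
  if (!length(universe)) stop("universe must be non-empty")
  nSets <- .assertCount(nSets, "nSets")
  if (max(setSizeRange) > length(universe))
    stop("set sizes must not exceed the universe size")
  sets <- .withSeed(seed, {
    rng <- seq(setSizeRange[1], setSizeRange[2])
    sizes <- if (nSets) rng[sample.int(length(rng), nSets,
                                       replace = TRUE)]
    else integer()
    lapply(sizes, function(k) sample(universe, k))
  })
  names(sets) <- if (nSets) sprintf("set%03d", seq_len(nSets)) else NULL
  cats <- rep(c("BP", "CC", "MF", "pathway"), length.out = nSets)
  if (!is.null(plantedSet)) {
    sets <- c(sets, list(planted_set = .normSymbols(plantedSet)))
    cats <- c(cats, "pathway")
  }
  GeneSetCollection(sets, universe, category = cats)
}
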