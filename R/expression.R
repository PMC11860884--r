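#' Two-group differential expression screen
#'
#' Per-gene unequal-variance (Welch) location test on log2-scale values,
#' with `log2fc = mean(case) - mean(control)`. Values whose range suggests
#' a linear scale are log2(x + 1) transformed automatically (overridable).
#' Degenerate genes are handled explicitly: zero variance in both groups
#' with equal means gives p = 1; with unequal means p = 0 (flagged in the
#' `degenerate` column). Duplicate gene symbols collapse to the row with
#' maximal mean expression before testing. No multiple-testing correction
#' is applied here — the downstream selection rule filters on raw p by
#' design; pass the table to [stats::p.adjust()] for a BH variant.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with
#'   `colData(se)$group` in \{"case", "control"\} and >= 2 samples per
#'   group, or a plain matrix plus `group`.
#' @param group character/factor of group labels (ignored when `se` is a
#'   SummarizedExperiment).
#' @param logTransform `"auto"` (range heuristic), `TRUE` or `FALSE`.
#' @param pThreshold,fcThreshold thresholds stamped into the
#'   `significant`/`direction` columns (defaults p < 0.05, |log2FC| > 2).
#' @return data.frame: `gene`, `log2fc`, `p_value`, `significant`,
#'   `direction` ("up"/"down"/"none"), `degenerate`.
#' @export
differentialExpression <- function(se, group = NULL,
                                   logTransform = "auto",
                                   pThreshold = 0.05, fcThreshold = 2) {
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
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("row%05d", seq_len(nrow(vals)))

  if (identical(logTransform, "auto"))
    logTransform <- max(vals, na.rm = TRUE) > 50
  if (isTRUE(logTransform)) {
    if (any(vals < 0, na.rm = TRUE))
      stop("cannot log-transform negative values")
    vals <- log2(vals + 1)
    message("values log2(x + 1) transformed (linear-scale heuristic)")
  }

  # collapse duplicate symbols to the highest-mean row
  if (anyDuplicated(rownames(vals))) {
    mm <- rowMeans(vals)
    keep <- !logical(nrow(vals))
    for (g in unique(rownames(vals)[duplicated(rownames(vals))])) {
      idx <- which(rownames(vals) == g)
      keep[idx] <- FALSE
      keep[idx[which.max(mm[idx])]] <- TRUE
    }
    vals <- vals[keep, , drop = FALSE]
  }

  x1 <- vals[, group == "case", drop = FALSE]
  x2 <- vals[, group == "control", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen & lfc == 0] <- 1
  p[degen & lfc != 0] <- 0
  if (any(degen & lfc != 0))
    message(sum(degen & lfc != 0),
            " zero-variance gene(s) with unequal means flagged (p = 0)")
  sig <- p < pThreshold & abs(lfc) > fcThreshold
  out <- data.frame(gene = rownames(vals), log2fc = unname(lfc),
                    p_value = unname(p), significant = unname(sig),
                    direction = ifelse(!sig, "none",
                                       ifelse(lfc > 0, "up", "down")),
                    degenerate = unname(degen),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(p = pThreshold, fc = fcThreshold)
  out
}

#' Select differentially expressed genes by threshold
#'
#' Partitions genes passing `p < pThreshold` and `|log2fc| > fcThreshold`
#' by the sign of the fold change, reporting counts in the up/down format
#' used for microarray screens.
#'
#' @param table DEG table from [differentialExpression()].
#' @param pThreshold,fcThreshold selection thresholds (> 0).
#' @return list with `up`, `down` (gene vectors) and `counts`
#'   (`significant`, `up`, `down`).
#' @export
selectDEGs <- function(table, pThreshold = 0.05, fcThreshold = 2) {
  stopifnot(pThreshold > 0, fcThreshold > 0)
  sig <- table$p_value < pThreshold & abs(table$log2fc) > fcThreshold
  up <- table$gene[sig & table$log2fc > 0]
  down <- table$gene[sig & table$log2fc < 0]
  message(sum(sig), " significant genes: ", length(up), " up, ",
          length(down), " down")
  list(up = up, down = down,
       counts = c(significant = sum(sig), up = length(up),
                  down = length(down)))
}

#' Intersect DEGs with compound-target lists
#'
#' Case-insensitive, whitespace-trimmed symbol matching. Target lists are
#' deduplicated into a union before intersecting with the DEG set; the
#' consensus is the target-union intersected with the DEGs, with Venn
#' region counts per list.
#'
#' @param degGenes character vector of DEG symbols.
#' @param targetLists named list of symbol vectors (one per compound).
#' @return list: `consensus`, `targetUnion`, and `counts` (per-list sizes,
#'   per-list DEG overlaps, union/DEG/consensus sizes).
#' @export
intersectTargets <- function(degGenes, targetLists) {
  degs <- unique(.normSymbols(degGenes))
  if (!length(degs))
    warning("empty DEG set: consensus will be empty")
  lists <- lapply(targetLists, function(x) unique(.normSymbols(x)))
  targetUnion <- unique(unlist(lists, use.names = FALSE))
  consensus <- sort(intersect(targetUnion, degs))
  perList <- vapply(lists, length, integer(1))
  perOverlap <- vapply(lists, function(x) length(intersect(x, degs)),
                       integer(1))
  list(consensus = consensus, targetUnion = sort(targetUnion),
       counts = list(per_list = perList, per_list_deg = perOverlap,
                     union = length(targetUnion), degs = length(degs),
                     consensus = length(consensus)))
}
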