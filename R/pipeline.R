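.defaultConfig <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    stages = list(mine = TRUE, walk = TRUE, dge = TRUE,
                  network = TRUE, enrich = TRUE),
    simulate = list(n_patients = 1283L, treated_fraction = 0.17,
                    noise_cv = 0.05, planted_marker = "Hs-CRP",
                    p_treated = 0.8, p_untreated = 0.5),
    mine = list(min_support = 0.01, min_confidence = 0, tolerance = 0),
    walk = list(outcome_item = "Hs-CRP_improved", n_shuffles = 199L,
                level = 0.05),
    dge = list(p_threshold = 0.05, fc_threshold = 2, n_genes = 2000L,
               n_per_group = 10L, n_spiked = 50L, spike_log2fc = 3,
               sigma = 1),
    network = list(top_k = 10L, top_core = 5L, auc_threshold = 0.7),
    enrich = list(mode = "raw", alpha = 0.05, n_sets = 15L))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills defaults, type- and
#' range-checks every field, and rejects unknown keys fail-fast with a
#' nearest-key suggestion. All violations are collected and reported
#' together. An empty file yields the all-defaults configuration.
#'
#' @param config path to a YAML file, or a (possibly partial) nested
#'   list; `NULL` or empty gives all defaults.
#' @return the completed configuration list (class `xfcnet_config`).
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- .defaultConfig()
  errs <- character()
  suggest <- function(key, known) {
    d <- utils::adist(key, known)
    if (min(d) <= 3) paste0(" (did you mean '", known[which.min(d)], "'?)")
    else ""
  }
  merge <- function(user, def, prefix = "") {
    unknown <- setdiff(names(user), names(def))
    for (u in unknown)
      errs <<- c(errs, paste0("unknown key '", prefix, u, "'",
                              suggest(u, names(def))))
    for (k in intersect(names(user), names(def))) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge(user[[k]], def[[k]], paste0(prefix, k, "."))
      } else {
        def[[k]] <- user[[k]]
      }
    }
    def
  }
  cfg <- merge(config, defaults)
  chkProb <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      errs <<- c(errs, paste0(what, " must be in [0, 1], got ",
                              deparse(x)))
  }
  chkPos <- function(x, what, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
      errs <<- c(errs, paste0(what, " must be numeric >= ", min))
  }
  chkProb(cfg$simulate$treated_fraction, "simulate.treated_fraction")
  chkProb(cfg$simulate$p_treated, "simulate.p_treated")
  chkProb(cfg$simulate$p_untreated, "simulate.p_untreated")
  chkPos(cfg$simulate$n_patients, "simulate.n_patients")
  chkPos(cfg$simulate$noise_cv, "simulate.noise_cv")
  chkProb(cfg$mine$min_support, "mine.min_support")
  chkProb(cfg$mine$min_confidence, "mine.min_confidence")
  chkPos(cfg$mine$tolerance, "mine.tolerance")
  chkPos(cfg$walk$n_shuffles, "walk.n_shuffles", 99)
  chkProb(cfg$walk$level, "walk.level")
  chkPos(cfg$dge$p_threshold, "dge.p_threshold")
  chkPos(cfg$dge$fc_threshold, "dge.fc_threshold")
  chkPos(cfg$dge$sigma, "dge.sigma")
  chkPos(cfg$network$top_k, "network.top_k", 1)
  chkProb(cfg$network$auc_threshold, "network.auc_threshold")
  if (!cfg$enrich$mode %in% c("raw", "bh"))
    errs <- c(errs, "enrich.mode must be 'raw' or 'bh'")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = c("xfcnet_config", "list"))
}

#' Run the full pipeline
#'
#' Executes the stages in workflow order — cohort simulation and rule
#' mining, the efficacy random walk, differential expression, target
#' intersection, network hub/core analysis with a biomarker screen, and
#' over-representation analysis — under one master seed with named
#' per-stage substreams, so toggling a stage never shifts another's
#' randomness. All inputs are generated by the synthetic-data module;
#' intermediates are written to `outdir` when given.
#'
#' @param config configuration accepted by [validateConfig()].
#' @return a run report list: per-stage blocks, the echoed configuration
#'   and the package version. Identical seed and configuration give an
#'   identical report (timings excluded).
#' @examples
#' \donttest{
#' rep <- runPipeline(list(simulate = list(n_patients = 200),
#'                         dge = list(n_genes = 300)))
#' rep$mine$rules
#' }
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  t0 <- proc.time()[["elapsed"]]
  report <- list(config = unclass(cfg),
                 version = as.character(utils::packageVersion("xfcnet")))
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(stage, ...) message("[", stage, "] ", ...)

  # --- cohort + mining -------------------------------------------------
  specs <- markerSpecs()
  em <- defaultEffectMap()
  pm <- cfg$simulate$planted_marker
  if (!pm %in% em$marker) stop("planted marker '", pm, "' unknown")
  em$p_treated[em$marker == pm] <- cfg$simulate$p_treated
  em$p_untreated[em$marker == pm] <- cfg$simulate$p_untreated
  emit("simulate", "cohort of ", cfg$simulate$n_patients, " patients")
  cohort <- simulateCohort(specs, nPatients = cfg$simulate$n_patients,
    treatedFraction = cfg$simulate$treated_fraction, effectMap = em,
    noiseCV = cfg$simulate$noise_cv,
    seed = deriveSeed(cfg$seed, "cohort"))
  tt <- codeImprovements(cohort, specs,
                         tolerance = cfg$mine$tolerance)
  report$simulate <- list(n_patients = nrow(cohort),
                          n_treated = sum(cohort$treated))
  if (!is.null(outdir)) writeCohort(cohort, file.path(outdir, "cohort.csv"))

  if (isTRUE(cfg$stages$mine)) {
    rules <- deriveRules(tt, minSupport = cfg$mine$min_support,
                         minConfidence = cfg$mine$min_confidence)
    emit("mine", nrow(rules), " rules derived")
    report$mine <- list(rules = rules)
    if (!is.null(outdir)) writeRules(rules, file.path(outdir, "rules.tsv"))
  }

  if (isTRUE(cfg$stages$walk)) {
    item <- cfg$walk$outcome_item
    if (!item %in% itemLabels(tt))
      stop("walk stage: outcome item '", item, "' not in transactions")
    w <- buildWalk(tt, item)
    fr <- testAlphaNull(w, nShuffles = cfg$walk$n_shuffles,
                        level = cfg$walk$level,
                        seed = deriveSeed(cfg$seed, "shuffle"))
    emit("walk", sprintf("alpha-hat = %.3f, null %s", fr@alphaHat,
         if (fr@nullRejected) "rejected" else "not rejected"))
    report$walk <- list(alpha_hat = fr@alphaHat, alpha_se = fr@alphaSE,
                        null_rejected = fr@nullRejected,
                        n_shuffles = fr@nShuffles)
    if (!is.null(outdir)) {
      utils::write.table(fluctuations(fr),
        file.path(outdir, "fluctuation.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE)
      jsonlite::write_json(report$walk,
        file.path(outdir, "walk_summary.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  consensus <- NULL
  if (isTRUE(cfg$stages$dge)) {
    se <- simulateExpression(nGenes = cfg$dge$n_genes,
      nPerGroup = cfg$dge$n_per_group, nSpiked = cfg$dge$n_spiked,
      spikeLog2FC = cfg$dge$spike_log2fc, sigma = cfg$dge$sigma,
      seed = deriveSeed(cfg$seed, "expression"))
    deg <- differentialExpression(se,
      pThreshold = cfg$dge$p_threshold,
      fcThreshold = cfg$dge$fc_threshold)
    sel <- suppressMessages(selectDEGs(deg, cfg$dge$p_threshold,
                                       cfg$dge$fc_threshold))
    emit("dge", sel$counts[["significant"]], " DEGs (",
         sel$counts[["up"]], " up, ", sel$counts[["down"]], " down)")
    # compound-target lists enriched in true spikes, one per herb
    spiked <- rownames(se)[SummarizedExperiment::rowData(se)$spiked]
    bg <- rownames(se)
    targets <- .withSeed(deriveSeed(cfg$seed, "targets"), {
      lapply(c(astragalus = 60, coix = 25, tripterygium = 45,
               scolopendra = 10), function(sz) {
        nHit <- min(length(spiked), max(1L, round(sz * 0.4)))
        unique(c(sample(spiked, nHit), sample(bg, sz - nHit)))
      })
    })
    degGenes <- c(sel$up, sel$down)
    inter <- intersectTargets(degGenes, targets)
    emit("intersect", inter$counts$consensus, " consensus target genes")
    report$dge <- list(counts = as.list(sel$counts),
                       consensus = inter$consensus,
                       venn = inter$counts)
    consensus <- inter$consensus
    if (!is.null(outdir)) {
      utils::write.table(deg, file.path(outdir, "deg_table.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      writeLines(inter$consensus, file.path(outdir, "consensus_genes.txt"))
      jsonlite::write_json(inter$counts, file.path(outdir, "venn.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (isTRUE(cfg$stages$network)) {
    if (is.null(consensus) || length(consensus) < 3)
      stop("network stage requires the dge stage (or >= 3 genes)")
    net <- simulateNetwork(length(consensus),
      model = "scale_free_like",
      seed = deriveSeed(cfg$seed, "network"))
    igraph::V(net)$name <- sort(consensus)
    centr <- computeCentralities(net)
    hubs <- selectHubGenes(centr, k = cfg$network$top_k)
    cores <- scoreCoreGenes(net, top = cfg$network$top_core)
    roc <- rocAucBiomarker(se, cores$node,
                           aucThreshold = cfg$network$auc_threshold)
    emit("network", length(hubs), " hub genes; core: ",
         paste(cores$node, collapse = ", "))
    report$network <- list(hubs = hubs, cores = cores, roc = roc)
    if (!is.null(outdir)) {
      utils::write.table(centr, file.path(outdir, "centralities.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(roc, file.path(outdir, "biomarkers.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if (isTRUE(cfg$stages$enrich)) {
    if (is.null(consensus))
      stop("enrich stage requires the dge stage for a query gene list")
    universe <- rownames(se)
    gsc <- suppressMessages(simulateGeneSets(universe,
      nSets = cfg$enrich$n_sets,
      setSizeRange = c(20, 80),
      plantedSet = utils::head(consensus, 20),
      seed = deriveSeed(cfg$seed, "genesets")))
    enr <- suppressMessages(hypergeomEnrich(consensus, gsc,
      mode = cfg$enrich$mode, alpha = cfg$enrich$alpha))
    emit("enrich", sum(enr$significant), " significant terms of ",
         nrow(enr))
    report$enrich <- list(table = enr)
    if (!is.null(outdir))
      utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
  }

  report$elapsed_s <- proc.time()[["elapsed"]] - t0
  if (!is.null(outdir)) {
    clean <- report
    clean$elapsed_s <- NULL
    jsonlite::write_json(clean, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
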