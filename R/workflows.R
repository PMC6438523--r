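## End-to-end workflow orchestration. Each stage's output feeds the next,
## every stage is timed and its full parameter map recorded in the
## provenance ledger, and a ledger can be replayed to reproduce the run.

.GWH_STAGES <- c("core_genes", "consensus", "core_samples", "final_heatmap")

## Registry of output-affecting parameters per workflow; the ledger
## exhaustiveness test asserts every entry appears in some recorded step.
outputAffectingParams <- function(workflow = c("gwh", "crc", "soc")) {
  switch(match.arg(workflow),
         gwh = c("measures", "percentile", "rule", "kRange", "reps",
                 "pItem", "pFeature", "innerParams", "kPolicy",
                 "deltaThreshold", "userK", "thresholds", "heatmapParams",
                 "seed", "stages"),
         crc = c("kRange", "reps", "pItem", "pFeature", "innerParams",
                 "platformK", "crcParams", "crcK", "seed"),
         soc = c("B", "params", "seed", "excludeObserved", "geneSet"))
}

#' Genome-wide heatmap (GWH) analysis workflow
#'
#' Runs the full single-data-type workflow: (1) core genes by a spread
#' measure percentile cut (integrated sum-of-ranks when two or more
#' measures are named); (2) resampling consensus clustering of the
#' core-gene matrix and estimation of k; (3) silhouette widths at the
#' selected k and per-cluster core-sample filtering; (4) an updated heatmap
#' clustering of core genes x core samples. Each stage's parameters, seed
#' and elapsed time are appended to a provenance ledger; the run can be
#' reproduced exactly with [replayGWH()].
#'
#' @param m a [FeatureMatrix-class].
#' @param measures spread measure(s); one measure uses
#'   [selectByPercentile()], two or more the integrated
#'   [integratedRankSelect()].
#' @param percentile,rule core-gene percentile cut (default: strictly above
#'   the 99th percentile).
#' @param kRange,reps,pItem,pFeature,innerParams consensus settings (see
#'   [runConsensus()]).
#' @param kPolicy,deltaThreshold,userK k-selection policy (see
#'   [selectK()]).
#' @param thresholds per-cluster silhouette thresholds, a single broadcast
#'   value, or `"auto"` (mean width minus one SD per cluster).
#' @param heatmapParams [ClusterParams-class] for the final heatmap axes.
#' @param seed integer seed governing all resampling.
#' @param stages prefix of the stage list to run (every stage is also
#'   independently runnable through its module function).
#' @param outDir optional directory for rendered heatmaps, the ledger YAML
#'   and the workflow summary.
#' @return List with `coreGenes`, `consensus` ([ConsensusResult-class]),
#'   `silhouette` ([SilhouetteReport-class]), `finalLabels`, `finalOrders`
#'   (heatmap leaf orders) and `ledger` ([ProvenanceRecord-class]).
#' @export
runGWH <- function(m, measures = "IQR", percentile = 99,
                   rule = "strictly_above", kRange = 2:6, reps = 100,
                   pItem = 0.8, pFeature = 1,
                   innerParams = ClusterParams(
                     scaling = "none", distance = "one_minus_pearson",
                     linkage = "average"),
                   kPolicy = "largest_delta_knee", deltaThreshold = 0.1,
                   userK = NA_integer_, thresholds = "auto",
                   heatmapParams = ClusterParams(
                     scaling = "row_then_col_z",
                     distance = "one_minus_pearson", linkage = "ward_d"),
                   seed, stages = .GWH_STAGES, outDir = NULL) {
  stopifnot(is(m, "FeatureMatrix"))
  if (missing(seed)) stop("a seed is required for replicability")
  stages <- match.arg(stages, .GWH_STAGES, several.ok = TRUE)
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ledger <- ProvenanceRecord()
  config <- list(measures = measures, percentile = percentile, rule = rule,
                 kRange = as.integer(kRange), reps = reps, pItem = pItem,
                 pFeature = pFeature,
                 innerParams = paramsAsList(innerParams),
                 kPolicy = kPolicy, deltaThreshold = deltaThreshold,
                 userK = userK, thresholds = thresholds,
                 heatmapParams = paramsAsList(heatmapParams),
                 seed = as.integer(seed), stages = stages)
  ledger <- recordStep(ledger, "config", config,
                       fingerprints = list(input = fingerprintObject(m)))
  out <- list(ledger = ledger)

  ## stage 1: core genes
  t0 <- proc.time()[["elapsed"]]
  profile <- computeSpread(m, measures = unique(c(measures)))
  coreGenes <- if (length(measures) >= 2L)
    integratedRankSelect(profile, measures, percentile, rule)
  else selectByPercentile(profile, measures, percentile, rule)
  coreM <- m[coreGenes, ]
  out$coreGenes <- coreGenes
  out$spread <- profile
  ledger <- recordStep(
    ledger, "core_genes",
    list(measures = measures, percentile = percentile, rule = rule),
    elapsed = proc.time()[["elapsed"]] - t0,
    fingerprints = list(coreGenes = fingerprintObject(coreGenes)))
  if (!"consensus" %in% stages) {
    out$ledger <- ledger
    return(.finishGWH(out, ledger, outDir))
  }

  ## stage 2: consensus clustering and k estimation
  t0 <- proc.time()[["elapsed"]]
  cons <- runConsensus(coreM, kRange = kRange, reps = reps, pItem = pItem,
                       pFeature = pFeature, innerParams = innerParams,
                       seed = seed)
  cons <- selectK(cons, policy = kPolicy, deltaThreshold = deltaThreshold,
                  userK = userK)
  out$consensus <- cons
  ledger <- recordStep(
    ledger, "consensus",
    list(kRange = as.integer(kRange), reps = reps, pItem = pItem,
         pFeature = pFeature, innerParams = paramsAsList(innerParams),
         kPolicy = kPolicy, deltaThreshold = deltaThreshold, userK = userK,
         seed = as.integer(seed), selectedK = cons@selectedK),
    elapsed = proc.time()[["elapsed"]] - t0,
    fingerprints = list(
      assignments = fingerprintObject(consensusAssignments(cons))))
  if (!"core_samples" %in% stages)
    return(.finishGWH(out, ledger, outDir))

  ## stage 3: silhouette widths and core samples
  t0 <- proc.time()[["elapsed"]]
  labs <- consensusAssignments(cons)
  d <- pairwiseDistance(scaleMatrix(coreM, innerParams@scaling),
                        innerParams@distance, axis = "samples")
  sil <- silhouetteWidths(d, labs)
  sil <- filterCoreSamples(sil, thresholds)
  out$silhouette <- sil
  ledger <- recordStep(
    ledger, "core_samples",
    list(thresholds = as.list(sil@thresholds),
         distance = innerParams@distance),
    elapsed = proc.time()[["elapsed"]] - t0,
    fingerprints = list(retained = fingerprintObject(sil@retained)))
  if (!"final_heatmap" %in% stages)
    return(.finishGWH(out, ledger, outDir))

  ## stage 4: updated heatmap of core genes x core samples
  t0 <- proc.time()[["elapsed"]]
  finalM <- m[coreGenes, sil@retained]
  hm <- renderHeatmap(
    finalM,
    rowParams = ClusterParams(scaling = heatmapParams@scaling,
                              distance = heatmapParams@distance,
                              linkage = heatmapParams@linkage,
                              axis = "features"),
    colParams = heatmapParams,
    file = if (!is.null(outDir))
      file.path(outDir, "final_heatmap.png") else NULL)
  scaled <- scaleMatrix(finalM, heatmapParams@scaling)
  finalTree <- hierarchicalLinkage(
    pairwiseDistance(scaled, heatmapParams@distance, axis = "samples"),
    heatmapParams@linkage)
  out$finalLabels <- cutTree(finalTree, min(cons@selectedK,
                                            length(sil@retained)))
  out$finalOrders <- hm[c("rowOrder", "colOrder")]
  ledger <- recordStep(
    ledger, "final_heatmap",
    list(heatmapParams = paramsAsList(heatmapParams),
         k = cons@selectedK),
    elapsed = proc.time()[["elapsed"]] - t0,
    fingerprints = list(labels = fingerprintObject(out$finalLabels),
                        leafOrders = fingerprintObject(out$finalOrders)))
  .finishGWH(out, ledger, outDir)
}

.finishGWH <- function(out, ledger, outDir) {
  out$ledger <- ledger
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeProvenance(ledger, file.path(outDir, "ledger.yaml"))
    renderWorkflowSummary(ledger, file.path(outDir, "workflow_summary.txt"))
  }
  out
}

#' Replay a GWH run from its provenance ledger
#'
#' Re-executes [runGWH()] on the same input with the parameters recorded in
#' the ledger's `config` step; with the same input matrix this reproduces
#' identical core genes, cluster labels and heatmap leaf orders.
#'
#' @param m the input [FeatureMatrix-class].
#' @param ledger a [ProvenanceRecord-class] emitted by [runGWH()] (or read
#'   back with [readProvenance()]).
#' @param outDir optional output directory.
#' @return As [runGWH()].
#' @export
replayGWH <- function(m, ledger, outDir = NULL) {
  cfg <- provenanceParams(ledger)[["config"]]
  if (is.null(cfg)) stop("ledger has no config step")
  cfg$innerParams <- paramsFromList(cfg$innerParams)
  cfg$heatmapParams <- paramsFromList(cfg$heatmapParams)
  cfg$kRange <- as.integer(unlist(cfg$kRange))
  cfg$stages <- unlist(cfg$stages)
  cfg$measures <- unlist(cfg$measures)
  if (is.list(cfg$thresholds)) cfg$thresholds <- unlist(cfg$thresholds)
  do.call(runGWH, c(list(m = m), cfg, list(outDir = outDir)))
}

#' Combined-results cluster (CrC) workflow
#'
#' Applies per-platform consensus clustering (on matrices of core features),
#' merges the resulting sub-cluster assignments into a binary membership
#' matrix, clusters it into combined (CrC) labels, and produces the
#' interpretation outputs: per-platform five-number summaries with
#' increased/decreased calls and pairwise contingency-table association
#' tests against each platform's clusters.
#'
#' @param platforms named list of 2-3 [FeatureMatrix-class] objects on
#'   shared samples (already reduced to core features).
#' @param platformK fixed per-platform k (single value or named vector);
#'   `NULL` estimates k per platform by consensus delta-areas.
#' @param kRange,reps,pItem,pFeature,innerParams consensus settings shared
#'   by all platforms (a named list of [ClusterParams-class] may be given
#'   as `innerParams` for per-platform settings).
#' @param crcParams distance/linkage for the membership-matrix clustering
#'   (default Euclidean + `ward_d`).
#' @param crcK number of combined clusters; `NULL` estimates it by
#'   consensus on the membership matrix.
#' @param seed integer seed.
#' @return List with `assignments` (per-platform labels),
#'   `membership` ([MembershipMatrix-class]), `crcLabels`, `summaries`,
#'   `contingency` (per-platform [ContingencyResult-class]) and `ledger`.
#' @export
runCrC <- function(platforms, platformK = 2L, kRange = 2:5, reps = 100,
                   pItem = 0.8, pFeature = 1,
                   innerParams = ClusterParams(
                     scaling = "none", distance = "one_minus_pearson",
                     linkage = "average"),
                   crcParams = ClusterParams(distance = "euclidean",
                                             linkage = "ward_d"),
                   crcK = NULL, seed) {
  stopifnot(is.list(platforms), length(platforms) >= 2L,
            !is.null(names(platforms)))
  if (missing(seed)) stop("a seed is required for replicability")
  ledger <- ProvenanceRecord()
  getParams <- function(p)
    if (is(innerParams, "ClusterParams")) innerParams else innerParams[[p]]
  assignments <- list()
  for (i in seq_along(platforms)) {
    p <- names(platforms)[i]
    t0 <- proc.time()[["elapsed"]]
    cons <- runConsensus(platforms[[p]], kRange = kRange, reps = reps,
                         pItem = pItem, pFeature = pFeature,
                         innerParams = getParams(p),
                         seed = as.integer(seed) + i)
    kp <- if (is.null(platformK)) {
      cons <- selectK(cons)
      cons@selectedK
    } else if (length(platformK) > 1L) platformK[[p]] else platformK
    assignments[[p]] <- consensusAssignments(cons, k = kp)
    ledger <- recordStep(
      ledger, paste0("platform_consensus_", p),
      list(kRange = as.integer(kRange), reps = reps, pItem = pItem,
           pFeature = pFeature, innerParams = paramsAsList(getParams(p)),
           platformK = kp, seed = as.integer(seed) + i),
      elapsed = proc.time()[["elapsed"]] - t0)
  }
  t0 <- proc.time()[["elapsed"]]
  mm <- buildMembershipMatrix(assignments)
  kCrc <- if (is.null(crcK)) {
    cc <- selectK(consensusMembership(mm, kRange = kRange, reps = reps,
                                      pItem = pItem,
                                      innerParams = ClusterParams(
                                        scaling = "none",
                                        distance = crcParams@distance,
                                        linkage = crcParams@linkage),
                                      seed = as.integer(seed)))
    cc@selectedK
  } else crcK
  crcLabels <- clusterMembership(mm, crcParams, kCrc)
  summaries <- summarizeByPlatform(platforms, crcLabels)
  contingency <- lapply(assignments, contingencyTest, labelsB = crcLabels)
  ledger <- recordStep(
    ledger, "crc",
    list(crcParams = paramsAsList(crcParams), crcK = kCrc,
         seed = as.integer(seed)),
    elapsed = proc.time()[["elapsed"]] - t0,
    fingerprints = list(labels = fingerprintObject(crcLabels)))
  list(assignments = assignments, membership = mm, crcLabels = crcLabels,
       summaries = summaries, contingency = contingency, ledger = ledger)
}

#' Significance-of-clusters (SoC) workflow
#'
#' Thin orchestration of [socBootstrap()] that also records the run in a
#' provenance ledger and can render the gene-set heatmap with the same
#' parameters as the GWH heatmap stage.
#'
#' @param m genome-wide [FeatureMatrix-class].
#' @param geneSet tested feature ids.
#' @param groupLabels known sample groups.
#' @param B number of random gene sets.
#' @param params [ClusterParams-class] for the separation clustering.
#' @param seed integer seed.
#' @param excludeObserved exclude the tested genes from the null pool.
#' @param outDir optional directory for the gene-set heatmap and ledger.
#' @return List with `result` ([SoCResult-class]) and `ledger`.
#' @export
runSoC <- function(m, geneSet, groupLabels, B = 1000,
                   params = ClusterParams(distance = "one_minus_pearson",
                                          linkage = "ward_d"),
                   seed, excludeObserved = FALSE, outDir = NULL) {
  if (missing(seed)) stop("a seed is required for replicability")
  t0 <- proc.time()[["elapsed"]]
  res <- socBootstrap(m, geneSet, groupLabels, B = B, params = params,
                      seed = seed, excludeObserved = excludeObserved)
  ledger <- recordStep(
    ProvenanceRecord(), "soc",
    list(B = B, params = paramsAsList(params), seed = as.integer(seed),
         excludeObserved = excludeObserved,
         geneSet = as.character(geneSet)),
    elapsed = proc.time()[["elapsed"]] - t0,
    fingerprints = list(input = fingerprintObject(m),
                        nullStats = fingerprintObject(res@nullStats)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    renderHeatmap(m[geneSet, ],
                  file = file.path(outDir, "geneset_heatmap.png"))
    writeProvenance(ledger, file.path(outDir, "ledger.yaml"))
  }
  list(result = res, ledger = ledger)
}
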