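#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats as.dist cor cutree dist hclust mad median quantile
#'   rnorm sd var setNames
#' @importFrom utils head read.table write.table packageVersion
NULL

.SCALINGS  <- c("none", "row_z", "col_z", "row_then_col_z")
.DISTANCES <- c("one_minus_pearson", "euclidean", "canberra", "manhattan",
                "one_minus_spearman")
.LINKAGES  <- c("ward_d", "average", "complete", "single", "mcquitty")
.AXES      <- c("samples", "features")
.MEASURES  <- c("VAR", "MAD", "IQR")

## Annotation caps: at most 10 levels per sample track, 6 per feature track.
.MAX_SAMPLE_LEVELS  <- 10L
.MAX_FEATURE_LEVELS <- 6L

#' FeatureMatrix: an annotated feature-by-sample numeric matrix
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single assay named `"values"` (features in rows, samples in columns),
#' optional categorical feature groups in `rowData` and zero or more
#' categorical sample-annotation tracks in `colData`. Validity enforces the
#' workflow's annotation limits: every sample track has at most 10 levels and
#' every feature track at most 6; identifiers are unique and all values are
#' finite.
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "values"))
    msg <- c(msg, "assay must be a single matrix named 'values'")
  v <- SummarizedExperiment::assay(object, withDimnames = TRUE)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "feature and sample identifiers are required")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate feature ids")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate sample ids")
  if (!is.numeric(v) || any(!is.finite(v)))
    msg <- c(msg, "values must all be finite numbers")
  rd <- SummarizedExperiment::rowData(object)
  for (nm in colnames(rd)) {
    n <- length(unique(as.character(rd[[nm]])))
    if (n > .MAX_FEATURE_LEVELS)
      msg <- c(msg, sprintf("feature track '%s' has %d levels (max %d)",
                            nm, n, .MAX_FEATURE_LEVELS))
  }
  cd <- SummarizedExperiment::colData(object)
  for (nm in colnames(cd)) {
    n <- length(unique(as.character(cd[[nm]])))
    if (n > .MAX_SAMPLE_LEVELS)
      msg <- c(msg, sprintf("sample track '%s' has %d levels (max %d)",
                            nm, n, .MAX_SAMPLE_LEVELS))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, features in rows and samples in columns,
#'   with unique row and column names.
#' @param featureGroups optional character/factor of length `nrow(values)`
#'   assigning each feature to one of at most 6 groups.
#' @param sampleAnnotations optional `data.frame` (or named list) of
#'   categorical tracks, one row per sample, each track with at most 10
#'   levels.
#' @param metadata optional list stored in the object's metadata.
#' @return A [FeatureMatrix-class] object.
#' @examples
#' v <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' fm <- FeatureMatrix(v, featureGroups = c("a", "a", "b", "b"))
#' @export
FeatureMatrix <- function(values, featureGroups = NULL,
                          sampleAnnotations = NULL, metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(featureGroups)) {
    stopifnot(length(featureGroups) == nrow(values))
    rd[["feature_group"]] <- as.character(featureGroups)
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(sampleAnnotations)) {
    sa <- as.data.frame(sampleAnnotations, stringsAsFactors = FALSE)
    stopifnot(nrow(sa) == ncol(values))
    for (nm in names(sa)) cd[[nm]] <- as.character(sa[[nm]])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), rowData = rd, colData = cd,
    metadata = metadata)
  new("FeatureMatrix", se)
}

#' ClusterParams: scaling, distance and linkage settings
#'
#' Validated bundle of the clustering choices shared by the heatmap,
#' consensus, cluster-of-clusters and gene-set-significance stages. All four
#' fields are closed vocabularies, checked at construction, and serialize
#' losslessly into the provenance ledger.
#'
#' @slot scaling one of `"none"`, `"row_z"`, `"col_z"`, `"row_then_col_z"`.
#' @slot distance one of `"one_minus_pearson"`, `"euclidean"`, `"canberra"`,
#'   `"manhattan"`, `"one_minus_spearman"`.
#' @slot linkage one of `"ward_d"`, `"average"`, `"complete"`, `"single"`,
#'   `"mcquitty"`. `"ward_d"` applies the Ward Lance-Williams update to the
#'   unsquared input distances (hclust's `ward.D`, not `ward.D2`).
#' @slot axis `"samples"` or `"features"`.
#' @export
setClass("ClusterParams", representation(
  scaling = "character", distance = "character",
  linkage = "character", axis = "character"))

setValidity("ClusterParams", function(object) {
  msg <- character()
  chk <- function(val, allowed, what) {
    if (length(val) != 1L || !val %in% allowed)
      sprintf("%s must be one of: %s", what, paste(allowed, collapse = ", "))
    else NULL
  }
  msg <- c(msg,
           chk(object@scaling, .SCALINGS, "scaling"),
           chk(object@distance, .DISTANCES, "distance"),
           chk(object@linkage, .LINKAGES, "linkage"),
           chk(object@axis, .AXES, "axis"))
  if (length(msg)) msg else TRUE
})

#' @param scaling,distance,linkage,axis see slots.
#' @return A `ClusterParams` object.
#' @rdname ClusterParams-class
#' @examples
#' ClusterParams(distance = "one_minus_pearson", linkage = "ward_d")
#' @export
ClusterParams <- function(scaling = "none", distance = "one_minus_pearson",
                          linkage = "ward_d", axis = "samples") {
  new("ClusterParams", scaling = scaling, distance = distance,
      linkage = linkage, axis = axis)
}

#' SpreadProfile: per-feature measures of spread and their ranks
#'
#' Holds, for every feature, one or more of the spread measures VAR (sample
#' variance), MAD (scaled median absolute deviation) and IQR (inter-quartile
#' range), together with ascending ranks (rank 1 = smallest spread, ties
#' averaged) used by the integrated sum-of-ranks selector.
#'
#' @slot featureIds character vector of feature identifiers.
#' @slot spreadValues named list of numeric vectors, one per measure.
#' @slot spreadRanks named list of numeric rank vectors (average ties).
#' @export
setClass("SpreadProfile", representation(
  featureIds = "character", spreadValues = "list", spreadRanks = "list"))

setValidity("SpreadProfile", function(object) {
  msg <- character()
  n <- length(object@featureIds)
  if (anyDuplicated(object@featureIds)) msg <- c(msg, "duplicate feature ids")
  if (!all(names(object@spreadValues) %in% .MEASURES))
    msg <- c(msg, "unknown spread measure")
  if (!identical(names(object@spreadValues), names(object@spreadRanks)))
    msg <- c(msg, "spreadValues and spreadRanks must carry the same measures")
  for (nm in names(object@spreadValues)) {
    v <- object@spreadValues[[nm]]
    r <- object@spreadRanks[[nm]]
    if (length(v) != n || length(r) != n)
      msg <- c(msg, sprintf("measure '%s' length mismatch", nm))
    if (any(v < 0)) msg <- c(msg, sprintf("measure '%s' has negative values", nm))
    # average-tie ranks of 1..n preserve the total n(n+1)/2
    if (length(r) == n && abs(sum(r) - n * (n + 1) / 2) > 1e-8)
      msg <- c(msg, sprintf("ranks for '%s' are not a tie-averaged permutation", nm))
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: resampling consensus-clustering output
#'
#' Per-k consensus matrices (co-clustering proportion among co-sampled
#' repetitions), CDF areas A(k), relative delta-areas, the selected k, and
#' per-k sample assignments.
#'
#' @slot kRange integer vector of evaluated cluster numbers.
#' @slot consensusMatrices named list, one samples-by-samples matrix per k.
#' @slot coSampleCounts integer matrix of pairwise co-sampling counts.
#' @slot cdfArea named numeric, area under the consensus-value CDF per k.
#' @slot deltaArea named numeric, relative CDF-area increase per k.
#' @slot selectedK integer, `NA` until [selectK()] is applied.
#' @slot assignments named list, per-k integer cluster labels per sample.
#' @slot spec list echoing every resampling/clustering parameter and the seed.
#' @export
setClass("ConsensusResult", representation(
  kRange = "integer", consensusMatrices = "list", coSampleCounts = "matrix",
  cdfArea = "numeric", deltaArea = "numeric", selectedK = "integer",
  assignments = "list", spec = "list"))

#' SilhouetteReport: silhouette widths and core-sample retention
#'
#' @slot sampleIds character sample identifiers.
#' @slot clusterLabels integer cluster label per sample.
#' @slot widths numeric silhouette width per sample, in `[-1, 1]`
#'   (singleton clusters get 0 by convention).
#' @slot thresholds named numeric per-cluster retention thresholds (empty
#'   until [filterCoreSamples()] is applied).
#' @slot retained character ids of samples with width >= their cluster's
#'   threshold.
#' @slot removedCounts named integer removals per cluster.
#' @export
setClass("SilhouetteReport", representation(
  sampleIds = "character", clusterLabels = "integer", widths = "numeric",
  thresholds = "numeric", retained = "character", removedCounts = "integer"))

setValidity("SilhouetteReport", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (length(object@clusterLabels) != n || length(object@widths) != n)
    msg <- c(msg, "labels/widths length mismatch")
  if (any(object@widths < -1 - 1e-12 | object@widths > 1 + 1e-12))
    msg <- c(msg, "silhouette widths outside [-1, 1]")
  if (!all(object@retained %in% object@sampleIds))
    msg <- c(msg, "retained ids not a subset of sample ids")
  if (length(msg)) msg else TRUE
})

#' MembershipMatrix: binary sub-cluster by sample matrix for CrC
#'
#' Each row is an indicator for one sub-cluster of one platform; each column
#' is a sample. Within a platform the rows partition the samples, so every
#' column sums to the number of platforms.
#'
#' @slot membership 0/1 matrix, sub-clusters in rows, samples in columns.
#' @slot platformOfRow character platform name per row.
#' @export
setClass("MembershipMatrix", representation(
  membership = "matrix", platformOfRow = "character"))

setValidity("MembershipMatrix", function(object) {
  msg <- character()
  m <- object@membership
  if (!all(m %in% c(0, 1))) msg <- c(msg, "entries must be 0 or 1")
  if (length(object@platformOfRow) != nrow(m))
    msg <- c(msg, "platformOfRow length must equal row count")
  plats <- unique(object@platformOfRow)
  if (!all(colSums(m) == length(plats)))
    msg <- c(msg, "column sums must equal the number of platforms")
  for (p in plats) {
    rows <- m[object@platformOfRow == p, , drop = FALSE]
    if (nrow(rows) < 2L)
      msg <- c(msg, sprintf("platform '%s' contributes fewer than 2 sub-clusters", p))
    if (!all(colSums(rows) == 1))
      msg <- c(msg, sprintf("platform '%s' rows do not partition the samples", p))
  }
  if (length(msg)) msg else TRUE
})

#' ContingencyResult: chi-squared association between two clusterings
#'
#' @slot table integer cross-tabulation of the two labelings.
#' @slot chi2 Pearson chi-squared statistic (no continuity correction by
#'   default).
#' @slot df degrees of freedom, `(r-1)(c-1)`.
#' @slot p p-value from the chi-squared reference distribution.
#' @slot lowCount `TRUE` when any expected count is below 1 (test still
#'   reported, flagged as unreliable).
#' @export
setClass("ContingencyResult", representation(
  table = "matrix", chi2 = "numeric", df = "integer", p = "numeric",
  lowCount = "logical"))

#' SoCResult: gene-set significance-of-clusters bootstrap result
#'
#' @slot observedStat separation statistic (adjusted Rand index between the
#'   gene-set-driven partition and the known groups) of the tested set.
#' @slot nullStats statistic for each of B size-matched random gene sets.
#' @slot pValue add-one empirical p-value,
#'   `(1 + #{null >= observed}) / (B + 1)`.
#' @slot B number of random gene sets drawn.
#' @slot statisticName statistic identifier recorded in outputs.
#' @slot seed RNG seed used for the draws.
#' @export
setClass("SoCResult", representation(
  observedStat = "numeric", nullStats = "numeric", pValue = "numeric",
  B = "integer", statisticName = "character", seed = "integer"))

setValidity("SoCResult", function(object) {
  msg <- character()
  if (length(object@nullStats) != object@B)
    msg <- c(msg, "nullStats length must equal B")
  expected <- (1 + sum(object@nullStats >= object@observedStat)) /
    (object@B + 1)
  if (abs(object@pValue - expected) > 1e-12)
    msg <- c(msg, "pValue inconsistent with add-one definition")
  if (length(msg)) msg else TRUE
})

#' ProvenanceRecord: ordered ledger of workflow steps
#'
#' Each step stores the step name, the complete parameter map consumed by
#' that stage (including seeds), elapsed wall-clock seconds, content
#' fingerprints of inputs/outputs, and the tool version. Serializes to YAML
#' and back losslessly; elapsed times are excluded from equality comparisons.
#'
#' @slot steps list of step records, in execution order.
#' @export
setClass("ProvenanceRecord", representation(steps = "list"))

#' @return An empty `ProvenanceRecord`.
#' @rdname ProvenanceRecord-class
#' @export
ProvenanceRecord <- function() new("ProvenanceRecord", steps = list())
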