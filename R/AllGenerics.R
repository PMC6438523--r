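#' Accessors for FeatureMatrix
#'
#' `featureValues()` returns the numeric matrix, `featureIds()` and
#' `sampleIds()` the identifiers, `featureGroups()` the feature grouping (or
#' `NULL`), and `sampleAnnotations()` the sample tracks as a `data.frame`.
#'
#' @param x a [FeatureMatrix-class].
#' @return See per-accessor description.
#' @name FeatureMatrix-accessors
NULL

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("sampleAnnotations", function(x) standardGeneric("sampleAnnotations"))

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x)
  SummarizedExperiment::assay(x, "values"))
#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureIds", "FeatureMatrix", function(x) rownames(x))
#' @rdname FeatureMatrix-accessors
#' @export
setMethod("sampleIds", "FeatureMatrix", function(x) colnames(x))
#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureGroups", "FeatureMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("feature_group" %in% colnames(rd))
    stats::setNames(as.character(rd[["feature_group"]]), rownames(x))
  else NULL
})
#' @rdname FeatureMatrix-accessors
#' @export
setMethod("sampleAnnotations", "FeatureMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  as.data.frame(cd, stringsAsFactors = FALSE)
})

#' Convert ClusterParams to a named list (for the provenance ledger)
#'
#' @param params a [ClusterParams-class].
#' @return Named list with scaling, distance, linkage and axis.
#' @export
paramsAsList <- function(params) {
  stopifnot(is(params, "ClusterParams"))
  list(scaling = params@scaling, distance = params@distance,
       linkage = params@linkage, axis = params@axis)
}

#' Rebuild ClusterParams from its list serialization
#'
#' @param x named list as produced by [paramsAsList()].
#' @return A [ClusterParams-class].
#' @export
paramsFromList <- function(x)
  ClusterParams(scaling = x$scaling, distance = x$distance,
                linkage = x$linkage, axis = x$axis)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d features x %d samples\n",
              nrow(object), ncol(object)))
  fg <- featureGroups(object)
  if (!is.null(fg))
    cat(sprintf("  feature groups: %s\n",
                paste(unique(fg), collapse = ", ")))
  sa <- sampleAnnotations(object)
  if (ncol(sa))
    cat(sprintf("  sample tracks: %s\n", paste(names(sa), collapse = ", ")))
})

setMethod("show", "ClusterParams", function(object) {
  cat(sprintf("ClusterParams(scaling=%s, distance=%s, linkage=%s, axis=%s)\n",
              object@scaling, object@distance, object@linkage, object@axis))
})

setMethod("show", "SpreadProfile", function(object) {
  cat(sprintf("SpreadProfile: %d features; measures: %s\n",
              length(object@featureIds),
              paste(names(object@spreadValues), collapse = ", ")))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k in {%s}; %d samples\n",
              paste(object@kRange, collapse = ", "),
              nrow(object@coSampleCounts)))
  if (length(object@deltaArea))
    cat("  delta-area:",
        paste(sprintf("k=%s: %.3f", names(object@deltaArea),
                      object@deltaArea), collapse = "; "), "\n")
  if (!is.na(object@selectedK))
    cat(sprintf("  selected k = %d\n", object@selectedK))
})

setMethod("show", "SilhouetteReport", function(object) {
  cat(sprintf("SilhouetteReport: %d samples in %d clusters; mean width %.3f\n",
              length(object@sampleIds),
              length(unique(object@clusterLabels)), mean(object@widths)))
  if (length(object@retained))
    cat(sprintf("  retained %d / %d core samples\n",
                length(object@retained), length(object@sampleIds)))
})

setMethod("show", "MembershipMatrix", function(object) {
  cat(sprintf("MembershipMatrix: %d sub-clusters x %d samples (%d platforms)\n",
              nrow(object@membership), ncol(object@membership),
              length(unique(object@platformOfRow))))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult: chi2 = %.4f, df = %d, p = %.4g%s\n",
              object@chi2, object@df, object@p,
              if (object@lowCount) " (low expected counts)" else ""))
})

setMethod("show", "SoCResult", function(object) {
  cat(sprintf("SoCResult: %s = %.4f; p = %.4g (B = %d)\n",
              object@statisticName, object@observedStat, object@pValue,
              object@B))
})

setMethod("show", "ProvenanceRecord", function(object) {
  cat(sprintf("ProvenanceRecord: %d steps\n", length(object@steps)))
  for (s in object@steps)
    cat(sprintf("  - %s (%.3g s)\n", s$name,
                if (is.null(s$elapsed) || is.na(s$elapsed)) NA else s$elapsed))
})
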