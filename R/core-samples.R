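#' Silhouette widths of a clustering
#'
#' For each sample, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is
#' the mean distance to the other members of its own cluster and `b(i)` the
#' smallest mean distance to any other cluster; members of singleton
#' clusters get width 0 by convention. Widths are computed on the same
#' distance matrix used for the clustering being evaluated, so the pairing
#' can be recorded and replayed.
#'
#' @param d a [stats::dist] object over the samples.
#' @param labels cluster labels (named by sample id, or in the order of
#'   `d`'s labels); at least 2 clusters.
#' @return A [SilhouetteReport-class] with widths (no retention applied
#'   yet).
#' @export
silhouetteWidths <- function(d, labels) {
  ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- as.character(seq_len(attr(d, "Size")))
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), ids))
      stop("label names do not match distance labels")
    labels <- labels[ids]
  }
  if (length(labels) != attr(d, "Size"))
    stop("labels must cover all samples")
  intLabs <- as.integer(factor(labels, levels = unique(labels)))
  if (length(unique(intLabs)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(intLabs, d)
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(ids))
  storedLabs <- if (is.numeric(labels)) as.integer(labels) else intLabs
  new("SilhouetteReport", sampleIds = ids,
      clusterLabels = storedLabs, widths = as.numeric(widths),
      thresholds = numeric(), retained = character(),
      removedCounts = integer())
}

#' Filter core samples by per-cluster silhouette thresholds
#'
#' Samples with width strictly below their cluster's threshold are removed
#' (retained means `width >= threshold`, mirroring the convention that
#' samples with a silhouette width *less than* the cut are dropped). A
#' single unnamed threshold broadcasts to every cluster. With
#' `thresholds = "auto"`, each cluster's threshold is its mean width minus
#' one SD of the within-cluster widths.
#'
#' @param report a [SilhouetteReport-class] from [silhouetteWidths()].
#' @param thresholds named numeric (one per cluster label), a single
#'   numeric broadcast to all clusters, or `"auto"`.
#' @return The report with `thresholds`, `retained` and `removedCounts`
#'   filled in; a warning names any cluster that loses all its samples.
#' @export
filterCoreSamples <- function(report, thresholds) {
  stopifnot(is(report, "SilhouetteReport"))
  labs <- report@clusterLabels
  clusters <- sort(unique(labs))
  if (identical(thresholds, "auto")) {
    thresholds <- vapply(clusters, function(cl) {
      w <- report@widths[labs == cl]
      mean(w) - if (length(w) > 1L) sd(w) else 0
    }, numeric(1))
    names(thresholds) <- as.character(clusters)
  } else if (is.null(names(thresholds))) {
    stopifnot(length(thresholds) == 1L)
    thresholds <- stats::setNames(rep(thresholds, length(clusters)),
                                  as.character(clusters))
  } else if (!all(as.character(clusters) %in% names(thresholds))) {
    stop("thresholds missing for cluster(s): ",
         paste(setdiff(as.character(clusters), names(thresholds)),
               collapse = ", "))
  }
  thr <- thresholds[as.character(labs)]
  keep <- report@widths >= thr
  removed <- vapply(clusters, function(cl) sum(!keep[labs == cl]),
                    integer(1))
  names(removed) <- as.character(clusters)
  emptied <- clusters[vapply(clusters, function(cl) !any(keep[labs == cl]),
                             logical(1))]
  if (length(emptied))
    warning("cluster(s) lost all samples and are dropped downstream: ",
            paste(emptied, collapse = ", "))
  report@thresholds <- thresholds[as.character(clusters)]
  report@retained <- report@sampleIds[keep]
  report@removedCounts <- removed
  report
}
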