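#' Build the binary sub-cluster membership matrix for CrC
#'
#' Merges per-platform cluster assignments on shared samples into a binary
#' matrix with one indicator row per platform sub-cluster (rows named e.g.
#' `expr1`, `expr2`, `meth1`, ...). Within each platform the rows partition
#' the samples, so every column sums to the number of platforms.
#'
#' @param assignments named list mapping platform name to a vector of
#'   cluster labels named by sample id; 2 to `maxPlatforms` platforms with
#'   identical sample-id sets.
#' @param maxPlatforms validated platform cap (default 3).
#' @return A [MembershipMatrix-class]; row order is platform order, then
#'   cluster index.
#' @export
buildMembershipMatrix <- function(assignments, maxPlatforms = 3L) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  nPlat <- length(assignments)
  if (nPlat < 2L || nPlat > maxPlatforms)
    stop("between 2 and ", maxPlatforms, " platforms are supported")
  ids <- names(assignments[[1L]])
  if (is.null(ids)) stop("assignments must be named by sample id")
  for (p in names(assignments)) {
    pid <- names(assignments[[p]])
    if (!setequal(pid, ids)) {
      diffs <- c(setdiff(ids, pid), setdiff(pid, ids))
      stop("sample-id mismatch across platforms (platform '", p, "'): ",
           paste(utils::head(diffs, 10L), collapse = ", "))
    }
  }
  rows <- list()
  platOf <- character()
  for (p in names(assignments)) {
    labs <- assignments[[p]][ids]
    for (cl in seq_along(sort(unique(labs)))) {
      lev <- sort(unique(labs))[cl]
      rows[[paste0(p, cl)]] <- as.integer(labs == lev)
      platOf[paste0(p, cl)] <- p
    }
  }
  mm <- do.call(rbind, rows)
  colnames(mm) <- ids
  new("MembershipMatrix", membership = mm, platformOfRow = platOf)
}

#' Cluster samples on the binary membership matrix (CrC labels)
#'
#' Hierarchically clusters the samples of a [MembershipMatrix-class] using
#' the given distance/linkage (the standard choice is Euclidean distance
#' with `ward_d` linkage) and cuts the tree at k.
#'
#' @param mm a [MembershipMatrix-class].
#' @param params a [ClusterParams-class] (scaling is ignored for the binary
#'   matrix; distance and linkage are used).
#' @param k number of combined clusters.
#' @return Named integer CrC cluster labels.
#' @export
clusterMembership <- function(mm, params = ClusterParams(
                                distance = "euclidean",
                                linkage = "ward_d"), k = 2L) {
  stopifnot(is(mm, "MembershipMatrix"))
  n <- ncol(mm@membership)
  if (k < 2L || k > n) stop("k must be in [2, ", n, "]")
  d <- pairwiseDistance(mm@membership, params@distance, axis = "samples")
  cutTree(hierarchicalLinkage(d, params@linkage), k)
}

#' Consensus clustering of the membership matrix
#'
#' Runs the same resampling consensus machinery on the binary membership
#' matrix to estimate the number of combined clusters.
#'
#' @param mm a [MembershipMatrix-class].
#' @param ... passed to [runConsensus()] (kRange, reps, pItem, innerParams,
#'   seed, ...).
#' @return A [ConsensusResult-class].
#' @export
consensusMembership <- function(mm, ...) {
  stopifnot(is(mm, "MembershipMatrix"))
  runConsensus(mm@membership, ...)
}

#' Per-platform distribution summaries of combined clusters
#'
#' For each platform and each CrC cluster, a five-number summary of the
#' pooled core-feature values plus a direction call (`"increased"` /
#' `"decreased"`) relative to the platform's overall median — the reporting
#' convention behind statements like "cluster 1 has increased expression and
#' increased methylation".
#'
#' @param platformMatrices named list of [FeatureMatrix-class] (core
#'   features per platform) on the same samples.
#' @param crcLabels named integer CrC labels.
#' @return `data.frame` with platform, cluster, n_samples, the five-number
#'   summary and the direction call; clusters absent from a platform's
#'   samples are skipped with a warning.
#' @export
summarizeByPlatform <- function(platformMatrices, crcLabels) {
  stopifnot(is.list(platformMatrices), !is.null(names(crcLabels)))
  out <- list()
  for (p in names(platformMatrices)) {
    v <- featureValues(platformMatrices[[p]])
    common <- intersect(colnames(v), names(crcLabels))
    overall <- median(v[, common])
    for (cl in sort(unique(crcLabels))) {
      ids <- intersect(names(crcLabels)[crcLabels == cl], colnames(v))
      if (!length(ids)) {
        warning("platform '", p, "': CrC cluster ", cl,
                " has no samples; summary row omitted")
        next
      }
      x <- as.vector(v[, ids])
      q <- unname(quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
      out[[length(out) + 1L]] <- data.frame(
        platform = p, cluster = cl, n_samples = length(ids),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        direction = if (q[3] >= overall) "increased" else "decreased",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Chi-squared test of association between two clusterings
#'
#' Cross-tabulates two labelings of the same samples and applies Pearson's
#' chi-squared test without continuity correction (optionally with Yates'
#' correction for 2x2 tables). Results with any expected count below 1 are
#' flagged `lowCount` but still reported.
#'
#' @param labelsA,labelsB label vectors over the same samples (aligned by
#'   names when present).
#' @param correct apply Yates' continuity correction (default `FALSE`).
#' @return A [ContingencyResult-class].
#' @export
contingencyTest <- function(labelsA, labelsB, correct = FALSE) {
  if (!is.null(names(labelsA)) && !is.null(names(labelsB))) {
    if (!setequal(names(labelsA), names(labelsB)))
      stop("labelings cover different samples")
    labelsB <- labelsB[names(labelsA)]
  }
  stopifnot(length(labelsA) == length(labelsB))
  tab <- table(labelsA, labelsB)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new("ContingencyResult", table = unclass(tab)[, , drop = FALSE],
      chi2 = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
      p = unname(ht$p.value), lowCount = any(ht$expected < 1))
}
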