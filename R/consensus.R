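#' Resampling consensus clustering
#'
#' Estimates cluster stability by repeatedly subsampling items (samples) and
#' optionally features, clustering each sub-matrix hierarchically, and
#' tallying how often every pair of samples co-clusters among the
#' repetitions in which both were drawn. The consensus matrix at each k has
#' entries `#co-clustered / #co-sampled` (0/0 treated as 0). Defaults follow
#' the workflow's standard settings: 100 repetitions, 80% item resampling,
#' 100% feature resampling.
#'
#' @param m a [FeatureMatrix-class] or numeric matrix (features x samples).
#' @param kRange contiguous integer range of candidate cluster numbers
#'   (each >= 2).
#' @param reps number of resampling repetitions.
#' @param pItem fraction of samples drawn (without replacement) per
#'   repetition.
#' @param pFeature fraction of features drawn per repetition.
#' @param innerParams [ClusterParams-class] used for every inner clustering
#'   run (scaling is applied to each sub-matrix before distances).
#' @param seed integer RNG seed; identical seed and spec give bitwise
#'   identical results.
#' @return A [ConsensusResult-class] with consensus matrices, CDF areas,
#'   delta-areas and per-k assignments (from hierarchical clustering of
#'   `1 - M_k` with the inner linkage).
#' @export
runConsensus <- function(m, kRange = 2:6, reps = 100, pItem = 0.8,
                         pFeature = 1,
                         innerParams = ClusterParams(
                           scaling = "none",
                           distance = "one_minus_pearson",
                           linkage = "average"),
                         seed) {
  v <- .asValues(m)
  kRange <- as.integer(kRange)
  stopifnot(all(kRange >= 2L), reps >= 1, pItem > 0, pItem <= 1,
            pFeature > 0, pFeature <= 1)
  n <- ncol(v)
  p <- nrow(v)
  if (n < max(kRange) + 1L)
    stop("need at least max(kRange) + 1 samples")
  if (missing(seed)) stop("a seed is required for replicability")
  set.seed(as.integer(seed))

  nItem <- ceiling(pItem * n)
  nFeat <- ceiling(pFeature * p)
  conn <- lapply(kRange, function(k) matrix(0, n, n))
  names(conn) <- as.character(kRange)
  count <- matrix(0L, n, n, dimnames = list(colnames(v), colnames(v)))

  for (b in seq_len(reps)) {
    items <- sort(sample.int(n, nItem))
    feats <- if (nFeat < p) sort(sample.int(p, nFeat)) else seq_len(p)
    sub <- v[feats, items, drop = FALSE]
    sub <- scaleMatrix(sub, innerParams@scaling)
    d <- pairwiseDistance(sub, innerParams@distance, axis = "samples")
    tree <- hierarchicalLinkage(d, innerParams@linkage)
    count[items, items] <- count[items, items] + 1L
    for (ki in seq_along(kRange)) {
      labs <- cutree(tree, k = kRange[ki])
      for (cl in unique(labs)) {
        idx <- items[labs == cl]
        conn[[ki]][idx, idx] <- conn[[ki]][idx, idx] + 1
      }
    }
  }

  offDiag <- count
  diag(offDiag) <- 1L
  neverPaired <- rowSums(offDiag > 0) <= 1L
  if (any(neverPaired))
    warning("sample(s) never co-sampled with any other: ",
            paste(colnames(v)[neverPaired], collapse = ", "))

  mats <- lapply(conn, function(cm) {
    M <- ifelse(count > 0, cm / pmax(count, 1L), 0)
    dimnames(M) <- dimnames(count)
    M
  })
  assignments <- lapply(seq_along(kRange), function(ki) {
    tree <- hierarchicalLinkage(as.dist(1 - mats[[ki]]),
                                innerParams@linkage)
    cutTree(tree, kRange[ki])
  })
  names(assignments) <- names(mats)

  res <- new("ConsensusResult", kRange = kRange, consensusMatrices = mats,
             coSampleCounts = count, cdfArea = numeric(),
             deltaArea = numeric(), selectedK = NA_integer_,
             assignments = assignments,
             spec = list(kRange = kRange, reps = reps, pItem = pItem,
                         pFeature = pFeature,
                         innerParams = paramsAsList(innerParams),
                         seed = as.integer(seed)))
  cdfDelta(res)
}

#' CDF areas and delta-areas of consensus matrices
#'
#' For each k, `A(k)` is the area under the empirical CDF of the
#' upper-triangle consensus entries over `[0, 1]`. The relative delta-area
#' is `A(2)` at the smallest k and `(A(k) - A(k-1)) / A(k-1)` beyond; a
#' large delta-area at k means moving to k clusters makes co-clustering
#' substantially more dichotomous.
#'
#' @param result a [ConsensusResult-class].
#' @return The result with `cdfArea` and `deltaArea` populated.
#' @export
cdfDelta <- function(result) {
  stopifnot(is(result, "ConsensusResult"))
  areas <- vapply(result@consensusMatrices, function(M) {
    x <- M[upper.tri(M)]
    xs <- sort(unique(c(x, 1)))
    f <- stats::ecdf(x)
    pts <- xs[xs < 1]
    sum(diff(c(pts, 1)) * f(pts))
  }, numeric(1))
  k <- result@kRange
  delta <- numeric(length(k))
  names(delta) <- names(areas)
  delta[1L] <- areas[1L]
  if (length(k) > 1L)
    for (i in 2L:length(k))
      delta[i] <- if (areas[i - 1L] > 0)
        (areas[i] - areas[i - 1L]) / areas[i - 1L] else areas[i]
  result@cdfArea <- areas
  result@deltaArea <- delta
  result
}

#' Select the number of clusters from consensus delta-areas
#'
#' `"largest_delta_knee"` returns the largest k whose relative delta-area
#' exceeds `deltaThreshold` (falling back to the smallest k, with a warning,
#' when none does); `"user_fixed"` returns `userK`. The policy and outcome
#' are meant to be recorded in the provenance ledger.
#'
#' @param result a [ConsensusResult-class] with delta-areas computed.
#' @param policy `"largest_delta_knee"` or `"user_fixed"`.
#' @param deltaThreshold knee threshold on the relative delta-area.
#' @param userK fixed k for `"user_fixed"`.
#' @return The result with `selectedK` set.
#' @export
selectK <- function(result, policy = c("largest_delta_knee", "user_fixed"),
                    deltaThreshold = 0.1, userK = NA_integer_) {
  stopifnot(is(result, "ConsensusResult"))
  policy <- match.arg(policy)
  if (policy == "user_fixed") {
    stopifnot(!is.na(userK), userK %in% result@kRange)
    result@selectedK <- as.integer(userK)
    return(result)
  }
  if (!length(result@deltaArea)) result <- cdfDelta(result)
  hits <- result@kRange[result@deltaArea > deltaThreshold]
  if (!length(hits)) {
    warning("no delta-area exceeds ", deltaThreshold,
            "; falling back to k = ", min(result@kRange))
    result@selectedK <- min(result@kRange)
  } else {
    result@selectedK <- max(hits)
  }
  result
}

#' Consensus assignments at a given k
#'
#' @param result a [ConsensusResult-class].
#' @param k one of the evaluated k values (default: the selected k).
#' @return Named integer cluster labels.
#' @export
consensusAssignments <- function(result, k = result@selectedK) {
  stopifnot(is(result, "ConsensusResult"), !is.na(k))
  labs <- result@assignments[[as.character(k)]]
  if (is.null(labs)) stop("k = ", k, " was not evaluated")
  labs
}
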