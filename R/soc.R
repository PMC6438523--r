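#' Separation statistic of a gene set for labelled sample groups
#'
#' Clusters the samples hierarchically using only the gene-set rows, cuts
#' the tree at g = number of groups, and scores agreement between the
#' resulting partition and the known group labels by the adjusted Rand
#' index (ARI): 1 means the gene set reproduces the groups exactly, values
#' near 0 mean chance-level agreement. The ARI is label-permutation
#' invariant and extends naturally beyond two groups.
#'
#' @param m a [FeatureMatrix-class] or numeric matrix (genome-wide).
#' @param geneSet character vector of feature ids (subset of `m`'s rows).
#' @param groupLabels known group per sample (named by sample id, or in
#'   column order).
#' @param params [ClusterParams-class] for the gene-set clustering.
#' @return Numeric ARI in `[-1, 1]`.
#' @export
separationStatistic <- function(m, geneSet, groupLabels,
                                params = ClusterParams(
                                  distance = "one_minus_pearson",
                                  linkage = "ward_d")) {
  v <- .asValues(m)
  missing <- setdiff(geneSet, rownames(v))
  if (length(missing))
    stop("gene set features absent from the matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  if (!is.null(names(groupLabels))) {
    stopifnot(setequal(names(groupLabels), colnames(v)))
    groupLabels <- groupLabels[colnames(v)]
  }
  g <- length(unique(groupLabels))
  if (g < 2L) stop("need at least 2 groups")
  labs <- .clusterSamples(v[geneSet, , drop = FALSE], params, g)
  mclust::adjustedRandIndex(labs, as.character(groupLabels))
}

#' Significance of a gene set versus size-matched random gene sets
#'
#' Empirical test of whether a gene set separates samples into known groups
#' better than chance: B random feature sets of the same size are drawn
#' (without replacement within each draw) from the genome-wide matrix, the
#' separation statistic computed for each, and the add-one p-value
#' `(1 + #{null >= observed}) / (B + 1)` reported, so p is never 0 and is
#' bounded below by `1/(B+1)`.
#'
#' @param m genome-wide [FeatureMatrix-class] or numeric matrix.
#' @param geneSet tested feature ids; must be a strict subset of the
#'   features.
#' @param groupLabels known group per sample.
#' @param B number of random gene sets (default 1000).
#' @param params [ClusterParams-class] shared by the observed and null
#'   clusterings.
#' @param seed integer RNG seed.
#' @param excludeObserved drop the tested set's own genes from the null
#'   sampling pool (default `FALSE`: random sets are unrestricted draws).
#' @return A [SoCResult-class].
#' @export
socBootstrap <- function(m, geneSet, groupLabels, B = 1000,
                         params = ClusterParams(
                           distance = "one_minus_pearson",
                           linkage = "ward_d"),
                         seed, excludeObserved = FALSE) {
  v <- .asValues(m)
  stopifnot(B >= 1)
  if (length(geneSet) >= nrow(v))
    stop("gene set must be smaller than the genome-wide feature count")
  if (missing(seed)) stop("a seed is required for replicability")
  observed <- separationStatistic(v, geneSet, groupLabels, params)
  pool <- rownames(v)
  if (excludeObserved) pool <- setdiff(pool, geneSet)
  if (length(pool) < length(geneSet))
    stop("null pool smaller than the gene-set size")
  set.seed(as.integer(seed))
  nullStats <- vapply(seq_len(B), function(b) {
    draw <- sample(pool, length(geneSet), replace = FALSE)
    separationStatistic(v, draw, groupLabels, params)
  }, numeric(1))
  p <- (1 + sum(nullStats >= observed)) / (B + 1)
  new("SoCResult", observedStat = observed, nullStats = nullStats,
      pValue = p, B = as.integer(B),
      statisticName = "adjusted_rand_index", seed = as.integer(seed))
}
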