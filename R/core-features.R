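#' Per-feature measures of spread and ranks
#'
#' Computes, for every feature (row), any of the three spread measures used
#' to define a most variable ("core") gene set: VAR, the sample variance
#' (n - 1 denominator); MAD, the median absolute deviation about the median
#' scaled by 1.4826; and IQR, Q3 - Q1 under linear-interpolation (type 7)
#' quantiles. Ascending ranks (rank 1 = smallest spread, ties averaged) are
#' attached for the integrated sum-of-ranks selector.
#'
#' @param m a [FeatureMatrix-class] or numeric matrix with at least 2
#'   samples (columns).
#' @param measures subset of `c("VAR", "MAD", "IQR")`.
#' @return A [SpreadProfile-class].
#' @examples
#' v <- matrix(rnorm(50), 10, 5,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
#' computeSpread(FeatureMatrix(v))
#' @export
computeSpread <- function(m, measures = c("VAR", "MAD", "IQR")) {
  v <- if (is(m, "FeatureMatrix")) featureValues(m) else as.matrix(m)
  measures <- match.arg(measures, .MEASURES, several.ok = TRUE)
  if (ncol(v) < 2L) stop("spread requires at least 2 samples")
  fun <- list(
    VAR = function(x) var(x),
    MAD = function(x) mad(x),  # constant 1.4826
    IQR = function(x) unname(diff(quantile(x, c(0.25, 0.75), type = 7))))
  vals <- lapply(measures, function(ms) apply(v, 1L, fun[[ms]]))
  names(vals) <- measures
  rks <- lapply(vals, rank, ties.method = "average")
  new("SpreadProfile", featureIds = rownames(v), spreadValues = vals,
      spreadRanks = rks)
}

.percentileCut <- function(values, ids, percentile, rule) {
  cutoff <- unname(quantile(values, percentile / 100, type = 7))
  keep <- if (rule == "strictly_above") values > cutoff else values >= cutoff
  sel <- ids[keep]
  if (!length(sel))
    warning("selection at percentile ", percentile, " is empty")
  sel
}

#' Select core features by a percentile of one spread measure
#'
#' Returns the features whose spread exceeds (or equals, under
#' `"at_or_above"`) the given percentile of that measure's distribution
#' across all features — e.g. genes with an IQR above the 99th percentile.
#' The cutoff uses linear-interpolation (type 7) quantiles.
#'
#' @param p a [SpreadProfile-class].
#' @param measure one of the measures present in `p`.
#' @param percentile percentile in (0, 100); 0 and 100 are allowed edges.
#' @param rule `"strictly_above"` (default) or `"at_or_above"`.
#' @return Character vector of selected feature ids (possibly empty, with a
#'   warning).
#' @export
selectByPercentile <- function(p, measure, percentile = 99,
                               rule = c("strictly_above", "at_or_above")) {
  stopifnot(is(p, "SpreadProfile"))
  rule <- match.arg(rule)
  if (!measure %in% names(p@spreadValues))
    stop("measure '", measure, "' not present in the profile")
  .percentileCut(p@spreadValues[[measure]], p@featureIds, percentile, rule)
}

#' Integrated most-variable selection by summed spread ranks
#'
#' For sparse data a single spread measure is unstable, so features are
#' ranked under each of two (or more) measures, the ranks summed, and the
#' percentile rule applied to the rank-sum distribution. Larger rank sums
#' mean more variable under the joint criterion.
#'
#' @param p a [SpreadProfile-class].
#' @param measures at least two measures present in `p` (e.g.
#'   `c("IQR", "MAD")`).
#' @param percentile,rule as in [selectByPercentile()].
#' @return Character vector of selected feature ids.
#' @export
integratedRankSelect <- function(p, measures = c("IQR", "MAD"),
                                 percentile = 99,
                                 rule = c("strictly_above", "at_or_above")) {
  stopifnot(is(p, "SpreadProfile"))
  rule <- match.arg(rule)
  if (length(measures) < 2L)
    stop("integrated selection needs >= 2 measures; ",
         "use selectByPercentile() for a single measure")
  missing <- setdiff(measures, names(p@spreadRanks))
  if (length(missing))
    stop("measures not present: ", paste(missing, collapse = ", "))
  rankSum <- Reduce(`+`, p@spreadRanks[measures])
  .percentileCut(rankSum, p@featureIds, percentile, rule)
}
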