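## Shared scaling / distance / linkage / cut primitives. Linkage and the
## standard metrics go through stats::hclust and stats::dist; Canberra is
## computed in-package because the convention here is sum(|x-y|/(|x|+|y|))
## with 0/0 terms contributing 0, which stats::dist does not implement.

.asValues <- function(m) {
  if (is(m, "FeatureMatrix")) featureValues(m) else as.matrix(m)
}

#' Z-score scaling of a feature-by-sample matrix
#'
#' `row_z` centres and scales each feature to mean 0 and sample SD 1;
#' `col_z` does the same per sample; `row_then_col_z` applies row scaling
#' first, then column scaling (the order is fixed and recorded so heatmaps
#' are replicable). Zero-spread vectors map to all zeros with a warning.
#'
#' @param m a [FeatureMatrix-class] or numeric matrix.
#' @param scaling one of `"none"`, `"row_z"`, `"col_z"`,
#'   `"row_then_col_z"`.
#' @return Object of the same class as `m` with scaled values.
#' @export
scaleMatrix <- function(m, scaling = c("none", "row_z", "col_z",
                                       "row_then_col_z")) {
  scaling <- match.arg(scaling)
  v <- .asValues(m)
  zRows <- function(x) {
    mu <- rowMeans(x)
    s <- apply(x, 1L, sd)
    flat <- s == 0
    if (any(flat)) {
      warning("zero-spread vector(s) scaled to all zeros: ",
              paste(utils::head(rownames(x)[flat], 5L), collapse = ", "))
      s[flat] <- 1
    }
    out <- (x - mu) / s
    out[flat, ] <- 0
    out
  }
  out <- switch(scaling,
                none = v,
                row_z = zRows(v),
                col_z = t(zRows(t(v))),
                row_then_col_z = t(zRows(t(zRows(v)))))
  if (is(m, "FeatureMatrix")) {
    sa <- sampleAnnotations(m)
    FeatureMatrix(out, featureGroups = featureGroups(m),
                  sampleAnnotations = if (ncol(sa)) sa else NULL,
                  metadata = S4Vectors::metadata(m))
  } else out
}

.canberraDist <- function(x) {
  # rows of x are items; 0/0 terms contribute 0, no rescaling
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    xi <- x[i, ]
    for (j in (i + 1L):n) {
      num <- abs(xi - x[j, ])
      den <- abs(xi) + abs(x[j, ])
      term <- ifelse(den == 0, 0, num / den)
      d[i, j] <- d[j, i] <- sum(term)
    }
  }
  as.dist(d)
}

#' Pairwise distances between samples or features
#'
#' Correlation distances are `1 - r` (Pearson or Spearman, range `[0, 2]`);
#' `euclidean` and `manhattan` are standard; `canberra` is
#' `sum(|x - y| / (|x| + |y|))` with 0/0 terms contributing 0 (suited to
#' sparse data).
#'
#' @param m a [FeatureMatrix-class] or numeric matrix (features x samples).
#' @param distance one of `"one_minus_pearson"`, `"euclidean"`,
#'   `"canberra"`, `"manhattan"`, `"one_minus_spearman"`.
#' @param axis `"samples"` (default) or `"features"`.
#' @return A [stats::dist] object labelled with the item ids.
#' @export
pairwiseDistance <- function(m, distance = c("one_minus_pearson",
                                             "euclidean", "canberra",
                                             "manhattan",
                                             "one_minus_spearman"),
                             axis = c("samples", "features")) {
  distance <- match.arg(distance)
  axis <- match.arg(axis)
  v <- .asValues(m)
  items <- if (axis == "samples") t(v) else v  # items in rows
  if (nrow(items) < 2L) stop("need at least 2 items on axis '", axis, "'")
  if (distance %in% c("one_minus_pearson", "one_minus_spearman")) {
    if (ncol(items) < 2L)
      stop("correlation distance requires >= 2 coordinates per item")
    s <- apply(items, 1L, sd)
    if (any(s == 0))
      stop("zero-spread item(s) under correlation distance: ",
           paste(utils::head(rownames(items)[s == 0], 5L), collapse = ", "))
    method <- if (distance == "one_minus_pearson") "pearson" else "spearman"
    as.dist(1 - cor(t(items), method = method))
  } else if (distance == "canberra") {
    .canberraDist(items)
  } else {
    dist(items, method = distance)
  }
}

.HCLUST_METHOD <- c(ward_d = "ward.D", average = "average",
                    complete = "complete", single = "single",
                    mcquitty = "mcquitty")

#' Agglomerative hierarchical clustering
#'
#' `ward_d` applies the Ward Lance-Williams update to the supplied,
#' unsquared distances (hclust's `"ward.D"`, as distinct from `"ward.D2"`);
#' `mcquitty` is WPGMA. Agglomeration order is deterministic for a fixed
#' input, so results are replicable across runs and platforms.
#'
#' @param d a [stats::dist] object (e.g. from [pairwiseDistance()]).
#' @param linkage one of `"ward_d"`, `"average"`, `"complete"`, `"single"`,
#'   `"mcquitty"`.
#' @return An [stats::hclust] tree.
#' @export
hierarchicalLinkage <- function(d, linkage = c("ward_d", "average",
                                               "complete", "single",
                                               "mcquitty")) {
  linkage <- match.arg(linkage)
  if (attr(d, "Size") < 2L) stop("need at least 2 items to cluster")
  hclust(d, method = .HCLUST_METHOD[[linkage]])
}

#' Cut a dendrogram into k clusters with canonical label numbering
#'
#' Labels are renumbered by order of first appearance along the tree's leaf
#' order, so cluster 1 is always the leftmost cluster in the dendrogram and
#' labels are stable across runs.
#'
#' @param tree an [stats::hclust] object.
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster labels (1..k).
#' @export
cutTree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  labs <- cutree(tree, k = k)
  canon <- match(labs, unique(labs[tree$order]))
  stats::setNames(as.integer(canon), names(labs))
}

## Convenience: scaled matrix -> distance -> tree -> k labels, per params.
.clusterSamples <- function(v, params, k) {
  v <- scaleMatrix(v, params@scaling)
  d <- pairwiseDistance(v, params@distance, axis = "samples")
  tree <- hierarchicalLinkage(d, params@linkage)
  cutTree(tree, k)
}
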