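#' Render a clustered heatmap with annotation tracks and a replicability
#' sidecar
#'
#' Scales the matrix per `scaling`, computes row/column dendrograms with the
#' package's own distance/linkage primitives, and draws the heatmap (via
#' pheatmap) with sample-annotation colour bars. Alongside the image, a
#' sidecar text file records the exact row and column leaf orders and a YAML
#' parameter file records every setting, so the figure can be reproduced
#' from the sidecar alone. Annotation tracks obey the workflow caps (10
#' levels per sample track, 6 per feature track), and group colours are
#' assigned from a fixed, documented palette so repeated renders are
#' identical.
#'
#' @param m a [FeatureMatrix-class].
#' @param rowParams,colParams [ClusterParams-class] for the feature and
#'   sample dendrograms (their shared `scaling` is taken from `colParams`).
#' @param clusterRows,clusterCols draw dendrograms on each axis; when
#'   `FALSE`, the leaf order is the input order.
#' @param file optional image path (`.png` or `.pdf`); when `NULL` nothing
#'   is drawn and only orders are computed.
#' @param colorBounds optional length-2 numeric clipping bounds for the
#'   colour scale.
#' @return Invisibly, a list with `rowOrder`, `colOrder` (leaf-order id
#'   vectors), `params`, and the written `files`.
#' @export
renderHeatmap <- function(m, rowParams = ClusterParams(axis = "features"),
                          colParams = ClusterParams(
                            scaling = "row_then_col_z",
                            distance = "one_minus_pearson",
                            linkage = "ward_d"),
                          clusterRows = TRUE, clusterCols = TRUE,
                          file = NULL, colorBounds = NULL) {
  stopifnot(is(m, "FeatureMatrix"))
  if (!is.null(colorBounds)) stopifnot(length(colorBounds) == 2L,
                                       all(is.finite(colorBounds)))
  scaled <- scaleMatrix(m, colParams@scaling)
  v <- featureValues(scaled)

  rowTree <- colTree <- NULL
  rowOrder <- rownames(v)
  colOrder <- colnames(v)
  if (clusterRows && nrow(v) > 1L) {
    rowTree <- hierarchicalLinkage(
      pairwiseDistance(v, rowParams@distance, axis = "features"),
      rowParams@linkage)
    rowOrder <- rownames(v)[rowTree$order]
  }
  if (clusterCols && ncol(v) > 1L) {
    colTree <- hierarchicalLinkage(
      pairwiseDistance(v, colParams@distance, axis = "samples"),
      colParams@linkage)
    colOrder <- colnames(v)[colTree$order]
  }

  params <- list(scaling = colParams@scaling,
                 row = paramsAsList(rowParams),
                 col = paramsAsList(colParams),
                 clusterRows = clusterRows, clusterCols = clusterCols,
                 colorBounds = colorBounds)
  files <- character()
  if (!is.null(file)) {
    sa <- sampleAnnotations(m)
    annCol <- if (ncol(sa)) sa else NA
    annColors <- NA
    if (ncol(sa)) {
      # fixed palette: level i of every track always gets palette colour i
      pal <- c("#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E",
               "#E6AB02", "#A6761D", "#666666", "#1F78B4", "#B2DF8A")
      annColors <- lapply(sa, function(tr) {
        lev <- sort(unique(as.character(tr)))
        stats::setNames(pal[seq_along(lev)], lev)
      })
    }
    vPlot <- v
    if (!is.null(colorBounds))
      vPlot <- pmin(pmax(vPlot, colorBounds[1L]), colorBounds[2L])
    pheatmap::pheatmap(
      vPlot,
      cluster_rows = if (clusterRows && !is.null(rowTree)) rowTree else FALSE,
      cluster_cols = if (clusterCols && !is.null(colTree)) colTree else FALSE,
      annotation_col = annCol, annotation_colors = annColors,
      filename = file, silent = TRUE)
    orderFile <- paste0(file, ".order.txt")
    paramFile <- paste0(file, ".params.yaml")
    utils::write.table(
      data.frame(axis = c(rep("row", length(rowOrder)),
                          rep("col", length(colOrder))),
                 position = c(seq_along(rowOrder), seq_along(colOrder)),
                 id = c(rowOrder, colOrder)),
      orderFile, sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(params, paramFile)
    files <- c(image = file, orders = orderFile, params = paramFile)
  }
  invisible(list(rowOrder = rowOrder, colOrder = colOrder,
                 params = params, files = files))
}
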