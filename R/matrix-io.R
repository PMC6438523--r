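## Delimited-text layout convention:
##   row 1                      sample-id header
##   rows 2..dataStartRow-1     sample-annotation tracks (name in column 1)
##   column 1                   feature ids
##   columns 2..dataStartCol-1  feature-annotation tracks (name in row 1)
##   block [dataStartRow.., dataStartCol..]  numeric values

.delimChar <- function(delimiter) {
  switch(match.arg(delimiter, c("tab", "comma")), tab = "\t", comma = ",")
}

#' Read an annotated feature-by-sample matrix from delimited text
#'
#' Parses the layout convention in which row 1 holds sample ids, rows up to
#' `dataStartRow - 1` hold categorical sample-annotation tracks, column 1
#' holds feature ids and columns up to `dataStartCol - 1` hold categorical
#' feature tracks (the first is the feature grouping). A file with sample
#' tracks ER/PR/HER2 plus a gene-group column therefore has its numeric data
#' starting at row 5, column 3.
#'
#' @param path file to read.
#' @param dataStartRow 1-based row where numeric data starts (>= 2).
#' @param dataStartCol 1-based column where numeric data starts (>= 2).
#' @param delimiter `"tab"` or `"comma"`.
#' @param onMalformed `"drop"` rejects every feature row containing a
#'   non-numeric or missing cell, with a warning naming the file row and
#'   column of each offending cell; `"error"` stops at the first one.
#' @return A [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path, dataStartRow = 2L, dataStartCol = 2L,
                              delimiter = c("tab", "comma"),
                              onMalformed = c("drop", "error")) {
  onMalformed <- match.arg(onMalformed)
  sep <- .delimChar(delimiter)
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(dataStartRow >= 2L, dataStartCol >= 2L)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fill = FALSE)
  raw <- as.matrix(raw)
  if (dataStartRow > nrow(raw) || dataStartCol > ncol(raw))
    stop("layout indices exceed file dimensions (",
         nrow(raw), " x ", ncol(raw), ")")

  sampleIds <- as.character(raw[1L, dataStartCol:ncol(raw)])
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids in header")

  trackRows <- seq_len(dataStartRow - 1L)[-1L]
  annot <- NULL
  if (length(trackRows)) {
    annot <- lapply(trackRows, function(r)
      as.character(raw[r, dataStartCol:ncol(raw)]))
    names(annot) <- make.unique(as.character(raw[trackRows, 1L]))
    annot <- as.data.frame(annot, stringsAsFactors = FALSE,
                           check.names = FALSE)
  }

  dataRows <- dataStartRow:nrow(raw)
  fids <- as.character(raw[dataRows, 1L])
  if (anyDuplicated(fids))
    stop("duplicate feature ids: ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))

  groups <- NULL
  if (dataStartCol > 2L) {
    # first feature-annotation column is the canonical feature grouping
    groups <- as.character(raw[dataRows, 2L])
    if (dataStartCol > 3L)
      warning("only the first feature-annotation column is retained")
  }

  block <- raw[dataRows, dataStartCol:ncol(raw), drop = FALSE]
  suppressWarnings(num <- matrix(as.numeric(block), nrow = nrow(block)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    badDesc <- sprintf("row %d, column %d ('%s')",
                       dataRows[bad[, 1L]],
                       (dataStartCol:ncol(raw))[bad[, 2L]],
                       block[bad])
    if (onMalformed == "error")
      stop("malformed numeric cell at file ", badDesc[1L])
    keep <- setdiff(seq_len(nrow(num)), unique(bad[, 1L]))
    warning(sprintf("rejected %d feature row(s) with malformed cells: %s",
                    length(unique(bad[, 1L])),
                    paste(utils::head(badDesc, 10L), collapse = "; ")))
    num <- num[keep, , drop = FALSE]
    fids <- fids[keep]
    if (!is.null(groups)) groups <- groups[keep]
  }
  dimnames(num) <- list(fids, sampleIds)
  FeatureMatrix(num, featureGroups = groups, sampleAnnotations = annot)
}

#' Write a FeatureMatrix in the annotated delimited-text layout
#'
#' The emitted layout is implied by the object's annotations:
#' `dataStartRow = 2 + #sample tracks`, `dataStartCol = 2` (or 3 when a
#' feature grouping is present). The file round-trips through
#' [readFeatureMatrix()] into an equal object.
#'
#' @param m a [FeatureMatrix-class].
#' @param path output file.
#' @param delimiter `"tab"` or `"comma"`.
#' @return Invisibly, the layout list (`dataStartRow`, `dataStartCol`,
#'   `delimiter`).
#' @export
writeFeatureMatrix <- function(m, path, delimiter = c("tab", "comma")) {
  stopifnot(is(m, "FeatureMatrix"))
  delimiter <- match.arg(delimiter)
  sep <- .delimChar(delimiter)
  v <- featureValues(m)
  sa <- sampleAnnotations(m)
  fg <- featureGroups(m)
  hasGroups <- !is.null(fg)

  idCols <- if (hasGroups) 2L else 1L
  header <- c("feature_id", if (hasGroups) "feature_group",
              colnames(v))
  lines <- paste(header, collapse = sep)
  for (nm in names(sa))
    lines <- c(lines, paste(c(nm, if (hasGroups) "", as.character(sa[[nm]])),
                            collapse = sep))
  body <- cbind(rownames(v), if (hasGroups) fg,
                format(v, trim = TRUE, digits = 17))
  lines <- c(lines, apply(body, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(list(dataStartRow = 2L + ncol(sa),
                 dataStartCol = idCols + 1L, delimiter = delimiter))
}

#' Elementwise value transforms for ingested matrices
#'
#' `log2_count` applies `log2(x + 1)` (expression counts); `beta_to_m`
#' converts methylation beta values via `log2((1 + beta) / (1 - beta))`;
#' `shift_nonneg` adds the absolute value of the global minimum to every
#' entry so the minimum becomes 0 (copy-number segment means), recording the
#' applied offset in the object's metadata.
#'
#' @param m a [FeatureMatrix-class].
#' @param kind `"log2_count"`, `"beta_to_m"` or `"shift_nonneg"`.
#' @return A transformed [FeatureMatrix-class]; shape, ids and annotations
#'   unchanged.
#' @export
transformValues <- function(m, kind = c("log2_count", "beta_to_m",
                                        "shift_nonneg")) {
  stopifnot(is(m, "FeatureMatrix"))
  kind <- match.arg(kind)
  v <- featureValues(m)
  offset <- NA_real_
  .offender <- function(bad) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    sprintf("feature '%s', sample '%s'", rownames(v)[ij[1L]],
            colnames(v)[ij[2L]])
  }
  if (kind == "log2_count") {
    if (any(v < 0))
      stop("log2_count requires nonnegative values; first offender: ",
           .offender(v < 0))
    out <- log2(v + 1)
  } else if (kind == "beta_to_m") {
    if (any(v < 0 | v >= 1))
      stop("beta_to_m requires values in [0, 1); first offender: ",
           .offender(v < 0 | v >= 1))
    out <- log2((1 + v) / (1 - v))
  } else {
    # shift so the global minimum maps to 0 (adds |min| when min < 0)
    offset <- -min(v)
    out <- v + offset
  }
  md <- S4Vectors::metadata(m)
  md$transform <- list(kind = kind, offset = offset)
  FeatureMatrix(out, featureGroups = featureGroups(m),
                sampleAnnotations = {
                  sa <- sampleAnnotations(m)
                  if (ncol(sa)) sa else NULL
                },
                metadata = md)
}
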