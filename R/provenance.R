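#' Append a step to a provenance ledger
#'
#' Each step records the step name, the complete parameter map the stage
#' consumed (including seeds), elapsed wall-clock seconds, content
#' fingerprints of its inputs/outputs and the package version — the minimum
#' documentation required to replicate the step exactly. Elapsed times are
#' informational and excluded from ledger equality.
#'
#' @param record a [ProvenanceRecord-class].
#' @param name non-empty step name.
#' @param params named list of every parameter the step consumed.
#' @param elapsed elapsed seconds (`NA` when not timed).
#' @param fingerprints named list of content hashes (see
#'   [fingerprintObject()]).
#' @return The updated record.
#' @export
recordStep <- function(record, name, params = list(), elapsed = NA_real_,
                       fingerprints = list()) {
  stopifnot(is(record, "ProvenanceRecord"), nzchar(name))
  record@steps[[length(record@steps) + 1L]] <- list(
    name = name, params = params, elapsed = as.numeric(elapsed),
    fingerprints = fingerprints,
    version = as.character(utils::packageVersion("coreclust")))
  record
}

#' Content fingerprint of an R object
#'
#' Stable hash of an object's serialized content, used to tie ledger steps
#' to their exact inputs and outputs.
#'
#' @param x any R object.
#' @return Character hash.
#' @export
fingerprintObject <- function(x) {
  if (is(x, "FeatureMatrix")) x <- featureValues(x)
  rlang::hash(x)
}

#' Serialize / read a provenance ledger (YAML)
#'
#' @param record a [ProvenanceRecord-class].
#' @param path output (input) file.
#' @return `writeProvenance` invisibly returns `path`; `readProvenance`
#'   returns the reconstructed [ProvenanceRecord-class].
#' @export
writeProvenance <- function(record, path) {
  stopifnot(is(record, "ProvenanceRecord"))
  yaml::write_yaml(list(steps = record@steps), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname writeProvenance
#' @export
readProvenance <- function(path) {
  x <- yaml::read_yaml(path)
  rec <- ProvenanceRecord()
  rec@steps <- lapply(x$steps, function(s) {
    s$elapsed <- as.numeric(s$elapsed %||% NA_real_)
    s
  })
  rec
}

#' Compare two ledgers ignoring elapsed times
#'
#' @param a,b [ProvenanceRecord-class] objects.
#' @return `TRUE` when step names, parameters and fingerprints all match.
#' @export
provenanceEquivalent <- function(a, b) {
  strip <- function(r) lapply(r@steps, function(s) {
    s$elapsed <- NULL
    s
  })
  isTRUE(all.equal(strip(a), strip(b), tolerance = 0))
}

#' Extract a named parameter map across ledger steps
#'
#' @param record a [ProvenanceRecord-class].
#' @return Named list mapping step name to its parameter map.
#' @export
provenanceParams <- function(record) {
  stopifnot(is(record, "ProvenanceRecord"))
  stats::setNames(lapply(record@steps, `[[`, "params"),
                  vapply(record@steps, `[[`, "", "name"))
}

#' Human-readable workflow summary
#'
#' Renders the ledger as a step-ordered plain-text report (parameters,
#' elapsed seconds and total time); when `path` is given, the text goes to
#' `path` and a machine-readable YAML twin to `paste0(path, ".yaml")`.
#'
#' @param record a non-empty [ProvenanceRecord-class].
#' @param path optional output file.
#' @return Character vector of report lines, invisibly when written.
#' @export
renderWorkflowSummary <- function(record, path = NULL) {
  stopifnot(is(record, "ProvenanceRecord"), length(record@steps) > 0)
  fmtVal <- function(v) {
    if (is.list(v)) paste0("{", paste(names(v), unlist(v), sep = "=",
                                      collapse = ", "), "}")
    else paste(v, collapse = ",")
  }
  lines <- character()
  total <- 0
  for (i in seq_along(record@steps)) {
    s <- record@steps[[i]]
    lines <- c(lines, sprintf("Step %d: %s", i, s$name))
    for (nm in names(s$params))
      lines <- c(lines, sprintf("  %s: %s", nm, fmtVal(s$params[[nm]])))
    el <- s$elapsed
    if (!is.na(el)) {
      lines <- c(lines, sprintf("  elapsed: %.3f s", el))
      total <- total + el
    }
  }
  lines <- c(lines, sprintf("Total elapsed: %.3f s", total))
  if (!is.null(path)) {
    writeLines(lines, path)
    writeProvenance(record, paste0(path, ".yaml"))
    return(invisible(lines))
  }
  lines
}
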