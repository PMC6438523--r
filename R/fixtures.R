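## Internal: generate a planted matrix for a given label vector, using the
## current RNG state (callers handle seeding).
.plantValues <- function(labels, nFeatures, informativeFraction, effect,
                         noiseSd, sparsity) {
  nSamples <- length(labels)
  k <- length(unique(labels))
  nInfo <- round(informativeFraction * nFeatures)
  v <- matrix(rnorm(nFeatures * nSamples, sd = noiseSd),
              nFeatures, nSamples)
  if (nInfo > 0 && effect > 0 && k > 1L) {
    levelMeans <- effect * noiseSd * (seq_len(k) - 1)
    for (f in seq_len(nInfo))
      v[f, ] <- v[f, ] + sample(levelMeans)[labels]
  }
  if (sparsity > 0)
    v[sample.int(length(v), round(sparsity * length(v)))] <- 0
  rownames(v) <- sprintf("g%04d", seq_len(nFeatures))
  colnames(v) <- sprintf("s%03d", seq_len(nSamples))
  v
}

#' Planted-cluster synthetic feature matrix
#'
#' Generates a Gaussian feature-by-sample matrix with k planted sample
#' clusters: a fraction of "informative" features carry cluster-specific
#' means separated by `effect` within-cluster SD units (each informative
#' feature assigns the k mean levels to the clusters in its own random
#' order, so no two clusters are distinguished by exactly the same feature
#' pattern); the remaining features are pure noise. Optional zero-inflation
#' (`sparsity`) emulates the sparseness of variant-type data. Fully
#' deterministic given `seed`. Defaults are the package's reference study
#' conditions: 100 features, 60 samples, 2 clusters, 20% informative
#' features, a 4-SD effect.
#'
#' @param nFeatures,nSamples matrix dimensions.
#' @param k number of planted sample clusters (balanced sizes).
#' @param informativeFraction fraction of features carrying signal.
#' @param effect between-cluster mean separation, in units of `noiseSd`.
#' @param noiseSd within-cluster standard deviation.
#' @param sparsity fraction of entries set to exact zero.
#' @param seed integer RNG seed.
#' @return List with `matrix` (a [FeatureMatrix-class] whose `truth` sample
#'   track holds the planted labels), `labels` (named integer truth) and
#'   `informative` (character ids of signal-carrying features).
#' @export
makePlantedMatrix <- function(nFeatures = 100, nSamples = 60, k = 2,
                              informativeFraction = 0.2, effect = 4,
                              noiseSd = 1, sparsity = 0, seed) {
  stopifnot(k <= nSamples, informativeFraction >= 0,
            informativeFraction <= 1, sparsity >= 0, sparsity <= 1,
            effect >= 0)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  labels <- rep(seq_len(k), length.out = nSamples)
  v <- .plantValues(labels, nFeatures, informativeFraction, effect,
                    noiseSd, sparsity)
  labels <- stats::setNames(as.integer(labels), colnames(v))
  fm <- FeatureMatrix(v, sampleAnnotations = data.frame(
    truth = as.character(labels), row.names = colnames(v)))
  list(matrix = fm, labels = labels,
       informative = rownames(v)[seq_len(round(informativeFraction *
                                                 nFeatures))])
}

#' Multi-platform synthetic data with a shared truth partition
#'
#' Generates one planted matrix per platform on the same samples. All
#' platforms share one truth partition; each platform's own cluster
#' structure agrees with it per its `concordance` (the probability a sample
#' keeps its truth cluster on that platform; discordant samples are
#' reassigned uniformly among the other clusters) and the platform's matrix
#' is planted around those platform labels.
#'
#' @param platformSpecs named list of argument lists for
#'   [makePlantedMatrix()] (`nFeatures`, `informativeFraction`, `effect`,
#'   `noiseSd`, `sparsity`); all platforms share `nSamples` and `k`.
#' @param concordance named numeric in `[0, 1]`, one entry per platform.
#' @param nSamples,k shared sample count and truth cluster count.
#' @param seed integer RNG seed.
#' @return List with `platforms` (named [FeatureMatrix-class] list),
#'   `truth` (shared labels) and `platformLabels` (per-platform planted
#'   labels).
#' @export
makeMultiomic <- function(platformSpecs, concordance, nSamples = 60, k = 2,
                          seed) {
  stopifnot(is.list(platformSpecs), !is.null(names(platformSpecs)),
            all(names(platformSpecs) %in% names(concordance)))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  truth <- rep(seq_len(k), length.out = nSamples)
  platforms <- list()
  platformLabels <- list()
  for (p in names(platformSpecs)) {
    labs <- truth
    flip <- stats::runif(nSamples) > concordance[[p]]
    if (any(flip) && k > 1L)
      labs[flip] <- vapply(truth[flip], function(cl)
        sample(setdiff(seq_len(k), cl), 1L), integer(1))
    spec <- platformSpecs[[p]]
    v <- .plantValues(
      labs,
      nFeatures = spec$nFeatures %||% 100,
      informativeFraction = spec$informativeFraction %||% 0.2,
      effect = spec$effect %||% 4,
      noiseSd = spec$noiseSd %||% 1,
      sparsity = spec$sparsity %||% 0)
    labsNamed <- stats::setNames(as.integer(labs), colnames(v))
    platforms[[p]] <- FeatureMatrix(
      v, sampleAnnotations = data.frame(
        truth = as.character(labsNamed), row.names = colnames(v)))
    platformLabels[[p]] <- labsNamed
  }
  list(platforms = platforms,
       truth = stats::setNames(as.integer(truth),
                               sprintf("s%03d", seq_len(nSamples))),
       platformLabels = platformLabels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
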