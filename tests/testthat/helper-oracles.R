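# Independent brute-force oracles, written from first principles so they
# share no code path with the package implementations they check.

# linear-interpolation quantile between order statistics
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracleVar <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

oracleMedian <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
}

oracleMad <- function(x) 1.4826 * oracleMedian(abs(x - oracleMedian(x)))

oracleIQR <- function(x) oracleQuantile(x, 0.75) - oracleQuantile(x, 0.25)

# sort-and-threshold selection reference
oracleSelect <- function(values, ids, percentile, rule) {
  cut <- oracleQuantile(values, percentile / 100)
  if (rule == "strictly_above") ids[values > cut] else ids[values >= cut]
}

# double-loop silhouette widths on a full distance matrix
oracleSilhouette <- function(D, labels) {
  n <- nrow(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      out[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, which(labels == cl)]))
    out[i] <- (b - a) / max(a, b)
  }
  out
}

# pair-counting adjusted Rand index
oracleARI <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(0)
  (s11 - expected) / (maxidx - expected)
}

# closed-form 2x2 Pearson chi-squared
oracleChi2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# naive agglomerative clustering with average linkage: repeatedly merge the
# closest pair of clusters, recomputing inter-cluster means from the
# original distances
oracleAverageLinkageHeights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestD <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < bestD) {
          bestD <- dd
          best <- c(i, j)
        }
      }
    heights <- c(heights, bestD)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

randomFeatureMatrix <- function(nf, ns, seed) {
  set.seed(seed)
  v <- matrix(rnorm(nf * ns), nf, ns,
              dimnames = list(sprintf("f%03d", seq_len(nf)),
                              sprintf("s%03d", seq_len(ns))))
  FeatureMatrix(v)
}
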