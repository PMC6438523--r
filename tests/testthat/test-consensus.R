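innerAvg <- ClusterParams(scaling = "none",
                          distance = "one_minus_pearson",
                          linkage = "average")

test_that("a single full-sample repetition gives the 0/1 co-membership matrix", {
  fx <- makePlantedMatrix(nFeatures = 40, nSamples = 12, k = 2,
                          effect = 5, seed = 2)
  res <- runConsensus(fx$matrix, kRange = 2:3, reps = 1, pItem = 1,
                      innerParams = innerAvg, seed = 2)
  labs <- cutTree(hierarchicalLinkage(
    pairwiseDistance(fx$matrix, "one_minus_pearson"), "average"), 2)
  want <- outer(labs, labs, `==`) * 1
  expect_equal(res@consensusMatrices[["2"]], want, ignore_attr = TRUE)
})

test_that("consensus with full item resampling is exactly 0/1 for any reps", {
  fx <- makePlantedMatrix(nFeatures = 30, nSamples = 10, k = 2,
                          effect = 4, seed = 9)
  res <- runConsensus(fx$matrix, kRange = 2:3, reps = 7, pItem = 1,
                      innerParams = innerAvg, seed = 9)
  for (M in res@consensusMatrices)
    expect_true(all(M %in% c(0, 1)))
})

test_that("consensus matrices are symmetric with entries in [0,1]", {
  m <- randomFeatureMatrix(25, 14, seed = 6)
  res <- suppressWarnings(
    runConsensus(m, kRange = 2:4, reps = 20, innerParams = innerAvg,
                 seed = 6))
  for (M in res@consensusMatrices) {
    expect_equal(M, t(M), tolerance = 0)
    expect_true(all(M >= 0 & M <= 1))
    expect_true(all(diag(M) == 1))  # every sample drawn at least once here
  }
})

test_that("well-separated blobs give within-consensus 1 and cross-consensus 0", {
  fx <- makePlantedMatrix(nFeatures = 60, nSamples = 20, k = 2,
                          effect = 8, seed = 3)
  res <- runConsensus(fx$matrix, kRange = 2:3, reps = 50,
                      innerParams = innerAvg, seed = 3)
  M <- res@consensusMatrices[["2"]]
  same <- outer(fx$labels, fx$labels, `==`)
  offdiag <- !diag(TRUE, nrow(M))
  expect_true(all(M[same & offdiag] == 1))
  expect_true(all(M[!same] == 0))
})

test_that("identical seed and spec reproduce bitwise-identical results", {
  m <- randomFeatureMatrix(30, 12, seed = 8)
  a <- runConsensus(m, kRange = 2:4, reps = 25, innerParams = innerAvg,
                    seed = 123)
  b <- runConsensus(m, kRange = 2:4, reps = 25, innerParams = innerAvg,
                    seed = 123)
  expect_identical(a@consensusMatrices, b@consensusMatrices)
  expect_identical(a@assignments, b@assignments)
})

test_that("CDF areas follow the empirical-CDF definition", {
  mk <- function(entries) {
    n <- 4
    M <- diag(1, n)
    M[upper.tri(M)] <- entries
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    dimnames(M) <- list(paste0("s", 1:n), paste0("s", 1:n))
    M
  }
  shell <- new("ConsensusResult", kRange = 2:3,
               consensusMatrices = list(
                 "2" = mk(c(0, 0, 1, 0, 1, 1)),   # half the entries zero
                 "3" = mk(rep(1, 6))),            # every pair always together
               coSampleCounts = matrix(1L, 4, 4), cdfArea = numeric(),
               deltaArea = numeric(), selectedK = NA_integer_,
               assignments = list(), spec = list())
  out <- cdfDelta(shell)
  expect_equal(unname(out@cdfArea[["2"]]), 0.5)
  expect_equal(unname(out@cdfArea[["3"]]), 0)

  # delta-area: A(2) = 0.5, A(3) = 0.6 -> relative increase 0.2
  shell@consensusMatrices <- list("2" = mk(c(0, 0, 0, 1, 1, 0.9)),
                                  "3" = mk(c(0, 0, 0, 0, 1, 0.4)))
  out2 <- cdfDelta(shell)
  expect_equal(unname(out2@deltaArea[["3"]]),
               (out2@cdfArea[["3"]] - out2@cdfArea[["2"]]) /
                 out2@cdfArea[["2"]], tolerance = 1e-12)
})

test_that("k selection applies the knee threshold and the user override", {
  shell <- new("ConsensusResult", kRange = 2:4,
               consensusMatrices = list(), coSampleCounts = matrix(0L, 1, 1),
               cdfArea = c("2" = 0.5, "3" = 0.51, "4" = 0.515),
               deltaArea = c("2" = 0.55, "3" = 0.02, "4" = 0.01),
               selectedK = NA_integer_, assignments = list(),
               spec = list())
  expect_identical(selectK(shell)@selectedK, 2L)
  expect_identical(selectK(shell, policy = "user_fixed",
                           userK = 3)@selectedK, 3L)
  shell@deltaArea <- c("2" = 0.05, "3" = 0.02, "4" = 0.01)
  expect_warning(low <- selectK(shell), "falling back")
  expect_identical(low@selectedK, 2L)
})

test_that("planted k is recovered and degrades monotonically with separation", {
  seeds <- 1:6
  recovery <- function(effect) {
    mean(vapply(seeds, function(s) {
      fx <- makePlantedMatrix(nFeatures = 100, nSamples = 60, k = 3,
                              effect = effect, seed = s)
      res <- suppressWarnings(
        runConsensus(fx$matrix, kRange = 2:5, reps = 40,
                     innerParams = innerAvg, seed = s))
      suppressWarnings(selectK(res))@selectedK == 3L
    }, logical(1)))
  }
  r_strong <- recovery(6)
  r_mid <- recovery(1.5)
  r_none <- recovery(0)
  expect_equal(r_strong, 1)
  expect_true(r_strong >= r_mid)
  expect_true(r_mid >= r_none)
})
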