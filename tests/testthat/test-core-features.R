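test_that("spread measures match their defining formulas", {
  v <- rbind(c(3, 3, 3, 3, 3), 1:5, c(2, 8, 4, 16, 1))
  dimnames(v) <- list(c("const", "lin", "mix"), paste0("s", 1:5))
  p <- computeSpread(FeatureMatrix(v))
  expect_equal(unname(p@spreadValues$VAR[1]), 0)
  expect_equal(unname(p@spreadValues$MAD[1]), 0)
  expect_equal(unname(p@spreadValues$IQR[1]), 0)
  # [1..5]: Q1 = 2, Q3 = 4 under linear interpolation; MAD = 1 * 1.4826
  expect_equal(unname(p@spreadValues$IQR[2]), 2)
  expect_equal(unname(p@spreadValues$MAD[2]), 1.4826)
  expect_equal(unname(p@spreadValues$VAR[2]), 2.5)
  expect_error(computeSpread(matrix(1, 3, 1)), "at least 2 samples")
})

test_that("spread and percentile selection match the brute-force reference", {
  for (seed in 1:10) {
    m <- randomFeatureMatrix(sample(10:50, 1), sample(4:9, 1), seed)
    v <- featureValues(m)
    p <- computeSpread(m)
    expect_equal(unname(p@spreadValues$VAR), unname(apply(v, 1, oracleVar)),
                 tolerance = 1e-12)
    expect_equal(unname(p@spreadValues$MAD), unname(apply(v, 1, oracleMad)),
                 tolerance = 1e-12)
    expect_equal(unname(p@spreadValues$IQR), unname(apply(v, 1, oracleIQR)),
                 tolerance = 1e-12)
    for (pc in c(10, 50, 90, 99)) for (rule in c("strictly_above",
                                                 "at_or_above")) {
      got <- selectByPercentile(p, "IQR", pc, rule)
      want <- oracleSelect(unname(p@spreadValues$IQR), featureIds(m),
                           pc, rule)
      expect_identical(got, want)
    }
  }
})

test_that("percentile selection edge cases behave as specified", {
  set.seed(42)
  vals <- sample(seq(1, 400, by = 2), 200)  # distinct spreads
  v <- t(vapply(vals, function(s) c(-s, 0, s), numeric(3)))
  dimnames(v) <- list(paste0("f", 1:200), c("a", "b", "c"))
  p <- computeSpread(FeatureMatrix(v), "IQR")
  sel <- selectByPercentile(p, "IQR", 95, "strictly_above")
  top10 <- featureIds(FeatureMatrix(v))[order(-p@spreadValues$IQR)][1:10]
  expect_setequal(sel, top10)

  const <- FeatureMatrix(matrix(rep(1:3, each = 5), 5, 3, byrow = FALSE,
                                dimnames = list(paste0("g", 1:5),
                                                c("a", "b", "c"))))
  pc <- computeSpread(const, "IQR")
  expect_warning(empty <- selectByPercentile(pc, "IQR", 99,
                                             "strictly_above"), "empty")
  expect_length(empty, 0)
  expect_identical(sort(selectByPercentile(pc, "IQR", 0, "at_or_above")),
                   sort(featureIds(const)))
})

test_that("integrated rank selection sums ranks then applies the cut", {
  # IQR ranks [5,4,3,2,1], MAD ranks [3,5,4,1,2] -> sums [8,9,7,3,3]
  p <- new("SpreadProfile", featureIds = paste0("f", 1:5),
           spreadValues = list(IQR = c(50, 40, 30, 20, 10),
                               MAD = c(3, 5, 4, 1, 2)),
           spreadRanks = list(IQR = c(5, 4, 3, 2, 1),
                              MAD = c(3, 5, 4, 1, 2)))
  sel <- integratedRankSelect(p, c("IQR", "MAD"), 50, "strictly_above")
  expect_setequal(sel, c("f1", "f2"))  # rank sums above the median of 7
  expect_error(integratedRankSelect(p, "IQR"), "selectByPercentile")
})

test_that("agreeing measures make integrated selection equal single-measure selection", {
  m <- randomFeatureMatrix(40, 6, seed = 3)
  p <- computeSpread(m)
  # force MAD to induce the identical ranking as IQR
  p@spreadValues$MAD <- p@spreadValues$IQR * 2
  p@spreadRanks$MAD <- p@spreadRanks$IQR
  expect_identical(
    integratedRankSelect(p, c("IQR", "MAD"), 80),
    selectByPercentile(p, "IQR", 80))
})

test_that("fully tied features select nothing under strictly_above", {
  p <- new("SpreadProfile", featureIds = paste0("f", 1:4),
           spreadValues = list(IQR = rep(2, 4), MAD = rep(1, 4)),
           spreadRanks = list(IQR = rep(2.5, 4), MAD = rep(2.5, 4)))
  expect_warning(sel <- integratedRankSelect(p, c("IQR", "MAD"), 50),
                 "empty")
  expect_length(sel, 0)
})

test_that("rank-based selection is invariant to strictly increasing transforms", {
  m <- randomFeatureMatrix(30, 5, seed = 9)
  p <- computeSpread(m, c("IQR", "MAD"))
  q <- p
  q@spreadValues$IQR <- exp(p@spreadValues$IQR)   # monotone transform
  q@spreadValues$MAD <- p@spreadValues$MAD^3 + 1
  expect_identical(integratedRankSelect(p, c("IQR", "MAD"), 70),
                   integratedRankSelect(q, c("IQR", "MAD"), 70))
})
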