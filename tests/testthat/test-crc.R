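test_that("membership matrix matches the worked two-platform example", {
  asg <- list(E = c(s1 = 1, s2 = 1, s3 = 2),
              M = c(s1 = 1, s2 = 2, s3 = 2))
  mm <- buildMembershipMatrix(asg)
  expect_identical(rownames(mm@membership), c("E1", "E2", "M1", "M2"))
  expect_equal(mm@membership["E1", ], c(s1 = 1, s2 = 1, s3 = 0))
  expect_equal(mm@membership["E2", ], c(s1 = 0, s2 = 0, s3 = 1))
  expect_equal(mm@membership["M1", ], c(s1 = 1, s2 = 0, s3 = 0))
  expect_equal(mm@membership["M2", ], c(s1 = 0, s2 = 1, s3 = 1))
  expect_true(all(colSums(mm@membership) == 2))
})

test_that("sample-id mismatches and the platform cap are rejected", {
  good <- c(s1 = 1, s2 = 2)
  expect_error(buildMembershipMatrix(list(A = good, B = c(s1 = 1, sX = 2))),
               "mismatch.*sX|sX.*mismatch")
  four <- list(A = good, B = good, C = good, D = good)
  expect_error(buildMembershipMatrix(four), "between 2 and 3")
  expect_s4_class(buildMembershipMatrix(four, maxPlatforms = 4L),
                  "MembershipMatrix")
  expect_error(buildMembershipMatrix(list(A = good)), "between 2 and 3")
})

test_that("column sums equal the platform count on random partitions", {
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(6:15, 1)
    ids <- paste0("s", seq_len(n))
    mkLabs <- function() {
      repeat {
        l <- sample(1:3, n, replace = TRUE)
        if (length(unique(l)) >= 2) return(stats::setNames(l, ids))
      }
    }
    nPlat <- sample(2:3, 1)
    asg <- stats::setNames(replicate(nPlat, mkLabs(), simplify = FALSE),
                           LETTERS[seq_len(nPlat)])
    mm <- buildMembershipMatrix(asg)
    expect_true(all(colSums(mm@membership) == nPlat))
  }
})

test_that("fully agreeing platforms are recovered exactly by CrC", {
  ids <- paste0("s", 1:10)
  split <- stats::setNames(rep(1:2, each = 5), ids)
  mm <- buildMembershipMatrix(list(expr = split, meth = split, cnv = split))
  labs <- clusterMembership(mm, k = 2)
  expect_equal(oracleARI(labs[ids], split), 1)
  expect_identical(length(unique(clusterMembership(mm, k = 10))), 10L)
})

test_that("a single dissenting platform is outvoted under ward linkage", {
  ids <- paste0("s", 1:8)
  truth <- stats::setNames(rep(1:2, each = 4), ids)
  dissent <- truth
  dissent["s4"] <- 2  # one platform moves one sample across
  mm <- buildMembershipMatrix(list(A = truth, B = truth, C = dissent))
  labs <- clusterMembership(mm, ClusterParams(distance = "euclidean",
                                              linkage = "ward_d"), k = 2)
  expect_equal(oracleARI(labs[ids], truth), 1)
})

test_that("contingency tests match the closed form and flag low counts", {
  a <- rep(1:2, each = 10)
  res <- contingencyTest(a, a)
  expect_equal(res@chi2, 20, tolerance = 1e-12)
  expect_identical(res@df, 1L)

  ind <- contingencyTest(rep(1:2, each = 10), rep(1:2, times = 10))
  expect_equal(ind@chi2, 0)
  expect_equal(ind@p, 1)

  threeByTwo <- contingencyTest(rep(1:3, each = 4), rep(1:2, times = 6))
  expect_identical(threeByTwo@df, 2L)

  set.seed(7)
  for (trial in 1:20) {
    x <- sample(1:2, 30, replace = TRUE)
    y <- sample(1:2, 30, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- contingencyTest(x, y)
    expect_equal(res@chi2, oracleChi2x2(res@table), tolerance = 1e-10)
  }

  low <- contingencyTest(c(rep(1, 19), 2), c(rep(1, 19), 2))
  expect_true(low@lowCount)
})

test_that("chi-squared p-values are approximately uniform under independence", {
  set.seed(2024)
  ps <- vapply(1:500, function(i) {
    x <- sample(1:2, 200, replace = TRUE)
    y <- sample(1:2, 200, replace = TRUE)
    contingencyTest(x, y)@p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("platform summaries expose planted median shifts and direction calls", {
  ids <- paste0("s", 1:20)
  labs <- stats::setNames(rep(1:2, each = 10), ids)
  set.seed(5)
  v <- matrix(rnorm(30 * 20, sd = 0.1), 30, 20,
              dimnames = list(paste0("g", 1:30), ids))
  v[, labs == 1] <- v[, labs == 1] + 2
  mats <- list(expr = FeatureMatrix(v))
  sm <- summarizeByPlatform(mats, labs)
  expect_equal(sm$median[sm$cluster == 1] - sm$median[sm$cluster == 2], 2,
               tolerance = 0.1)
  expect_identical(sm$direction, c("increased", "decreased"))
  expect_warning(
    summarizeByPlatform(mats, stats::setNames(c(rep(1, 19), 3), ids)[1:19]),
    NA)
})

test_that("empty CrC clusters are skipped with a warning", {
  ids <- paste0("s", 1:4)
  v <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), ids))
  labs <- stats::setNames(c(1, 1, 2, 2), c("s1", "s2", "x1", "x2"))
  expect_warning(summarizeByPlatform(list(p = FeatureMatrix(v)), labs),
                 "no samples")
})
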