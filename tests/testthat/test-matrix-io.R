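test_that("annotated layout with sample tracks and a gene-group column reads back", {
  f <- withr::local_tempfile(fileext = ".txt")
  lines <- c(
    "feature_id\tgroup\ts1\ts2\ts3",
    "ER\t\tpos\tneg\tpos",
    "PR\t\tpos\tpos\tneg",
    "HER2\t\tneg\tneg\tpos",
    "geneA\tgrp1\t1.5\t2.5\t3.5",
    "geneB\tgrp2\t0\t-1\t4")
  writeLines(lines, f)
  m <- readFeatureMatrix(f, dataStartRow = 5, dataStartCol = 3)
  expect_s4_class(m, "FeatureMatrix")
  expect_identical(featureIds(m), c("geneA", "geneB"))
  expect_identical(sampleIds(m), c("s1", "s2", "s3"))
  expect_identical(names(sampleAnnotations(m)), c("ER", "PR", "HER2"))
  expect_identical(unname(featureGroups(m)), c("grp1", "grp2"))
  expect_equal(featureValues(m)["geneB", ], c(s1 = 0, s2 = -1, s3 = 4))
})

test_that("minimal layout (header only) yields no annotation tracks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id\ta\tb", "g1\t1\t2", "g2\t3\t4"), f)
  m <- readFeatureMatrix(f, dataStartRow = 2, dataStartCol = 2)
  expect_identical(ncol(sampleAnnotations(m)), 0L)
  expect_null(featureGroups(m))
})

test_that("write/read round trip preserves values, ids and annotations", {
  for (seed in 1:5) {
    set.seed(seed)
    nf <- sample(3:8, 1)
    ns <- sample(3:6, 1)
    v <- matrix(round(rnorm(nf * ns), 6), nf, ns,
                dimnames = list(paste0("g", seq_len(nf)),
                                paste0("s", seq_len(ns))))
    ann <- if (seed %% 2) data.frame(grp = sample(c("x", "y"), ns, TRUE),
                                     row.names = colnames(v))
    fg <- if (seed > 2) sample(c("a", "b"), nf, TRUE)
    m <- FeatureMatrix(v, featureGroups = fg, sampleAnnotations = ann)
    f <- withr::local_tempfile(fileext = ".txt")
    layout <- writeFeatureMatrix(m, f)
    m2 <- readFeatureMatrix(f, layout$dataStartRow, layout$dataStartCol)
    expect_equal(featureValues(m2), featureValues(m))
    expect_identical(featureGroups(m2), featureGroups(m))
    expect_identical(sampleAnnotations(m2), sampleAnnotations(m))
  }
})

test_that("layout implied by annotations counts header plus tracks", {
  v <- matrix(1:8, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  m <- FeatureMatrix(v, sampleAnnotations = data.frame(
    t1 = c("x", "y"), t2 = c("p", "q"), row.names = c("a", "b")))
  f <- withr::local_tempfile(fileext = ".txt")
  layout <- writeFeatureMatrix(m, f)
  expect_identical(layout$dataStartRow, 4L)  # header + 2 tracks + data
  expect_identical(layout$dataStartCol, 2L)
})

test_that("malformed numeric cells are rejected with a located report", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id\ta\tb", "g1\t1\tok?", "g2\t3\t4"), f)
  expect_warning(m <- readFeatureMatrix(f), "row 2, column 3")
  expect_identical(featureIds(m), "g2")
  expect_error(readFeatureMatrix(f, onMalformed = "error"), "malformed")
})

test_that("duplicate ids and annotation level caps are enforced", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id\ta\tb", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(readFeatureMatrix(f), "duplicate feature ids")
  v <- matrix(rnorm(22), 2, 11,
              dimnames = list(c("g1", "g2"), paste0("s", 1:11)))
  expect_error(
    FeatureMatrix(v, sampleAnnotations = data.frame(
      grp = paste0("lvl", 1:11), row.names = colnames(v))),
    "max 10")
  v2 <- matrix(rnorm(14), 7, 2,
               dimnames = list(paste0("g", 1:7), c("a", "b")))
  expect_error(FeatureMatrix(v2, featureGroups = paste0("grp", 1:7)),
               "max 6")
})

test_that("value transforms match their closed forms", {
  v <- matrix(c(0, 1, 3, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  m <- FeatureMatrix(v)
  expect_equal(featureValues(transformValues(m, "log2_count"))[1, 1], 0)
  expect_equal(featureValues(transformValues(m, "log2_count"))[2, 2], 3)

  beta <- FeatureMatrix(matrix(c(0, 0.5, 0.25, 0.9), 2, 2,
                               dimnames = dimnames(v)))
  mv <- featureValues(transformValues(beta, "beta_to_m"))
  expect_equal(mv[1, 1], 0)
  expect_equal(mv[2, 1], log2(3), tolerance = 1e-12)

  sh <- FeatureMatrix(matrix(c(-2, 0, 1, -1), 2, 2,
                             dimnames = dimnames(v)))
  out <- featureValues(transformValues(sh, "shift_nonneg"))
  expect_equal(min(out), 0)
  expect_equal(as.vector(out), c(0, 2, 3, 1))
})

test_that("transform domain violations name the offending cell", {
  m <- FeatureMatrix(matrix(c(-1, 2, 3, 4), 2, 2,
                            dimnames = list(c("gA", "gB"), c("s1", "s2"))))
  expect_error(transformValues(m, "log2_count"), "gA.*s1")
  expect_error(transformValues(m, "beta_to_m"), "offender")
})

test_that("beta_to_m is strictly increasing on [0,1) and preserves shape", {
  x <- seq(0, 0.99, length.out = 25)
  m <- FeatureMatrix(matrix(x, 5, 5,
                            dimnames = list(paste0("g", 1:5),
                                            paste0("s", 1:5))))
  out <- transformValues(m, "beta_to_m")
  expect_identical(dim(featureValues(out)), dim(featureValues(m)))
  expect_identical(featureIds(out), featureIds(m))
  expect_true(all(diff(sort(as.vector(featureValues(out)))) > 0))
})
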