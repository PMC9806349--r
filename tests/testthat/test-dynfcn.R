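# Sliding-window dynamic FC construction and lower-triangle vectorization.

test_that("window enumeration matches exhaustive search over random settings", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      M <- sample(5:60, 1)
      w <- sample(2:M, 1)
      s <- sample(1:8, 1)
      got <- enumerateWindows(M, slidingWindowConfig(w, s))
      expect_identical(got, oracleWindows(M, w, s))
      expect_length(got, floor((M - w) / s) + 1)
    }
  })
  # the standard protocol: 137 volumes, w = 30, s = 2 -> 54 windows
  offs <- enumerateWindows(137, slidingWindowConfig(30, 2))
  expect_length(offs, 54)
  expect_identical(offs[1], 0L)
  expect_identical(offs[54], 106L)
  # degenerate single full-length window
  expect_identical(enumerateWindows(30, slidingWindowConfig(30, 2)), 0L)
  # trailing remainder dropped
  expect_identical(enumerateWindows(10, slidingWindowConfig(3, 3)),
                   c(0L, 3L, 6L))
  expect_error(enumerateWindows(10, slidingWindowConfig(11, 1)),
               class = "siamfcn_config_error")
})

test_that("short-term FC is the windowed Pearson correlation", {
  # identical sub-series correlate at 1, negated at -1
  x <- RoiTimeSeries(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(-1, -2, -3, -4)))
  C <- shortTermFC(x, 0, 4)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(diag(C), setNames(rep(1, 3), roiLabels(x)))
  # hand-checkable 3-point window: cor((1,2,3), (1,3,2)) = 0.5
  y <- RoiTimeSeries(rbind(c(1, 2, 3), c(1, 3, 2)))
  expect_equal(shortTermFC(y, 0, 3)[2, 1], 0.5)
  expect_equal(shortTermFC(y, 0, 3)[2, 1], oraclePearson(c(1, 2, 3), c(1, 3, 2)))
})

test_that("zero-variance windows give neutral FC 0 with a warning", {
  x <- RoiTimeSeries(rbind(c(5, 5, 5, 1), c(1, 2, 3, 4), c(4, 3, 2, 1)))
  expect_warning(C <- shortTermFC(x, 0, 3), "zero-variance")
  expect_equal(C[1, 2], 0)
  expect_equal(C[1, 3], 0)
  expect_equal(C[2, 3], -1)
  expect_equal(diag(C), setNames(rep(1, 3), roiLabels(x)))
})

test_that("dynamic FCN equals the brute-force per-window loop", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      N <- sample(2:6, 1)
      M <- sample(6:20, 1)
      w <- sample(3:min(8, M), 1)
      s <- sample(1:3, 1)
      x <- randomScan(N, M)
      d <- buildDynamicFCN(x, slidingWindowConfig(w, s))
      expect_equal(d@tensor, oracleDynFCN(x@values, w, s), tolerance = 1e-12)
    }
  })
})

test_that("dynamic FCN has the protocol shape and bounded symmetric slices", {
  x <- randomScan(5, 137)
  d <- buildDynamicFCN(x, slidingWindowConfig(30, 2))
  expect_identical(dim(d@tensor), c(54L, 5L, 5L))
  expect_true(all(abs(d@tensor) <= 1))
  for (k in c(1, 27, 54)) {
    expect_equal(d@tensor[k, , ], t(d@tensor[k, , ]))
    expect_equal(diag(d@tensor[k, , ]), rep(1, 5))
  }
})

test_that("stationary signals give nearly constant FC across windows", {
  withr::with_seed(3, {
    shared <- rnorm(400)
    x <- RoiTimeSeries(rbind(shared + 0.01 * rnorm(400),
                             shared + 0.01 * rnorm(400),
                             rnorm(400)))
  })
  d <- buildDynamicFCN(x, slidingWindowConfig(200, 100))
  f <- vectorizeLowerTriangle(d)
  # the strongly coupled pair is essentially constant; the noise pairs
  # fluctuate only within correlation sampling error (~2/sqrt(w))
  expect_lt(diff(range(fcSeries(f)[1, ])), 0.01)
  expect_lt(max(apply(fcSeries(f), 1, function(r) diff(range(r)))), 0.2)
})

test_that("lower-triangle vectorization is lossless and ordered by rows", {
  withr::with_seed(5, {
    x <- randomScan(4, 12)
    d <- buildDynamicFCN(x, slidingWindowConfig(5, 3))
    f <- vectorizeLowerTriangle(d)
    expect_identical(dim(fcSeries(f)), c(6L, 3L))
    # documented pair order: (2,1), (3,1), (3,2), (4,1), (4,2), (4,3)
    expect_identical(pairIndex(f),
                     cbind(i = c(2L, 3L, 3L, 4L, 4L, 4L),
                           j = c(1L, 1L, 2L, 1L, 2L, 3L)))
    # row p of the series is the FC series of pair p
    for (p in 1:6) {
      expect_equal(fcSeries(f)[p, ],
                   d@tensor[, pairIndex(f)[p, 1], pairIndex(f)[p, 2]])
    }
    # round trip through reconstruction is the identity
    for (k in 1:3) {
      expect_equal(unname(reconstructSlice(f, k)), d@tensor[k, , ])
    }
  })
})

test_that("pair count is N(N-1)/2, including the full-atlas case", {
  tens <- array(0, dim = c(1, 116, 116))
  for (k in 1) {
    m <- diag(1, 116)
    tens[k, , ] <- m
  }
  d <- new("DynamicFCN", tensor = tens, windowStarts = 0L, w = 30L, s = 2L,
           roiLabels = sprintf("AAL%03d", 1:116), subjectId = "s",
           scanId = "s", label = "unknown")
  expect_identical(nrow(fcSeries(vectorizeLowerTriangle(d))), 6670L)
  # smallest case: N = 2 has a single pair
  x <- randomScan(2, 10)
  f <- vectorizeLowerTriangle(buildDynamicFCN(x, slidingWindowConfig(4, 2)))
  expect_identical(nrow(fcSeries(f)), 1L)
})

test_that("mean FC features average each pair's series", {
  f <- fcmFromMatrix(rbind(c(0.2, 0.2, 0.2), c(1, -1, 0), c(0.1, 0.5, 0.9)), 3)
  expect_equal(unname(meanFCFeatures(f)), c(0.2, 0, 0.5))
  expect_named(meanFCFeatures(f),
               c("ROI002~ROI001", "ROI003~ROI001", "ROI003~ROI002"))
})
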