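# Episodic 2-way K-shot machinery: splits, episodes, query
# classification and the ACC/SPE/PPV/NPV report.

# scan-level cohort with several scans per subject
multiScanCohort <- function(nSubj, scansPer, P = 6, K = 4, seed = 1) {
  N <- (1 + sqrt(1 + 8 * P)) / 2
  stopifnot(N == round(N))
  withr::with_seed(seed, {
    out <- list()
    for (cls in c("NC", "patient")) {
      for (i in seq_len(nSubj)) {
        sid <- sprintf("%s_%02d", cls, i)
        for (sc in seq_len(scansPer)) {
          out[[length(out) + 1L]] <- fcmFromMatrix(
            matrix(rnorm(P * K), P, K), N, subjectId = sid, label = cls,
            scanId = sprintf("%s_scan%d", sid, sc))
        }
      }
    }
    out
  })
}

test_that("cohort splitting is stratified, subject-level and reproducible", {
  cohort <- multiScanCohort(10, 1)  # 10 subjects per class
  parts <- splitCohort(cohort, c(0.6, 0.2, 0.2), seed = 3)
  lens <- vapply(parts, length, 1L)
  expect_identical(unname(lens), c(12L, 4L, 4L))  # 6/2/2 subjects per class
  for (p in parts) {
    tab <- table(vapply(p, groupLabel, ""))
    expect_identical(length(unique(tab)), 1L)  # class-balanced
  }
  expect_identical(
    lapply(splitCohort(cohort, seed = 3), function(p) vapply(p, scanId, "")),
    lapply(parts, function(p) vapply(p, scanId, "")))
  # all scans of one subject stay in one part
  triScan <- multiScanCohort(5, 3)
  parts3 <- splitCohort(triScan, seed = 9)
  whichPart <- rep(names(parts3), vapply(parts3, length, 1L))
  subj <- unlist(lapply(parts3, function(p) vapply(p, subjectId, "")))
  expect_true(all(tapply(whichPart, subj, function(v) length(unique(v))) == 1))
  # too few subjects to populate three parts
  expect_error(splitCohort(multiScanCohort(2, 1), seed = 1),
               class = "siamfcn_input_error")
  expect_error(splitCohort(cohort, c(0.5, 0.5, 0.5)),
               class = "siamfcn_config_error")
})

test_that("episodes have the 2-way K-shot structure without leakage", {
  cohort <- multiScanCohort(8, 1)
  eps <- buildEpisodes(cohort, nShot = 5, nQuery = 3, nEpisodes = 20, seed = 2)
  expect_length(eps, 20)
  for (ep in eps) {
    supLab <- vapply(ep@support, groupLabel, "")
    expect_identical(as.integer(table(supLab)), c(5L, 5L))  # 5-shot, 2-way
    quIds <- vapply(ep@query, scanId, "")
    expect_length(intersect(vapply(ep@support, scanId, ""), quIds), 0L)
    expect_identical(as.integer(table(vapply(ep@query, groupLabel, ""))),
                     c(3L, 3L))
  }
  ids <- function(es) lapply(es, function(e) vapply(e@support, scanId, ""))
  expect_identical(ids(buildEpisodes(cohort, 5, 3, 20, seed = 2)), ids(eps))
  # a class with exactly nShot scans leaves nothing to query
  small <- multiScanCohort(5, 1)
  expect_error(buildEpisodes(small, nShot = 5, nQuery = 1, nEpisodes = 1),
               class = "siamfcn_input_error")
})

test_that("query classification follows the dominant class similarity", {
  withr::with_seed(13, {
    # supports: class patient contains an exact copy of the query
    q <- fcmFromMatrix(matrix(rnorm(6 * 4) + 1, 6, 4), 4, subjectId = "q",
                       label = "patient", scanId = "q")
    mkSup <- function(cls, i, mat) {
      fcmFromMatrix(mat, 4, subjectId = sprintf("%s%d", cls, i), label = cls,
                    scanId = sprintf("%s%d", cls, i))
    }
    sup <- c(
      lapply(1:2, function(i) mkSup("NC", i, matrix(rnorm(6 * 4), 6, 4))),
      list(mkSup("patient", 1, fcSeries(q)),
           mkSup("patient", 2, matrix(rnorm(6 * 4), 6, 4)))
    )
    ep <- new("Episode", support = sup, query = list())
    expect_identical(classifyQuery(q, ep), "patient")
    # exact ties break toward NC: identical supports in both classes
    tieSup <- c(list(mkSup("NC", 1, fcSeries(q))),
                list(mkSup("patient", 1, fcSeries(q))))
    epTie <- new("Episode", support = tieSup, query = list())
    expect_identical(classifyQuery(q, epTie), "NC")
  })
})

test_that("classification agrees with a brute-force loop over supports", {
  cohort <- multiScanCohort(8, 1, P = 10, K = 5, seed = 21)
  params <- initAttentionParams(5, seed = 3)
  eps <- buildEpisodes(cohort, nShot = 3, nQuery = 2, nEpisodes = 5, seed = 4)
  for (ep in eps) {
    for (q in ep@query) {
      got <- classifyQuery(q, ep, params)
      # brute force: average aggregated similarity per class
      sims <- sapply(ep@support, function(su) {
        mean(oracleCosine(fcSeries(attend(q, params)),
                          fcSeries(attend(su, params))))
      })
      lab <- vapply(ep@support, groupLabel, "")
      want <- if (mean(sims[lab == "patient"]) > mean(sims[lab == "NC"])) {
        "patient"
      } else "NC"
      expect_identical(got, want)
    }
  }
})

test_that("metric formulas match hand computation and mark undefined cases", {
  perfect <- computeMetrics(confusionCounts(TP = 5, TN = 5))
  expect_equal(c(perfect@ACC, perfect@SPE, perfect@PPV, perfect@NPV),
               rep(1, 4))
  m <- computeMetrics(confusionCounts(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(m@ACC, 0.7)
  expect_equal(m@SPE, 0.8)
  expect_equal(m@PPV, 0.75)
  expect_equal(m@NPV, 2 / 3)
  # no predicted positives: PPV undefined, not an error
  noPos <- computeMetrics(confusionCounts(TP = 0, TN = 4, FP = 0, FN = 2))
  expect_true(is.na(noPos@PPV))
  expect_false(is.na(noPos@ACC))
  expect_error(computeMetrics(confusionCounts()), class = "siamfcn_input_error")
  # random tables: formulas and the ACC convexity bound
  withr::with_seed(31, {
    for (rep in 1:50) {
      v <- rpois(4, 5)
      if (sum(v) == 0) next
      cc <- confusionCounts(v[1], v[2], v[3], v[4])
      mm <- computeMetrics(cc)
      expect_equal(mm@ACC, (v[1] + v[2]) / sum(v))
      if (v[2] + v[3] > 0) expect_equal(mm@SPE, v[2] / (v[2] + v[3]))
      sens <- if (v[1] + v[4] > 0) v[1] / (v[1] + v[4]) else NA
      if (!is.na(sens) && !is.na(mm@SPE)) {
        expect_gte(mm@ACC, min(sens, mm@SPE) - 1e-12)
        expect_lte(mm@ACC, max(sens, mm@SPE) + 1e-12)
      }
    }
  })
})

test_that("evaluation pools per-episode counts and honors an oracle decision", {
  cohort <- multiScanCohort(8, 1, P = 10, K = 5, seed = 5)
  # oracle decision function: always the true label -> perfect metrics
  oracleFun <- function(qi, ep) groupLabel(ep@query[[qi]])
  ev <- evaluateFewShot(cohort, NULL, nShot = 3, nQuery = 2, nEpisodes = 10,
                        seed = 6, decisionFun = oracleFun)
  expect_equal(ev$pooled@ACC, 1)
  expect_equal(unname(ev$macro["meanACC"]), 1)
  # pooled counts are the sum of per-episode counts
  ev2 <- evaluateFewShot(cohort, initAttentionParams(5, seed = 2),
                         nShot = 3, nQuery = 2, nEpisodes = 10, seed = 6)
  expect_identical(ev2$pooled@counts@TP, sum(ev2$perEpisode$TP))
  expect_identical(ev2$pooled@counts@FN, sum(ev2$perEpisode$FN))
  expect_identical(ev2$pooled@counts@TP + ev2$pooled@counts@TN +
                     ev2$pooled@counts@FP + ev2$pooled@counts@FN,
                   10L * 4L)
})

test_that("fast evaluation agrees with per-query classifyQuery", {
  cohort <- multiScanCohort(7, 1, P = 10, K = 5, seed = 8)
  params <- initAttentionParams(5, seed = 9)
  for (rule in c("meanSimilarity", "nearestSupport")) {
    ev <- evaluateFewShot(cohort, params, nShot = 3, nQuery = 2,
                          nEpisodes = 6, seed = 10, rule = rule)
    eps <- buildEpisodes(cohort, nShot = 3, nQuery = 2, nEpisodes = 6,
                         seed = 10)
    tp <- tn <- fp <- fn <- 0L
    for (ep in eps) {
      for (q in ep@query) {
        pred <- classifyQuery(q, ep, params, rule = rule)
        truth <- groupLabel(q)
        if (truth == "patient" && pred == "patient") tp <- tp + 1L
        else if (truth == "NC" && pred == "NC") tn <- tn + 1L
        else if (truth == "NC") fp <- fp + 1L
        else fn <- fn + 1L
      }
    }
    expect_identical(ev$pooled@counts@TP, tp)
    expect_identical(ev$pooled@counts@TN, tn)
    expect_identical(ev$pooled@counts@FP, fp)
    expect_identical(ev$pooled@counts@FN, fn)
  }
})
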