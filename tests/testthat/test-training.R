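# Contrastive loss, pair sampling, the shared-parameter Siamese forward
# pass and the training loop.

test_that("contrastive loss matches the closed form on a grid", {
  # same-category pairs above the margin incur no loss
  expect_equal(contrastiveLoss(1.2, 1, margin = 1), 0)
  expect_equal(contrastiveLoss(1, 1, margin = 1), 0)
  # direct substitutions
  expect_equal(contrastiveLoss(0.5, 0), 0.25)
  expect_equal(contrastiveLoss(0.2, 1, margin = 1), 0.64)
  # grid: nonnegative everywhere, zero exactly when the pair is satisfied
  for (s in seq(-1, 1.5, by = 0.25)) {
    for (y in c(0, 1)) {
      for (margin in c(0.5, 1)) {
        L <- contrastiveLoss(s, y, margin)
        expect_gte(L, 0)
        expect_equal(L == 0, (y == 1 && s >= margin) || (y == 0 && s == 0))
        expect_equal(L, (1 - y) * s^2 + y * max(margin - s, 0)^2)
      }
    }
  }
  expect_error(contrastiveLoss(0.5, 0.3), class = "siamfcn_input_error")
  expect_error(contrastiveLoss(0.5, 1, margin = 0),
               class = "siamfcn_config_error")
})

test_that("pair sampling is seeded, balanced, and never pairs a scan with itself", {
  cohort <- randomFCCohort(5, 6, 4, seed = 2)
  p1 <- samplePairs(cohort, 100, balance = 0.5, seed = 7)
  p2 <- samplePairs(cohort, 100, balance = 0.5, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, samplePairs(cohort, 100, balance = 0.5, seed = 8)))
  expect_identical(sum(p1$y), 50L)
  expect_true(all(p1$first != p1$second))
  lab <- vapply(cohort, groupLabel, "")
  expect_identical(p1$y, as.integer(lab[p1$first] == lab[p1$second]))
  # one class only: no different-category pairs can be formed
  oneClass <- cohort[lab == "NC"]
  expect_error(samplePairs(oneClass, 10), class = "siamfcn_input_error")
})

test_that("forward pass is symmetric and zero-loss for identical same-class pairs", {
  withr::with_seed(53, {
    a <- fcmFromMatrix(matrix(rnorm(6 * 4), 6, 4), 4, label = "NC")
    b <- fcmFromMatrix(matrix(rnorm(6 * 4), 6, 4), 4, label = "NC",
                       subjectId = "s2", scanId = "s2")
    params <- initAttentionParams(4, seed = 5)
    # identical inputs through shared weights: s = 1, hinge satisfied
    same <- forwardPair(a, a, 1, params, margin = 1)
    expect_equal(same$similarity, 1)
    expect_equal(same$loss, 0)
    # swapping branches changes nothing (cosine symmetry + shared weights)
    fwd <- forwardPair(a, b, 0, params)
    rev <- forwardPair(b, a, 0, params)
    expect_equal(fwd$similarity, rev$similarity)
    expect_equal(fwd$loss, rev$loss)
  })
})

test_that("forward pass matches a straight-line independent implementation", {
  withr::with_seed(59, {
    for (rep in 1:5) {
      N <- sample(3:5, 1); P <- N * (N - 1) / 2; K <- sample(2:4, 1)
      a <- fcmFromMatrix(matrix(rnorm(P * K), P, K), N)
      b <- fcmFromMatrix(matrix(rnorm(P * K), P, K), N,
                         subjectId = "s2", scanId = "s2")
      params <- initAttentionParams(K, dk = sample(1:3, 1), seed = rep)
      y <- rep %% 2
      margin <- 0.8
      got <- forwardPair(a, b, y, params, margin = margin)
      want <- oracleForwardPair(fcSeries(a), fcSeries(b), y, params, margin)
      expect_equal(got$similarity, want$similarity, tolerance = 1e-10)
      expect_equal(got$loss, want$loss, tolerance = 1e-10)
    }
  })
})

test_that("analytic gradients match central finite differences", {
  numGrad <- function(fun, mat, eps = 1e-5) {
    g <- mat * 0
    for (idx in seq_along(mat)) {
      up <- mat; up[idx] <- up[idx] + eps
      dn <- mat; dn[idx] <- dn[idx] - eps
      g[idx] <- (fun(up) - fun(dn)) / (2 * eps)
    }
    g
  }
  withr::with_seed(61, {
    nChecked <- 0
    rep <- 0
    while (nChecked < 20) {
      rep <- rep + 1
      P <- 6; K <- 3; dk <- 2
      a <- fcmFromMatrix(matrix(rnorm(P * K), P, K), 4)
      b <- fcmFromMatrix(matrix(rnorm(P * K), P, K), 4, subjectId = "s2",
                         scanId = "s2")
      # alternate between random and identity-anchored starting points
      params <- initAttentionParams(K, dk = dk, seed = 1000 + rep,
                                    identityScale = rep %% 2)
      y <- rep %% 2
      margin <- 0.7
      agg <- if (rep %% 3 == 0) "sum" else "mean"
      base <- siamfcn:::.forwardPairGrad(a, b, y, params, margin, agg)
      # stay away from the hinge point where the loss is not differentiable
      if (y == 1 && abs(margin - base$similarity) < 1e-3) next
      lossAt <- function(which, mat) {
        p2 <- params
        slot(p2, which) <- mat
        forwardPair(a, b, y, p2, margin, agg)$loss
      }
      for (which in c("WQ", "WK", "WV")) {
        ng <- numGrad(function(m) lossAt(which, m), slot(params, which))
        scale <- max(abs(ng), abs(base[[which]]), 1e-8)
        expect_lt(max(abs(ng - base[[which]])) / scale, 1e-4)
      }
      nChecked <- nChecked + 1
    }
  })
})

test_that("training is deterministic and inert at zero learning rate", {
  cohort <- randomFCCohort(4, 6, 4, seed = 3)
  init <- initAttentionParams(4, seed = 2)
  frozen <- trainSiamese(cohort, params = init, epochs = 5, learningRate = 0,
                         pairsPerEpoch = 20, seed = 4)
  expect_identical(attentionParams(frozen)@WQ, init@WQ)
  expect_identical(attentionParams(frozen)@WV, init@WV)
  expect_equal(diff(range(lossHistory(frozen))), 0)
  a <- trainSiamese(cohort, params = init, epochs = 5, pairsPerEpoch = 20,
                    seed = 4)
  b <- trainSiamese(cohort, params = init, epochs = 5, pairsPerEpoch = 20,
                    seed = 4)
  expect_identical(lossHistory(a), lossHistory(b))
  expect_identical(attentionParams(a)@WQ, attentionParams(b)@WQ)
  expect_length(lossHistory(a), 5)
  expect_true(all(is.finite(lossHistory(a))))
})

test_that("training reduces the contrastive loss on a separable cohort", {
  # two classes with opposite-signed series in half the pairs: the loss
  # has an easy discriminative direction to descend
  withr::with_seed(67, {
    mk <- function(cls, i) {
      base <- matrix(rnorm(10 * 6, sd = 0.3), 10, 6)
      base[1:5, ] <- base[1:5, ] + if (cls == "NC") 1 else -1
      fcmFromMatrix(base, 5, subjectId = sprintf("%s%d", cls, i), label = cls,
                    scanId = sprintf("%s%d", cls, i))
    }
    cohort <- c(lapply(1:6, function(i) mk("NC", i)),
                lapply(1:6, function(i) mk("patient", i)))
  })
  st <- trainSiamese(cohort, epochs = 30, pairsPerEpoch = 60, seed = 9)
  expect_lt(lossHistory(st)[30], lossHistory(st)[1])
})
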