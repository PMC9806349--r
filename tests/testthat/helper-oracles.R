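# Independent brute-force oracles: straight-line implementations kept free
# of the package's vectorized code paths, used to pin down expected values.

# textbook Pearson correlation of two vectors
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) 0 else num / den
}

# all window offsets by exhaustive search
oracleWindows <- function(M, w, s) {
  offs <- integer(0)
  o <- 0L
  while (o + w <= M) {
    offs <- c(offs, o)
    o <- o + s
  }
  offs
}

# dynamic FCN by explicit per-window, per-pair loops
oracleDynFCN <- function(values, w, s) {
  M <- ncol(values)
  N <- nrow(values)
  offs <- oracleWindows(M, w, s)
  tens <- array(NA_real_, dim = c(length(offs), N, N))
  for (k in seq_along(offs)) {
    sub <- values[, (offs[k] + 1):(offs[k] + w), drop = FALSE]
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        tens[k, i, j] <- if (i == j) 1 else oraclePearson(sub[i, ], sub[j, ])
      }
    }
  }
  tens
}

# single-head attention by explicit loops over tokens and features
oracleAttention <- function(Fm, WQ, WK, WV, dk) {
  P <- nrow(Fm); K <- ncol(Fm)
  Q <- matrix(0, P, dk); Ky <- matrix(0, P, dk); V <- matrix(0, P, K)
  for (p in 1:P) {
    for (d in 1:dk) {
      for (k in 1:K) {
        Q[p, d] <- Q[p, d] + Fm[p, k] * WQ[d, k]
        Ky[p, d] <- Ky[p, d] + Fm[p, k] * WK[d, k]
      }
    }
    for (kk in 1:K) {
      for (k in 1:K) V[p, kk] <- V[p, kk] + Fm[p, k] * WV[kk, k]
    }
  }
  S <- matrix(0, P, P)
  for (p in 1:P) for (q in 1:P) S[p, q] <- sum(Q[p, ] * Ky[q, ]) / sqrt(dk)
  A <- matrix(0, P, P)
  for (p in 1:P) {
    e <- exp(S[p, ] - max(S[p, ]))
    A[p, ] <- e / sum(e)
  }
  out <- matrix(0, P, K)
  for (p in 1:P) for (k in 1:K) out[p, k] <- sum(A[p, ] * V[, k])
  out
}

# per-pair cosine by explicit loops
oracleCosine <- function(A, B) {
  sapply(seq_len(nrow(A)), function(p) {
    num <- sum(A[p, ] * B[p, ])
    den <- sqrt(sum(A[p, ]^2)) * sqrt(sum(B[p, ]^2))
    if (den == 0) 0 else num / den
  })
}

# straight-line Siamese pair loss (attention -> cosine -> mean -> loss)
oracleForwardPair <- function(Fa, Fb, y, params, margin, aggregation = "mean") {
  outA <- oracleAttention(Fa, params@WQ, params@WK, params@WV, params@dk)
  outB <- oracleAttention(Fb, params@WQ, params@WK, params@WV, params@dk)
  cosv <- oracleCosine(outA, outB)
  s <- if (aggregation == "mean") mean(cosv) else sum(cosv)
  list(similarity = s,
       loss = (1 - y) * s^2 + y * max(margin - s, 0)^2)
}

# fixture builders -----------------------------------------------------------

randomScan <- function(N, M, subjectId = "s1", label = "NC",
                       scanId = subjectId) {
  RoiTimeSeries(matrix(rnorm(N * M), N, M), subjectId = subjectId,
                scanId = scanId, label = label)
}

# FCSeriesMatrix straight from a numeric matrix (bypasses the BOLD pipeline)
fcmFromMatrix <- function(series, N, subjectId = "s1", label = "NC",
                          scanId = subjectId) {
  new("FCSeriesMatrix", series = series, pairIndex = siamfcn:::.pairIndexFor(N),
      w = 2L, s = 1L, roiLabels = sprintf("ROI%03d", seq_len(N)),
      subjectId = subjectId, scanId = scanId, label = label)
}

# small cohort of FC-series objects with iid noise series per scan
randomFCCohort <- function(nPerClass, P, K, seed = 1) {
  withr::with_seed(seed, {
    N <- (1 + sqrt(1 + 8 * P)) / 2
    stopifnot(N == round(N))
    c(
      lapply(seq_len(nPerClass), function(i) {
        fcmFromMatrix(matrix(rnorm(P * K), P, K), N,
                      subjectId = sprintf("NC_%02d", i), label = "NC",
                      scanId = sprintf("NC_%02d", i))
      }),
      lapply(seq_len(nPerClass), function(i) {
        fcmFromMatrix(matrix(rnorm(P * K), P, K), N,
                      subjectId = sprintf("PT_%02d", i), label = "patient",
                      scanId = sprintf("PT_%02d", i))
      })
    )
  })
}
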