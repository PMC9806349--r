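# Siamese training of the attention parameters under the contrastive
# objective  L = (1 - y) s^2 + y max(margin - s, 0)^2,
# where s is the aggregated pairwise cosine similarity between the two
# branch outputs and y = 1 for a same-category subject pair, 0 otherwise.
#
# Both branches share one AttentionParams (weight sharing is structural:
# there is a single parameter object, and gradients from both branches
# accumulate into it).  Gradients are computed by hand-derived
# backpropagation through attention -> cosine -> aggregation -> loss;
# tests verify them against central finite differences.

#' Contrastive loss
#'
#' \code{(1 - y) * s^2 + y * max(margin - s, 0)^2}: same-category pairs
#' (y = 1) are penalized when their similarity falls below the margin,
#' different-category pairs (y = 0) are penalized for any positive
#' similarity.  Vectorized over \code{s} and \code{y}.
#'
#' @param s similarity value(s)
#' @param y pair label(s): 1 for same category, 0 otherwise
#' @param margin positive margin hyperparameter
#' @return nonnegative loss value(s)
#' @export
contrastiveLoss <- function(s, y, margin = 1) {
  if (!all(y %in% c(0, 1))) .inputError("y must be 0 or 1")
  if (margin <= 0) .configError("margin must be positive")
  (1 - y) * s^2 + y * pmax(margin - s, 0)^2
}

# dL/ds (subgradient 0 at the hinge point s == margin)
.contrastiveLossGrad <- function(s, y, margin) {
  2 * (1 - y) * s - 2 * y * pmax(margin - s, 0)
}

# pair-level loss and gradient w.r.t. the two attention outputs
# outA, outB: P x K attention outputs of the two branches
.pairLossGrad <- function(outA, outB, y, margin, aggregation) {
  na <- sqrt(rowSums(outA^2)); nb <- sqrt(rowSums(outB^2))
  denom <- na * nb
  bad <- denom == 0
  denom[bad] <- 1
  cosv <- rowSums(outA * outB) / denom
  cosv[bad] <- 0
  P <- nrow(outA)
  s <- if (aggregation == "mean") mean(cosv) else sum(cosv)
  loss <- contrastiveLoss(s, y, margin)
  coef <- .contrastiveLossGrad(s, y, margin) *
    (if (aggregation == "mean") 1 / P else 1)
  dA <- coef * (outB / denom - outA * (cosv / pmax(na^2, .Machine$double.xmin)))
  dB <- coef * (outA / denom - outB * (cosv / pmax(nb^2, .Machine$double.xmin)))
  dA[bad, ] <- 0
  dB[bad, ] <- 0
  list(similarity = s, loss = loss, dOutA = dA, dOutB = dB)
}

#' Forward pass of one Siamese subject pair
#'
#' Passes both scans through \code{\link{attend}} with the same shared
#' parameters, computes the per-pair cosine similarities, aggregates them
#' into the subject similarity s, and evaluates the contrastive loss.
#'
#' @param a,b \linkS4class{FCSeriesMatrix} objects with identical layout
#' @param y pair label: 1 if same category, 0 otherwise
#' @param params shared \linkS4class{AttentionParams}
#' @param margin contrastive margin
#' @param aggregation \code{"mean"} or \code{"sum"}
#' @return list with elements \code{similarity} and \code{loss}
#' @export
forwardPair <- function(a, b, y, params, margin = 1,
                        aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  .checkSameLayout(a, b)
  outA <- attend(a, params)@series
  outB <- attend(b, params)@series
  r <- .pairLossGrad(outA, outB, y, margin, aggregation)
  list(similarity = r$similarity, loss = r$loss)
}

# internal sampler; assumes the RNG state is already set by the caller
.samplePairsRaw <- function(labels, nPairs, balance) {
  classes <- split(seq_along(labels), labels)
  if (length(classes) < 2L) {
    .inputError("cohort must contain two classes to form different-category pairs")
  }
  if (any(vapply(classes, length, 1L) < 2L)) {
    .inputError("each class needs at least 2 scans to form same-category pairs")
  }
  nSame <- round(nPairs * balance)
  ij <- matrix(NA_integer_, nrow = nPairs, ncol = 2L)
  same <- c(rep(TRUE, nSame), rep(FALSE, nPairs - nSame))
  for (r in seq_len(nPairs)) {
    if (same[r]) {
      cls <- classes[[sample.int(length(classes), 1L)]]
      ij[r, ] <- sample(cls, 2L)
    } else {
      cl2 <- sample.int(length(classes), 2L)
      ij[r, 1] <- sample(classes[[cl2[1]]], 1L)
      ij[r, 2] <- sample(classes[[cl2[2]]], 1L)
    }
  }
  data.frame(first = ij[, 1], second = ij[, 2], y = as.integer(same))
}

#' Sample labeled subject pairs for contrastive training
#'
#' Draws a reproducible sample of scan pairs with approximately
#' \code{balance} fraction same-category (y = 1) pairs; a scan is never
#' paired with itself.
#'
#' @param cohort list of labeled \linkS4class{FCSeriesMatrix} objects
#' @param nPairs number of pairs to draw
#' @param balance fraction of same-category pairs, in (0, 1)
#' @param seed integer RNG seed
#' @return data.frame with columns first, second (indices into
#'   \code{cohort}) and y
#' @export
samplePairs <- function(cohort, nPairs, balance = 0.5, seed = 1L) {
  if (balance <= 0 || balance >= 1) .configError("balance must lie in (0, 1)")
  labels <- vapply(cohort, groupLabel, "")
  withr::with_seed(as.integer(seed), .samplePairsRaw(labels, nPairs, balance))
}

#' TrainState: trained attention parameters and training record
#'
#' @slot params the trained \linkS4class{AttentionParams}
#' @slot lossHistory mean pair loss per epoch
#' @slot config list of training settings (learning rate, epochs, pairs per
#'   epoch, margin, aggregation, balance, seed)
#'
#' @aliases attentionParams lossHistory
#' @export
setClass("TrainState",
  representation(params = "AttentionParams", lossHistory = "numeric",
                 config = "list")
)

#' @rdname TrainState-class
#' @export
setMethod("attentionParams", "TrainState", function(x) x@params)
#' @rdname TrainState-class
#' @export
setMethod("lossHistory", "TrainState", function(x) x@lossHistory)

setMethod("show", "TrainState", function(object) {
  n <- length(object@lossHistory)
  cat(sprintf("TrainState: %d epochs (margin = %g, aggregation = %s)\n",
              n, object@config$margin, object@config$aggregation))
  if (n > 0) {
    cat(sprintf("  mean pair loss: %.5f (first) -> %.5f (last)\n",
                object@lossHistory[1], object@lossHistory[n]))
  }
})

# one Adam step per parameter matrix
.adamStep <- function(theta, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the Siamese attention model
#'
#' Draws \code{pairsPerEpoch} labeled scan pairs, and each epoch runs every
#' involved scan once through the shared attention module, accumulates the
#' contrastive-loss gradient of the mean pair loss into the shared
#' parameters by backpropagation, and applies one Adam update.  Fully
#' reproducible given \code{seed}.
#'
#' When a \code{validation} cohort is supplied the returned parameters are
#' the checkpoint (the initial state included) with the highest pooled
#' episodic accuracy on validation episodes, evaluated every
#' \code{evalEvery} epochs — the standard few-shot model-selection role of
#' the validation split, which guards against the contrastive objective
#' overfitting the training scans.  Without a validation cohort the final
#' epoch's parameters are returned.
#'
#' @param cohort list of labeled \linkS4class{FCSeriesMatrix} objects
#'   (the training split), at least 2 scans per class
#' @param params starting \linkS4class{AttentionParams}; when NULL they are
#'   initialized from the cohort's K with \code{seed}
#' @param epochs number of epochs
#' @param learningRate Adam step size
#' @param pairsPerEpoch sampled pairs per epoch
#' @param margin contrastive margin
#' @param aggregation \code{"mean"} or \code{"sum"} subject similarity
#' @param balance fraction of same-category pairs per epoch
#' @param resamplePairs when FALSE (default) one seeded pair sample is
#'   reused every epoch (a fixed empirical objective, so the loss history
#'   is monotone-comparable across epochs); when TRUE a fresh pair sample
#'   is drawn each epoch
#' @param dk key dimension used when \code{params} is NULL
#' @param seed integer RNG seed controlling initialization and sampling
#' @param validation optional labeled cohort for checkpoint selection
#' @param evalEvery validation evaluation period in epochs
#' @param valShot,valQuery,valEpisodes validation episode protocol
#' @return a \linkS4class{TrainState}
#' @export
trainSiamese <- function(cohort, params = NULL, epochs = 50L,
                         learningRate = 1e-3, pairsPerEpoch = 256L,
                         margin = 0.5, aggregation = c("mean", "sum"),
                         balance = 0.5, resamplePairs = FALSE,
                         dk = NULL, seed = 1L, validation = NULL,
                         evalEvery = 5L, valShot = 5L, valQuery = 5L,
                         valEpisodes = 30L) {
  aggregation <- match.arg(aggregation)
  if (length(cohort) < 4L) .inputError("training cohort too small")
  labels <- vapply(cohort, groupLabel, "")
  K <- ncol(cohort[[1L]]@series)
  if (is.null(params)) {
    params <- initAttentionParams(K, dk = if (is.null(dk)) K else dk,
                                  seed = as.integer(seed))
  }
  opt <- list(
    WQ = list(m = params@WQ * 0, v = params@WQ * 0),
    WK = list(m = params@WK * 0, v = params@WK * 0),
    WV = list(m = params@WV * 0, v = params@WV * 0)
  )
  lossHist <- numeric(epochs)
  valACC <- function(p) {
    evaluateFewShot(validation, p, nShot = valShot, nQuery = valQuery,
                    nEpisodes = valEpisodes,
                    seed = as.integer(seed) + 1009L)$pooled@ACC
  }
  valHist <- numeric(0)
  bestParams <- params
  bestVal <- if (!is.null(validation)) valACC(params) else -Inf
  withr::with_seed(as.integer(seed), {
    fixedPairs <- if (!resamplePairs) {
      .samplePairsRaw(labels, pairsPerEpoch, balance)
    }
    for (ep in seq_len(epochs)) {
      pairs <- if (resamplePairs) {
        .samplePairsRaw(labels, pairsPerEpoch, balance)
      } else {
        fixedPairs
      }
      used <- sort(unique(c(pairs$first, pairs$second)))
      caches <- lapply(used, function(i)
        .attentionForward(cohort[[i]]@series, params))
      names(caches) <- as.character(used)
      dOut <- lapply(caches, function(cc) cc$out * 0)
      total <- 0
      for (r in seq_len(nrow(pairs))) {
        ia <- as.character(pairs$first[r]); ib <- as.character(pairs$second[r])
        g <- .pairLossGrad(caches[[ia]]$out, caches[[ib]]$out,
                           pairs$y[r], margin, aggregation)
        total <- total + g$loss
        dOut[[ia]] <- dOut[[ia]] + g$dOutA
        dOut[[ib]] <- dOut[[ib]] + g$dOutB
      }
      meanLoss <- total / nrow(pairs)
      if (!is.finite(meanLoss)) {
        .trainError(sprintf("training diverged at epoch %d (non-finite loss)", ep))
      }
      gWQ <- params@WQ * 0; gWK <- params@WK * 0; gWV <- params@WV * 0
      for (key in names(caches)) {
        if (all(dOut[[key]] == 0)) next
        g <- .attentionBackward(caches[[key]], dOut[[key]] / nrow(pairs))
        gWQ <- gWQ + g$WQ; gWK <- gWK + g$WK; gWV <- gWV + g$WV
      }
      uq <- .adamStep(params@WQ, gWQ, opt$WQ, learningRate, ep)
      uk <- .adamStep(params@WK, gWK, opt$WK, learningRate, ep)
      uv <- .adamStep(params@WV, gWV, opt$WV, learningRate, ep)
      opt$WQ <- uq$state; opt$WK <- uk$state; opt$WV <- uv$state
      params <- new("AttentionParams", WQ = uq$theta, WK = uk$theta,
                    WV = uv$theta, dk = params@dk)
      lossHist[ep] <- meanLoss
      if (!is.null(validation) && (ep %% evalEvery == 0L || ep == epochs)) {
        va <- valACC(params)
        valHist <- c(valHist, va)
        if (va > bestVal) {
          bestVal <- va
          bestParams <- params
        }
      }
    }
  })
  if (is.null(validation)) bestParams <- params
  new("TrainState", params = bestParams, lossHistory = lossHist,
      config = list(epochs = epochs, learningRate = learningRate,
                    pairsPerEpoch = pairsPerEpoch, margin = margin,
                    aggregation = aggregation, balance = balance,
                    resamplePairs = resamplePairs,
                    seed = as.integer(seed),
                    validationACC = valHist,
                    bestValidationACC = if (is.finite(bestVal)) bestVal))
}

# full-pair gradient (both branches through the shared parameters),
# used by the finite-difference checks and exposed for diagnostics
.forwardPairGrad <- function(a, b, y, params, margin = 1,
                             aggregation = "mean") {
  ca <- .attentionForward(a@series, params)
  cb <- .attentionForward(b@series, params)
  g <- .pairLossGrad(ca$out, cb$out, y, margin, aggregation)
  ga <- .attentionBackward(ca, g$dOutA)
  gb <- .attentionBackward(cb, g$dOutB)
  list(similarity = g$similarity, loss = g$loss,
       WQ = ga$WQ + gb$WQ, WK = ga$WK + gb$WK, WV = ga$WV + gb$WV)
}
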