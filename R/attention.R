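# Single-head self-attention over ROI-pair FC series.
#
# Tokens are the P ROI-pair FC series (rows of the FCSeriesMatrix); the
# feature dimension is the K windows.  With F the P x K input,
#   Query = F W_Q', Key = F W_K'  (P x d_k),  Value = F W_V'  (P x K),
#   output = softmax(Query Key' / sqrt(d_k)) Value,
# so the weighted matrix has exactly the input's P x K shape.

#' AttentionParams: learnable self-attention weights
#'
#' Parameter container for the single-head self-attention that weights the
#' FC-series matrix.  \code{WQ} and \code{WK} are d_k x K, \code{WV} is
#' K x K (so the attention output keeps the input's shape).
#'
#' @slot WQ,WK numeric d_k x K query/key projection matrices
#' @slot WV numeric K x K value projection matrix
#' @slot dk key dimension
#' @export
setClass("AttentionParams",
  representation(WQ = "matrix", WK = "matrix", WV = "matrix", dk = "integer")
)

setValidity("AttentionParams", function(object) {
  K <- ncol(object@WV)
  if (object@dk < 1L) return("dk must be >= 1")
  if (nrow(object@WQ) != object@dk || nrow(object@WK) != object@dk) {
    return("WQ and WK must have dk rows")
  }
  if (ncol(object@WQ) != K || ncol(object@WK) != K || nrow(object@WV) != K) {
    return("WQ, WK must be dk x K and WV must be K x K")
  }
  if (!all(is.finite(object@WQ)) || !all(is.finite(object@WK)) ||
      !all(is.finite(object@WV))) {
    return("parameters must be finite")
  }
  TRUE
})

setMethod("show", "AttentionParams", function(object) {
  cat(sprintf("AttentionParams: K = %d windows, d_k = %d\n",
              ncol(object@WV), object@dk))
})

#' Initialize attention parameters
#'
#' Identity-anchored initialization (default): \code{WQ} and \code{WK} start
#' at \code{identityScale} times the (rectangular) identity plus a small
#' seeded Gaussian perturbation, and \code{WV} at the identity plus the same
#' perturbation.  At this starting point the attention scores are scaled
#' inner products between FC series, so each ROI pair attends to pairs with
#' similar dynamics (itself included) and the weighted output preserves
#' per-pair information.  With \code{identityScale = 0} the initialization
#' falls back to pure zero-mean Gaussian entries of standard deviation
#' 1/sqrt(K); at the token counts typical here (P of order 10^2-10^3) that
#' start collapses the softmax to near-uniform row weights, which erases
#' per-pair structure, so it is kept only as an ablation.
#'
#' @param K feature dimension (number of windows)
#' @param dk key dimension; defaults to K
#' @param seed integer RNG seed
#' @param identityScale scale of the identity anchor on WQ/WK; 0 for pure
#'   random initialization
#' @param perturbation relative scale of the random perturbation around the
#'   anchored matrices
#' @return an \linkS4class{AttentionParams}
#' @export
initAttentionParams <- function(K, dk = K, seed = 1L, identityScale = 8,
                                perturbation = 0.1) {
  K <- as.integer(K); dk <- as.integer(dk)
  if (K < 1L || dk < 1L) .configError("K and dk must be >= 1")
  rectEye <- diag(1, dk, K)
  withr::with_seed(as.integer(seed), {
    if (identityScale == 0) {
      sc <- 1 / sqrt(K)
      new("AttentionParams",
          WQ = matrix(stats::rnorm(dk * K, sd = sc), dk, K),
          WK = matrix(stats::rnorm(dk * K, sd = sc), dk, K),
          WV = matrix(stats::rnorm(K * K, sd = sc), K, K),
          dk = dk)
    } else {
      sc <- perturbation / sqrt(K)
      new("AttentionParams",
          WQ = identityScale * rectEye + matrix(stats::rnorm(dk * K, sd = sc), dk, K),
          WK = identityScale * rectEye + matrix(stats::rnorm(dk * K, sd = sc), dk, K),
          WV = diag(K) + matrix(stats::rnorm(K * K, sd = sc), K, K),
          dk = dk)
    }
  })
}

# numerically stable row-wise softmax
.softmaxRows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

# forward pass keeping intermediates for backpropagation
.attentionForward <- function(Fm, params) {
  Q <- Fm %*% t(params@WQ)
  Km <- Fm %*% t(params@WK)
  V <- Fm %*% t(params@WV)
  A <- .softmaxRows(tcrossprod(Q, Km) / sqrt(params@dk))
  list(input = Fm, Q = Q, K = Km, V = V, A = A, out = A %*% V)
}

# gradient of a scalar loss w.r.t. WQ, WK, WV given dOut = dL/d(output)
.attentionBackward <- function(cache, dOut) {
  dV <- crossprod(cache$A, dOut)                 # P x K
  dA <- tcrossprod(dOut, cache$V)                # P x P
  dS <- (dA - rowSums(dA * cache$A)) * cache$A   # softmax backward, row-wise
  sq <- sqrt(ncol(cache$Q))
  dQ <- dS %*% cache$K / sq
  dK <- crossprod(dS, cache$Q) / sq
  list(WQ = crossprod(dQ, cache$input),
       WK = crossprod(dK, cache$input),
       WV = crossprod(dV, cache$input))
}

#' @rdname attend
#' @export
setMethod("attend", signature(x = "FCSeriesMatrix", params = "AttentionParams"),
  function(x, params) {
    if (ncol(x@series) != ncol(params@WV)) {
      .configError(sprintf(
        "attention parameters built for K = %d windows, input has K = %d",
        ncol(params@WV), ncol(x@series)))
    }
    out <- .attentionForward(x@series, params)$out
    new("WeightedFCSeries", series = out, pairIndex = x@pairIndex,
        w = x@w, s = x@s, roiLabels = x@roiLabels,
        subjectId = x@subjectId, scanId = x@scanId, label = x@label)
  })

# checkpointing --------------------------------------------------------------

#' Write attention parameters to a JSON checkpoint
#'
#' @param params an \linkS4class{AttentionParams}
#' @param path output file path (JSON)
#' @param meta optional named list of extra metadata to store
#' @return \code{path}, invisibly
#' @export
writeAttentionParams <- function(params, path, meta = list()) {
  stopifnot(is(params, "AttentionParams"))
  payload <- c(list(WQ = params@WQ, WK = params@WK, WV = params@WV,
                    dk = params@dk, K = ncol(params@WV)), meta)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read attention parameters from a JSON checkpoint
#'
#' @param path checkpoint file written by \code{\link{writeAttentionParams}}
#' @return an \linkS4class{AttentionParams}
#' @export
readAttentionParams <- function(path) {
  if (!file.exists(path)) .ioError(sprintf("checkpoint not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("AttentionParams", WQ = as.matrix(p$WQ), WK = as.matrix(p$WK),
      WV = as.matrix(p$WV), dk = as.integer(p$dk))
}
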