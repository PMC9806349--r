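# Dynamic functional connectivity networks: sliding-window Pearson
# correlation matrices and their lower-triangle vectorization.

#' DynamicFCN: stacked short-term functional connectivity matrices
#'
#' K sliding-window Pearson correlation matrices D(1)...D(K) for one scan,
#' stored as a K x N x N array.  Window offsets are 0-based and windows are
#' half-open: offset o covers time points o+1 ... o+w in 1-based R indexing.
#'
#' @slot tensor numeric K x N x N array of windowed correlations
#' @slot windowStarts integer vector of K 0-based window offsets
#' @slot w,s window length and step used
#' @slot roiLabels,subjectId,scanId,label scan annotation carried through
#' @export
setClass("DynamicFCN",
  representation(
    tensor = "array",
    windowStarts = "integer",
    w = "integer",
    s = "integer",
    roiLabels = "character",
    subjectId = "character",
    scanId = "character",
    label = "character"
  )
)

setValidity("DynamicFCN", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 3L || d[2] != d[3]) return("tensor must be K x N x N")
  if (d[1] != length(object@windowStarts)) return("windowStarts must have length K")
  if (length(object@roiLabels) != d[2]) return("roiLabels must have length N")
  if (!all(is.finite(object@tensor))) return("tensor contains non-finite values")
  if (max(abs(object@tensor)) > 1 + 1e-8) return("correlations must lie in [-1, 1]")
  for (k in seq_len(d[1])) {
    slice <- object@tensor[k, , ]
    if (max(abs(slice - t(slice))) > 1e-8) return("every slice must be symmetric")
    if (max(abs(diag(slice) - 1)) > 1e-8) return("every slice must have unit diagonal")
  }
  TRUE
})

#' @rdname DynamicFCN-class
#' @param x a DynamicFCN
#' @export
setMethod("roiLabels", "DynamicFCN", function(x) x@roiLabels)
#' @rdname DynamicFCN-class
#' @export
setMethod("subjectId", "DynamicFCN", function(x) x@subjectId)
#' @rdname DynamicFCN-class
#' @export
setMethod("groupLabel", "DynamicFCN", function(x) x@label)
#' @rdname DynamicFCN-class
#' @export
setMethod("scanId", "DynamicFCN", function(x) x@scanId)

setMethod("show", "DynamicFCN", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("DynamicFCN: K = %d windows of %d x %d correlations (w = %d, s = %d)\n",
              d[1], d[2], d[3], object@w, object@s))
  cat(sprintf("  subject: %s  scan: %s  label: %s\n",
              object@subjectId, object@scanId, object@label))
})

#' FCSeriesMatrix: vectorized dynamic FC series
#'
#' The P x K matrix of FC series, one row per ROI pair, where
#' P = N(N-1)/2.  Row p holds (FC_ij(1), ..., FC_ij(K)) for the pair in row
#' p of \code{pairIndex}.  Pairs are ordered row-major over the strict lower
#' triangle: (2,1), (3,1), (3,2), (4,1), ... in 1-based ROI indices
#' (i > j, rows of the matrix scanned top to bottom, each row left to right).
#'
#' @slot series numeric P x K matrix of FC series
#' @slot pairIndex integer P x 2 matrix, columns (i, j) with i > j (1-based)
#' @slot w,s window parameters carried from the source DynamicFCN
#' @slot roiLabels,subjectId,scanId,label scan annotation carried through
#'
#' @aliases fcSeries pairIndex
#' @export
setClass("FCSeriesMatrix",
  representation(
    series = "matrix",
    pairIndex = "matrix",
    w = "integer",
    s = "integer",
    roiLabels = "character",
    subjectId = "character",
    scanId = "character",
    label = "character"
  )
)

setValidity("FCSeriesMatrix", function(object) {
  n <- length(object@roiLabels)
  p <- n * (n - 1L) / 2L
  if (nrow(object@series) != p) return("series must have N(N-1)/2 rows")
  if (nrow(object@pairIndex) != p || ncol(object@pairIndex) != 2L) {
    return("pairIndex must be a P x 2 matrix")
  }
  if (!all(object@pairIndex[, 1] > object@pairIndex[, 2])) {
    return("pairIndex rows must satisfy i > j")
  }
  if (!all(is.finite(object@series))) return("series contains non-finite values")
  TRUE
})

#' @rdname FCSeriesMatrix-class
#' @export
setMethod("fcSeries", "FCSeriesMatrix", function(x) x@series)
#' @rdname FCSeriesMatrix-class
#' @export
setMethod("pairIndex", "FCSeriesMatrix", function(x) x@pairIndex)
#' @rdname FCSeriesMatrix-class
#' @export
setMethod("roiLabels", "FCSeriesMatrix", function(x) x@roiLabels)
#' @rdname FCSeriesMatrix-class
#' @export
setMethod("subjectId", "FCSeriesMatrix", function(x) x@subjectId)
#' @rdname FCSeriesMatrix-class
#' @export
setMethod("groupLabel", "FCSeriesMatrix", function(x) x@label)
#' @rdname FCSeriesMatrix-class
#' @export
setMethod("scanId", "FCSeriesMatrix", function(x) x@scanId)
#' @rdname FCSeriesMatrix-class
#' @export
setMethod("dim", "FCSeriesMatrix", function(x) dim(x@series))

setMethod("show", "FCSeriesMatrix", function(object) {
  d <- dim(object@series)
  cat(sprintf("%s: P = %d ROI pairs x K = %d windows (N = %d ROIs)\n",
              class(object), d[1], d[2], length(object@roiLabels)))
  cat(sprintf("  subject: %s  scan: %s  label: %s\n",
              object@subjectId, object@scanId, object@label))
})

#' WeightedFCSeries: self-attention weighted FC series
#'
#' Same layout as \linkS4class{FCSeriesMatrix}; produced by \code{\link{attend}}.
#' The attention output has exactly the input's P x K shape, so both classes
#' share all accessors and every similarity operation accepts either.
#'
#' @export
setClass("WeightedFCSeries", contains = "FCSeriesMatrix")

# pair ordering -------------------------------------------------------------

# Row-major scan of the strict lower triangle: i = 2..N, j = 1..(i-1).
.pairIndexFor <- function(N) {
  N <- as.integer(N)
  cbind(i = rep(2:N, 1:(N - 1L)), j = sequence(1:(N - 1L)))
}

# operations ----------------------------------------------------------------

#' Enumerate sliding-window offsets
#'
#' Returns the 0-based window start offsets 0, s, 2s, ... such that each
#' half-open window [o, o+w) fits within M time points.  The number of
#' offsets is K = floor((M - w)/s) + 1; trailing time points not covered by
#' any full window are dropped.
#'
#' @param M number of time points
#' @param cfg a \linkS4class{SlidingWindowConfig}
#' @return integer vector of 0-based offsets
#' @examples
#' length(enumerateWindows(137, slidingWindowConfig(30, 2)))  # 54
#' @export
enumerateWindows <- function(M, cfg = slidingWindowConfig()) {
  stopifnot(is(cfg, "SlidingWindowConfig"))
  M <- as.integer(M)
  if (cfg@w > M) {
    .configError(sprintf("window length w = %d exceeds series length M = %d",
                         cfg@w, M))
  }
  seq.int(0L, M - cfg@w, by = cfg@s)
}

#' Short-term functional connectivity for one window
#'
#' Pearson correlation matrix of the ROI sub-series over the half-open
#' window [offset, offset + w).  ROIs with zero variance inside the window
#' make the correlation undefined; those entries are set to 0 (a neutral
#' value for downstream cosine similarity) with a warning.
#'
#' @param x a \linkS4class{RoiTimeSeries}
#' @param offset 0-based window start
#' @param w window length in time points
#' @return symmetric N x N correlation matrix with unit diagonal
#' @export
shortTermFC <- function(x, offset, w) {
  stopifnot(is(x, "RoiTimeSeries"))
  M <- ncol(x@values)
  offset <- as.integer(offset); w <- as.integer(w)
  if (offset < 0L || offset + w > M) {
    .configError(sprintf("window [%d, %d) outside 0..%d", offset, offset + w, M))
  }
  sub <- x@values[, (offset + 1L):(offset + w), drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  C <- suppressWarnings(stats::cor(t(sub)))
  if (any(sds == 0)) {
    warning("zero-variance window sub-series; affected FC entries set to 0")
    C[sds == 0, ] <- 0
    C[, sds == 0] <- 0
  }
  C[!is.finite(C)] <- 0
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(x@roiLabels, x@roiLabels)
  C
}

#' Build a dynamic functional connectivity network
#'
#' Stacks \code{\link{shortTermFC}} over all \code{\link{enumerateWindows}}
#' offsets in chronological order.
#'
#' @param x a \linkS4class{RoiTimeSeries}
#' @param cfg a \linkS4class{SlidingWindowConfig}
#' @return a \linkS4class{DynamicFCN}
#' @export
buildDynamicFCN <- function(x, cfg = slidingWindowConfig()) {
  stopifnot(is(x, "RoiTimeSeries"))
  offsets <- enumerateWindows(ncol(x@values), cfg)
  N <- nrow(x@values)
  tens <- array(NA_real_, dim = c(length(offsets), N, N))
  for (k in seq_along(offsets)) {
    tens[k, , ] <- shortTermFC(x, offsets[k], cfg@w)
  }
  new("DynamicFCN", tensor = tens, windowStarts = offsets,
      w = cfg@w, s = cfg@s, roiLabels = x@roiLabels,
      subjectId = x@subjectId, scanId = x@scanId, label = x@label)
}

#' @rdname vectorizeLowerTriangle
#' @export
setMethod("vectorizeLowerTriangle", "DynamicFCN", function(d) {
  dd <- dim(d@tensor)
  K <- dd[1]; N <- dd[2]
  pairs <- .pairIndexFor(N)
  lin <- (pairs[, 2] - 1L) * N + pairs[, 1]  # column-major index of (i, j)
  series <- matrix(NA_real_, nrow = nrow(pairs), ncol = K)
  for (k in seq_len(K)) {
    series[, k] <- d@tensor[k, , ][lin]
  }
  new("FCSeriesMatrix", series = series, pairIndex = pairs,
      w = d@w, s = d@s, roiLabels = d@roiLabels,
      subjectId = d@subjectId, scanId = d@scanId, label = d@label)
})

#' Reconstruct one short-term FCN slice from vectorized FC series
#'
#' Inverse of \code{\link{vectorizeLowerTriangle}} for window k: refolds
#' column k of the series into a symmetric N x N matrix with unit diagonal.
#'
#' @param fcm a \linkS4class{FCSeriesMatrix}
#' @param k window index (1-based)
#' @return symmetric N x N matrix
#' @export
reconstructSlice <- function(fcm, k) {
  stopifnot(is(fcm, "FCSeriesMatrix"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(fcm@series)) .inputError("window index k out of range")
  N <- length(fcm@roiLabels)
  m <- diag(1, N)
  m[fcm@pairIndex] <- fcm@series[, k]
  m[fcm@pairIndex[, c(2, 1)]] <- fcm@series[, k]
  dimnames(m) <- list(fcm@roiLabels, fcm@roiLabels)
  m
}

#' @rdname meanFCFeatures
#' @export
setMethod("meanFCFeatures", "FCSeriesMatrix", function(x) {
  feats <- rowMeans(x@series)
  names(feats) <- paste(x@roiLabels[x@pairIndex[, 1]],
                        x@roiLabels[x@pairIndex[, 2]], sep = "~")
  feats
})
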