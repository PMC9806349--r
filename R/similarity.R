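# Pairwise FC-series similarity between subjects: per-ROI-pair cosine,
# subject-level aggregation, average similarity matrices, and
# discriminative ROI-pair ranking.

.checkSameLayout <- function(a, b) {
  if (!identical(dim(a@series), dim(b@series)) ||
      !identical(a@pairIndex, b@pairIndex)) {
    .configError("inputs must share P, K and ROI-pair order")
  }
}

# row-wise cosine between two P x K matrices; zero-norm rows -> 0
.rowCosine <- function(A, B, warn = TRUE) {
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  denom <- na * nb
  bad <- denom == 0
  if (any(bad) && warn) {
    warning("zero-norm FC series; affected cosine similarities set to 0")
  }
  denom[bad] <- 1
  v <- rowSums(A * B) / denom
  v[bad] <- 0
  pmin(pmax(v, -1), 1)
}

#' Per-ROI-pair cosine similarity between two subjects
#'
#' Element p is the cosine similarity between the length-K FC series of ROI
#' pair p in the two inputs.  Zero-norm series make the cosine undefined;
#' those entries are set to 0 with a warning.  The cosine is invariant to
#' any permutation of the K windows applied jointly to both inputs, so the
#' comparison does not require phase alignment of the window sequence.
#'
#' @param a,b \linkS4class{FCSeriesMatrix} or \linkS4class{WeightedFCSeries}
#'   objects with identical layout (same P, K, pair order)
#' @return numeric vector of length P in [-1, 1], with the pair index
#'   attached as attribute \code{"pairIndex"}
#' @export
pairwiseCosine <- function(a, b) {
  stopifnot(is(a, "FCSeriesMatrix"), is(b, "FCSeriesMatrix"))
  .checkSameLayout(a, b)
  v <- .rowCosine(a@series, b@series)
  attr(v, "pairIndex") <- a@pairIndex
  v
}

#' Aggregate per-pair similarities into one subject-level similarity
#'
#' The mean aggregation (default) normalizes the subject similarity to
#' [-1, 1] so the contrastive margin is independent of the number of ROI
#' pairs; \code{"sum"} gives the plain summed similarity over all P pairs.
#'
#' @param psv numeric vector of per-pair cosine similarities
#' @param aggregation \code{"mean"} or \code{"sum"}
#' @return a single numeric similarity
#' @export
subjectSimilarity <- function(psv, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "mean") mean(psv) else sum(psv)
}

#' Average similarity matrix between query and support subjects
#'
#' For every ROI pair, the mean cosine similarity over all (query, support)
#' combinations, refolded into a symmetric N x N matrix (diagonal set to 1;
#' self-FC is not part of the pair set).
#'
#' @param queries,supports non-empty lists of layout-compatible
#'   \linkS4class{FCSeriesMatrix}/\linkS4class{WeightedFCSeries} objects
#' @return symmetric N x N matrix with ROI labels as dimnames
#' @export
averageSimilarityMatrix <- function(queries, supports) {
  if (length(queries) == 0L || length(supports) == 0L) {
    .inputError("queries and supports must be non-empty lists")
  }
  acc <- 0
  for (q in queries) {
    for (su in supports) {
      .checkSameLayout(q, su)
      acc <- acc + .rowCosine(q@series, su@series)
    }
  }
  meanCos <- acc / (length(queries) * length(supports))
  ref <- queries[[1L]]
  N <- length(ref@roiLabels)
  m <- diag(1, N)
  m[ref@pairIndex] <- meanCos
  m[ref@pairIndex[, c(2, 1)]] <- meanCos
  dimnames(m) <- list(ref@roiLabels, ref@roiLabels)
  m
}

# per-pair mean cosine over all (query, support) combinations
.meanPairCosine <- function(queries, supports) {
  acc <- 0
  for (q in queries) for (su in supports) {
    .checkSameLayout(q, su)
    acc <- acc + .rowCosine(q@series, su@series, warn = FALSE)
  }
  acc / (length(queries) * length(supports))
}

#' Rank discriminative ROI pairs
#'
#' For each support class, computes the per-pair mean similarity of NC
#' queries versus that support set and of patient queries versus the same
#' support set.  Each ROI pair is scored by the absolute
#' patient-minus-NC difference, averaged over the two support classes;
#' signed per-support-class differences are reported alongside.  Ties are
#' broken by pair order.
#'
#' @param ncQueries,patientQueries,ncSupports,patientSupports non-empty
#'   lists of layout-compatible FC series objects
#' @param topK number of top-scoring pairs to return (default 10)
#' @return data.frame with columns roi_i, roi_j, score,
#'   diff_vs_nc_support, diff_vs_patient_support, ordered by
#'   decreasing score
#' @export
rankDiscriminativePairs <- function(ncQueries, patientQueries,
                                    ncSupports, patientSupports,
                                    topK = 10L) {
  lists <- list(ncQueries, patientQueries, ncSupports, patientSupports)
  if (any(vapply(lists, length, 1L) == 0L)) {
    .inputError("all four query/support lists must be non-empty")
  }
  dNC  <- .meanPairCosine(patientQueries, ncSupports) -
          .meanPairCosine(ncQueries, ncSupports)
  dPat <- .meanPairCosine(patientQueries, patientSupports) -
          .meanPairCosine(ncQueries, patientSupports)
  score <- (abs(dNC) + abs(dPat)) / 2
  ref <- ncQueries[[1L]]
  ord <- order(-score, seq_along(score))
  top <- utils::head(ord, as.integer(topK))
  data.frame(
    roi_i = ref@roiLabels[ref@pairIndex[top, 1]],
    roi_j = ref@roiLabels[ref@pairIndex[top, 2]],
    score = score[top],
    diff_vs_nc_support = dNC[top],
    diff_vs_patient_support = dPat[top],
    stringsAsFactors = FALSE
  )
}
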