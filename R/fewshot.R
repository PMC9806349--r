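# Episodic 2-way K-shot evaluation: subject-level cohort splitting,
# support/query episode construction, similarity-based query
# classification and ACC/SPE/PPV/NPV reporting.
#
# The positive class is "patient" (eMCI), so TP counts correctly detected
# patients and SPE is the NC-side accuracy.

#' Episode: one 2-way K-shot evaluation round
#'
#' @slot support list of \linkS4class{FCSeriesMatrix} scans, exactly n_shot
#'   per class
#' @slot query list of query scans to classify
#' @export
setClass("Episode", representation(support = "list", query = "list"))

setValidity("Episode", function(object) {
  supLab <- vapply(object@support, groupLabel, "")
  counts <- table(supLab)
  if (length(counts) != 2L) return("support must contain exactly two classes")
  if (length(unique(counts)) != 1L) return("support classes must have equal counts")
  supIds <- vapply(object@support, scanId, "")
  quIds <- vapply(object@query, scanId, "")
  if (length(intersect(supIds, quIds)) > 0L) {
    return("a scan appears in both support and query")
  }
  TRUE
})

setMethod("show", "Episode", function(object) {
  cat(sprintf("Episode: %d support, %d query scans\n",
              length(object@support), length(object@query)))
})

#' ConfusionCounts: binary confusion-matrix counts
#'
#' @slot TP,TN,FP,FN nonnegative integer counts; positive class = patient
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", TN = "integer", FP = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be nonnegative integers")
  TRUE
})

#' @param TP,TN,FP,FN nonnegative integer counts
#' @rdname ConfusionCounts-class
#' @export
confusionCounts <- function(TP = 0L, TN = 0L, FP = 0L, FN = 0L) {
  new("ConfusionCounts", TP = as.integer(TP), TN = as.integer(TN),
      FP = as.integer(FP), FN = as.integer(FN))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d\n",
              object@TP, object@TN, object@FP, object@FN))
})

#' MetricsReport: ACC, SPE, PPV and NPV with their confusion counts
#'
#' Metrics with a zero denominator are NA (undefined), never an error.
#'
#' @slot counts the \linkS4class{ConfusionCounts} the metrics derive from
#' @slot ACC,SPE,PPV,NPV metric values in [0, 1], or NA when undefined
#' @export
setClass("MetricsReport",
  representation(counts = "ConfusionCounts", ACC = "numeric", SPE = "numeric",
                 PPV = "numeric", NPV = "numeric"))

setMethod("show", "MetricsReport", function(object) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("MetricsReport: ACC=%s SPE=%s PPV=%s NPV=%s (n=%d)\n",
              fmt(object@ACC), fmt(object@SPE), fmt(object@PPV), fmt(object@NPV),
              object@counts@TP + object@counts@TN +
                object@counts@FP + object@counts@FN))
})

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SPE = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN).  A zero denominator yields NA for that metric.
#'
#' @param counts a \linkS4class{ConfusionCounts} with at least one count
#' @return a \linkS4class{MetricsReport}
#' @export
computeMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@TP; tn <- counts@TN; fp <- counts@FP; fn <- counts@FN
  if (tp + tn + fp + fn == 0L) .inputError("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  new("MetricsReport", counts = counts,
      ACC = ratio(tp + tn, tp + tn + fp + fn),
      SPE = ratio(tn, tn + fp),
      PPV = ratio(tp, tp + fp),
      NPV = ratio(tn, tn + fn))
}

#' Subject-level stratified cohort split
#'
#' Splits a cohort of scans into train/validation/test parts at the subject
#' level (all scans of one subject land in the same part, preventing
#' leakage), stratified by class, with largest-remainder rounding of the
#' per-class subject counts.
#'
#' @param cohort list of labeled scans (\linkS4class{RoiTimeSeries} or
#'   \linkS4class{FCSeriesMatrix})
#' @param fractions length-3 positive numeric summing to 1
#'   (train, validation, test)
#' @param seed integer RNG seed
#' @return list with elements \code{train}, \code{validation}, \code{test}
#' @export
splitCohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    .configError("fractions must be three positive numbers summing to 1")
  }
  subj <- vapply(cohort, subjectId, "")
  lab <- vapply(cohort, groupLabel, "")
  subjLab <- vapply(split(lab, subj), function(v) v[1L], "")
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  withr::with_seed(as.integer(seed), {
    for (cls in sort(unique(subjLab))) {
      ids <- sample(names(subjLab)[subjLab == cls])
      n <- length(ids)
      exact <- n * fractions
      base <- floor(exact)
      rem <- exact - base
      extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
      base[extra] <- base[extra] + 1L
      if (any(base == 0L)) {
        .inputError(sprintf(
          "class '%s' has too few subjects (%d) to populate all three parts",
          cls, n))
      }
      assign1 <- rep(1:3, times = base)
      for (p in 1:3) {
        chosen <- ids[assign1 == p]
        parts[[p]] <- c(parts[[p]], which(subj %in% chosen))
      }
    }
  })
  lapply(parts, function(idx) cohort[sort(idx)])
}

#' Build 2-way K-shot episodes
#'
#' Each episode draws exactly \code{nShot} support scans per class and up to
#' \code{nQuery} query scans per class from the remaining scans; a scan
#' never appears in both sets of the same episode.
#'
#' @param cohort list of labeled \linkS4class{FCSeriesMatrix} scans
#' @param nShot support scans per class
#' @param nQuery query scans per class (fewer are used when not available)
#' @param nEpisodes number of episodes
#' @param seed integer RNG seed
#' @return list of \linkS4class{Episode} objects
#' @export
buildEpisodes <- function(cohort, nShot = 5L, nQuery = 5L, nEpisodes = 50L,
                          seed = 1L) {
  lab <- vapply(cohort, groupLabel, "")
  classes <- split(seq_along(cohort), lab)
  if (length(classes) != 2L) .inputError("cohort must contain exactly two classes")
  short <- vapply(classes, length, 1L) < nShot + 1L
  if (any(short)) {
    .inputError(sprintf(
      "class '%s' has too few scans for %d-shot episodes with a query set",
      names(classes)[short][1L], nShot))
  }
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nEpisodes), function(e) {
      supIdx <- integer(0); quIdx <- integer(0)
      for (cls in classes) {
        sup <- sample(cls, nShot)
        rest <- setdiff(cls, sup)
        qu <- if (length(rest) > nQuery) sample(rest, nQuery) else rest
        supIdx <- c(supIdx, sup); quIdx <- c(quIdx, qu)
      }
      new("Episode", support = cohort[supIdx], query = cohort[quIdx])
    })
  })
}

#' Classify one query scan within an episode
#'
#' Computes the aggregated similarity between the query and every support
#' scan (after attention weighting when \code{params} is supplied) and
#' predicts the class whose supports are most similar: under the default
#' \code{"meanSimilarity"} rule the class with the greater mean similarity,
#' under \code{"nearestSupport"} the class of the single most similar
#' support scan.  Exact ties go to "NC".
#'
#' @param q query \linkS4class{FCSeriesMatrix}
#' @param episode an \linkS4class{Episode}
#' @param params \linkS4class{AttentionParams}, or NULL to compare raw FC
#'   series (ablation)
#' @param aggregation \code{"mean"} or \code{"sum"}
#' @param rule decision rule
#' @return predicted label, \code{"NC"} or \code{"patient"}
#' @export
classifyQuery <- function(q, episode, params = NULL,
                          aggregation = c("mean", "sum"),
                          rule = c("meanSimilarity", "nearestSupport")) {
  aggregation <- match.arg(aggregation)
  rule <- match.arg(rule)
  wq <- if (is.null(params)) q else attend(q, params)
  sims <- vapply(episode@support, function(su) {
    ws <- if (is.null(params)) su else attend(su, params)
    subjectSimilarity(pairwiseCosine(wq, ws), aggregation)
  }, 0)
  supLab <- vapply(episode@support, groupLabel, "")
  scorePer <- if (rule == "meanSimilarity") {
    tapply(sims, supLab, mean)
  } else {
    tapply(sims, supLab, max)
  }
  patScore <- scorePer[["patient"]]
  ncScore <- scorePer[["NC"]]
  if (patScore > ncScore) "patient" else "NC"
}

# Flatten each scan's (weighted) series into a row-normalized vector so the
# mean-aggregated subject similarity between scans a and b is the plain dot
# product of their vectors divided by P (or times 1 for "sum").
.similarityMatrix <- function(cohort, params, aggregation) {
  stopifnot(length(cohort) > 0L)
  X <- vapply(cohort, function(sc) {
    S <- if (is.null(params)) sc@series else attend(sc, params)@series
    nrm <- sqrt(rowSums(S^2))
    nrm[nrm == 0] <- Inf       # zero-norm rows contribute cosine 0
    as.vector(S / nrm)
  }, numeric(nrow(cohort[[1L]]@series) * ncol(cohort[[1L]]@series)))
  S <- crossprod(X)
  if (aggregation == "mean") S / nrow(cohort[[1L]]@series) else S
}

#' Episodic few-shot evaluation
#'
#' Builds \code{nEpisodes} 2-way \code{nShot}-shot episodes from the test
#' cohort, classifies every query scan, pools the confusion counts over all
#' episodes (micro-average) and also reports the per-episode accuracy
#' distribution (macro mean and sd).
#'
#' @param cohort list of labeled \linkS4class{FCSeriesMatrix} scans
#'   (typically the test split)
#' @param params trained \linkS4class{AttentionParams}, or NULL for the
#'   unweighted ablation
#' @param nShot,nQuery,nEpisodes,seed episode protocol settings
#' @param aggregation \code{"mean"} or \code{"sum"}
#' @param rule decision rule, see \code{\link{classifyQuery}}
#' @param decisionFun optional function(queryIndex, episode) -> label
#'   overriding the similarity classifier (used for calibration checks)
#' @return list with elements \code{pooled} (a
#'   \linkS4class{MetricsReport}), \code{perEpisode} (data.frame of
#'   per-episode counts and ACC) and \code{macro} (mean and sd of
#'   per-episode ACC)
#' @export
evaluateFewShot <- function(cohort, params, nShot = 5L, nQuery = 5L,
                            nEpisodes = 50L, seed = 1L,
                            aggregation = c("mean", "sum"),
                            rule = c("meanSimilarity", "nearestSupport"),
                            decisionFun = NULL) {
  aggregation <- match.arg(aggregation)
  rule <- match.arg(rule)
  episodes <- buildEpisodes(cohort, nShot, nQuery, nEpisodes, seed)
  ids <- vapply(cohort, scanId, "")
  simMat <- if (is.null(decisionFun)) {
    .similarityMatrix(cohort, params, aggregation)
  }
  per <- data.frame(episode = seq_along(episodes), TP = 0L, TN = 0L,
                    FP = 0L, FN = 0L, ACC = NA_real_)
  for (e in seq_along(episodes)) {
    ep <- episodes[[e]]
    supIdx <- match(vapply(ep@support, scanId, ""), ids)
    supLab <- vapply(ep@support, groupLabel, "")
    tp <- tn <- fp <- fn <- 0L
    for (qi in seq_along(ep@query)) {
      truth <- groupLabel(ep@query[[qi]])
      pred <- if (!is.null(decisionFun)) {
        decisionFun(qi, ep)
      } else {
        qIdx <- match(scanId(ep@query[[qi]]), ids)
        sims <- simMat[qIdx, supIdx]
        scorePer <- if (rule == "meanSimilarity") {
          tapply(sims, supLab, mean)
        } else {
          tapply(sims, supLab, max)
        }
        if (scorePer[["patient"]] > scorePer[["NC"]]) "patient" else "NC"
      }
      if (truth == "patient" && pred == "patient") tp <- tp + 1L
      else if (truth == "NC" && pred == "NC") tn <- tn + 1L
      else if (truth == "NC" && pred == "patient") fp <- fp + 1L
      else fn <- fn + 1L
    }
    per[e, c("TP", "TN", "FP", "FN")] <- c(tp, tn, fp, fn)
    per$ACC[e] <- (tp + tn) / (tp + tn + fp + fn)
  }
  pooled <- computeMetrics(confusionCounts(sum(per$TP), sum(per$TN),
                                           sum(per$FP), sum(per$FN)))
  list(pooled = pooled, perEpisode = per,
       macro = c(meanACC = mean(per$ACC), sdACC = stats::sd(per$ACC)))
}
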