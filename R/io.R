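# Plain-text readers and writers: per-scan TSV/CSV tables, cohort
# manifests, array containers with JSON sidecars, metrics and ranked-pair
# tables.

.readTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read one ROI-by-time scan table
#'
#' Expects a TSV (or CSV) table with a header, the first column holding ROI
#' labels and the remaining columns the time points.  Non-numeric cells are
#' reported with file, row and column.
#'
#' @param path scan file
#' @param subjectId,scanId,label annotation attached to the scan; scanId
#'   defaults to the file name without extension
#' @return a \linkS4class{RoiTimeSeries}
#' @export
readScan <- function(path, subjectId = "subject",
                     scanId = sub("\\.[^.]+$", "", basename(path)),
                     label = "unknown") {
  if (!file.exists(path)) .ioError(sprintf("scan file not found: %s", path))
  tab <- tryCatch(.readTable(path), error = function(e) {
    .ioError(sprintf("cannot parse scan file %s: %s", path, conditionMessage(e)))
  })
  if (ncol(tab) < 3L) .ioError(sprintf("scan file %s has fewer than 2 time points", path))
  labels <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in 2:ncol(tab)) {
      num <- suppressWarnings(as.numeric(tab[[j]]))
      bad <- which(is.na(num) & !is.na(tab[[j]]))
      if (length(bad)) {
        .ioError(sprintf("non-numeric value '%s' in %s (row %d, column %d)",
                         tab[[j]][bad[1L]], path, bad[1L], j))
      }
    }
    storage.mode(vals) <- "double"
  }
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    .ioError(sprintf("missing or non-finite value in %s (row %d, column %d)",
                     path, bad[1L], bad[2L] + 1L))
  }
  RoiTimeSeries(vals, roiLabels = labels, subjectId = subjectId,
                scanId = scanId, label = label)
}

#' Read a labeled cohort from a manifest
#'
#' The manifest (TSV or CSV) must provide columns \code{subject_id},
#' \code{path} and \code{label} (\code{"NC"} or \code{"patient"});
#' an optional \code{scan_id} column names individual scans.  Relative
#' paths are resolved against the manifest's directory.  All scans must
#' share the same ROI count and labels.
#'
#' @param manifestPath manifest file
#' @return list of \linkS4class{RoiTimeSeries}
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath)) {
    .ioError(sprintf("manifest not found: %s", manifestPath))
  }
  man <- .readTable(manifestPath)
  needed <- c("subject_id", "path", "label")
  missing <- setdiff(needed, names(man))
  if (length(missing)) {
    .ioError(sprintf("manifest %s lacks column(s): %s", manifestPath,
                     paste(missing, collapse = ", ")))
  }
  if (!all(man$label %in% c("NC", "patient"))) {
    badLab <- setdiff(unique(man$label), c("NC", "patient"))
    .ioError(sprintf("unknown label(s) in manifest: %s",
                     paste(badLab, collapse = ", ")))
  }
  base <- dirname(manifestPath)
  scans <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    p <- man$path[k]
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) {
      .ioError(sprintf("manifest references missing file: %s", man$path[k]))
    }
    sid <- if ("scan_id" %in% names(man)) man$scan_id[k] else NULL
    scans[[k]] <- readScan(p, subjectId = man$subject_id[k],
                           scanId = if (is.null(sid)) {
                             sub("\\.[^.]+$", "", basename(p))
                           } else sid,
                           label = man$label[k])
  }
  ns <- vapply(scans, function(s) nrow(s@values), 1L)
  if (length(unique(ns)) != 1L) {
    .ioError(sprintf("inconsistent ROI count across cohort: %s",
                     paste(unique(ns), collapse = ", ")))
  }
  scans
}

# array containers -----------------------------------------------------------

#' Write an FCSeriesMatrix to TSV plus JSON sidecar
#'
#' The series go to \code{<prefix>.tsv} (full precision, one row per ROI
#' pair) and the layout metadata (N, K, w, s, pair order convention, ROI
#' labels, annotation) to \code{<prefix>.json}.
#'
#' @param fcm a \linkS4class{FCSeriesMatrix}
#' @param prefix output path prefix
#' @return \code{prefix}, invisibly
#' @export
writeFCSeriesMatrix <- function(fcm, prefix) {
  stopifnot(is(fcm, "FCSeriesMatrix"))
  lines <- vapply(seq_len(nrow(fcm@series)), function(p) {
    paste(sprintf("%.17g", fcm@series[p, ]), collapse = "\t")
  }, "")
  writeLines(lines, paste0(prefix, ".tsv"))
  jsonlite::write_json(list(
    N = length(fcm@roiLabels), P = nrow(fcm@series), K = ncol(fcm@series),
    w = fcm@w, s = fcm@s, pairOrder = "row-major lower triangle, i > j",
    roiLabels = fcm@roiLabels, subjectId = fcm@subjectId,
    scanId = fcm@scanId, label = fcm@label,
    weighted = is(fcm, "WeightedFCSeries")
  ), paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' Read an FCSeriesMatrix written by \code{\link{writeFCSeriesMatrix}}
#'
#' @param prefix path prefix used when writing
#' @return a \linkS4class{FCSeriesMatrix} (or \linkS4class{WeightedFCSeries})
#' @export
readFCSeriesMatrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  series <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(series) <- NULL
  cls <- if (isTRUE(meta$weighted)) "WeightedFCSeries" else "FCSeriesMatrix"
  new(cls, series = series, pairIndex = .pairIndexFor(meta$N),
      w = as.integer(meta$w), s = as.integer(meta$s),
      roiLabels = meta$roiLabels, subjectId = meta$subjectId,
      scanId = meta$scanId, label = meta$label)
}

#' Write a DynamicFCN to TSV plus JSON sidecar
#'
#' The K N x N slices are stacked row-wise into a (K N) x N table.
#'
#' @param d a \linkS4class{DynamicFCN}
#' @param prefix output path prefix
#' @return \code{prefix}, invisibly
#' @export
writeDynamicFCN <- function(d, prefix) {
  stopifnot(is(d, "DynamicFCN"))
  dd <- dim(d@tensor)
  stacked <- matrix(aperm(d@tensor, c(2, 1, 3)), nrow = dd[1] * dd[2])
  lines <- vapply(seq_len(nrow(stacked)), function(r) {
    paste(sprintf("%.17g", stacked[r, ]), collapse = "\t")
  }, "")
  writeLines(lines, paste0(prefix, ".tsv"))
  jsonlite::write_json(list(
    K = dd[1], N = dd[2], w = d@w, s = d@s, windowStarts = d@windowStarts,
    roiLabels = d@roiLabels, subjectId = d@subjectId, scanId = d@scanId,
    label = d@label
  ), paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a DynamicFCN written by \code{\link{writeDynamicFCN}}
#'
#' @param prefix path prefix used when writing
#' @return a \linkS4class{DynamicFCN}
#' @export
readDynamicFCN <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stacked <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(stacked) <- NULL
  tens <- aperm(array(stacked, dim = c(meta$N, meta$K, meta$N)), c(2, 1, 3))
  new("DynamicFCN", tensor = tens,
      windowStarts = as.integer(meta$windowStarts),
      w = as.integer(meta$w), s = as.integer(meta$s),
      roiLabels = meta$roiLabels, subjectId = meta$subjectId,
      scanId = meta$scanId, label = meta$label)
}

# result tables ---------------------------------------------------------------

#' Write a similarity matrix as TSV with ROI labels on both axes
#'
#' @param m symmetric matrix with dimnames (e.g. from
#'   \code{\link{averageSimilarityMatrix}})
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeSimilarityMatrix <- function(m, path) {
  utils::write.table(format(m, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write a ranked ROI-pair table as TSV
#'
#' @param ranked data.frame from \code{\link{rankDiscriminativePairs}}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeRankedPairs <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a metrics report (plus protocol metadata) as JSON
#'
#' @param report list as returned by \code{\link{evaluateFewShot}}
#' @param path output file
#' @param extra optional named list merged into the JSON object
#' @return \code{path}, invisibly
#' @export
writeMetricsJSON <- function(report, path, extra = list()) {
  pooled <- report$pooled
  payload <- c(list(
    pooled = list(
      ACC = pooled@ACC, SPE = pooled@SPE, PPV = pooled@PPV, NPV = pooled@NPV,
      TP = pooled@counts@TP, TN = pooled@counts@TN,
      FP = pooled@counts@FP, FN = pooled@counts@FN
    ),
    macro = as.list(report$macro),
    perEpisodeACC = report$perEpisode$ACC
  ), extra)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Write (or append) a flat one-row TSV metrics record
#'
#' One row per run with columns method, seed, ACC, SPE, PPV, NPV — handy
#' for collecting many runs into one table.
#'
#' @param report list as returned by \code{\link{evaluateFewShot}}
#' @param path output file; a header is written when the file is new
#' @param method method label for the row
#' @param seed seed recorded for the row
#' @return \code{path}, invisibly
#' @export
writeMetricsRow <- function(report, path, method = "siamfcn", seed = NA) {
  pooled <- report$pooled
  row <- data.frame(method = method, seed = seed, ACC = pooled@ACC,
                    SPE = pooled@SPE, PPV = pooled@PPV, NPV = pooled@NPV)
  fresh <- !file.exists(path)
  suppressWarnings(
    utils::write.table(row, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = fresh, append = !fresh))
  invisible(path)
}
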