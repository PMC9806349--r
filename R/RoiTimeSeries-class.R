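#' RoiTimeSeries: one scan's ROI-by-time BOLD matrix
#'
#' Container for a single resting-state scan after parcellation: an N x M
#' matrix whose rows are the mean BOLD time series of N regions of interest
#' (ROIs) at M sequential time points.  Group labels are \code{"NC"}
#' (normal control), \code{"patient"} (here, early MCI) or \code{"unknown"}.
#'
#' @slot values numeric N x M matrix, one row per ROI (arbitrary signal units)
#' @slot roiLabels character vector of N unique ROI names (e.g. AAL labels)
#' @slot subjectId subject identifier; several scans may share a subject
#' @slot scanId unique identifier of this scan
#' @slot label group label: "NC", "patient" or "unknown"
#'
#' @aliases roiLabels subjectId groupLabel scanId
#' @export
setClass("RoiTimeSeries",
  representation(
    values = "matrix",
    roiLabels = "character",
    subjectId = "character",
    scanId = "character",
    label = "character"
  )
)

setValidity("RoiTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L || ncol(v) < 2L) return("need at least 2 ROIs and 2 time points")
  if (!all(is.finite(v))) return("'values' contains non-finite entries")
  if (length(object@roiLabels) != nrow(v)) return("length(roiLabels) must equal the number of ROIs")
  if (anyDuplicated(object@roiLabels)) return("ROI labels must be unique")
  if (!object@label %in% c("NC", "patient", "unknown")) {
    return("label must be one of 'NC', 'patient', 'unknown'")
  }
  TRUE
})

#' @param values numeric N x M matrix (rows = ROIs, columns = time points)
#' @param roiLabels character vector of N unique ROI names; default ROI001...
#' @param subjectId subject identifier
#' @param scanId scan identifier; defaults to the subject id
#' @param label group label: "NC", "patient" or "unknown"
#' @return a \code{RoiTimeSeries}
#' @rdname RoiTimeSeries-class
#' @export
RoiTimeSeries <- function(values, roiLabels = NULL, subjectId = "subject",
                          scanId = subjectId, label = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  if (is.null(roiLabels)) roiLabels <- sprintf("ROI%03d", seq_len(nrow(values)))
  new("RoiTimeSeries", values = values, roiLabels = as.character(roiLabels),
      subjectId = as.character(subjectId), scanId = as.character(scanId),
      label = as.character(label))
}

#' @rdname RoiTimeSeries-class
#' @export
setMethod("roiLabels", "RoiTimeSeries", function(x) x@roiLabels)
#' @rdname RoiTimeSeries-class
#' @export
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)
#' @rdname RoiTimeSeries-class
#' @export
setMethod("groupLabel", "RoiTimeSeries", function(x) x@label)
#' @rdname RoiTimeSeries-class
#' @export
setMethod("scanId", "RoiTimeSeries", function(x) x@scanId)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("dim", "RoiTimeSeries", function(x) dim(x@values))

setMethod("show", "RoiTimeSeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiTimeSeries: %d ROIs x %d time points\n", d[1], d[2]))
  cat(sprintf("  subject: %s  scan: %s  label: %s\n",
              object@subjectId, object@scanId, object@label))
})

#' Sliding-window configuration
#'
#' Window length \code{w} and step \code{s}, both in time points.  The
#' default w = 30, s = 2 corresponds to a 90 s window advanced by 6 s at a
#' 3 s repetition time.
#'
#' @slot w window length (time points), at least 2
#' @slot s window step (time points), at least 1
#' @export
setClass("SlidingWindowConfig", representation(w = "integer", s = "integer"))

setValidity("SlidingWindowConfig", function(object) {
  if (length(object@w) != 1L || is.na(object@w) || object@w < 2L) {
    return("window length w must be a single integer >= 2")
  }
  if (length(object@s) != 1L || is.na(object@s) || object@s < 1L) {
    return("step s must be a single integer >= 1")
  }
  TRUE
})

#' @param w window length in time points
#' @param s window step in time points
#' @rdname SlidingWindowConfig-class
#' @export
slidingWindowConfig <- function(w = 30, s = 2) {
  new("SlidingWindowConfig", w = as.integer(w), s = as.integer(s))
}

setMethod("show", "SlidingWindowConfig", function(object) {
  cat(sprintf("SlidingWindowConfig: w = %d, s = %d (time points)\n",
              object@w, object@s))
})
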