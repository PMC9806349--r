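#' @import methods
NULL

#' @rdname RoiTimeSeries-class
#' @param x an object with ROI annotation
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))

#' @rdname FCSeriesMatrix-class
#' @param x an object carrying vectorized FC series
#' @export
setGeneric("fcSeries", function(x) standardGeneric("fcSeries"))

#' @rdname FCSeriesMatrix-class
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' Vectorize the lower triangle of a dynamic FCN
#'
#' @param d a \linkS4class{DynamicFCN}
#' @return a \linkS4class{FCSeriesMatrix}
#' @export
setGeneric("vectorizeLowerTriangle", function(d) standardGeneric("vectorizeLowerTriangle"))

#' Mean dynamic-FC feature vector
#'
#' @param x a \linkS4class{FCSeriesMatrix}
#' @return numeric vector of length P (one mean FC value per ROI pair)
#' @export
setGeneric("meanFCFeatures", function(x) standardGeneric("meanFCFeatures"))

#' Self-attention weighting of an FC-series matrix
#'
#' @param x a \linkS4class{FCSeriesMatrix}
#' @param params an \linkS4class{AttentionParams}
#' @return a \linkS4class{WeightedFCSeries}
#' @export
setGeneric("attend", function(x, params) standardGeneric("attend"))

#' @rdname TrainState-class
#' @param x a \linkS4class{TrainState}
#' @export
setGeneric("attentionParams", function(x) standardGeneric("attentionParams"))

#' @rdname TrainState-class
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

# internal condition helpers ------------------------------------------------

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "siamfcn_error")))
}

.configError <- function(msg) .err(msg, "siamfcn_config_error")
.inputError  <- function(msg) .err(msg, "siamfcn_input_error")
.ioError     <- function(msg) .err(msg, "siamfcn_io_error")
.trainError  <- function(msg) .err(msg, "siamfcn_training_error")
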