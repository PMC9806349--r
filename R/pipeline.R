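# Run configuration and the end-to-end pipeline: dynamic FCN construction,
# Siamese attention training, few-shot evaluation, similarity matrices and
# discriminative ROI-pair ranking, with every artifact written under one
# output directory.

#' Default run configuration
#'
#' Nested list of every pipeline setting with its default: sliding window
#' (w = 30, s = 2 time points), attention (d_k = K), contrastive loss
#' (margin 1, mean aggregation), training (Adam, learning rate 1e-3,
#' 50 epochs, 256 pairs), 2-way 5-shot protocol (5 queries per class,
#' 50 episodes, 60/20/20 subject-level split) and the synthetic-cohort
#' settings used when no manifest is given.  All randomness flows from the
#' named seeds.
#'
#' @return named nested list
#' @export
defaultRunConfig <- function() {
  list(
    window = list(w = 30L, s = 2L),
    attention = list(dk = NULL, seed = 11L),
    loss = list(margin = 0.5, aggregation = "mean"),
    training = list(learningRate = 1e-3, epochs = 50L, pairsPerEpoch = 256L,
                    balance = 0.5, resamplePairs = FALSE, evalEvery = 5L,
                    seed = 21L),
    protocol = list(nShot = 5L, nQuery = 5L, nEpisodes = 50L,
                    fractions = c(0.6, 0.2, 0.2), rule = "meanSimilarity",
                    seed = 31L),
    simulate = list(nRois = 20L, nTimepoints = 137L, nSubjectsPerGroup = 40L,
                    scansPerSubject = 2L, effectSize = 0.6, seed = 41L),
    paths = list(manifest = NULL, outDir = "siamfcn_results")
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML, filling unset values with defaults
#'
#' @param path YAML file; values present override
#'   \code{\link{defaultRunConfig}}
#' @return named nested list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .ioError(sprintf("config not found: %s", path))
  .mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

#' Write a run configuration as YAML
#'
#' @param config nested configuration list
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.cohortSpecFromConfig <- function(sim) {
  do.call(cohortSpec, sim[names(sim) %in% names(formals(cohortSpec))])
}

#' Run the full pipeline
#'
#' Loads (or simulates) a labeled cohort, builds the vectorized dynamic FC
#' series for every scan, splits the cohort at subject level, trains the
#' Siamese attention model on the training split, evaluates it in the
#' episodic few-shot protocol on the test split, computes the four
#' query/support average similarity matrices (NC/patient crossings, with
#' validation scans as supports and test scans as queries) and the
#' discriminative ROI-pair ranking, and writes all artifacts plus the
#' resolved configuration under \code{config$paths$outDir}.
#'
#' @param config nested configuration list
#'   (see \code{\link{defaultRunConfig}})
#' @param quiet suppress progress messages
#' @return invisibly, a list with the train state, evaluation report,
#'   similarity matrices, ranked pairs and the resolved config
#' @export
runPipeline <- function(config = defaultRunConfig(), quiet = FALSE) {
  config <- .mergeConfig(defaultRunConfig(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  scans <- if (!is.null(config$paths$manifest)) {
    readCohort(config$paths$manifest)
  } else {
    generateCohort(.cohortSpecFromConfig(config$simulate))$scans
  }
  wcfg <- slidingWindowConfig(config$window$w, config$window$s)
  M <- ncol(scans[[1L]]@values)
  offsets <- enumerateWindows(M, wcfg)  # fails fast when w > M
  labCount <- table(vapply(scans, groupLabel, ""))
  say("cohort: %s scans (%s), N = %d ROIs, M = %d time points, K = %d windows",
      length(scans), paste(names(labCount), labCount, sep = "=", collapse = ", "),
      nrow(scans[[1L]]@values), M, length(offsets))

  fcms <- lapply(scans, function(s) {
    vectorizeLowerTriangle(buildDynamicFCN(s, wcfg))
  })
  parts <- splitCohort(fcms, config$protocol$fractions, config$protocol$seed)
  say("split: %d train / %d validation / %d test scans",
      length(parts$train), length(parts$validation), length(parts$test))

  K <- ncol(fcms[[1L]]@series)
  dk <- if (is.null(config$attention$dk)) K else as.integer(config$attention$dk)
  init <- initAttentionParams(K, dk = dk, seed = config$attention$seed)
  state <- trainSiamese(
    parts$train, params = init,
    epochs = config$training$epochs,
    learningRate = config$training$learningRate,
    pairsPerEpoch = config$training$pairsPerEpoch,
    margin = config$loss$margin,
    aggregation = config$loss$aggregation,
    balance = config$training$balance,
    resamplePairs = isTRUE(config$training$resamplePairs),
    seed = config$training$seed,
    validation = parts$validation,
    evalEvery = config$training$evalEvery,
    valShot = config$protocol$nShot, valQuery = config$protocol$nQuery)
  say("training: mean pair loss %.5f -> %.5f",
      state@lossHistory[1L], state@lossHistory[length(state@lossHistory)])

  report <- evaluateFewShot(
    parts$test, attentionParams(state),
    nShot = config$protocol$nShot, nQuery = config$protocol$nQuery,
    nEpisodes = config$protocol$nEpisodes, seed = config$protocol$seed,
    aggregation = config$loss$aggregation, rule = config$protocol$rule)
  say("evaluation: pooled ACC %.3f over %d episodes",
      report$pooled@ACC, config$protocol$nEpisodes)

  weighted <- lapply(c(parts$validation, parts$test), attend,
                     params = attentionParams(state))
  lab <- vapply(weighted, groupLabel, "")
  nVal <- length(parts$validation)
  sup <- split(weighted[seq_len(nVal)], lab[seq_len(nVal)])
  qu <- split(weighted[nVal + seq_len(length(parts$test))],
              lab[nVal + seq_len(length(parts$test))])
  simMats <- list(
    nc_query_nc_support = averageSimilarityMatrix(qu$NC, sup$NC),
    nc_query_patient_support = averageSimilarityMatrix(qu$NC, sup$patient),
    patient_query_nc_support = averageSimilarityMatrix(qu$patient, sup$NC),
    patient_query_patient_support = averageSimilarityMatrix(qu$patient,
                                                            sup$patient)
  )
  ranked <- rankDiscriminativePairs(qu$NC, qu$patient, sup$NC, sup$patient,
                                    topK = 10L)

  outDir <- config$paths$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(config, file.path(outDir, "config.yaml"))
  writeAttentionParams(attentionParams(state),
                       file.path(outDir, "checkpoint.json"),
                       meta = list(lossHistory = state@lossHistory,
                                   training = state@config))
  writeMetricsRow(report, file.path(outDir, "metrics.tsv"),
                  seed = config$protocol$seed)
  writeMetricsJSON(report, file.path(outDir, "metrics.json"),
                   extra = list(seeds = list(
                     attention = config$attention$seed,
                     training = config$training$seed,
                     protocol = config$protocol$seed,
                     simulate = config$simulate$seed)))
  for (nm in names(simMats)) {
    writeSimilarityMatrix(simMats[[nm]],
                          file.path(outDir, paste0("similarity_", nm, ".tsv")))
  }
  writeRankedPairs(ranked, file.path(outDir, "ranked_pairs.tsv"))
  say("artifacts written under %s", outDir)
  invisible(list(state = state, report = report, similarity = simMats,
                 rankedPairs = ranked, config = config))
}
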