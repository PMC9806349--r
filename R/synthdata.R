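# Synthetic two-group BOLD cohort generator.
#
# Signal model: every scan is a latent-factor Gaussian mixture.  All latent
# components (one global factor, one factor per altered ROI pair, one
# idiosyncratic factor and one measurement-noise series per ROI) are white
# Gaussian series passed through the same unit-energy band-pass FIR filter,
# which leaves all instantaneous cross-correlations intact while giving the
# slow band-limited autocorrelation of BOLD.  ROI i is mixed as
#
#   x_i(t) = sqrt(b) g(t) + sum_p s_i sqrt(c_p(t)) h_p(t)
#            + sqrt(1 - b - sum_p c_p(t)) e_i(t) + sigma eps_i(t)
#
# with b the background coupling, c_p(t) the (optionally slowly
# oscillating) coupling planted at altered pair p in patient scans, and
# sigma the measurement noise.  The expected instantaneous correlation is
# then (b + c_p(t)) / (1 + sigma^2) at altered pairs of patient scans and
# b / (1 + sigma^2) everywhere else — a closed form the tests check by
# Monte Carlo.

#' CohortSpec: synthetic cohort specification
#'
#' Defines a two-group (NC vs patient) ROI BOLD cohort in which a designated
#' subset of ROI pairs carries group-dependent dynamic functional
#' connectivity.  Defaults emulate a desk-scale version of a 116-ROI
#' rs-fMRI cohort: 20 ROIs, 137 time points, background coupling 0.35
#' (mean pairwise FC in band-passed parcellated rs-fMRI is typically
#' 0.2-0.4), 5 altered pairs whose coupling is lowered by 0.6 in the
#' patient group (sign-reversing hypo-/anti-connectivity), and a
#' band-limited spectrum (band as fraction of Nyquist, matching a
#' 0.015-0.15 Hz pass band at a 3 s repetition time).
#'
#' @slot nRois number of ROIs (N)
#' @slot nTimepoints time points per scan (M)
#' @slot nSubjectsPerGroup subjects per group
#' @slot scansPerSubject scans per subject
#' @slot alteredPairs integer matrix of ROI pairs (columns i, j with i > j)
#'   whose coupling differs between groups
#' @slot effectSize group difference in latent coupling at altered pairs,
#'   in [0, 1]
#' @slot effectSign +1 (patient coupling = base + effect) or -1
#' @slot baseCoupling background latent coupling, in [0, 1)
#' @slot noiseSd measurement noise standard deviation (signal units)
#' @slot band band-pass edges as fractions of Nyquist, 0 < low < high < 1
#' @slot dynamicCoupling when TRUE (default) the planted coupling
#'   oscillates slowly over time, so FC *series* (not just their means)
#'   differ between groups
#' @slot couplingPeriod oscillation period of the planted coupling
#'   (time points)
#' @slot modulationDepth relative oscillation amplitude, in [0, 1]
#' @slot seed integer RNG seed
#' @export
setClass("CohortSpec",
  representation(
    nRois = "integer", nTimepoints = "integer",
    nSubjectsPerGroup = "integer", scansPerSubject = "integer",
    alteredPairs = "matrix", effectSize = "numeric", effectSign = "numeric",
    baseCoupling = "numeric", noiseSd = "numeric", band = "numeric",
    dynamicCoupling = "logical", couplingPeriod = "numeric",
    modulationDepth = "numeric", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (object@nRois < 2L || object@nTimepoints < 2L) {
    return("need at least 2 ROIs and 2 time points")
  }
  if (object@nSubjectsPerGroup < 1L || object@scansPerSubject < 1L) {
    return("need at least 1 subject per group and 1 scan per subject")
  }
  ap <- object@alteredPairs
  if (nrow(ap) > 0L) {
    if (ncol(ap) != 2L) return("alteredPairs must have two columns")
    if (any(ap < 1L) || any(ap > object@nRois)) return("alteredPairs out of ROI range")
    if (any(ap[, 1] <= ap[, 2])) return("alteredPairs rows must satisfy i > j")
    if (anyDuplicated(ap)) return("alteredPairs must be distinct")
  }
  if (object@effectSize < 0 || object@effectSize > 1) {
    return("effectSize must lie in [0, 1]")
  }
  if (!object@effectSign %in% c(-1, 1)) return("effectSign must be +1 or -1")
  if (object@baseCoupling < 0 || object@baseCoupling >= 1) {
    return("baseCoupling must lie in [0, 1)")
  }
  if (object@effectSize + object@baseCoupling > 1) {
    return("effectSize + baseCoupling must not exceed 1")
  }
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  if (length(object@band) != 2L || object@band[1] <= 0 ||
      object@band[2] <= object@band[1] || object@band[2] >= 1) {
    return("band must be 0 < low < high < 1 (fractions of Nyquist)")
  }
  if (object@modulationDepth < 0 || object@modulationDepth > 1) {
    return("modulationDepth must lie in [0, 1]")
  }
  if (object@couplingPeriod <= 0) return("couplingPeriod must be positive")
  TRUE
})

#' @param nRois,nTimepoints,nSubjectsPerGroup,scansPerSubject cohort shape
#' @param alteredPairs two-column matrix of ROI pairs; any order per row
#'   (normalized to i > j); default: five disjoint pairs among the first
#'   ten ROIs
#' @param effectSize,effectSign,baseCoupling,noiseSd,band coupling model
#' @param dynamicCoupling,couplingPeriod,modulationDepth temporal coupling
#'   dynamics
#' @param seed integer RNG seed
#' @rdname CohortSpec-class
#' @export
cohortSpec <- function(nRois = 20L, nTimepoints = 137L,
                       nSubjectsPerGroup = 20L, scansPerSubject = 1L,
                       alteredPairs = cbind(c(2L, 4L, 6L, 8L, 10L),
                                            c(1L, 3L, 5L, 7L, 9L)),
                       effectSize = 0.6, effectSign = -1,
                       baseCoupling = 0.35, noiseSd = 0.2,
                       band = c(0.09, 0.9), dynamicCoupling = TRUE,
                       couplingPeriod = 60, modulationDepth = 0.5,
                       seed = 1L) {
  ap <- matrix(as.integer(alteredPairs), ncol = 2L)
  swap <- ap[, 1] < ap[, 2]
  ap[swap, ] <- ap[swap, c(2, 1)]
  new("CohortSpec",
      nRois = as.integer(nRois), nTimepoints = as.integer(nTimepoints),
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      scansPerSubject = as.integer(scansPerSubject),
      alteredPairs = ap, effectSize = effectSize,
      effectSign = as.numeric(effectSign), baseCoupling = baseCoupling,
      noiseSd = noiseSd, band = as.numeric(band),
      dynamicCoupling = dynamicCoupling,
      couplingPeriod = as.numeric(couplingPeriod),
      modulationDepth = modulationDepth, seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0(
    "CohortSpec: %d ROIs x %d time points, %d subjects/group x %d scan(s)\n",
    "  %d altered pair(s), effect %s%.2f on base %.2f, noise sd %.2f\n"),
    object@nRois, object@nTimepoints, object@nSubjectsPerGroup,
    object@scansPerSubject, nrow(object@alteredPairs),
    if (object@effectSign > 0) "+" else "-", object@effectSize,
    object@baseCoupling, object@noiseSd))
})

# expected time-average planted coupling: phase-grid average of the
# clamped (optionally oscillating) trajectory
.expectedPlantedCoupling <- function(spec) {
  if (!spec@dynamicCoupling || spec@effectSize == 0) {
    return(min(spec@effectSize, 1 - spec@baseCoupling))
  }
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  mean(pmin(pmax(spec@effectSize * (1 + spec@modulationDepth * sin(th)), 0),
            1 - spec@baseCoupling))
}

# unit-energy band-pass FIR coefficients (fractions of Nyquist)
.firCoefficients <- function(band, order = 32L) {
  b <- signal::fir1(order, band, type = "pass")
  b / sqrt(sum(b^2))
}

# one scan's N x M BOLD matrix
.simulateScan <- function(spec, patient) {
  N <- spec@nRois; M <- spec@nTimepoints
  ap <- spec@alteredPairs
  nP <- nrow(ap)
  b <- .firCoefficients(spec@band)
  pad <- length(b)
  Mpad <- M + 2L * pad
  ncomp <- 1L + nP + 2L * N
  W <- matrix(stats::rnorm(Mpad * ncomp), Mpad, ncomp)
  Wf <- stats::filter(W, b, sides = 2)
  keep <- (pad + 1L):(pad + M)
  Wf <- as.matrix(Wf[keep, , drop = FALSE])
  g <- Wf[, 1L]
  H <- Wf[, 1L + seq_len(nP), drop = FALSE]
  E <- Wf[, 1L + nP + seq_len(N), drop = FALSE]
  Eps <- Wf[, 1L + nP + N + seq_len(N), drop = FALSE]
  phases <- stats::runif(max(nP, 1L), 0, 2 * pi)
  # planted coupling trajectory per altered pair (patient scans only)
  cmat <- matrix(0, M, max(nP, 1L))
  if (patient && nP > 0L && spec@effectSize > 0) {
    tgrid <- seq_len(M)
    for (p in seq_len(nP)) {
      cp <- if (spec@dynamicCoupling) {
        spec@effectSize * (1 + spec@modulationDepth *
                             sin(2 * pi * tgrid / spec@couplingPeriod + phases[p]))
      } else {
        rep(spec@effectSize, M)
      }
      cmat[, p] <- pmin(pmax(cp, 0), 1 - spec@baseCoupling)
    }
  }
  X <- matrix(0, N, M)
  base <- spec@baseCoupling
  for (i in seq_len(N)) {
    inPair <- which(ap[, 1] == i | ap[, 2] == i)
    pairPart <- 0
    csum <- 0
    for (p in inPair) {
      sgn <- if (ap[, 2][p] == i && spec@effectSign < 0) -1 else 1
      pairPart <- pairPart + sgn * sqrt(cmat[, p]) * H[, p]
      csum <- csum + cmat[, p]
    }
    resid <- sqrt(pmax(1 - base - csum, 0))
    X[i, ] <- sqrt(base) * g + pairPart + resid * E[, i] +
      spec@noiseSd * Eps[, i]
  }
  X
}

#' Generate a synthetic two-group cohort
#'
#' Draws every scan from the latent-factor model described in
#' \linkS4class{CohortSpec} and returns the scans together with a
#' ground-truth record (altered pairs, closed-form expected couplings,
#' seed) sufficient to score recovery experiments.
#'
#' @param spec a \linkS4class{CohortSpec}
#' @return list with elements \code{scans} (list of
#'   \linkS4class{RoiTimeSeries}) and \code{truth}
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  atten <- 1 / (1 + spec@noiseSd^2)
  scans <- list()
  withr::with_seed(spec@seed, {
    for (grp in c("NC", "patient")) {
      tag <- if (grp == "NC") "NC" else "PT"
      for (sj in seq_len(spec@nSubjectsPerGroup)) {
        sid <- sprintf("%s_s%03d", tag, sj)
        for (sc in seq_len(spec@scansPerSubject)) {
          X <- .simulateScan(spec, patient = grp == "patient")
          scans[[length(scans) + 1L]] <- RoiTimeSeries(
            X, roiLabels = sprintf("ROI%03d", seq_len(spec@nRois)),
            subjectId = sid, scanId = sprintf("%s_scan%02d", sid, sc),
            label = grp)
        }
      }
    }
  })
  truth <- list(
    alteredPairs = spec@alteredPairs,
    expectedCoupling = list(
      background = spec@baseCoupling * atten,
      ncAltered = spec@baseCoupling * atten,
      patientAltered = (spec@baseCoupling + spec@effectSign *
                          .expectedPlantedCoupling(spec)) * atten
    ),
    attenuation = atten,
    effectSize = spec@effectSize,
    dynamicCoupling = spec@dynamicCoupling,
    seed = spec@seed
  )
  list(scans = scans, truth = truth)
}

#' Write a cohort to per-scan TSV files plus a manifest
#'
#' Each scan goes to \code{scans/<scanId>.tsv} (first column the ROI label,
#' then one column per time point, full double precision) and the manifest
#' (\code{manifest.tsv}: subject_id, scan_id, path, label) binds scans to
#' classes.  When a ground-truth record is present it is written to
#' \code{truth.json}.  The written tree round-trips exactly through
#' \code{\link{readCohort}}.
#'
#' @param cohort a list of \linkS4class{RoiTimeSeries}, or the
#'   \code{list(scans, truth)} returned by \code{\link{generateCohort}}
#' @param dir output directory (created if needed)
#' @return path of the written manifest, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  truth <- NULL
  if (!is.null(cohort$scans)) {
    truth <- cohort$truth
    cohort <- cohort$scans
  }
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    scan <- cohort[[k]]
    rel <- file.path("scans", paste0(scanId(scan), ".tsv"))
    path <- file.path(dir, rel)
    M <- ncol(scan@values)
    header <- paste(c("roi", sprintf("t%d", seq_len(M))), collapse = "\t")
    body <- vapply(seq_len(nrow(scan@values)), function(i) {
      paste(c(scan@roiLabels[i], sprintf("%.17g", scan@values[i, ])),
            collapse = "\t")
    }, "")
    writeLines(c(header, body), path)
    rows[[k]] <- data.frame(subject_id = subjectId(scan),
                            scan_id = scanId(scan), path = rel,
                            label = groupLabel(scan),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(manifestPath)
}
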