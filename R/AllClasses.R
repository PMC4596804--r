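#' StrideSeries: a raw multi-channel joint-angle recording
#'
#' Holds one subject's treadmill recording: six joint-angle channels (hip,
#' knee and ankle in the sagittal and frontal planes, degrees) sampled at a
#' fixed rate, together with the gait events (foot-strike / toe-off) that
#' delimit strides.
#'
#' @slot samplingRate sampling frequency in Hz.
#' @slot time numeric vector of sample times in seconds.
#' @slot angles numeric matrix, one column per channel in the canonical
#'   channel order (see \code{\link{channelNames}}), degrees.
#' @slot events data.frame with columns \code{time} (s) and \code{type}
#'   (\code{"foot_strike"} or \code{"toe_off"}), strictly increasing in time
#'   and alternating beginning with a foot-strike.
#'
#' @exportClass StrideSeries
setClass("StrideSeries",
  representation(samplingRate = "numeric",
                 time = "numeric",
                 angles = "matrix",
                 events = "data.frame"))

setValidity("StrideSeries", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!identical(colnames(object@angles), .CHANNELS))
    msg <- c(msg, sprintf("angles must have columns %s",
                          paste(.CHANNELS, collapse = ", ")))
  if (nrow(object@angles) != length(object@time))
    msg <- c(msg, "angles and time must have the same length")
  ev <- object@events
  if (!all(c("time", "type") %in% names(ev))) {
    msg <- c(msg, "events needs columns 'time' and 'type'")
  } else if (nrow(ev) > 0) {
    if (any(diff(ev$time) <= 0))
      msg <- c(msg, "event times must be strictly increasing")
    expected <- rep(c("foot_strike", "toe_off"), length.out = nrow(ev))
    if (!identical(as.character(ev$type), expected))
      msg <- c(msg, "event types must alternate beginning with foot_strike")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn StrideSeries constructor.
#' @param samplingRate sampling frequency (Hz).
#' @param time sample times (s).
#' @param angles numeric matrix of angles (degrees), columns in canonical
#'   channel order.
#' @param events data.frame of gait events.
#' @return A \code{StrideSeries} object.
#' @export
StrideSeries <- function(samplingRate, time, angles, events) {
  events$type <- as.character(events$type)
  methods::new("StrideSeries", samplingRate = samplingRate, time = time,
               angles = angles, events = events)
}

setMethod("show", "StrideSeries", function(object) {
  nfs <- sum(object@events$type == "foot_strike")
  cat("StrideSeries:", nrow(object@angles), "samples @",
      object@samplingRate, "Hz,", max(nfs - 1L, 0L), "strides\n")
})

#' GaitCohort: a simulated or imported cohort
#'
#' Container for a cohort before waveform preprocessing: a subject table
#' (id, role, true responder label where known), one \code{StrideSeries} per
#' subject, and a long-format KOOS table (one row per subject and phase).
#'
#' @slot subjects DataFrame with columns \code{id}, \code{role}
#'   (\code{reduction}, \code{intervention}, \code{control},
#'   \code{followup}) and \code{trueLabel} (\code{Non}/\code{Low}/
#'   \code{High} or \code{NA}).
#' @slot strides named list of \code{StrideSeries}, one per subject id.
#' @slot koos data.frame with columns \code{id}, \code{phase}
#'   (\code{"pre"}/\code{"post"}), \code{pain}, \code{symptoms}, \code{adl},
#'   \code{qol}.
#'
#' @exportClass GaitCohort
setClass("GaitCohort",
  representation(subjects = "DataFrame",
                 strides = "list",
                 koos = "data.frame"))

setValidity("GaitCohort", function(object) {
  msg <- character()
  sub <- object@subjects
  if (!all(c("id", "role", "trueLabel") %in% colnames(sub)))
    msg <- c(msg, "subjects needs columns id, role, trueLabel")
  else {
    if (!all(sub$role %in% c("reduction", "intervention", "control",
                             "followup")))
      msg <- c(msg, "unknown subject role")
    if (!setequal(names(object@strides), sub$id))
      msg <- c(msg, "strides must be a named list keyed by subject id")
    kn <- c("id", "phase", "pain", "symptoms", "adl", "qol")
    if (!all(kn %in% names(object@koos)))
      msg <- c(msg, sprintf("koos needs columns %s", paste(kn, collapse = ", ")))
    else {
      sc <- as.matrix(object@koos[, c("pain", "symptoms", "adl", "qol")])
      if (nrow(sc) && (min(sc) < 0 || max(sc) > 100))
        msg <- c(msg, "KOOS subscale scores must lie in [0, 100]")
      iv <- sub$id[sub$role == "intervention"]
      post <- object@koos$id[object@koos$phase == "post"]
      if (!all(iv %in% post))
        msg <- c(msg, "every intervention subject needs a post KOOS record")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GaitCohort", function(object) {
  tab <- table(object@subjects$role)
  cat("GaitCohort with", nrow(object@subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
})

#' WaveformExperiment: cohort gait-signature matrix
#'
#' A \linkS4class{SummarizedExperiment} holding the 600-point gait
#' signatures of a cohort: one column per subject, 600 rows (6 channels
#' \eqn{\times} 100 time-normalized points, 60 stance + 40 swing).
#' \code{rowData} records channel, phase and point index; \code{colData}
#' carries subject metadata (role, responder label, KOOS subscales).
#'
#' @exportClass WaveformExperiment
setClass("WaveformExperiment", contains = "SummarizedExperiment")

setValidity("WaveformExperiment", function(object) {
  msg <- character()
  if (nrow(object) != .N_POINTS)
    msg <- c(msg, sprintf("a WaveformExperiment has exactly %d rows", .N_POINTS))
  if (!all(c("channel", "phase", "point") %in%
           colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData needs columns channel, phase, point")
  if (!"angles" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'angles' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a WaveformExperiment from a subjects-by-600 matrix
#'
#' @param waveforms numeric matrix, one row per subject and 600 columns in
#'   the canonical coordinate order (or its transpose with subjects in
#'   columns).
#' @param colData optional \code{DataFrame} of subject metadata.
#' @return A \code{WaveformExperiment}.
#' @export
WaveformExperiment <- function(waveforms, colData = NULL) {
  if (ncol(waveforms) == .N_POINTS && nrow(waveforms) != .N_POINTS)
    waveforms <- t(waveforms)
  if (nrow(waveforms) != .N_POINTS)
    stop("'waveforms' must have 600 coordinates per subject")
  rownames(waveforms) <- .waveformPointNames()
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(waveforms))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(angles = waveforms),
    rowData = .waveformRowData(),
    colData = colData)
  methods::as(se, "WaveformExperiment")
}

#' PcaModel: standardization + principal components of the waveform matrix
#'
#' Stores everything needed to project any 600-point gait signature into the
#' reduction cohort's principal-component space: per-column means and
#' standard deviations, loading vectors, and explained-variance shares.
#'
#' @slot center per-column means (length 600, degrees).
#' @slot scale per-column standard deviations (length 600, degrees).
#' @slot rotation 600 x nComponents loading matrix, columns orthonormal.
#' @slot sdev component score standard deviations, non-increasing.
#' @slot varShare share of total variance per component.
#' @slot nComponents number of retained components, min(n - 1, 600).
#' @slot scores fitted subject scores (subjects x components).
#'
#' @exportClass PcaModel
setClass("PcaModel",
  representation(center = "numeric", scale = "numeric",
                 rotation = "matrix", sdev = "numeric",
                 varShare = "numeric", nComponents = "integer",
                 scores = "matrix"))

setValidity("PcaModel", function(object) {
  msg <- character()
  if (ncol(object@rotation) != object@nComponents)
    msg <- c(msg, "rotation must have nComponents columns")
  if (length(object@sdev) != object@nComponents)
    msg <- c(msg, "sdev must have one entry per component")
  if (is.unsorted(rev(object@sdev)))
    msg <- c(msg, "components must be ordered by decreasing variance")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", object@nComponents, "components over",
      length(object@center), "coordinates;",
      sprintf("PC1 explains %.1f%% of variance\n", 100 * object@varShare[1]))
})

#' DiscriminantFit: a fitted canonical linear discriminant model
#'
#' @slot featureNames ordered predictor names (p of them).
#' @slot classLevels group labels in fixed order.
#' @slot priors per-class prior probabilities.
#' @slot groupMeans k x p matrix of class means.
#' @slot pooledCov p x p pooled within-class covariance.
#' @slot grandMean length-p grand mean of the training data.
#' @slot coefficients p x m raw canonical coefficients (m = min(p, k-1)),
#'   scaled so discriminant scores have pooled within-group variance 1.
#' @slot constants length-m constants so that scores = x %*% coefficients +
#'   constants.
#' @slot eigenvalues canonical eigenvalues, one per function.
#' @slot betweenVarShares eigenvalue shares (percent of between-group
#'   variation captured by each function).
#' @slot centroids k x m matrix of class centroids in discriminant space.
#' @slot wilksLambda Wilks' Lambda over all functions.
#' @slot bartlettChi2,bartlettDf,bartlettP Bartlett's chi-squared
#'   approximation, its degrees of freedom and p-value.
#' @slot n number of training subjects.
#'
#' @exportClass DiscriminantFit
setClass("DiscriminantFit",
  representation(featureNames = "character", classLevels = "character",
                 priors = "numeric", groupMeans = "matrix",
                 pooledCov = "matrix", grandMean = "numeric",
                 coefficients = "matrix", constants = "numeric",
                 eigenvalues = "numeric", betweenVarShares = "numeric",
                 centroids = "matrix", wilksLambda = "numeric",
                 bartlettChi2 = "numeric", bartlettDf = "numeric",
                 bartlettP = "numeric", n = "integer"))

setValidity("DiscriminantFit", function(object) {
  msg <- character()
  p <- length(object@featureNames)
  k <- length(object@classLevels)
  m <- min(p, k - 1L)
  if (ncol(object@coefficients) != m)
    msg <- c(msg, "number of discriminant functions must be min(p, k - 1)")
  if (length(object@eigenvalues) != m)
    msg <- c(msg, "one eigenvalue per discriminant function")
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiscriminantFit", function(object) {
  cat("DiscriminantFit:", length(object@featureNames), "predictors,",
      length(object@classLevels), "groups,",
      ncol(object@coefficients), "discriminant functions\n")
  cat(sprintf("  Wilks' Lambda = %.4g, chi2(%d) = %.2f, p = %.3g\n",
              object@wilksLambda, as.integer(object@bartlettDf),
              object@bartlettChi2, object@bartlettP))
})

#' Canonical channel names
#'
#' The fixed channel order used for every waveform in the package:
#' hip, knee, ankle; sagittal before frontal within each joint.
#' @return Character vector of six channel names.
#' @export
channelNames <- function() .CHANNELS

#' Responder label levels
#' @return Character vector \code{c("Non", "Low", "High")}.
#' @export
responderLevels <- function() .LABELS
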