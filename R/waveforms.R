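# Waveform preprocessing: raw stride series -> 600-point standardized gait
# signature (6 channels x 100 time-normalized points, 60 stance + 40 swing).

#' Zero-phase low-pass Butterworth filter
#'
#' Filters an angle series with a 2nd-order low-pass Butterworth filter
#' applied forward and backward (zero phase lag, the gait-lab standard).
#' The series is extended by odd reflection at both ends before filtering
#' and cropped afterwards, so edge transients are suppressed.
#'
#' @param x numeric series (degrees).
#' @param samplingRate sampling rate (Hz).
#' @param cutoff low-pass cutoff (Hz), default 10.
#' @param order filter order, default 2.
#' @return Filtered series, same length as \code{x}.
#' @export
butterworthLowpass <- function(x, samplingRate, cutoff = 10, order = 2) {
  .assertScalarNumber(samplingRate, "samplingRate")
  if (cutoff >= samplingRate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  n <- length(x)
  if (n <= 3 * order)
    stop(sprintf("series too short to filter (%d samples)", n),
         call. = FALSE)
  bf <- signal::butter(order, cutoff / (samplingRate / 2), type = "low")
  pad <- min(n - 1L, max(3L * (order + 1L),
                         as.integer(round(6 * samplingRate / cutoff))))
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[seq(pad + 1L, pad + n)]
}

#' Segment a recording into stance/swing stride segments
#'
#' Stride \eqn{i} spans foot-strike \eqn{i} to foot-strike \eqn{i+1};
#' stance runs to the interleaved toe-off and swing from there to the next
#' foot-strike. A missing interleaved toe-off is an error naming the stride.
#'
#' @param series a \linkS4class{StrideSeries}.
#' @return List of strides, each a list with \code{stance} and \code{swing}
#'   segments (\code{time}, \code{angles}, \code{start}, \code{end}).
#' @export
segmentStrides <- function(series) {
  ev <- series@events
  fs <- ev$time[ev$type == "foot_strike"]
  if (length(fs) < 2L)
    stop("need at least two foot-strike events", call. = FALSE)
  dt <- 1 / series@samplingRate
  cut <- function(start, end) {
    keep <- series@time >= start - 2 * dt & series@time <= end + 2 * dt
    if (sum(series@time >= start & series@time <= end) < 2L)
      stop("degenerate segment: fewer than two samples", call. = FALSE)
    list(time = series@time[keep], angles = series@angles[keep, , drop = FALSE],
         start = start, end = end)
  }
  lapply(seq_len(length(fs) - 1L), function(i) {
    to <- ev$time[ev$type == "toe_off" & ev$time > fs[i] & ev$time < fs[i + 1L]]
    if (length(to) != 1L)
      stop(sprintf("stride %d: expected one toe-off between foot-strikes", i),
           call. = FALSE)
    list(stance = cut(fs[i], to), swing = cut(to, fs[i + 1L]))
  })
}

#' Time-normalize one stride to a fixed 100-point gait cycle
#'
#' Stance is linearly resampled to \code{nStance} points (including both
#' the foot-strike and toe-off endpoints) and swing to \code{nSwing} points
#' (excluding the shared toe-off sample, ending at the next foot-strike),
#' then concatenated.
#'
#' @param stance,swing segments as returned by \code{\link{segmentStrides}}.
#' @param nStance,nSwing points per phase (defaults 60 and 40).
#' @return Numeric matrix, \code{nStance + nSwing} rows by one column per
#'   channel.
#' @export
timeNormalizeStride <- function(stance, swing, nStance = 60L, nSwing = 40L) {
  for (seg in list(stance, swing))
    if (length(seg$time) < 2L || seg$end <= seg$start)
      stop("degenerate segment: fewer than two samples", call. = FALSE)
  tSt <- seq(stance$start, stance$end, length.out = nStance)
  tSw <- seq(swing$start, swing$end, length.out = nSwing + 1L)[-1L]
  chans <- colnames(stance$angles)
  out <- vapply(chans, function(ch) {
    c(stats::approx(stance$time, stance$angles[, ch], xout = tSt)$y,
      stats::approx(swing$time, swing$angles[, ch], xout = tSw)$y)
  }, numeric(nStance + nSwing))
  colnames(out) <- chans
  out
}

#' Average the first consecutive time-normalized strides
#'
#' @param cycles list of 100-point-by-channel matrices from
#'   \code{\link{timeNormalizeStride}}.
#' @param nRequired number of consecutive strides to average (default 10);
#'   only the first \code{nRequired} are used.
#' @return Pointwise mean cycle matrix.
#' @export
averageStrides <- function(cycles, nRequired = 10L) {
  if (length(cycles) < nRequired)
    stop(sprintf("need %d strides, only %d available", nRequired,
                 length(cycles)), call. = FALSE)
  Reduce(`+`, cycles[seq_len(nRequired)]) / nRequired
}

#' Concatenate the six mean channel cycles into a 600-point signature
#'
#' @param meanCycle 100-row matrix with one column per channel (any column
#'   order; matched by name).
#' @return Named numeric vector of length 600 in the canonical channel
#'   order.
#' @export
concatenateChannels <- function(meanCycle) {
  missing <- setdiff(.CHANNELS, colnames(meanCycle))
  if (length(missing))
    stop(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  v <- as.vector(meanCycle[, .CHANNELS])
  names(v) <- .waveformPointNames()
  v
}

#' Full per-subject waveform pipeline
#'
#' Filter each channel (10 Hz low-pass, 2nd-order zero-phase Butterworth),
#' segment into strides, time-normalize each to 60 stance + 40 swing
#' points, average the first \code{nStrides} consecutive strides, and
#' concatenate the six channels.
#'
#' @param series a \linkS4class{StrideSeries}.
#' @param cutoff,order filter settings.
#' @param nStrides strides averaged (default 10).
#' @param filter set \code{FALSE} to skip filtering.
#' @return Named 600-point waveform vector.
#' @export
processStrideSeries <- function(series, cutoff = 10, order = 2,
                                nStrides = 10L, filter = TRUE) {
  if (filter) {
    flt <- apply(series@angles, 2L, butterworthLowpass,
                 samplingRate = series@samplingRate, cutoff = cutoff,
                 order = order)
    series@angles <- flt
  }
  strides <- segmentStrides(series)
  cycles <- lapply(strides, function(s) timeNormalizeStride(s$stance, s$swing))
  concatenateChannels(averageStrides(cycles, nStrides))
}

#' Build the cohort gait-signature matrix
#'
#' Runs the per-subject waveform pipeline over a cohort and assembles a
#' \linkS4class{WaveformExperiment} (600 coordinates x subjects) with
#' subject roles, true labels and baseline KOOS subscales in
#' \code{colData}.
#'
#' @param cohort a \linkS4class{GaitCohort}.
#' @param roles subject roles to include (default: the OA reduction cohort,
#'   i.e. reduction-only plus intervention subjects).
#' @param ... passed to \code{\link{processStrideSeries}}.
#' @return A \linkS4class{WaveformExperiment}.
#' @export
buildWaveformMatrix <- function(cohort,
                                roles = c("reduction", "intervention"),
                                ...) {
  sub <- cohort@subjects[cohort@subjects$role %in% roles, , drop = FALSE]
  mat <- vapply(sub$id,
                function(id) processStrideSeries(cohort@strides[[id]], ...),
                numeric(.N_POINTS))
  pre <- cohort@koos[cohort@koos$phase == "pre", , drop = FALSE]
  idx <- match(sub$id, pre$id)
  cd <- S4Vectors::DataFrame(
    role = sub$role, trueLabel = sub$trueLabel,
    pain = pre$pain[idx], symptoms = pre$symptoms[idx],
    adl = pre$adl[idx], qol = pre$qol[idx],
    row.names = sub$id)
  WaveformExperiment(mat, colData = cd)
}
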