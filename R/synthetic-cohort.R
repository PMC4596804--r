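# Synthetic cohort generator: emulates the statistical structure the
# analysis assumes (group-dependent waveform effects, KOOS effect-size
# distributions, stride timing jitter and smooth waveform noise) so that
# every downstream stage is testable without patient data.

# Low-order Fourier coefficients (degrees) per channel: a0, cosine and sine
# amplitudes for harmonics 1 and 2 of the gait cycle. Shapes are smooth,
# periodic caricatures of normal walking (hip flexion peak at foot-strike,
# knee flexion peak in swing, plantarflexion burst at toe-off, modest
# frontal-plane excursions).
.TEMPLATE_COEF <- list(
  hip_sagittal   = c(a0 = 10,  a1 = 18,   b1 = 6,    a2 = 2,   b2 = 0),
  hip_frontal    = c(a0 = 2,   a1 = 0,    b1 = 5,    a2 = 0,   b2 = 1.5),
  knee_sagittal  = c(a0 = 25,  a1 = -13,  b1 = -15,  a2 = 6,   b2 = 3),
  knee_frontal   = c(a0 = 1,   a1 = 0,    b1 = 2,    a2 = 1,   b2 = 0),
  ankle_sagittal = c(a0 = -2,  a1 = 3,    b1 = 6,    a2 = 0,   b2 = -9),
  ankle_frontal  = c(a0 = -1,  a1 = 2,    b1 = 0,    a2 = 0,   b2 = 1.5))

#' Reference joint-angle template for one channel
#'
#' Deterministic, smooth, periodic mean angle curve over one gait cycle,
#' built from low-order Fourier harmonics. Cycle phase 0 is foot-strike;
#' stance occupies the first \code{stanceFraction} of the cycle.
#'
#' @param channel one of \code{\link{channelNames}()}.
#' @param phase numeric vector of cycle fractions in \code{[0, 1]}
#'   (default: a 100-point grid).
#' @return Numeric vector of angles (degrees), same length as \code{phase}.
#' @examples
#' curve <- waveformTemplate("hip_sagittal")
#' @export
waveformTemplate <- function(channel, phase = seq(0, 0.99, by = 0.01)) {
  if (!channel %in% .CHANNELS)
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  cf <- .TEMPLATE_COEF[[channel]]
  w <- 2 * pi * phase
  cf["a0"] + cf["a1"] * cos(w) + cf["b1"] * sin(w) +
    cf["a2"] * cos(2 * w) + cf["b2"] * sin(2 * w)
}

# Phase windows (cycle fractions, stance = [0, stanceFraction)):
# loading response = first 15% of stance, toe-off window = last 10% of
# stance. Standard gait-phase conventions; the smooth decay flanks keep the
# injected effects continuous and periodic.
.loadingWindow <- function(stanceFraction) c(0, 0.15 * stanceFraction)
.toeOffWindow <- function(stanceFraction)
  c(0.90 * stanceFraction, stanceFraction)

# Unit-magnitude movement patterns. The loading-response ramp rises
# smoothly over the loading window, peaks at its end and decays over an
# equal flank (a C1 sine-squared lobe, so the 10 Hz low-pass filter leaves
# it essentially untouched); the toe-off bump is a smooth squared-cosine
# lobe centred on toe-off. Group effects and subject-level pattern
# variability are both multiples of these shapes.
.loadingRampShape <- function(phase, stanceFraction = 0.6) {
  w <- .loadingWindow(stanceFraction)[2]
  out <- numeric(length(phase))
  lobe <- phase >= 0 & phase <= 2 * w
  out[lobe] <- sin(pi * phase[lobe] / (2 * w))^2
  out
}

.toeOffBumpShape <- function(phase, stanceFraction = 0.6) {
  win <- .toeOffWindow(stanceFraction)
  half <- diff(win)
  out <- numeric(length(phase))
  near <- abs(phase - win[2]) <= half
  out[near] <- cos(pi * (phase[near] - win[2]) / (2 * half))^2
  out
}

#' Inject a responder-group waveform effect into a template curve
#'
#' Effects are multiples of two smooth localized movement patterns chosen
#' by channel: on the hip frontal plane, an adduction ramp over the loading
#' response (rising smoothly over the first 15\% of stance, decaying over
#' the next 15\%); on the ankle sagittal plane, a bump centred on toe-off
#' that reduces plantarflexion magnitude. At the defaults, High-Responders
#' receive a positive hip-adduction ramp, Non-Responders a positive
#' (dorsiflexion-direction) toe-off bump plus a slight negative hip ramp
#' (they tend to reduce hip adduction during loading where High-Responders
#' increase it), and Low-Responders and unlabeled subjects are unchanged.
#'
#' @param curve numeric vector of angles evaluated at \code{phase}.
#' @param phase cycle fractions matching \code{curve}.
#' @param channel channel name for \code{curve}.
#' @param label responder label (\code{"Non"}, \code{"Low"}, \code{"High"})
#'   or \code{"none"}.
#' @param effectScales named list mapping label to a named vector of
#'   per-channel effect magnitudes in degrees (see
#'   \code{\link{cohortConfig}}).
#' @param stanceFraction stance share of the gait cycle.
#' @return Modified curve, same length as \code{curve}.
#' @export
injectGroupEffect <- function(curve, phase, channel, label,
                              effectScales = cohortConfig()$effectScales,
                              stanceFraction = 0.6) {
  stopifnot(length(curve) == length(phase))
  if (!label %in% c(.LABELS, "none"))
    stop(sprintf("unknown responder label '%s'", label), call. = FALSE)
  eff <- effectScales[[label]]
  if (is.null(eff) || is.na(eff[channel]) || !channel %in% names(eff))
    return(curve)
  e <- unname(eff[channel])
  if (channel == "hip_frontal")
    curve <- curve + e * .loadingRampShape(phase, stanceFraction)
  else if (channel == "ankle_sagittal")
    curve <- curve + e * .toeOffBumpShape(phase, stanceFraction)
  curve
}

#' Default synthetic-cohort configuration
#'
#' Defaults mirror the study conditions the pipeline assumes: 98 subjects
#' with knee OA in the reduction cohort, of whom 39 completed the
#' intervention and split 14/14/11 into Non-/Low-/High-Responders; 43
#' pain-free controls; 120 Hz kinematics; at least 10 usable consecutive
#' strides per subject.
#'
#' @param nReductionOnly OA subjects used only for data reduction.
#' @param groupSizes named intervention subgroup sizes (Non/Low/High).
#' @param nControls pain-free controls.
#' @param samplingRate kinematic sampling rate (Hz).
#' @param nStrides strides recorded per subject.
#' @param strideDuration nominal stride time (s).
#' @param stanceFraction stance share of the stride.
#' @param noiseSdDeg SD of the smooth stride-level waveform noise (deg).
#' @param offsetSdDeg SD of subject-level constant channel offsets (deg).
#' @param subjectShapeSdDeg SD of subject-level smooth waveform shape
#'   variation (low-order harmonics fixed per subject and channel, deg).
#' @param effectPatternSdDeg SDs of subject-level variability in the two
#'   localized movement patterns (hip-frontal loading-response ramp,
#'   ankle-sagittal toe-off bump, deg): every subject expresses a random
#'   amount of each pattern; the group effects shift only the means, so
#'   subgroup score distributions overlap as in real cohorts. Distinct SDs
#'   keep the two patterns in separate principal components.
#' @param timingJitterSd relative SD of stride-duration jitter.
#' @param stanceJitterSd relative SD of stance-duration jitter.
#' @param effectScales per-label, per-channel waveform effect sizes (deg).
#' @param koosEffectTargets per-label target mean Cohen's d of KOOS change.
#' @param koosBaselineSd SD of baseline KOOS subscale scores.
#' @param koosSubscaleCor correlation between a subject's baseline
#'   subscale deviations (shared severity factor). Real KOOS subscales
#'   correlate substantially; the default keeps them independent so each
#'   subscale's predictive value can be attributed unambiguously.
#' @param koosChangeNoiseSd SD of per-subscale change noise (score points).
#' @param seed default generation seed.
#' @return A named list; validated by \code{\link{simulateCohort}}.
#' @export
cohortConfig <- function(nReductionOnly = 59L,
                         groupSizes = c(Non = 14L, Low = 14L, High = 11L),
                         nControls = 43L,
                         samplingRate = 120,
                         nStrides = 12L,
                         strideDuration = 1.1,
                         stanceFraction = 0.6,
                         noiseSdDeg = 1.5,
                         offsetSdDeg = 2,
                         subjectShapeSdDeg = 2,
                         effectPatternSdDeg = c(hipRamp = 1.75,
                                                ankleBump = 1.5),
                         timingJitterSd = 0.03,
                         stanceJitterSd = 0.015,
                         effectScales = list(
                           High = c(hip_frontal = 4),
                           Non = c(ankle_sagittal = 2.5,
                                   hip_frontal = -3)),
                         koosEffectTargets = c(Non = 0, Low = 0.5,
                                               High = 1.2),
                         koosBaselineSd = 10,
                         koosSubscaleCor = 0,
                         koosChangeNoiseSd = 2,
                         seed = 1L) {
  cfg <- list(nReductionOnly = as.integer(nReductionOnly),
              groupSizes = groupSizes, nControls = as.integer(nControls),
              samplingRate = samplingRate, nStrides = as.integer(nStrides),
              strideDuration = strideDuration,
              stanceFraction = stanceFraction, noiseSdDeg = noiseSdDeg,
              offsetSdDeg = offsetSdDeg,
              subjectShapeSdDeg = subjectShapeSdDeg,
              effectPatternSdDeg = effectPatternSdDeg,
              timingJitterSd = timingJitterSd,
              stanceJitterSd = stanceJitterSd, effectScales = effectScales,
              koosEffectTargets = koosEffectTargets,
              koosBaselineSd = koosBaselineSd,
              koosSubscaleCor = koosSubscaleCor,
              koosChangeNoiseSd = koosChangeNoiseSd, seed = as.integer(seed))
  .validateCohortConfig(cfg)
  cfg
}

.validateCohortConfig <- function(cfg) {
  if (!all(.LABELS %in% names(cfg$groupSizes)))
    stop("groupSizes must be named Non, Low, High", call. = FALSE)
  if (any(cfg$groupSizes <= 0) || cfg$nReductionOnly <= 0 ||
      cfg$nControls < 0 || cfg$nStrides <= 0)
    stop("all cohort counts must be positive", call. = FALSE)
  if (cfg$stanceFraction <= 0 || cfg$stanceFraction >= 1)
    stop("stanceFraction must lie strictly between 0 and 1", call. = FALSE)
  .assertScalarNumber(cfg$samplingRate, "samplingRate")
  .assertScalarNumber(cfg$strideDuration, "strideDuration")
  invisible(cfg)
}

# Map a time within stride i onto a cycle fraction using the stride's own
# stance/swing boundaries (phase is piecewise linear in time).
.cyclePhase <- function(t, fs, to, fsNext, stanceFraction) {
  ifelse(t < to,
         stanceFraction * (t - fs) / (to - fs),
         stanceFraction + (1 - stanceFraction) * (t - to) / (fsNext - to))
}

#' Synthesize a multi-stride recording for one subject
#'
#' Emits \code{nStrides} consecutive strides sampled at
#' \code{samplingRate}, with per-stride timing jitter, smooth low-frequency
#' harmonic noise per stride and channel, and a lead-in/lead-out of half a
#' stride so that filtering transients never touch the analyzed strides.
#' Draws from the current RNG stream; seed it for reproducibility.
#'
#' @param templates named list of functions, one per channel, mapping cycle
#'   phase in \code{[0, 1]} to an angle in degrees.
#' @param config a \code{\link{cohortConfig}} list.
#' @return A \linkS4class{StrideSeries}.
#' @export
synthesizeStrides <- function(templates, config = cohortConfig()) {
  stopifnot(all(.CHANNELS %in% names(templates)))
  n <- config$nStrides
  sf <- config$stanceFraction
  # virtual strides 0 and n+1 supply the lead-in and lead-out
  durs <- config$strideDuration *
    (1 + if (config$timingJitterSd > 0)
      stats::rnorm(n + 2L, 0, config$timingJitterSd) else numeric(n + 2L))
  stanceDurs <- sf * durs *
    (1 + if (config$stanceJitterSd > 0)
      stats::rnorm(n + 2L, 0, config$stanceJitterSd) else numeric(n + 2L))
  leadIn <- 0.5
  fs <- leadIn + c(0, cumsum(durs[-length(durs)]))
  fs <- fs - durs[1]                       # fs[1] is the virtual stride
  to <- fs + stanceDurs
  total <- fs[length(fs)] + durs[length(durs)]
  time <- seq(0, total, by = 1 / config$samplingRate)

  stride <- findInterval(time, fs)         # 1..n+2, samples before fs[1] -> 0
  stride[stride < 1L] <- 1L
  phase <- .cyclePhase(time, fs[stride], to[stride],
                       fs[stride] + durs[stride], sf)
  phase <- pmin(pmax(phase, 0), 1)

  noisy <- config$noiseSdDeg > 0
  angles <- matrix(0, length(time), length(.CHANNELS),
                   dimnames = list(NULL, .CHANNELS))
  for (ch in .CHANNELS) {
    vals <- templates[[ch]](phase)
    if (noisy) {
      amp <- config$noiseSdDeg / sqrt(2)
      co <- matrix(stats::rnorm(4L * (n + 2L), 0, amp), ncol = 4L)
      w <- 2 * pi * phase
      vals <- vals + co[stride, 1L] * cos(w) + co[stride, 2L] * sin(w) +
        co[stride, 3L] * cos(2 * w) + co[stride, 4L] * sin(2 * w)
    }
    angles[, ch] <- vals
  }

  realIdx <- 2:(n + 2L)                    # fs of strides 1..n plus final fs
  evTime <- as.vector(rbind(fs[realIdx], to[realIdx]))
  evType <- rep(c("foot_strike", "toe_off"), n + 1L)
  keep <- evTime <= fs[n + 2L]             # drop the trailing virtual toe-off
  events <- data.frame(time = evTime[keep], type = evType[keep])

  StrideSeries(samplingRate = config$samplingRate, time = time,
               angles = angles, events = events)
}

# Baseline KOOS subscale means; High-Responders report lower function in
# daily living at baseline, mirroring the subgroup contrast the classifier
# must recover.
.koosBaselineMean <- function(label) {
  m <- c(pain = 65, symptoms = 70, adl = 70, qol = 60)
  if (identical(label, "High")) m["adl"] <- 52
  m
}

#' Synthesize pre/post KOOS subscale scores for one intervention subject
#'
#' Baseline scores are drawn around group-specific means (High-Responders
#' lower in ADL); the post-pre change is scaled so the subject's mean
#' per-patient Cohen's d (denominator: baseline subscale SD, matching
#' \code{\link{subgroupCohort}}) lands in the label's responder bin. All
#' scores are clipped to \code{[0, 100]}. Draws from the current RNG stream.
#'
#' @param label responder label (\code{"Non"}, \code{"Low"}, \code{"High"}).
#' @param config a \code{\link{cohortConfig}} list.
#' @return List with elements \code{pre} and \code{post}, each a named
#'   numeric vector (pain, symptoms, adl, qol).
#' @export
synthesizeKoos <- function(label, config = cohortConfig()) {
  if (!label %in% .LABELS)
    stop(sprintf("unknown responder label '%s'", label), call. = FALSE)
  mu <- .koosBaselineMean(label)
  r <- config$koosSubscaleCor
  dev <- if (r > 0)
    sqrt(r) * stats::rnorm(1L) + sqrt(1 - r) * stats::rnorm(4L)
  else stats::rnorm(4L)
  pre <- pmin(pmax(mu + config$koosBaselineSd * dev, 0), 100)
  names(pre) <- names(mu)
  d <- config$koosEffectTargets[[label]]
  change <- d * config$koosBaselineSd +
    if (config$koosChangeNoiseSd > 0)
      stats::rnorm(4L, 0, config$koosChangeNoiseSd) else numeric(4L)
  post <- pmin(pmax(pre + change, 0), 100)
  names(post) <- names(mu)
  list(pre = pre, post = post)
}

#' Simulate a full synthetic cohort
#'
#' Generates the reduction-only, intervention and control subjects of a
#' study cohort: per-subject stride recordings built from channel templates
#' with group waveform effects and subject-level offsets, and KOOS records
#' for intervention subjects (pre and post) and controls (perfect scores,
#' pre only). Deterministic for a given config and seed.
#'
#' @param config a \code{\link{cohortConfig}} list.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return A \linkS4class{GaitCohort}.
#' @examples
#' cohort <- simulateCohort(cohortConfig(nReductionOnly = 4,
#'   groupSizes = c(Non = 2, Low = 2, High = 2), nControls = 2), seed = 1)
#' @export
simulateCohort <- function(config = cohortConfig(), seed = config$seed) {
  .validateCohortConfig(config)
  .withSeed(seed, {
    gs <- config$groupSizes[.LABELS]
    ids <- c(sprintf("red%03d", seq_len(config$nReductionOnly)),
             sprintf("int%03d", seq_len(sum(gs))),
             if (config$nControls > 0)
               sprintf("ctl%03d", seq_len(config$nControls)))
    roles <- c(rep("reduction", config$nReductionOnly),
               rep("intervention", sum(gs)),
               rep("control", config$nControls))
    labels <- c(rep(NA_character_, config$nReductionOnly),
                rep(.LABELS, times = gs),
                rep(NA_character_, config$nControls))

    strides <- vector("list", length(ids))
    names(strides) <- ids
    koos <- list()
    for (i in seq_along(ids)) {
      lab <- if (is.na(labels[i])) "none" else labels[i]
      offs <- stats::rnorm(length(.CHANNELS), 0, config$offsetSdDeg)
      names(offs) <- .CHANNELS
      shapeAmp <- config$subjectShapeSdDeg / sqrt(2)
      shapes <- matrix(if (shapeAmp > 0)
        stats::rnorm(4L * length(.CHANNELS), 0, shapeAmp)
        else 0, nrow = length(.CHANNELS), ncol = 4L,
        dimnames = list(.CHANNELS, NULL))
      patSd <- rep(config$effectPatternSdDeg, length.out = 2L)
      pat <- ifelse(patSd > 0, stats::rnorm(2L, 0, pmax(patSd, 1e-12)), 0)
      templates <- lapply(.CHANNELS, function(ch) {
        off <- offs[[ch]]
        sh <- shapes[ch, ]
        ramp <- if (ch == "hip_frontal") pat[1L] else 0
        bump <- if (ch == "ankle_sagittal") pat[2L] else 0
        force(ch); force(off); force(lab); force(sh)
        function(u) {
          w <- 2 * pi * u
          injectGroupEffect(waveformTemplate(ch, u), u, ch, lab,
                            config$effectScales,
                            config$stanceFraction) + off +
            ramp * .loadingRampShape(u, config$stanceFraction) +
            bump * .toeOffBumpShape(u, config$stanceFraction) +
            sh[1L] * cos(w) + sh[2L] * sin(w) +
            sh[3L] * cos(2 * w) + sh[4L] * sin(2 * w)
        }
      })
      names(templates) <- .CHANNELS
      strides[[i]] <- synthesizeStrides(templates, config)
      if (roles[i] == "intervention") {
        k <- synthesizeKoos(lab, config)
        koos[[length(koos) + 1L]] <- data.frame(
          id = ids[i], phase = c("pre", "post"),
          rbind(k$pre, k$post), row.names = NULL)
      } else if (roles[i] == "control") {
        koos[[length(koos) + 1L]] <- data.frame(
          id = ids[i], phase = "pre", pain = 100, symptoms = 100,
          adl = 100, qol = 100)
      }
    }
    methods::new("GaitCohort",
                 subjects = S4Vectors::DataFrame(id = ids, role = roles,
                                                 trueLabel = labels),
                 strides = strides,
                 koos = do.call(rbind, koos))
  })
}
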