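# Internal helpers shared across modules.

# Canonical channel order used everywhere in the package. The order follows
# the usual proximal-to-distal narration (hip, knee, ankle), sagittal before
# frontal within each joint.
.CHANNELS <- c("hip_sagittal", "hip_frontal",
               "knee_sagittal", "knee_frontal",
               "ankle_sagittal", "ankle_frontal")

.N_STANCE <- 60L
.N_SWING  <- 40L
.N_CYCLE  <- 100L
.N_POINTS <- 600L

.LABELS <- c("Non", "Low", "High")

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded internals never disturb
#' the caller's RNG stream.
#' @noRd
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; keeps results < 2^31 and spreads
# stages across the stream.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483647)
}

# Systematic names for the 600 waveform coordinates: channel_phase_index,
# e.g. hip_frontal_stance_07.
.waveformPointNames <- function() {
  phase <- c(rep("stance", .N_STANCE), rep("swing", .N_SWING))
  idx <- c(seq_len(.N_STANCE), seq_len(.N_SWING))
  unlist(lapply(.CHANNELS, function(ch)
    sprintf("%s_%s_%02d", ch, phase, idx)), use.names = FALSE)
}

# rowData scaffold for a WaveformExperiment.
.waveformRowData <- function() {
  S4Vectors::DataFrame(
    channel = factor(rep(.CHANNELS, each = .N_CYCLE), levels = .CHANNELS),
    phase = factor(rep(c(rep("stance", .N_STANCE), rep("swing", .N_SWING)),
                       times = length(.CHANNELS)),
                   levels = c("stance", "swing")),
    point = rep(c(seq_len(.N_STANCE), seq_len(.N_SWING)),
                times = length(.CHANNELS)),
    row.names = .waveformPointNames())
}

.assertScalarNumber <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
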