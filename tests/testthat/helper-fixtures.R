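# Shared fixtures: all synthetic, built in code at test time.

# A small cohort configuration that keeps unit tests fast while preserving
# the generator's structure.
tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(nReductionOnly = 6L,
         groupSizes = c(Non = 4L, Low = 4L, High = 4L),
         nControls = 3L, nStrides = 11L),
    list(...))
  do.call(cohortConfig, args)
}

# A configuration with every noise source off: strides are exact copies of
# the injected templates.
noiselessConfig <- function(...) {
  tinyConfig(noiseSdDeg = 0, offsetSdDeg = 0, subjectShapeSdDeg = 0,
             effectPatternSdDeg = 0, timingJitterSd = 0,
             stanceJitterSd = 0, koosChangeNoiseSd = 0, ...)
}

# Build a StrideSeries directly from a phase -> angle function, with exact
# gait events; one value per channel function in `fns` (defaults: zeros).
makeSeries <- function(fns = NULL, rate = 120, strideDur = 1, nStrides = 2,
                       stanceFrac = 0.6) {
  time <- seq(0, nStrides * strideDur, by = 1 / rate)
  u <- (time %% strideDur) / strideDur
  u[length(u)] <- 1
  angles <- sapply(channelNames(), function(ch) {
    if (!is.null(fns) && !is.null(fns[[ch]])) fns[[ch]](u) else numeric(length(u))
  })
  fsT <- seq(0, nStrides * strideDur, by = strideDur)
  toT <- head(fsT, -1) + stanceFrac * strideDur
  ev <- data.frame(time = sort(c(fsT, toT)),
                   type = rep(c("foot_strike", "toe_off"),
                              length.out = 2 * nStrides + 1))
  StrideSeries(samplingRate = rate, time = time, angles = angles,
               events = ev)
}

# Three well-separated Gaussian clusters for classifier tests.
makeClusters <- function(n = 15, p = 3, sep = 10, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = sep), n, p),
             matrix(rnorm(n * p, mean = 2 * sep), n, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = factor(rep(c("a", "b", "c"), each = n)))
}
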