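test_that("channel templates are periodic, non-degenerate and distinct", {
  grid <- seq(0, 0.99, by = 0.01)
  curves <- sapply(channelNames(), waveformTemplate, phase = grid)
  for (ch in channelNames()) {
    expect_equal(waveformTemplate(ch, 0), waveformTemplate(ch, 1),
                 tolerance = 1e-12)
    expect_gt(diff(range(curves[, ch])), 0)
  }
  pairs <- utils::combn(channelNames(), 2)
  for (j in seq_len(ncol(pairs)))
    expect_gt(max(abs(curves[, pairs[1, j]] - curves[, pairs[2, j]])), 0)
  expect_error(waveformTemplate("knee_transverse"), "unknown channel")
})

test_that("group effects modify only the documented channel and window", {
  grid <- seq(0, 0.999, by = 0.001)
  scales <- list(High = c(hip_frontal = 3), Non = c(ankle_sagittal = 3))
  for (ch in channelNames()) {
    base <- waveformTemplate(ch, grid)
    expect_identical(injectGroupEffect(base, grid, ch, "Low", scales), base)
    expect_identical(injectGroupEffect(base, grid, ch, "none", scales), base)
  }
  # High-Responders: greater mean hip adduction over the loading response
  base <- waveformTemplate("hip_frontal", grid)
  mod <- injectGroupEffect(base, grid, "hip_frontal", "High", scales)
  load <- grid <= 0.15 * 0.6
  expect_gt(mean(mod[load]), mean(base[load]))
  expect_equal(mod[grid > 0.2], base[grid > 0.2])
  # Non-Responders: reduced plantarflexion magnitude at toe-off
  base <- waveformTemplate("ankle_sagittal", grid)
  mod <- injectGroupEffect(base, grid, "ankle_sagittal", "Non", scales)
  toeoff <- grid >= 0.9 * 0.6 & grid <= 0.6
  expect_lt(abs(min(mod[toeoff])), abs(min(base[toeoff])))
  expect_error(injectGroupEffect(base, grid, "ankle_sagittal", "Huge",
                                 scales), "unknown responder label")
})

test_that("cohort configuration invariants are enforced", {
  expect_error(cohortConfig(stanceFraction = 1.2), "stanceFraction")
  expect_error(cohortConfig(nReductionOnly = 0), "positive")
  expect_error(cohortConfig(groupSizes = c(Non = 5, Low = 5)), "named")
})

test_that("noise-free strides are identical after time normalization", {
  cfg <- noiselessConfig()
  templates <- lapply(channelNames(), function(ch)
    function(u) waveformTemplate(ch, u))
  names(templates) <- channelNames()
  ss <- synthesizeStrides(templates, cfg)
  cycles <- lapply(segmentStrides(ss), function(s)
    timeNormalizeStride(s$stance, s$swing))
  for (i in seq_along(cycles)[-1])
    expect_lt(max(abs(cycles[[i]] - cycles[[1]])), 1e-9)
})

test_that("synthesizeStrides emits the requested number of strides", {
  cfg <- tinyConfig(nStrides = 12L)
  templates <- lapply(channelNames(), function(ch)
    function(u) waveformTemplate(ch, u))
  names(templates) <- channelNames()
  set.seed(7)
  ss <- synthesizeStrides(templates, cfg)
  ev <- ss@events
  expect_gte(sum(ev$type == "foot_strike") - 1L, 12L)
  expect_true(all(diff(ev$time) > 0))
  expect_identical(as.character(ev$type[1]), "foot_strike")
  # stance duration ~ stanceFraction x stride duration
  fs <- ev$time[ev$type == "foot_strike"]
  to <- ev$time[ev$type == "toe_off"]
  frac <- (to - head(fs, -1)) / diff(fs)
  expect_true(all(abs(frac - cfg$stanceFraction) < 0.15))
})

test_that("KOOS synthesis hits its anchors and stays in range", {
  cfg <- noiselessConfig()
  set.seed(1)
  k <- synthesizeKoos("Non", cfg)   # target d = 0, zero change noise
  expect_identical(k$pre, k$post)
  set.seed(2)
  draws <- replicate(400, {
    h <- synthesizeKoos("High", tinyConfig())
    l <- synthesizeKoos("Low", tinyConfig())
    c(high_adl = unname(h$pre["adl"]), low_adl = unname(l$pre["adl"]),
      range_ok = all(c(h$pre, h$post, l$pre, l$post) >= 0 &
                     c(h$pre, h$post, l$pre, l$post) <= 100))
  })
  expect_lt(mean(draws["high_adl", ]), mean(draws["low_adl", ]))
  expect_true(all(draws["range_ok", ] == 1))
})

test_that("cohort generation is seeded and reproducible", {
  cfg <- tinyConfig()
  a <- simulateCohort(cfg, seed = 11)
  b <- simulateCohort(cfg, seed = 11)
  expect_identical(a@koos, b@koos)
  expect_identical(a@strides[[1]]@angles, b@strides[[1]]@angles)
  expect_identical(as.data.frame(a@subjects), as.data.frame(b@subjects))
  d <- simulateCohort(cfg, seed = 12)
  expect_false(identical(a@koos, d@koos))
  # structure: roles and labels as configured; controls have perfect KOOS
  expect_identical(as.integer(table(a@subjects$role)[c("control",
                                                       "intervention",
                                                       "reduction")]),
                   c(3L, 12L, 6L))
  ctl <- a@koos[grepl("^ctl", a@koos$id), c("pain", "symptoms", "adl", "qol")]
  expect_true(all(as.matrix(ctl) == 100))
})

test_that("noise-free generation round-trips through the waveform pipeline", {
  cfg <- noiselessConfig()
  co <- simulateCohort(cfg, seed = 3)
  id <- co@subjects$id[co@subjects$trueLabel %in% "High"][1]
  uSt <- cfg$stanceFraction * (seq_len(60) - 1) / 59
  uSw <- cfg$stanceFraction + (1 - cfg$stanceFraction) * seq_len(40) / 40
  u <- c(uSt, uSw)
  expected <- unlist(lapply(channelNames(), function(ch)
    injectGroupEffect(waveformTemplate(ch, u), u, ch, "High",
                      cfg$effectScales, cfg$stanceFraction)))
  # segmentation + normalization + averaging reproduce the injected
  # templates to interpolation accuracy
  raw <- processStrideSeries(co@strides[[id]], nStrides = 10L,
                             filter = FALSE)
  expect_lt(max(abs(raw - expected)), 0.1)
  # the 10 Hz zero-phase filter additionally attenuates the ~5 Hz
  # loading-response lobe (and smears it slightly across the adjacent
  # foot-strike) but leaves the other channels essentially untouched
  flt <- processStrideSeries(co@strides[[id]], nStrides = 10L)
  expect_lt(max(abs(flt - expected)), 0.2)
  notHipFrontal <- setdiff(seq_len(600), 101:200)
  expect_lt(max(abs(flt - expected)[notHipFrontal]), 0.05)
})
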