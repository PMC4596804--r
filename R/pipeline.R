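# End-to-end pipeline: waveform preprocessing -> PCA reduction -> KOOS
# subgrouping -> wrapper feature selection -> cumulative-entry discriminant
# model -> subspace projection and stability.

#' Pipeline configuration
#'
#' Collects the analysis constants in one place. Defaults are the study
#' conditions the pipeline assumes: 10 Hz 2nd-order low-pass filtering,
#' 60/40 stance/swing points, 10-stride averages, 10x10-fold
#' cross-validation, 10 selection iterations, a feature cap of one less
#' than the smallest subgroup, equal priors.
#'
#' @param cutoffHz,filterOrder Butterworth low-pass settings.
#' @param nStrides strides averaged per subject.
#' @param folds,repeats cross-validation scheme.
#' @param selectionIterations sequential-selection runs.
#' @param denominator Cohen's d denominator convention
#'   (\code{"baseline"} or \code{"change"}).
#' @param regionMethod subspace-region convention (\code{"voronoi"} or
#'   \code{"df1Tertile"}).
#' @param priors class priors for the discriminant model (\code{NULL} =
#'   equal).
#' @return Named list of settings.
#' @export
pipelineConfig <- function(cutoffHz = 10, filterOrder = 2, nStrides = 10L,
                           folds = 10L, repeats = 10L,
                           selectionIterations = 10L,
                           denominator = "baseline",
                           regionMethod = "voronoi", priors = NULL) {
  list(cutoffHz = cutoffHz, filterOrder = filterOrder,
       nStrides = as.integer(nStrides), folds = as.integer(folds),
       repeats = as.integer(repeats),
       selectionIterations = as.integer(selectionIterations),
       denominator = denominator, regionMethod = regionMethod,
       priors = priors)
}

#' Run the full prediction pipeline on a cohort
#'
#' Stages: (1) per-subject waveform processing of the OA reduction cohort
#' into the subjects-by-600 signature matrix; (2) standardization and PCA;
#' (3) KOOS responder subgrouping of the intervention subjects; (4)
#' candidate predictor table (gait PC scores + four baseline KOOS
#' subscales); (5) repeated sequential forward selection, frequency
#' ranking and the subgroup-size cap; (6) cumulative-entry discriminant
#' model search with diagnostics (Wilks' Lambda/Bartlett, Box's M,
#' Lilliefors screen, structure matrix); (7) projection of baseline
#' subjects and pain-free controls into the discriminant subspace with
#' centroid regions. All stage seeds derive deterministically from
#' \code{seed}.
#'
#' @param cohort a \linkS4class{GaitCohort}, or a path to a cohort
#'   directory readable by \code{\link{readCohortDir}}.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param seed master seed.
#' @return A list of artifacts: \code{waveforms}
#'   (\linkS4class{WaveformExperiment}), \code{pca}, \code{subgroups},
#'   \code{featureTable}, \code{selectionRuns}, \code{ranking},
#'   \code{search} (with the fitted model), \code{diagnostics},
#'   \code{projection} and a compact \code{report} list.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), seed = 1L) {
  if (is.character(cohort)) {
    issues <- validateCohortDir(cohort)
    if (any(issues$severity == "fatal"))
      stop(paste(c("cohort validation failed:", issues$message),
                 collapse = "\n  "), call. = FALSE)
    cohort <- readCohortDir(cohort)
  }
  stopifnot(methods::is(cohort, "GaitCohort"))

  we <- buildWaveformMatrix(cohort, roles = c("reduction", "intervention"),
                            cutoff = config$cutoffHz,
                            order = config$filterOrder,
                            nStrides = config$nStrides)
  pca <- fitPcaModel(we)

  subgroups <- subgroupCohort(cohort@koos, denominator = config$denominator)
  labels <- stats::setNames(subgroups$label, subgroups$id)

  ids <- subgroups$id
  scores <- pca@scores[ids, , drop = FALSE]
  koosPre <- cohort@koos[cohort@koos$phase == "pre", , drop = FALSE]
  ft <- buildFeatureTable(scores, koosPre, labels = labels)
  X <- ft[, setdiff(names(ft), "label"), drop = FALSE]
  y <- ft$label

  runs <- selectFeatures(X, y,
                         iterations = config$selectionIterations,
                         baseSeed = .deriveSeed(seed, 1L),
                         folds = config$folds, repeats = config$repeats)
  rc <- rankAndCap(runs, groupSizes = table(y))

  search <- cumulativeModelSearch(rc$capped, X, y,
                                  seed = .deriveSeed(seed, 2L),
                                  folds = config$folds,
                                  repeats = config$repeats,
                                  priors = config$priors)
  fit <- search$fit
  Xent <- as.matrix(X[, fit@featureNames, drop = FALSE])

  diag <- list(
    wilks = wilksBartlett(fit),
    boxM = tryCatch(boxM(Xent, y), error = function(e) {
      warning("Box's M unavailable: ", conditionMessage(e))
      NULL
    }),
    lilliefors = lapply(stats::setNames(fit@featureNames,
                                        fit@featureNames),
                        function(f) lillieforsTest(Xent[, f],
                                                   seed = .deriveSeed(seed, 3L))),
    structure = structureMatrix(fit, Xent, y))
  if (!is.null(diag$boxM) && diag$boxM$p <= 0.05)
    warning(sprintf("Box's M rejects covariance homogeneity (p = %.3g)",
                    diag$boxM$p))
  for (f in fit@featureNames)
    if (diag$lilliefors[[f]]$p.value < 0.05)
      warning(sprintf("Lilliefors screen flags '%s' (p = %.3g)",
                      f, diag$lilliefors[[f]]$p.value))

  basePts <- projectCohort(pca, fit,
                           t(SummarizedExperiment::assay(we, "angles"))[ids, ,
                                                                        drop = FALSE],
                           koosPre, tag = "pre")
  baseCen <- groupCentroids(basePts, labels[basePts$id])
  projection <- list(points = basePts, baselineCentroids = baseCen)
  ctlIds <- cohort@subjects$id[cohort@subjects$role == "control"]
  if (length(ctlIds)) {
    ctlMat <- t(vapply(ctlIds, function(id)
      processStrideSeries(cohort@strides[[id]], cutoff = config$cutoffHz,
                          order = config$filterOrder,
                          nStrides = config$nStrides),
      numeric(.N_POINTS)))
    ctlPts <- projectControls(pca, fit, ctlMat)
    ctlCen <- groupCentroids(ctlPts, rep("control", nrow(ctlPts)))
    ctlCen$nearestBaseline <- assignRegion(ctlCen, baseCen,
                                           method = config$regionMethod)
    projection$points <- rbind(projection$points, ctlPts)
    projection$controlCentroid <- ctlCen
  }

  report <- list(
    nSubjects = ncol(we), nCandidatePredictors = ncol(X),
    groupSizes = as.list(table(y)), cap = rc$cap,
    cappedFeatures = rc$capped, enteredFeatures = fit@featureNames,
    nDiscriminantFunctions = ncol(fit@coefficients),
    wilksLambda = diag$wilks$lambda, bartlettChi2 = diag$wilks$chi2,
    bartlettDf = diag$wilks$df, bartlettP = diag$wilks$p,
    betweenVarShares = fit@betweenVarShares,
    boxMP = if (is.null(diag$boxM)) NA_real_ else diag$boxM$p,
    cvAccuracy = search$meanAccuracy, seed = seed)

  list(waveforms = we, pca = pca, subgroups = subgroups,
       featureTable = ft, selectionRuns = runs, ranking = rc,
       search = search, diagnostics = diag, projection = projection,
       report = report)
}
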