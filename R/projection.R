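# Projection of new cohorts (post-intervention, long-term follow-up,
# pain-free controls) into the fitted discriminant subspace, and centroid
# stability assessment.

# Split a fit's entered predictors into gait PCs and KOOS subscales.
.splitEnteredFeatures <- function(fit) {
  isPC <- grepl("^PC[0-9]+$", fit@featureNames)
  list(pcs = fit@featureNames[isPC],
       koos = fit@featureNames[!isPC])
}

#' Project one subject into the discriminant subspace
#'
#' Standardizes the subject's 600-point waveform with the PCA model's
#' stored means and SDs, scores only the principal components entered in
#' the discriminant fit, assembles the feature vector with the entered
#' KOOS subscales, and applies the discriminant coefficients and
#' constants.
#'
#' @param pca the \linkS4class{PcaModel} from the training run.
#' @param fit the \linkS4class{DiscriminantFit} from the same run.
#' @param waveform 600-point waveform vector.
#' @param koos named vector (or one-row data.frame) of KOOS subscale
#'   scores; every entered subscale must be present.
#' @return Named vector of discriminant-function scores.
#' @export
projectSubject <- function(pca, fit, waveform, koos) {
  parts <- .splitEnteredFeatures(fit)
  x <- numeric(0)
  if (length(parts$pcs)) {
    idx <- as.integer(sub("^PC", "", parts$pcs))
    sc <- pcScores(pca, waveform, components = idx)
    x <- stats::setNames(as.vector(sc), parts$pcs)
  }
  if (length(parts$koos)) {
    koos <- unlist(koos)
    missing <- setdiff(parts$koos, names(koos))
    if (length(missing))
      stop(sprintf("missing entered KOOS subscale(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    x <- c(x, koos[parts$koos])
  }
  drop(discriminantScores(fit, matrix(x[fit@featureNames], nrow = 1L,
                                      dimnames = list(NULL,
                                                      fit@featureNames))))
}

#' Project a cohort of waveforms into the discriminant subspace
#'
#' @param pca,fit the training-run \linkS4class{PcaModel} and
#'   \linkS4class{DiscriminantFit}.
#' @param waveforms subjects-by-600 matrix (rownames = ids) or a
#'   \linkS4class{WaveformExperiment}.
#' @param koos data.frame with \code{id} and subscale columns, or
#'   \code{NULL} when no KOOS subscale was entered.
#' @param tag cohort tag stored with the points (e.g. \code{"pre"},
#'   \code{"post"}, \code{"followup"}, \code{"control"}).
#' @return data.frame of subspace points: \code{id}, \code{tag}, one
#'   column per discriminant function (\code{df1}, \code{df2}, ...).
#' @export
projectCohort <- function(pca, fit, waveforms, koos = NULL, tag = "pre") {
  if (methods::is(waveforms, "WaveformExperiment"))
    waveforms <- t(SummarizedExperiment::assay(waveforms, "angles"))
  ids <- rownames(waveforms)
  pts <- t(vapply(seq_len(nrow(waveforms)), function(i) {
    kv <- if (is.null(koos)) numeric(0)
          else unlist(koos[match(ids[i], koos$id), .KOOS_SUBSCALES])
    projectSubject(pca, fit, waveforms[i, ], kv)
  }, numeric(ncol(fit@coefficients))))
  out <- data.frame(id = ids, tag = tag, pts, row.names = NULL)
  names(out)[-(1:2)] <- tolower(colnames(fit@coefficients))
  out
}

#' Project pain-free controls with perfect KOOS scores
#'
#' Controls are pain-free, so every KOOS subscale is set to 100 before
#' projection.
#'
#' @inheritParams projectCohort
#' @return data.frame of subspace points tagged \code{"control"}.
#' @export
projectControls <- function(pca, fit, waveforms) {
  if (methods::is(waveforms, "WaveformExperiment"))
    waveforms <- t(SummarizedExperiment::assay(waveforms, "angles"))
  if (nrow(waveforms) == 0L)
    return(data.frame(id = character(), tag = character(),
                      df1 = numeric(), df2 = numeric()))
  ids <- rownames(waveforms)
  koos <- data.frame(id = ids, pain = 100, symptoms = 100, adl = 100,
                     qol = 100)
  projectCohort(pca, fit, waveforms, koos, tag = "control")
}

#' Group centroids of subspace points
#'
#' @param points data.frame with discriminant-score columns (\code{df1},
#'   \code{df2}, ...).
#' @param grouping vector of group labels, one per point.
#' @return data.frame with one row per non-empty group (empty groups are
#'   omitted with a warning) and the mean score per function.
#' @export
groupCentroids <- function(points, grouping) {
  dfCols <- grep("^df[0-9]+$", names(points), value = TRUE)
  grouping <- as.factor(grouping)
  empty <- setdiff(levels(grouping), unique(as.character(grouping)))
  if (length(empty))
    warning(sprintf("omitting empty group(s): %s",
                    paste(empty, collapse = ", ")))
  agg <- stats::aggregate(points[dfCols], by = list(group = grouping),
                          FUN = mean, drop = TRUE)
  agg
}

#' Assign subspace points to responder regions
#'
#' Operationalizes the "thirds" of the classification subspace. The
#' default partitions the plane into the Voronoi cells of the three
#' baseline subgroup centroids (nearest centroid in Euclidean distance;
#' exact ties resolve in the order Non, Low, High). The alternative
#' partitions by DF1 alone, with boundaries at the midpoints between
#' adjacent baseline centroids' DF1 coordinates.
#'
#' @param points data.frame with \code{df1} (and \code{df2}, ...) columns,
#'   or a numeric vector for a single point.
#' @param baselineCentroids data.frame from \code{\link{groupCentroids}}
#'   computed on the baseline cohort, with a \code{group} column.
#' @param method \code{"voronoi"} (default) or \code{"df1Tertile"}.
#' @return Factor of region labels.
#' @export
assignRegion <- function(points, baselineCentroids,
                         method = c("voronoi", "df1Tertile")) {
  method <- match.arg(method)
  if (is.null(dim(points)))
    points <- as.data.frame(as.list(points))
  labs <- as.character(baselineCentroids$group)
  ord <- match(.LABELS, labs)
  if (any(is.na(ord)))
    stop("need baseline centroids for all of Non, Low, High", call. = FALSE)
  cen <- baselineCentroids[ord, , drop = FALSE]
  dfCols <- grep("^df[0-9]+$", names(cen), value = TRUE)
  if (method == "voronoi") {
    d2 <- vapply(seq_len(nrow(cen)), function(i)
      rowSums(sweep(as.matrix(points[dfCols]), 2L,
                    as.numeric(cen[i, dfCols]))^2),
      numeric(nrow(points)))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
    factor(.LABELS[apply(d2, 1L, which.min)], levels = .LABELS)
  } else {
    o <- order(cen$df1)
    mids <- (cen$df1[o][-3] + cen$df1[o][-1]) / 2
    idx <- findInterval(points$df1, mids) + 1L
    factor(.LABELS[o][idx], levels = .LABELS)
  }
}

#' Centroid stability across projected cohorts
#'
#' For every subgroup and cohort tag, computes the subgroup centroid of
#' the projected points and asks whether it falls in the subgroup's
#' baseline region. Baseline centroids are, by construction, in their own
#' regions.
#'
#' @param points data.frame of subspace points with \code{tag} column.
#' @param grouping responder label per point.
#' @param baselineTag which tag defines the baseline regions (default
#'   \code{"pre"}).
#' @param method region convention, see \code{\link{assignRegion}}.
#' @return data.frame with group, tag, centroid coordinates, assigned
#'   \code{region} and logical \code{stable}.
#' @export
stabilityReport <- function(points, grouping, baselineTag = "pre",
                            method = c("voronoi", "df1Tertile")) {
  method <- match.arg(method)
  base <- points$tag == baselineTag
  baseCen <- groupCentroids(points[base, , drop = FALSE], grouping[base])
  out <- do.call(rbind, lapply(unique(points$tag), function(tg) {
    sel <- points$tag == tg
    cen <- groupCentroids(points[sel, , drop = FALSE], grouping[sel])
    cen$tag <- tg
    cen
  }))
  out$region <- assignRegion(out, baseCen, method = method)
  out$stable <- as.character(out$region) == as.character(out$group)
  out
}
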