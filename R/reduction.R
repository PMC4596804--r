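# Data reduction: column standardization of the cohort waveform matrix and
# principal component analysis, plus scoring of new subjects against the
# stored model.

#' Standardize the columns of a waveform matrix
#'
#' Centers each column to mean 0 and scales to standard deviation 1
#' (sample SD, n - 1 denominator), storing the means and SDs for later
#' projection of new data.
#'
#' @param m numeric matrix, subjects in rows.
#' @return List with \code{z} (standardized matrix), \code{center} and
#'   \code{scale}.
#' @export
standardizeColumns <- function(m) {
  if (nrow(m) < 2L)
    stop("need at least two rows to standardize", call. = FALSE)
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  if (any(scale == 0))
    stop(sprintf("constant column(s): %s",
                 paste(which(scale == 0), collapse = ", ")), call. = FALSE)
  list(z = sweep(sweep(m, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

# Deterministic component signs: force the largest-magnitude loading of
# each component positive.
.fixSigns <- function(rotation, scores) {
  flip <- vapply(seq_len(ncol(rotation)), function(j) {
    v <- rotation[, j]
    v[which.max(abs(v))] < 0
  }, logical(1L))
  rotation[, flip] <- -rotation[, flip, drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  list(rotation = rotation, scores = scores)
}

#' Fit a PCA model to a cohort waveform matrix
#'
#' Standardizes the subjects-by-600 matrix and computes principal
#' components by singular value decomposition, retaining
#' \code{min(n - 1, ncol)} components ordered by explained variance. With
#' the study's 98-subject reduction cohort this yields 97 components.
#'
#' @param m numeric matrix (subjects x coordinates), or a
#'   \linkS4class{WaveformExperiment}.
#' @return A \linkS4class{PcaModel}.
#' @export
fitPcaModel <- function(m) {
  if (methods::is(m, "WaveformExperiment"))
    m <- t(SummarizedExperiment::assay(m, "angles"))
  std <- standardizeColumns(m)
  fitPca(std$z, center = std$center, scale = std$scale)
}

#' Fit a PCA to an already-standardized matrix
#'
#' @param z standardized matrix (each column mean 0, SD 1); anything else
#'   is an error.
#' @param center,scale the standardization parameters to store with the
#'   model (defaults: zeros and ones).
#' @return A \linkS4class{PcaModel}.
#' @export
fitPca <- function(z, center = rep(0, ncol(z)), scale = rep(1, ncol(z))) {
  if (max(abs(colMeans(z))) > 1e-6)
    stop("input is not column-standardized (non-zero column mean)",
         call. = FALSE)
  n <- nrow(z)
  k <- min(n - 1L, ncol(z))
  sv <- svd(z, nu = k, nv = k)
  sdev <- sv$d / sqrt(n - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  fx <- .fixSigns(sv$v, scores)
  rotation <- fx$rotation
  scores <- fx$scores
  pcNames <- paste0("PC", seq_len(k))
  dimnames(rotation) <- list(colnames(z), pcNames)
  dimnames(scores) <- list(rownames(z), pcNames)
  methods::new("PcaModel", center = center, scale = scale,
               rotation = rotation, sdev = sdev[seq_len(k)],
               varShare = sdev[seq_len(k)]^2 / sum(sdev^2),
               nComponents = k, scores = scores)
}

#' Score waveforms against a fitted PCA model
#'
#' Standardizes each 600-point waveform with the model's stored means and
#' SDs and projects onto the loading vectors. A training subject's scores
#' reproduce the fit-time scores exactly.
#'
#' @param model a \linkS4class{PcaModel}.
#' @param waveform a 600-point vector, a subjects-by-600 matrix, or a
#'   \linkS4class{WaveformExperiment}.
#' @param components indices of components to score (default: all).
#' @return Matrix of scores (subjects x components).
#' @export
pcScores <- function(model, waveform, components = NULL) {
  if (methods::is(waveform, "WaveformExperiment"))
    waveform <- t(SummarizedExperiment::assay(waveform, "angles"))
  if (is.null(dim(waveform))) waveform <- matrix(waveform, nrow = 1L)
  if (ncol(waveform) != length(model@center))
    stop(sprintf("waveform length %d does not match model (%d)",
                 ncol(waveform), length(model@center)), call. = FALSE)
  z <- sweep(sweep(waveform, 2L, model@center), 2L, model@scale, "/")
  rot <- model@rotation
  if (!is.null(components)) rot <- rot[, components, drop = FALSE]
  z %*% rot
}

#' Assemble the candidate predictor table
#'
#' Combines gait PC scores with the four baseline KOOS subscales into one
#' modeling table: with a 98-subject reduction cohort this gives
#' 97 + 4 = 101 candidate predictors. Subjects without complete baseline
#' KOOS are dropped with a warning.
#'
#' @param scores matrix of PC scores (subjects x components), rownames =
#'   subject ids.
#' @param koosBaseline data.frame with \code{id} and the four subscale
#'   columns (one row per subject).
#' @param labels optional named vector/factor of responder labels.
#' @return data.frame of predictors (PC columns then pain, symptoms, adl,
#'   qol), with a \code{label} column appended when labels are given.
#' @export
buildFeatureTable <- function(scores, koosBaseline, labels = NULL) {
  ids <- rownames(scores)
  idx <- match(ids, koosBaseline$id)
  km <- as.data.frame(koosBaseline[idx, .KOOS_SUBSCALES, drop = FALSE])
  ok <- stats::complete.cases(km)
  if (any(!ok))
    warning(sprintf("dropping %d subject(s) without baseline KOOS",
                    sum(!ok)))
  out <- cbind(as.data.frame(scores[ok, , drop = FALSE]),
               km[ok, , drop = FALSE])
  rownames(out) <- ids[ok]
  if (!is.null(labels)) out$label <- labels[ids[ok]]
  out
}
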