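# Wrapper feature selection: sequential forward selection around the
# discriminant classifier under repeated stratified 10-fold cross-validated
# error, with frequency ranking over iterations and a subgroup-size cap.

# Stratified fold assignments: class proportions preserved in every fold.
# Returns an n x repeats integer matrix of fold ids (1..folds).
.makeFolds <- function(y, folds = 10L, repeats = 10L, seed = 1L) {
  y <- as.factor(y)
  minClass <- min(table(y))
  nf <- min(folds, minClass)
  if (nf < folds)
    warning(sprintf("reducing folds from %d to %d (smallest class has %d)",
                    folds, nf, minClass))
  .withSeed(seed, {
    vapply(seq_len(repeats), function(r) {
      f <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep(seq_len(nf), length.out = length(idx)))
      }
      f
    }, integer(length(y)))
  })
}

.asModelMatrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X[, setdiff(colnames(X), "label"),
                                         drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Repeated stratified k-fold cross-validated LDA error
#'
#' For each repeat the subjects are partitioned into stratified folds; the
#' equal-prior linear discriminant classifier is fit on the training folds
#' and the held-out fold classified. Returns the mean misclassification
#' proportion over repeats. Deterministic for a given seed.
#'
#' @param X predictor matrix or data.frame (a \code{label} column is
#'   ignored).
#' @param y class labels (factor or coercible).
#' @param features columns to use (names or indices; default all).
#' @param folds,repeats cross-validation scheme (default 10 x 10).
#' @param seed RNG seed for the fold partitions.
#' @return Mean misclassification proportion; per-repeat proportions in
#'   attribute \code{"perRepeat"}.
#' @export
cvError <- function(X, y, features = NULL, folds = 10L, repeats = 10L,
                    seed = 1L) {
  X <- .asModelMatrix(X)
  y <- as.factor(y)
  if (is.null(features)) features <- seq_len(ncol(X))
  if (is.character(features)) features <- match(features, colnames(X))
  fm <- .makeFolds(y, folds, repeats, seed)
  counts <- cpp_cv_counts(X, as.integer(y), nlevels(y),
                          as.integer(features), fm)
  err <- counts / length(y)
  structure(mean(err), perRepeat = err)
}

#' One sequential-forward-selection run
#'
#' Starts with no predictors and greedily adds the feature giving the
#' greatest reduction in repeated-CV misclassification, stopping when no
#' addition strictly reduces the error. Ties are broken by the smallest
#' column index. The number of selected features is capped at
#' \code{maxFeatures} (default: one less than the smallest class).
#'
#' @inheritParams cvError
#' @param cvSeed seed for this run's fold partitions.
#' @param maxFeatures upper bound on selected features.
#' @return List with \code{selected} (ordered feature names),
#'   \code{errorTrace} (CV error after each addition, strictly decreasing)
#'   and \code{cvSeed}.
#' @export
sequentialForwardSelect <- function(X, y, cvSeed = 1L, folds = 10L,
                                    repeats = 10L,
                                    maxFeatures = min(table(y)) - 1L) {
  X <- .asModelMatrix(X)
  y <- as.factor(y)
  if (ncol(X) < 2L) stop("need at least two candidate features",
                         call. = FALSE)
  fm <- .makeFolds(y, folds, repeats, cvSeed)
  res <- cpp_sfs(X, as.integer(y), nlevels(y), fm,
                 as.integer(maxFeatures))
  list(selected = colnames(X)[res$selected],
       errorTrace = res$errorTrace, cvSeed = cvSeed)
}

#' Repeated selection runs with distinct CV partitions
#'
#' Runs \code{\link{sequentialForwardSelect}} \code{iterations} times, each
#' with a distinct derived seed (so each iteration sees different fold
#' partitions).
#'
#' @inheritParams sequentialForwardSelect
#' @param iterations number of selection runs (default 10).
#' @param baseSeed base seed; run \eqn{i} uses \code{baseSeed + i}.
#' @return List of selection runs.
#' @export
selectFeatures <- function(X, y, iterations = 10L, baseSeed = 1L,
                           folds = 10L, repeats = 10L,
                           maxFeatures = min(table(y)) - 1L) {
  lapply(seq_len(iterations), function(i)
    sequentialForwardSelect(X, y, cvSeed = baseSeed + i, folds = folds,
                            repeats = repeats, maxFeatures = maxFeatures))
}

#' Rank selected features by frequency and cap at the subgroup rule
#'
#' Features are ranked by the fraction of runs selecting them (descending);
#' ties are broken by mean selection position (earlier is better), then by
#' name. The list is capped at one less than the smallest subgroup size.
#'
#' @param runs list of selection runs from \code{\link{selectFeatures}}.
#' @param groupSizes class sizes (vector or table).
#' @return List with \code{ranking} (data.frame: feature, frequency,
#'   meanPosition, rank), \code{cap} and \code{capped} (ordered capped
#'   feature names).
#' @export
rankAndCap <- function(runs, groupSizes) {
  if (length(runs) < 1L) stop("need at least one selection run",
                              call. = FALSE)
  cap <- as.integer(min(groupSizes) - 1L)
  if (cap < 1L) stop("feature cap below 1; smallest subgroup too small",
                     call. = FALSE)
  feats <- unique(unlist(lapply(runs, `[[`, "selected")))
  if (length(feats) == 0L)
    return(list(ranking = data.frame(feature = character(),
                                     frequency = numeric(),
                                     meanPosition = numeric(),
                                     rank = integer()),
                cap = cap, capped = character()))
  freq <- vapply(feats, function(f)
    mean(vapply(runs, function(r) f %in% r$selected, logical(1L))),
    numeric(1L))
  pos <- vapply(feats, function(f) {
    ps <- vapply(runs, function(r) {
      m <- match(f, r$selected)
      if (is.na(m)) NA_real_ else as.numeric(m)
    }, numeric(1L))
    mean(ps, na.rm = TRUE)
  }, numeric(1L))
  ord <- order(-freq, pos, feats)
  ranking <- data.frame(feature = feats[ord], frequency = freq[ord],
                        meanPosition = pos[ord],
                        rank = seq_along(feats), row.names = NULL)
  list(ranking = ranking, cap = cap,
       capped = utils::head(ranking$feature, cap))
}
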