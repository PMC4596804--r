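# Canonical linear discriminant analysis and its diagnostics: Wilks'
# Lambda with Bartlett's chi-squared, Box's M, the structure matrix, a
# Lilliefors normality screen, and the cumulative-entry model search.

#' Fit a canonical linear discriminant model
#'
#' Solves the generalized eigenproblem of the between- and within-group
#' scatter matrices. Discriminant functions are ordered by eigenvalue and
#' scaled so scores have pooled within-group variance 1; class centroids
#' are the class means of the scores. Equal priors by default (configurable).
#'
#' @param X numeric matrix or data.frame of predictors (subjects x p).
#' @param y class labels (factor or coercible); k classes give
#'   \code{min(p, k - 1)} discriminant functions.
#' @param priors per-class prior probabilities (default equal).
#' @return A \linkS4class{DiscriminantFit}.
#' @export
fitLda <- function(X, y, priors = NULL) {
  X <- .asModelMatrix(X)
  y <- as.factor(y)
  k <- nlevels(y)
  n <- nrow(X)
  p <- ncol(X)
  if (k < 2L) stop("need at least two classes", call. = FALSE)
  if (is.null(priors)) priors <- rep(1 / k, k)
  counts <- as.integer(table(y))
  grand <- colMeans(X)
  M <- do.call(rbind, lapply(levels(y), function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  dimnames(M) <- list(levels(y), colnames(X))

  Wsc <- matrix(0, p, p)
  for (cl in seq_len(k)) {
    Xc <- sweep(X[y == levels(y)[cl], , drop = FALSE], 2L, M[cl, ])
    Wsc <- Wsc + crossprod(Xc)
  }
  Bsc <- crossprod(sweep(M, 2L, grand) * sqrt(counts))
  Sw <- Wsc / (n - k)

  U <- tryCatch(chol(Sw), error = function(e)
    stop("singular pooled within-class covariance; reduce the feature set",
         call. = FALSE))
  Ui <- backsolve(U, diag(p))
  eig <- eigen(crossprod(Ui, Bsc %*% Ui), symmetric = TRUE)
  m <- min(p, k - 1L)
  lambda <- pmax(eig$values[seq_len(m)] / (n - k), 0)  # eigenvalues of W^-1 B
  A <- Ui %*% eig$vectors[, seq_len(m), drop = FALSE]

  # deterministic signs: largest-|coefficient| positive per function
  for (j in seq_len(m)) if (A[which.max(abs(A[, j])), j] < 0)
    A[, j] <- -A[, j]
  dimnames(A) <- list(colnames(X), paste0("DF", seq_len(m)))
  constants <- -as.vector(grand %*% A)
  centroids <- sweep(M, 2L, grand) %*% A

  wilks <- prod(1 / (1 + lambda))
  bt <- bartlettChi2(wilks, n = n, p = p, k = k)

  methods::new("DiscriminantFit",
               featureNames = colnames(X), classLevels = levels(y),
               priors = priors, groupMeans = M, pooledCov = Sw,
               grandMean = grand, coefficients = A, constants = constants,
               eigenvalues = lambda,
               betweenVarShares = if (sum(lambda) > 0) lambda / sum(lambda)
                                  else rep(NA_real_, m),
               centroids = centroids, wilksLambda = wilks,
               bartlettChi2 = bt$chi2, bartlettDf = bt$df,
               bartlettP = bt$p, n = as.integer(n))
}

#' Bartlett's chi-squared approximation for Wilks' Lambda
#'
#' \eqn{\chi^2 = -(n - 1 - (p + k)/2) \ln\Lambda} on
#' \eqn{(p - q + 1)(k - q)} degrees of freedom, where \eqn{q} is the index
#' of the first discriminant function under test.
#'
#' @param lambda Wilks' Lambda.
#' @param n number of subjects.
#' @param p number of predictors.
#' @param k number of classes.
#' @param functionsFrom first function tested (default 1: all functions).
#' @return List with \code{lambda}, \code{chi2}, \code{df}, \code{p}.
#' @export
bartlettChi2 <- function(lambda, n, p, k, functionsFrom = 1L) {
  chi2 <- -(n - 1 - (p + k) / 2) * log(lambda)
  df <- (p - functionsFrom + 1) * (k - functionsFrom)
  list(lambda = lambda, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Wilks' Lambda test of the discriminant functions
#'
#' Computes \eqn{\Lambda = \prod_{i \ge q} 1/(1 + \lambda_i)} over the
#' canonical eigenvalues from function \code{functionsFrom} on, with
#' Bartlett's chi-squared approximation.
#'
#' @param fit a \linkS4class{DiscriminantFit}.
#' @param functionsFrom first function included (default 1).
#' @return List with \code{lambda}, \code{chi2}, \code{df}, \code{p}.
#' @export
wilksBartlett <- function(fit, functionsFrom = 1L) {
  lam <- fit@eigenvalues[seq(functionsFrom, length(fit@eigenvalues))]
  bartlettChi2(prod(1 / (1 + lam)), n = fit@n,
               p = length(fit@featureNames),
               k = length(fit@classLevels), functionsFrom = functionsFrom)
}

#' Box's M test of homogeneity of class covariance matrices
#'
#' \eqn{M = (N - k)\ln|S_{pooled}| - \sum_j (n_j - 1)\ln|S_j|} with the
#' standard chi-squared scaling on \eqn{(k - 1)p(p + 1)/2} degrees of
#' freedom.
#'
#' @param X predictor matrix (subjects x p).
#' @param y class labels.
#' @return List with \code{M}, \code{chi2}, \code{df}, \code{p}.
#' @export
boxM <- function(X, y) {
  X <- .asModelMatrix(X)
  y <- as.factor(y)
  k <- nlevels(y)
  p <- ncol(X)
  n <- nrow(X)
  nj <- as.integer(table(y))
  if (any(nj <= p))
    stop("every class needs more than p members for Box's M", call. = FALSE)
  logDet <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)
  Sj <- lapply(levels(y), function(cl) stats::cov(X[y == cl, , drop = FALSE]))
  Sp <- Reduce(`+`, Map(function(S, m) (m - 1) * S, Sj, nj)) / (n - k)
  M <- (n - k) * logDet(Sp) - sum((nj - 1) * vapply(Sj, logDet, numeric(1L)))
  c1 <- (sum(1 / (nj - 1)) - 1 / (n - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi2 <- M * (1 - c1)
  df <- (k - 1) * p * (p + 1) / 2
  list(M = M, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Structure matrix: pooled within-group predictor/function correlations
#'
#' The pooled within-group correlation between each entered predictor and
#' each discriminant-function score; entries of magnitude \eqn{\ge} 0.3 are
#' conventionally read as the variables that define a function. Predictors
#' with zero within-group variance get \code{NA}.
#'
#' @param fit a \linkS4class{DiscriminantFit}.
#' @param X the training predictor matrix.
#' @param y the training labels.
#' @return p x m matrix of correlations in \code{[-1, 1]}.
#' @export
structureMatrix <- function(fit, X, y) {
  X <- .asModelMatrix(X)[, fit@featureNames, drop = FALSE]
  y <- as.factor(y)
  S <- discriminantScores(fit, X)
  Xc <- X
  Sc <- S
  for (cl in levels(y)) {
    idx <- y == cl
    Xc[idx, ] <- sweep(X[idx, , drop = FALSE], 2L,
                       colMeans(X[idx, , drop = FALSE]))
    Sc[idx, ] <- sweep(S[idx, , drop = FALSE], 2L,
                       colMeans(S[idx, , drop = FALSE]))
  }
  covXS <- crossprod(Xc, Sc)
  sdX <- sqrt(colSums(Xc^2))
  sdS <- sqrt(colSums(Sc^2))
  out <- covXS / outer(sdX, sdS)
  out[sdX == 0, ] <- NA_real_
  dimnames(out) <- list(fit@featureNames, colnames(fit@coefficients))
  out
}

#' Lilliefors statistic of a sample
#'
#' Kolmogorov-Smirnov distance between the empirical CDF of the
#' standardized sample and the standard normal CDF.
#'
#' @param x numeric sample.
#' @return The statistic D.
#' @export
lillieforsStatistic <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) stop("constant sample", call. = FALSE)
  z <- sort((x - mean(x)) / s)
  Fz <- stats::pnorm(z)
  max(max(seq_len(n) / n - Fz), max(Fz - (seq_len(n) - 1) / n))
}

#' Lilliefors normality screen with Monte-Carlo p-value
#'
#' The null distribution of the statistic (normal samples with estimated
#' mean and SD) is simulated with a seeded Monte-Carlo table, which is
#' accurate at small n where asymptotic approximations are not.
#'
#' @param x numeric sample (n >= 5).
#' @param nsim Monte-Carlo draws for the null table (default 10000).
#' @param seed seed for the null table.
#' @return List with \code{statistic}, \code{p.value}, \code{n},
#'   \code{nsim}.
#' @export
lillieforsTest <- function(x, nsim = 10000L, seed = 1L) {
  if (length(x) < 5L) stop("need at least 5 observations", call. = FALSE)
  D <- lillieforsStatistic(x)
  sims <- lillieforsNullTable(length(x), nsim = nsim, seed = seed)
  list(statistic = D, p.value = (1 + sum(sims >= D)) / (nsim + 1),
       n = length(x), nsim = nsim)
}

#' Simulated null distribution of the Lilliefors statistic
#'
#' @param n sample size.
#' @param nsim number of null draws.
#' @param seed RNG seed.
#' @return Numeric vector of \code{nsim} null statistics.
#' @export
lillieforsNullTable <- function(n, nsim = 10000L, seed = 1L) {
  .withSeed(seed, vapply(seq_len(nsim), function(i)
    lillieforsStatistic(stats::rnorm(n)), numeric(1L)))
}

#' Discriminant-function scores for new data
#'
#' @param fit a \linkS4class{DiscriminantFit}.
#' @param X matrix or data.frame with the fit's predictors (columns
#'   matched by name when available).
#' @return Matrix of scores (subjects x functions).
#' @export
discriminantScores <- function(fit, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, fit@featureNames))
  X <- .asModelMatrix(X)
  if (!is.null(colnames(X))) {
    missing <- setdiff(fit@featureNames, colnames(X))
    if (length(missing))
      stop(sprintf("missing predictor(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    X <- X[, fit@featureNames, drop = FALSE]
  } else if (ncol(X) != length(fit@featureNames)) {
    stop(sprintf("expected %d predictors, got %d",
                 length(fit@featureNames), ncol(X)), call. = FALSE)
  }
  sweep(X %*% fit@coefficients, 2L, -fit@constants)
}

#' Classify new subjects with a fitted discriminant model
#'
#' Assigns each subject to the class minimizing the squared Euclidean
#' distance to the class centroid in discriminant space (equivalent to
#' Mahalanobis distance under the pooled covariance) adjusted by
#' \eqn{-2\ln(\mathrm{prior})}; exact ties resolve to the first class in
#' the fit's level order.
#'
#' @param fit a \linkS4class{DiscriminantFit}.
#' @param X predictor matrix, data.frame or single feature vector.
#' @return List with \code{class} (factor) and \code{scores}
#'   (discriminant-function scores).
#' @export
classifyLda <- function(fit, X) {
  S <- discriminantScores(fit, X)
  d2 <- vapply(seq_along(fit@classLevels), function(cl)
    rowSums(sweep(S, 2L, fit@centroids[cl, ])^2) - 2 * log(fit@priors[cl]),
    numeric(nrow(S)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  cls <- factor(fit@classLevels[apply(d2, 1L, which.min)],
                levels = fit@classLevels)
  list(class = cls, scores = S)
}

#' @describeIn classifyLda \code{predict} method.
#' @param object a \linkS4class{DiscriminantFit}.
#' @param newdata predictors to classify.
#' @param ... ignored.
#' @export
setMethod("predict", "DiscriminantFit", function(object, newdata, ...)
  classifyLda(object, newdata))

#' Repeated cross-validated classification accuracy
#'
#' @inheritParams cvError
#' @return List with \code{meanAccuracy} and \code{perRepeat}.
#' @export
cvAccuracy <- function(X, y, features = NULL, folds = 10L, repeats = 10L,
                       seed = 1L) {
  err <- cvError(X, y, features = features, folds = folds,
                 repeats = repeats, seed = seed)
  list(meanAccuracy = 1 - as.numeric(err),
       perRepeat = 1 - attr(err, "perRepeat"))
}

#' Cumulative-entry discriminant model search
#'
#' Enters the capped features one at a time in ranking order, computes the
#' repeated-CV classification accuracy of each prefix, and returns the
#' prefix with the greatest mean accuracy (ties to the smaller model),
#' refit on the full data.
#'
#' @param capped ordered capped feature names from \code{\link{rankAndCap}}.
#' @param X predictor table.
#' @param y class labels.
#' @param seed seed for the CV partitions.
#' @param folds,repeats CV scheme.
#' @param priors passed to \code{\link{fitLda}}.
#' @return List with \code{fit} (the refit \linkS4class{DiscriminantFit}),
#'   \code{nFeatures}, \code{meanAccuracy}, \code{perRepeat} and
#'   \code{accuracyByM} (mean accuracy of every prefix).
#' @export
cumulativeModelSearch <- function(capped, X, y, seed = 1L, folds = 10L,
                                  repeats = 10L, priors = NULL) {
  if (length(capped) < 1L) stop("capped feature list is empty",
                                call. = FALSE)
  X <- .asModelMatrix(X)
  accs <- vector("list", length(capped))
  for (m in seq_along(capped)) {
    accs[[m]] <- cvAccuracy(X, y, features = capped[seq_len(m)],
                            folds = folds, repeats = repeats, seed = seed)
  }
  meanAcc <- vapply(accs, `[[`, numeric(1L), "meanAccuracy")
  best <- which.max(meanAcc)   # first max: ties go to the smaller model
  fit <- fitLda(X[, capped[seq_len(best)], drop = FALSE], y,
                priors = priors)
  list(fit = fit, nFeatures = best, meanAccuracy = meanAcc[best],
       perRepeat = accs[[best]]$perRepeat, accuracyByM = meanAcc)
}
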