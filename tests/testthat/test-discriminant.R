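test_that("three groups yield two discriminant functions with unit pooled variance", {
  cl <- makeClusters(n = 13, p = 7, sep = 3, seed = 31)
  fit <- fitLda(cl$X, cl$y)
  expect_equal(ncol(fit@coefficients), 2L)
  expect_equal(length(fit@eigenvalues), 2L)
  expect_gte(fit@eigenvalues[1], fit@eigenvalues[2])
  expect_equal(sum(fit@betweenVarShares), 1, tolerance = 1e-12)
  # scores have pooled within-group variance 1 and are uncorrelated
  S <- discriminantScores(fit, cl$X)
  Sc <- S
  for (g in levels(cl$y)) {
    idx <- cl$y == g
    Sc[idx, ] <- sweep(S[idx, , drop = FALSE], 2,
                       colMeans(S[idx, , drop = FALSE]))
  }
  pooled <- crossprod(Sc) / (nrow(S) - nlevels(cl$y))
  expect_equal(unname(diag(pooled)), c(1, 1), tolerance = 1e-8)
  expect_lt(abs(pooled[1, 2]), 1e-8)
  # centroids are the class means of the scores
  expect_equal(unname(fit@centroids["a", ]),
               unname(colMeans(S[cl$y == "a", ])), tolerance = 1e-10)
})

test_that("two-group solution matches the Fisher closed form", {
  set.seed(32)
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 1.5), 20, 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- fitLda(X, y)
  expect_equal(ncol(fit@coefficients), 1L)
  fisher <- solve(fit@pooledCov,
                  fit@groupMeans["b", ] - fit@groupMeans["a", ])
  cosang <- sum(fit@coefficients * fisher) /
    sqrt(sum(fit@coefficients^2) * sum(fisher^2))
  expect_gt(abs(cosang), 1 - 1e-8)
})

test_that("duplicating every subject preserves directions and separation", {
  cl <- makeClusters(n = 10, p = 4, sep = 2, seed = 33)
  fit1 <- fitLda(cl$X, cl$y)
  fit2 <- fitLda(rbind(cl$X, cl$X), factor(c(as.character(cl$y),
                                             as.character(cl$y))))
  # scatter matrices scale jointly: eigenvalues and Lambda are unchanged
  expect_equal(fit1@eigenvalues, fit2@eigenvalues, tolerance = 1e-8)
  expect_equal(fit1@wilksLambda, fit2@wilksLambda, tolerance = 1e-10)
  # coefficient directions are unchanged; only the unit-within-variance
  # scaling shifts through the (n - k) divisor
  for (j in 1:2) {
    a <- fit1@coefficients[, j] / sqrt(sum(fit1@coefficients[, j]^2))
    b <- fit2@coefficients[, j] / sqrt(sum(fit2@coefficients[, j]^2))
    expect_lt(max(abs(a - b)), 1e-8)
  }
  expect_equal(fit1@coefficients, fit2@coefficients, tolerance = 0.05)
  expect_equal(fit1@centroids, fit2@centroids, tolerance = 0.05)
})

test_that("discriminant scores correlate perfectly with MASS::lda's", {
  skip_if_not_installed("MASS")
  cl <- makeClusters(n = 14, p = 5, sep = 2, seed = 34)
  fit <- fitLda(cl$X, cl$y)
  ref <- MASS::lda(cl$X, grouping = cl$y)
  ours <- discriminantScores(fit, cl$X)
  theirs <- predict(ref, cl$X)$x
  for (j in 1:2)
    expect_gt(abs(cor(ours[, j], theirs[, j])), 1 - 1e-8)
  # and the hardest-margin classifications agree
  expect_identical(as.character(classifyLda(fit, cl$X)$class),
                   as.character(predict(ref, cl$X)$class))
})

test_that("Wilks' Lambda from eigenvalues equals the det(W)/det(T) ratio", {
  for (seed in 35:39) {
    set.seed(seed)
    n <- 30; p <- 4
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- factor(sample(rep(c("a", "b", "c"), each = 10)))
    X[y == "b", 1] <- X[y == "b", 1] + 1
    fit <- fitLda(X, y)
    W <- matrix(0, p, p)
    for (g in levels(y)) {
      Xc <- sweep(X[y == g, ], 2, colMeans(X[y == g, ]))
      W <- W + crossprod(Xc)
    }
    Tt <- crossprod(sweep(X, 2, colMeans(X)))
    expect_equal(fit@wilksLambda, det(W) / det(Tt), tolerance = 1e-10)
  }
})

test_that("Bartlett diagnostics reproduce printed degrees of freedom", {
  bt <- bartlettChi2(0.095, n = 39, p = 7, k = 3)
  expect_equal(bt$df, 14)
  expect_lt(bt$p, 0.001)
  # no-separation limit
  expect_equal(bartlettChi2(1, n = 39, p = 7, k = 3)$chi2, 0)
  # partial test df: functions from the second on
  expect_equal(bartlettChi2(0.5, n = 39, p = 7, k = 3,
                            functionsFrom = 2)$df, 6)
})

test_that("Box's M is zero for identical class data and has the right df", {
  set.seed(45)
  base <- matrix(rnorm(80 * 7), 80, 7)
  X <- rbind(base, base, base)
  y <- factor(rep(c("a", "b", "c"), each = 80))
  bm <- boxM(X, y)
  expect_equal(bm$M, 0, tolerance = 1e-6)
  expect_equal(bm$df, 2 * 7 * 8 / 2)   # (k-1) p (p+1) / 2 = 56
  expect_error(boxM(X[c(1:7, 81:160, 161:240), ],
                    y[c(1:7, 81:160, 161:240)]), "more than p")
})

test_that("structure matrix is a bounded within-group correlation", {
  # class means span a plane so both functions are signal-defined
  set.seed(40)
  n <- 40
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 4), rnorm(n, 0)),
             cbind(rnorm(n, 0), rnorm(n, 4)))
  X <- cbind(X, rnorm(3 * n))
  colnames(X) <- c("s1", "s2", "noise")
  y <- factor(rep(c("a", "b", "c"), each = n))
  fit <- fitLda(X, y)
  sm <- structureMatrix(fit, X, y)
  expect_true(all(abs(sm) <= 1 + 1e-12))
  expect_lt(max(abs(sm["noise", ])), 0.25)
  # with a single predictor the DF score is affine in it: correlation 1
  set.seed(46)
  x1 <- matrix(c(rnorm(20), rnorm(20, 2)), dimnames = list(NULL, "f"))
  y1 <- factor(rep(c("a", "b"), each = 20))
  fit1 <- fitLda(x1, y1)
  sm1 <- structureMatrix(fit1, x1, y1)
  expect_equal(abs(sm1["f", "DF1"]), 1, tolerance = 1e-10)
})

test_that("Lilliefors statistic matches nortest and detects non-normality", {
  skip_if_not_installed("nortest")
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(39)
    expect_equal(lillieforsStatistic(x),
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-10)
  }
  u <- runif(500)
  expect_lt(lillieforsTest(u, nsim = 2000, seed = 2)$p.value, 0.05)
  expect_error(lillieforsStatistic(rep(3, 10)), "constant")
  expect_error(lillieforsTest(rnorm(4)), "at least 5")
})

test_that("classification follows centroids and priors", {
  cl <- makeClusters(n = 12, p = 3, sep = 8, seed = 42)
  fit <- fitLda(cl$X, cl$y)
  # class centroids classify to their own class
  for (g in seq_along(fit@classLevels)) {
    x <- fit@groupMeans[g, ]
    expect_identical(as.character(classifyLda(fit, x)$class),
                     fit@classLevels[g])
  }
  # separable training data classify perfectly
  expect_equal(mean(classifyLda(fit, cl$X)$class == cl$y), 1)
  # equidistant point with unequal priors goes to the higher prior
  set.seed(44)
  X2 <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 4), 20, 2))
  colnames(X2) <- c("f1", "f2")
  y2 <- factor(rep(c("a", "b"), each = 20))
  fit2 <- fitLda(X2, y2, priors = c(0.2, 0.8))
  mid <- colMeans(fit2@groupMeans)   # exactly between the two centroids
  expect_identical(as.character(classifyLda(fit2, mid)$class), "b")
  fit3 <- fitLda(X2, y2, priors = c(0.8, 0.2))
  expect_identical(as.character(classifyLda(fit3, mid)$class), "a")
})

test_that("cumulative entry picks the smallest best prefix", {
  set.seed(43)
  y <- factor(rep(c("a", "b", "c"), each = 15))
  X <- cbind(sep = as.integer(y) * 10 + rnorm(45, sd = 0.2),
             n1 = rnorm(45), n2 = rnorm(45), n3 = rnorm(45))
  res <- cumulativeModelSearch(colnames(X), X, y, seed = 8)
  expect_equal(res$nFeatures, 1L)
  expect_identical(res$fit@featureNames, "sep")
  expect_equal(res$meanAccuracy, 1)
  expect_equal(res$meanAccuracy, max(res$accuracyByM))
  expect_length(res$perRepeat, 10L)
})

test_that("singular pooled covariance is reported, not silently fixed", {
  X <- cbind(a = rep(1:6, 3), b = rep(1:6, 3) * 2)  # collinear
  y <- factor(rep(c("a", "b", "c"), each = 6))
  expect_error(fitLda(X, y), "singular")
})
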