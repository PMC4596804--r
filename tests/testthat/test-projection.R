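# Fixture: a small trained model (PCA + discriminant fit on PC scores and
# baseline ADL) shared by the projection tests.
projFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(50)
    n <- 30
    m <- matrix(rnorm(n * 600, mean = 10, sd = 4), n, 600,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
    grp <- factor(rep(c("Non", "Low", "High"), each = 10),
                  levels = c("Non", "Low", "High"))
    m[grp == "High", 101:118] <- m[grp == "High", 101:118] + 6
    m[grp == "Non", 455:460] <- m[grp == "Non", 455:460] - 6
    pca <- fitPcaModel(m)
    koos <- data.frame(id = rownames(m), pain = rnorm(n, 60, 8),
                       symptoms = rnorm(n, 65, 8),
                       adl = 70 - 8 * (grp == "High") + rnorm(n, sd = 6),
                       qol = rnorm(n, 55, 8))
    ft <- buildFeatureTable(pca@scores, koos)
    feats <- c("PC1", "PC2", "adl")
    fit <- fitLda(ft[, feats], grp)
    cache <<- list(m = m, grp = grp, pca = pca, koos = koos, ft = ft,
                   fit = fit)
    cache
  }
})

test_that("projection round-trips training subjects exactly", {
  fx <- projFixture()
  trainScores <- discriminantScores(fx$fit, fx$ft[, fx$fit@featureNames])
  for (i in c(1, 15, 30)) {
    got <- projectSubject(fx$pca, fx$fit, fx$m[i, ],
                          fx$koos[i, c("pain", "symptoms", "adl", "qol")])
    expect_lt(max(abs(got - trainScores[i, ])), 1e-10)
  }
})

test_that("the mean waveform with mean KOOS projects to the grand centroid", {
  fx <- projFixture()
  koosMean <- colMeans(fx$koos[, c("pain", "symptoms", "adl", "qol")])
  got <- projectSubject(fx$pca, fx$fit, fx$pca@center, koosMean)
  expect_lt(max(abs(got)), 1e-8)   # scores are centred at the grand mean
})

test_that("non-entered PC directions do not move the projection", {
  fx <- projFixture()
  w1 <- fx$m[4, ]
  w2 <- w1 + 3 * fx$pca@scale * fx$pca@rotation[, "PC7"]
  koos <- fx$koos[4, c("pain", "symptoms", "adl", "qol")]
  expect_lt(max(abs(projectSubject(fx$pca, fx$fit, w1, koos) -
                    projectSubject(fx$pca, fx$fit, w2, koos))), 1e-8)
})

test_that("projection is affine in its feature-space inputs", {
  fx <- projFixture()
  k1 <- fx$koos[2, c("pain", "symptoms", "adl", "qol")]
  k2 <- fx$koos[9, c("pain", "symptoms", "adl", "qol")]
  for (a in c(0.25, 0.5, 0.8)) {
    mix <- projectSubject(fx$pca, fx$fit,
                          a * fx$m[2, ] + (1 - a) * fx$m[9, ],
                          a * unlist(k1) + (1 - a) * unlist(k2))
    lin <- a * projectSubject(fx$pca, fx$fit, fx$m[2, ], k1) +
      (1 - a) * projectSubject(fx$pca, fx$fit, fx$m[9, ], k2)
    expect_lt(max(abs(mix - lin)), 1e-8)
  }
})

test_that("missing entered KOOS subscales are named in the error", {
  fx <- projFixture()
  expect_error(projectSubject(fx$pca, fx$fit, fx$m[1, ],
                              c(pain = 60, symptoms = 60, qol = 60)),
               "adl")
})

test_that("controls are projected with perfect scores only", {
  fx <- projFixture()
  ctl <- matrix(fx$pca@center, 2, 600, byrow = TRUE,
                dimnames = list(c("c1", "c2"), NULL))
  pts <- projectControls(fx$pca, fx$fit, ctl)
  expect_identical(pts$tag, rep("control", 2))
  manual <- projectSubject(fx$pca, fx$fit, fx$pca@center,
                           c(pain = 100, symptoms = 100, adl = 100,
                             qol = 100))
  expect_equal(unname(unlist(pts[1, c("df1", "df2")])), unname(manual),
               tolerance = 1e-10)
  empty <- projectControls(fx$pca, fx$fit, ctl[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("group centroids are means with affine equivariance", {
  pts <- data.frame(id = letters[1:4], tag = "pre",
                    df1 = c(-1, 1, 2, 4), df2 = c(-2, 2, 1, 3))
  g <- factor(c("x", "x", "y", "y"))
  cen <- groupCentroids(pts, g)
  expect_equal(cen$df1, c(0, 3))
  expect_equal(cen$df2, c(0, 2))
  single <- groupCentroids(pts[3, ], factor("y"))
  expect_equal(unlist(single[c("df1", "df2")]), c(df1 = 2, df2 = 1))
  shifted <- pts
  shifted$df1 <- pts$df1 + 5
  shifted$df2 <- pts$df2 - 2
  cen2 <- groupCentroids(shifted, g)
  expect_equal(cen2$df1, cen$df1 + 5)
  expect_equal(cen2$df2, cen$df2 - 2)
  expect_warning(groupCentroids(pts, factor(c("x", "x", "y", "y"),
                                            levels = c("x", "y", "z"))),
                 "empty group")
})

test_that("region assignment is the Voronoi partition of the centroids", {
  cen <- data.frame(group = c("Non", "Low", "High"),
                    df1 = c(-2, 0, 3), df2 = c(0, 1, -1))
  # centroids belong to their own regions
  expect_identical(as.character(assignRegion(cen, cen)),
                   c("Non", "Low", "High"))
  # a midpoint nudged toward one centroid takes its label
  mid <- data.frame(df1 = -1 + 1e-6, df2 = 0.5)   # toward Low
  expect_identical(as.character(assignRegion(mid, cen)), "Low")
  mid2 <- data.frame(df1 = -1 - 1e-6, df2 = 0.5)  # toward Non
  expect_identical(as.character(assignRegion(mid2, cen)), "Non")
  # Voronoi property on random points
  set.seed(51)
  pts <- data.frame(df1 = runif(200, -5, 6), df2 = runif(200, -4, 4))
  lab <- assignRegion(pts, cen)
  d <- sapply(1:3, function(i)
    (pts$df1 - cen$df1[i])^2 + (pts$df2 - cen$df2[i])^2)
  expect_identical(as.integer(lab), apply(d, 1, which.min))
  # exact tie resolves in Non < Low < High order
  tie <- data.frame(df1 = -1, df2 = 0.5)  # equidistant Non/Low
  expect_identical(as.character(assignRegion(tie, cen)), "Non")
  # DF1-tertile alternative partitions by df1 midpoints
  t1 <- assignRegion(data.frame(df1 = -1.2, df2 = 99), cen,
                     method = "df1Tertile")
  expect_identical(as.character(t1), "Non")
  t2 <- assignRegion(data.frame(df1 = 2, df2 = -99), cen,
                     method = "df1Tertile")
  expect_identical(as.character(t2), "High")
})

test_that("no-change cohorts keep every subgroup centroid in its region", {
  fx <- projFixture()
  base <- projectCohort(fx$pca, fx$fit, fx$m, fx$koos, tag = "pre")
  post <- projectCohort(fx$pca, fx$fit, fx$m, fx$koos, tag = "post")
  pts <- rbind(base, post)
  grp <- rep(fx$grp, 2)
  rep <- stabilityReport(pts, grp)
  expect_true(all(rep$stable))
  expect_setequal(as.character(rep$tag), c("pre", "post"))
})
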