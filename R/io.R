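# Plain-text cohort interchange: manifest CSV (id, role, true_label), one
# angles CSV per subject (time_s, six channel columns in canonical order,
# event flag column), and a long KOOS CSV (id, phase, four subscales).

#' Write a cohort to a directory of CSV files
#'
#' Writes \code{manifest.csv}, \code{koos.csv} and one
#' \code{angles_<id>.csv} per subject. Gait events are flagged on the
#' nearest sample row of the angles file.
#'
#' @param cohort a \linkS4class{GaitCohort}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeCohortDir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- as.data.frame(cohort@subjects)
  names(manifest) <- c("id", "role", "true_label")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@koos, file.path(dir, "koos.csv"),
                   row.names = FALSE)
  for (id in manifest$id) {
    ss <- cohort@strides[[id]]
    flag <- rep("", length(ss@time))
    idx <- vapply(ss@events$time, function(tm)
      which.min(abs(ss@time - tm)), integer(1L))
    flag[idx] <- ss@events$type
    df <- data.frame(time_s = ss@time, ss@angles, event = flag,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("angles_%s.csv", id)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' Inverse of \code{\link{writeCohortDir}} (event times are recovered at
#' sample resolution).
#'
#' @param dir directory holding \code{manifest.csv}, \code{koos.csv} and
#'   the per-subject angles files.
#' @return A \linkS4class{GaitCohort}.
#' @export
readCohortDir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              colClasses = "character")
  koos <- utils::read.csv(file.path(dir, "koos.csv"))
  strides <- lapply(manifest$id, function(id) {
    df <- utils::read.csv(file.path(dir, sprintf("angles_%s.csv", id)))
    ev <- df$event != ""
    rate <- 1 / stats::median(diff(df$time_s))
    StrideSeries(samplingRate = rate, time = df$time_s,
                 angles = as.matrix(df[.CHANNELS]),
                 events = data.frame(time = df$time_s[ev],
                                     type = df$event[ev]))
  })
  names(strides) <- manifest$id
  lbl <- manifest$true_label
  lbl[lbl == "" | is.na(lbl)] <- NA_character_
  methods::new("GaitCohort",
               subjects = S4Vectors::DataFrame(id = manifest$id,
                                               role = manifest$role,
                                               trueLabel = lbl),
               strides = strides, koos = koos)
}

#' Validate a cohort directory before running the pipeline
#'
#' Checks that files exist and cross-reference (every manifest id has an
#' angles file; every intervention id has pre and post KOOS), that time
#' columns are strictly increasing, that events alternate starting with a
#' foot-strike, and that KOOS values lie in \code{[0, 100]}.
#'
#' @param dir cohort directory.
#' @return data.frame with columns \code{severity} (\code{"fatal"} or
#'   \code{"warning"}) and \code{message}; zero rows when clean.
#' @export
validateCohortDir <- function(dir) {
  issues <- data.frame(severity = character(), message = character())
  add <- function(sev, msg)
    rbind(issues, data.frame(severity = sev, message = msg))
  mf <- file.path(dir, "manifest.csv")
  kf <- file.path(dir, "koos.csv")
  for (f in c(mf, kf)) if (!file.exists(f))
    issues <- add("fatal", sprintf("missing file: %s", f))
  if (nrow(issues)) return(issues)
  manifest <- utils::read.csv(mf, colClasses = "character")
  koos <- utils::read.csv(kf)
  for (id in manifest$id) {
    af <- file.path(dir, sprintf("angles_%s.csv", id))
    if (!file.exists(af)) {
      issues <- add("fatal", sprintf("subject %s: missing angles file", id))
      next
    }
    df <- utils::read.csv(af)
    if (!all(c("time_s", .CHANNELS, "event") %in% names(df)))
      issues <- add("fatal", sprintf("subject %s: bad angles schema", id))
    else {
      if (any(diff(df$time_s) <= 0))
        issues <- add("fatal",
                      sprintf("subject %s: non-monotone time column", id))
      ev <- df$event[df$event != ""]
      if (length(ev)) {
        expect <- rep(c("foot_strike", "toe_off"), length.out = length(ev))
        if (!identical(as.character(ev), expect))
          issues <- add("fatal",
                        sprintf("subject %s: events do not alternate", id))
      }
    }
  }
  sc <- as.matrix(koos[.KOOS_SUBSCALES])
  bad <- which(sc < 0 | sc > 100, arr.ind = TRUE)
  for (i in seq_len(nrow(bad)))
    issues <- add("fatal", sprintf("koos.csv row %d: %s = %g out of [0,100]",
                                   bad[i, 1L], .KOOS_SUBSCALES[bad[i, 2L]],
                                   sc[bad[i, 1L], bad[i, 2L]]))
  iv <- manifest$id[manifest$role == "intervention"]
  post <- koos$id[koos$phase == "post"]
  pre <- koos$id[koos$phase == "pre"]
  for (id in setdiff(iv, intersect(pre, post)))
    issues <- add("fatal",
                  sprintf("intervention subject %s lacks pre+post KOOS", id))
  issues
}

#' Persist a PCA model as a plain-text bundle
#'
#' Writes \code{pca.json} (sdev, variance shares) and CSV files for the
#' centering/scaling vectors and loading matrix, so projections are
#' reproducible across sessions without binary artifacts.
#'
#' @param model a \linkS4class{PcaModel}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writePcaModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(nComponents = model@nComponents,
                            sdev = model@sdev, varShare = model@varShare),
                       file.path(dir, "pca.json"), digits = NA,
                       auto_unbox = TRUE)
  nm <- names(model@center)
  if (is.null(nm)) nm <- sprintf("p%04d", seq_along(model@center))
  utils::write.csv(data.frame(point = nm,
                              center = model@center, scale = model@scale),
                   file.path(dir, "pca_standardization.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(model@rotation),
                   file.path(dir, "pca_loadings.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read back a persisted PCA model
#'
#' @param dir directory written by \code{\link{writePcaModel}}.
#' @return A \linkS4class{PcaModel} (without fitted scores).
#' @export
readPcaModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pca.json"),
                              simplifyVector = TRUE)
  std <- utils::read.csv(file.path(dir, "pca_standardization.csv"))
  rot <- as.matrix(utils::read.csv(file.path(dir, "pca_loadings.csv")))
  rownames(rot) <- std$point
  methods::new("PcaModel",
               center = stats::setNames(std$center, std$point),
               scale = stats::setNames(std$scale, std$point),
               rotation = rot, sdev = meta$sdev, varShare = meta$varShare,
               nComponents = as.integer(meta$nComponents),
               scores = matrix(numeric(0), 0, ncol(rot),
                               dimnames = list(NULL, colnames(rot))))
}

#' Persist a discriminant fit as JSON
#'
#' @param fit a \linkS4class{DiscriminantFit}.
#' @param path output JSON path.
#' @param structure optional structure matrix to store alongside.
#' @return \code{path}, invisibly.
#' @export
writeDiscriminantFit <- function(fit, path, structure = NULL) {
  obj <- list(featureNames = fit@featureNames,
              classLevels = fit@classLevels, priors = fit@priors,
              coefficients = as.data.frame(fit@coefficients),
              constants = fit@constants,
              centroids = as.data.frame(fit@centroids),
              eigenvalues = fit@eigenvalues,
              betweenVarShares = fit@betweenVarShares,
              wilksLambda = fit@wilksLambda,
              bartlettChi2 = fit@bartlettChi2,
              bartlettDf = fit@bartlettDf, bartlettP = fit@bartlettP,
              n = fit@n)
  if (!is.null(structure)) obj$structureMatrix <- as.data.frame(structure)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
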