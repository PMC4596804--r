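# KOOS scoring and responder subgrouping. Each subscale is scored 0-100
# (100 = no symptoms); intervention patients are labeled Non-, Low- or
# High-Responders by the per-patient Cohen's d of KOOS change averaged
# across the four subscales (thresholds 0.2 and 0.8).

.KOOS_SUBSCALES <- c("pain", "symptoms", "adl", "qol")

#' Score one KOOS subscale from Likert item responses
#'
#' Items are scored 0 (no problems) to 4 (extreme problems); the subscale
#' score is \code{100 - mean(items) * 100 / 4}. Missing items are mean-
#' imputed if at most half are missing (the KOOS manual rule); otherwise
#' the subscale is marked missing (\code{NA}).
#'
#' @param responses integer vector of item responses in \code{0:4}
#'   (\code{NA} allowed).
#' @return Score in \code{[0, 100]}, or \code{NA} if more than half the
#'   items are missing.
#' @examples
#' scoreKoosSubscale(c(1, 1, 2, 2))  # 62.5
#' @export
scoreKoosSubscale <- function(responses) {
  ok <- !is.na(responses)
  if (any(!responses[ok] %in% 0:4))
    stop("item responses must be integers in 0..4", call. = FALSE)
  if (sum(!ok) > length(responses) / 2) return(NA_real_)
  100 - mean(responses, na.rm = TRUE) * 100 / 4
}

#' Per-patient Cohen's d of a score change
#'
#' \code{d = (post - pre) / sdRef}; improvement (higher KOOS) is positive.
#'
#' @param pre,post subscale scores.
#' @param sdRef reference standard deviation (> 0).
#' @return Signed effect size (vectorized over \code{pre}/\code{post}).
#' @export
cohenD <- function(pre, post, sdRef) {
  if (any(!is.finite(sdRef)) || any(sdRef <= 0))
    stop("sdRef must be positive", call. = FALSE)
  (post - pre) / sdRef
}

#' Assign a responder label from a mean effect size
#'
#' Non-Responders: \code{d < 0.2}; Low-Responders: \code{0.2 <= d < 0.8};
#' High-Responders: \code{d >= 0.8}. Vectorized.
#'
#' @param meanD signed mean effect size(s); must be finite.
#' @return Factor with levels Non, Low, High.
#' @export
assignResponder <- function(meanD) {
  if (any(!is.finite(meanD)))
    stop("meanD must be finite", call. = FALSE)
  cut(meanD, breaks = c(-Inf, 0.2, 0.8, Inf), labels = .LABELS,
      right = FALSE)
}

#' Subgroup an intervention cohort by per-patient KOOS effect sizes
#'
#' Computes, for every subject with pre and post records, the Cohen's d of
#' change per subscale and its mean across the four subscales, then assigns
#' responder labels. The d denominator is, per subscale, the standard
#' deviation of the cohort's baseline scores (default) or of its change
#' scores.
#'
#' @param koos data.frame with columns \code{id}, \code{phase}
#'   (\code{"pre"}/\code{"post"}) and the four subscale columns
#'   \code{pain}, \code{symptoms}, \code{adl}, \code{qol}.
#' @param denominator \code{"baseline"} (default) or \code{"change"}.
#' @return data.frame with one row per subject: per-subscale d columns
#'   (\code{d_pain}, ...), \code{meanD} and \code{label}; the reference SDs
#'   are attached as attribute \code{"denominators"}. Subjects missing a
#'   subscale are dropped with a warning.
#' @export
subgroupCohort <- function(koos, denominator = c("baseline", "change")) {
  denominator <- match.arg(denominator)
  pre <- koos[koos$phase == "pre", , drop = FALSE]
  post <- koos[koos$phase == "post", , drop = FALSE]
  ids <- intersect(pre$id, post$id)
  if (length(ids) < 2L)
    stop("need at least two subjects with pre and post records",
         call. = FALSE)
  preM <- as.matrix(pre[match(ids, pre$id), .KOOS_SUBSCALES])
  postM <- as.matrix(post[match(ids, post$id), .KOOS_SUBSCALES])
  complete <- stats::complete.cases(preM) & stats::complete.cases(postM)
  if (any(!complete)) {
    warning(sprintf("dropping %d subject(s) with missing subscales: %s",
                    sum(!complete),
                    paste(ids[!complete], collapse = ", ")))
    ids <- ids[complete]
    preM <- preM[complete, , drop = FALSE]
    postM <- postM[complete, , drop = FALSE]
  }
  sds <- if (denominator == "baseline") apply(preM, 2L, stats::sd)
         else apply(postM - preM, 2L, stats::sd)
  if (any(sds <= 0))
    stop(sprintf(
      "zero %s SD in subscale(s) %s; consider denominator = \"change\"",
      denominator, paste(.KOOS_SUBSCALES[sds <= 0], collapse = ", ")),
      call. = FALSE)
  d <- sweep(postM - preM, 2L, sds, "/")
  colnames(d) <- paste0("d_", .KOOS_SUBSCALES)
  meanD <- rowMeans(d)
  out <- data.frame(id = ids, d, meanD = meanD,
                    label = assignResponder(meanD), row.names = NULL)
  attr(out, "denominators") <- sds
  out
}
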