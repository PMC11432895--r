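# DeLong structural components of an AUROC.
# V10[i]: placement of diseased subject i among controls; V01[j]: placement
# of control j among cases. mean(V10) = mean(V01) = AUROC.
delong_components <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  x1 <- scores[y]
  x0 <- scores[!y]
  n1 <- length(x1)
  n0 <- length(x0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  # midrank identity (fast DeLong): the placement count of case i among the
  # controls, with ties worth 1/2, equals its midrank in the pooled sample
  # minus its midrank among the cases. Midranks are exact half-integers, so
  # the AUROC stays bit-identical to exhaustive pair counting.
  r_all <- rank(c(x1, x0), ties.method = "average")
  r1 <- rank(x1, ties.method = "average")
  r0 <- rank(x0, ties.method = "average")
  c10 <- r_all[seq_len(n1)] - r1
  c01 <- n1 - (r_all[n1 + seq_len(n0)] - r0)
  list(v10 = c10 / n0, v01 = c01 / n1, auroc = sum(c10) / (n1 * n0),
       n1 = n1, n0 = n0)
}

#' ROC curve and AUROC with DeLong confidence interval
#'
#' The AUROC is the Mann-Whitney concordance probability, with tied
#' case/control score pairs counted 1/2 (nonparametric, distribution-free).
#' Its variance and 95% CI come from the DeLong structural-components
#' estimator (asymptotic normal bounds, clamped to [0, 1]).
#'
#' @param scores Numeric marker values; higher means more disease-like.
#' @param outcomes Logical/0-1 disease status; both classes required.
#' @return Object of class `roc_result`: `auroc`, `ci_low`, `ci_high`,
#'   `variance`, and `curve` — a data.frame of `threshold`, `sensitivity`,
#'   `specificity` for the positivity rule score >= threshold.
#' @export
roc_auroc <- function(scores, outcomes) {
  comp <- delong_components(scores, outcomes)
  v <- if (comp$n1 > 1) stats::var(comp$v10) / comp$n1 else 0
  v <- v + if (comp$n0 > 1) stats::var(comp$v01) / comp$n0 else 0
  half <- stats::qnorm(0.975) * sqrt(v)
  y <- as.logical(outcomes)
  thr <- sort(unique(scores))
  s1 <- sort(scores[y])
  s0 <- sort(scores[!y])
  n_below_1 <- findInterval(thr, s1, left.open = TRUE)
  n_below_0 <- findInterval(thr, s0, left.open = TRUE)
  curve <- data.frame(
    threshold = c(thr, Inf),
    sensitivity = c((length(s1) - n_below_1) / length(s1), 0),
    specificity = c(n_below_0 / length(s0), 1)
  )
  structure(list(auroc = comp$auroc,
                 ci_low = max(0, comp$auroc - half),
                 ci_high = min(1, comp$auroc + half),
                 variance = v, curve = curve),
            class = "roc_result")
}

#' DeLong test comparing two correlated AUROCs
#'
#' Both markers are measured on the same subjects; the covariance of the two
#' AUROC estimates is taken from the paired DeLong structural components and
#' the two-sided p-value from the normal approximation.
#'
#' @param scores_a,scores_b Paired marker values (same subjects, same order).
#' @param outcomes Logical/0-1 disease status.
#' @return List `auroc_a`, `auroc_b`, `z`, `p_value`, `variance` (of the
#'   difference).
#' @export
delong_test <- function(scores_a, scores_b, outcomes) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(outcomes)) {
    stop("scores_a, scores_b and outcomes must have equal length", call. = FALSE)
  }
  ca <- delong_components(scores_a, outcomes)
  cb <- delong_components(scores_b, outcomes)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / ca$n1 + s01 / ca$n0
  v_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auroc - cb$auroc
  if (v_diff <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v_diff)
  }
  list(auroc_a = ca$auroc, auroc_b = cb$auroc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), variance = v_diff)
}

#' Optimal cut-off by Youden's J
#'
#' Returns the curve threshold maximising J = sensitivity + specificity - 1,
#' operationalising "maximise sensitivity and specificity". Ties are broken
#' towards the higher-sensitivity point (screening intent).
#'
#' @param roc A [roc_auroc()] result with at least 2 curve points.
#' @return List `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_cutoff <- function(roc) {
  curve <- roc$curve
  if (is.null(curve) || nrow(curve) < 2) {
    stop("degenerate ROC curve: need at least 2 points", call. = FALSE)
  }
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[which.max(curve$sensitivity[best])]
  }
  list(threshold = curve$threshold[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       youden_j = j[best])
}
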