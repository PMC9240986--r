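# Discrimination and association statistics: the c statistic with the
# Hanley-McNeil standard error, comparison of two c statistics, Yates-
# corrected chi-squared, and the pooled-variance t test.

#' The c statistic (area under the ROC curve) with Hanley-McNeil SE
#'
#' Estimates the probability that a randomly chosen outcome-positive
#' subject scores higher than a randomly chosen outcome-negative one, with
#' tied pairs counting one half (the Mann-Whitney convention — essential
#' here, because a 4-level score makes ties ubiquitous). Computed from
#' mid-ranks, which is algebraically identical to the all-pairs count.
#'
#' @param scores Numeric or ordinal score per subject (higher = sicker).
#' @param outcomes Binary outcome per subject (logical, or 0/1).
#' @return List of class `khds_roc`: `auc`, `se` (Hanley-McNeil),
#'   `n_pos`, `n_neg`.
#' @seealso [hanley_mcneil_se], [compare_c_statistics]
#' @export
#' @examples
#' c_statistic(c(3, 2, 2, 1, 0, 0), c(1, 1, 0, 0, 0, 0))$auc  # 0.9375
c_statistic <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]
  outcomes <- outcomes[keep]
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  if (n_pos < 1 || n_neg < 1) {
    stop_khds("discrimination undefined: need at least one positive and one negative outcome",
              "khds_degenerate_error")
  }
  r <- rank(scores)  # mid-ranks handle ties
  auc <- (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc,
                 se = hanley_mcneil_se(auc, n_pos, n_neg),
                 n_pos = n_pos, n_neg = n_neg),
            class = "khds_roc")
}

#' @export
print.khds_roc <- function(x, ...) {
  cat(sprintf("c statistic %.3f SE %.3f (%d positive, %d negative)\n",
              x$auc, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil standard error of a c statistic
#'
#' Closed-form SE depending only on the area A and the group sizes:
#' with Q1 = A / (2 - A) and Q2 = 2 A^2 / (1 + A),
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_+ - 1)(Q_1 - A^2) + (n_- - 1)(Q_2 - A^2)}{n_+ n_-}}}
#' It is zero at A = 0 or 1 and strictly decreasing in either group size
#' for fixed A in (0, 1).
#'
#' @param auc The c statistic A, in \[0, 1\].
#' @param n_pos,n_neg Counts of outcome-positive and -negative subjects
#'   (each at least 1).
#' @return The standard error (scalar, vectorises over inputs).
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (any(auc < 0 | auc > 1)) {
    stop_khds("auc must lie in [0, 1]", "khds_argument_error")
  }
  if (any(n_pos < 1) || any(n_neg < 1)) {
    stop_khds("n_pos and n_neg must each be at least 1",
              "khds_argument_error")
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(pmax(v, 0))
}

#' Compare two c statistics by a z test
#'
#' Standardises the difference A1 - A2 by
#' sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2) and reports the one-tailed upper
#' normal tail probability P(Z >= |z|); the sign of the difference is
#' carried separately in `delta`. The default treats the two estimates as
#' uncorrelated (`method = "independent"`, r = 0); `method = "paired"`
#' accepts a user-supplied correlation for comparisons made on the same
#' patients.
#'
#' @param r1,r2 `khds_roc` results (or lists with `auc` and `se`).
#' @param method `"independent"` (default) or `"paired"`.
#' @param r Correlation between the two estimates, used when
#'   `method = "paired"`; in \[0, 1\].
#' @return List of class `khds_auc_cmp`: `delta` (A1 - A2), `z`, `p`
#'   (one-tailed).
#' @export
compare_c_statistics <- function(r1, r2,
                                 method = c("independent", "paired"),
                                 r = 0) {
  method <- match.arg(method)
  if (method == "independent") r <- 0
  if (r < 0 || r > 1) {
    stop_khds("correlation r must lie in [0, 1]", "khds_argument_error")
  }
  denom2 <- r1$se^2 + r2$se^2 - 2 * r * r1$se * r2$se
  if (denom2 <= 0) {
    stop_khds("degenerate comparison: variance of the difference is zero",
              "khds_degenerate_error")
  }
  delta <- r1$auc - r2$auc
  z <- delta / sqrt(denom2)
  structure(list(delta = delta, z = z,
                 p = stats::pnorm(abs(z), lower.tail = FALSE)),
            class = "khds_auc_cmp")
}

#' @export
print.khds_auc_cmp <- function(x, ...) {
  cat(sprintf("delta %+.3f, z %.2f, one-tailed p %s\n",
              x$delta, x$z, format_p(x$p)))
  invisible(x)
}

#' Chi-squared association test with Yates' continuity correction
#'
#' For a 2x2 table the Yates-corrected statistic
#' \eqn{n(|ad - bc| - n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]} is used (clamped at
#' zero when the correction exceeds |ad - bc|); larger tables use the
#' uncorrected Pearson statistic — the correction applies to 2x2 tables
#' only.
#'
#' @param table Matrix of non-negative integer counts with positive
#'   margins.
#' @return List of class `khds_chi2`: `chi2`, `df`, `p`, `yates_applied`.
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) {
    stop_khds("counts must be non-negative", "khds_argument_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_khds("undefined test: table has a zero margin",
              "khds_degenerate_error")
  }
  yates <- all(dim(table) == c(2, 2))
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(list(chi2 = unname(ct$statistic),
                 df = as.integer(unname(ct$parameter)),
                 p = unname(ct$p.value), yates_applied = yates),
            class = "khds_chi2")
}

#' Pooled-variance two-sample t test
#'
#' Student's t with the pooled variance estimate and a two-sided p-value,
#' for comparing numeric variables between two groups.
#'
#' @param sample1,sample2 Numeric vectors, each of length at least 2.
#' @return List with `t`, `df`, `p`.
#' @export
student_t <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    stop_khds("each sample needs at least 2 observations",
              "khds_argument_error")
  }
  if (stats::var(sample1) == 0 && stats::var(sample2) == 0) {
    stop_khds("degenerate test: zero pooled variance",
              "khds_degenerate_error")
  }
  tt <- stats::t.test(sample1, sample2, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}
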