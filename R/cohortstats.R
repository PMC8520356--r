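## Cohort-level statistical evaluation: two-sample t-tests (pooled and
## Welch, one- or two-tailed), 2x2 chi-squared, two-rater ICC(2,1),
## empirical ROC with Mann-Whitney AUC, and the Youden-optimal cutoff.

test_result <- function(statistic, df, p_value, tails, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 tails = tails, method = method),
            class = "neoventry_test")
}

#' @export
print.neoventry_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, df = %.4g, p (%s-tailed) = %.4g\n",
              x$method, x$statistic, x$df, x$tails, x$p_value))
  invisible(x)
}

#' Independent two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] exposing the pooled-variance and
#' Welch forms and one- or two-tailed p-values. The one-tailed alternative
#' is `x > y` (upper tail of t). The degenerate case of two constant
#' samples with equal means returns t = 0 (p = 1 two-tailed, 0.5
#' one-tailed); constant samples otherwise are an error for the pooled
#' form.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param tails `"one"` or `"two"`.
#' @param method `"pooled"` or `"welch"`.
#' @return a test-result object: `statistic`, `df`, `p_value`, `tails`,
#'   `method`.
#' @export
t_two_sample <- function(x, y, tails = c("two", "one"),
                         method = c("pooled", "welch")) {
  tails <- match.arg(tails); method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      df <- if (method == "pooled") length(x) + length(y) - 2 else NA_real_
      return(test_result(0, df, if (tails == "two") 1 else 0.5, tails, method))
    }
    if (method == "pooled") stop("pooled t undefined: zero variance in both groups")
  }
  alt <- if (tails == "two") "two.sided" else "greater"
  ht <- stats::t.test(x, y, alternative = alt,
                      var.equal = (method == "pooled"))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              tails, method)
}

#' Two-sample t-test from group summary statistics
#'
#' Pooled: `t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`. Welch uses the separate-variance statistic with
#' Welch-Satterthwaite degrees of freedom. One-tailed p is the upper-tail
#' probability for the direction group 1 > group 2.
#'
#' @param m1,s1,n1 mean, SD, and size of group 1 (`n1 >= 2`, `s1 > 0`).
#' @param m2,s2,n2 likewise for group 2.
#' @param tails,method as in [t_two_sample()].
#' @return a test-result object.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                           tails = c("two", "one"),
                           method = c("pooled", "welch")) {
  tails <- match.arg(tails); method <- match.arg(method)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("SDs must be > 0")
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- if (tails == "two") 2 * stats::pt(-abs(t), df) else
    stats::pt(t, df, lower.tail = FALSE)
  test_result(t, df, p, tails, method)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param yates apply the Yates continuity correction.
#' @return a test-result object (`df = 1`).
#' @export
chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty table")
  tab <- rbind(c(a, b), c(c, d))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a marginal total is zero; chi-squared undefined")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  test_result(unname(ht$statistic), 1, ht$p.value, "two",
              if (yates) "chi2_yates" else "chi2")
}

#' Two-rater intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#' with k = 2 raters, where MS_R, MS_C, MS_E are the subject, rater, and
#' residual mean squares of the two-way ANOVA (via [stats::aov()]).
#' Absolute agreement penalizes a systematic between-rater bias.
#'
#' @param pairs n x 2 numeric matrix (or data frame): one row per subject,
#'   one column per rater; `n >= 3`.
#' @return an `icc_result`: `icc`, `n_subjects`, `n_raters`, the three
#'   mean squares, and the model label.
#' @export
icc_two_rater <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have exactly two rater columns")
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(pairs)) stop("missing measurements")
  if (stats::var(as.vector(pairs)) == 0)
    stop("zero total variance; ICC undefined")
  k <- 2
  long <- data.frame(y = as.vector(pairs),
                     subject = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, n_subjects = n, n_raters = k,
                 ms_subjects = msr, ms_raters = msc, ms_error = mse,
                 model = "two-way-random-absolute-agreement-single"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  (n = %d subjects, %d raters, absolute agreement)\n",
              x$icc, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Empirical (non-parametric) ROC curve
#'
#' Cutoffs are the distinct observed scores. With direction `"high"` a
#' subject is called positive when its score exceeds the cutoff (for
#' direction `"low"`, when below). The AUC is the Mann-Whitney
#' probability: concordant pairs plus half the tied pairs, over all
#' positive-negative pairs.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or two-level factor);
#'   1/TRUE = positive class. Both classes must be present.
#' @param positive_direction `"high"` (default) or `"low"`.
#' @return a `roc_result`: `cutoffs`, `sensitivity`, `specificity`, `auc`,
#'   `youden_cutoff`, `youden_value`, `positive_direction`.
#' @export
roc_empirical <- function(scores, labels, positive_direction = c("high", "low")) {
  positive_direction <- match.arg(positive_direction)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("missing values")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  s <- if (positive_direction == "high") scores else -scores
  cutoffs <- sort(unique(s))
  ## positive call: s > c
  sens <- vapply(cutoffs, function(cc) sum(s > cc & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(cutoffs, function(cc) sum(s <= cc & labels == 0) / n_neg,
                 numeric(1))
  ## Mann-Whitney AUC via midranks (ties get half credit)
  r <- rank(s)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  j <- sens + spec - 1
  i_best <- which.max(j)    # first maximum = smallest cutoff
  cut_best <- cutoffs[i_best]
  report_cut <- if (positive_direction == "high") cut_best else -cut_best
  structure(list(cutoffs = if (positive_direction == "high") cutoffs else rev(-cutoffs),
                 sensitivity = if (positive_direction == "high") sens else rev(sens),
                 specificity = if (positive_direction == "high") spec else rev(spec),
                 auc = auc,
                 youden_cutoff = report_cut, youden_value = j[i_best],
                 positive_direction = positive_direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f over %d cutoffs (positive = %s); Youden J = %.3f at cutoff %.4g\n",
              x$auc, length(x$cutoffs), x$positive_direction,
              x$youden_value, x$youden_cutoff))
  invisible(x)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' The cutoff maximizing `J = sensitivity + specificity - 1`; ties are
#' broken by the smallest cutoff.
#'
#' @param roc a `roc_result` from [roc_empirical()].
#' @return list `cutoff`, `youden_value`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  i <- best[which.min(roc$cutoffs[best])]
  list(cutoff = roc$cutoffs[i], youden_value = j[i])
}

#' Closed-form AUC for two normal classes
#'
#' `Phi((m1 - m2) / sqrt(s1^2 + s2^2))`: the ROC area when the positive
#' class is N(m1, s1^2) and the negative class is N(m2, s2^2). Used as the
#' analytic oracle for the ROC simulation checks.
#'
#' @param m1,s1 positive-class mean and SD.
#' @param m2,s2 negative-class mean and SD.
#' @return the binormal AUC.
#' @export
binormal_auc <- function(m1, s1, m2, s2) {
  if (s1 <= 0 || s2 <= 0) stop("SDs must be > 0")
  stats::pnorm((m1 - m2) / sqrt(s1^2 + s2^2))
}

#' Per-index group comparison report for a cohort
#'
#' For each index: group means and SDs, the two-sample t-test (direction
#' group 1 > group 2 when one-tailed), and for the indices compared by ROC
#' the empirical AUC and Youden-optimal cutoff (positive class = first
#' group, positive direction = high).
#'
#' @param cohort a `cohort_table` (see [sample_cohort()]); the first group
#'   level in `positive_group` is treated as the diseased class.
#' @param positive_group group label of the positive class (default the
#'   first group in the table).
#' @param tails,method forwarded to [t_two_sample()].
#' @param roc_indices indices for which ROC/Youden are computed.
#' @return list keyed by index, plus `groups`; each entry carries
#'   `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`, `t`, and optionally `roc`.
#' @export
cohort_stats <- function(cohort, positive_group = NULL,
                         tails = "two", method = "pooled",
                         roc_indices = c("d_ratio", "c_ratio")) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  groups <- unique(cohort$group)
  if (length(groups) != 2) stop("cohort must contain exactly two groups")
  if (is.null(positive_group)) positive_group <- groups[1]
  neg_group <- setdiff(groups, positive_group)
  out <- list()
  for (index in c("f_ratio", "d_ratio", "c_ratio", "evans")) {
    xs <- cohort[[index]][cohort$group == positive_group]
    ys <- cohort[[index]][cohort$group == neg_group]
    entry <- list(mean_pos = mean(xs), sd_pos = stats::sd(xs),
                  mean_neg = mean(ys), sd_neg = stats::sd(ys),
                  t = t_two_sample(xs, ys, tails = tails, method = method))
    if (index %in% roc_indices) {
      roc <- roc_empirical(cohort[[index]],
                           cohort$group == positive_group,
                           positive_direction = "high")
      entry$roc <- roc
    }
    out[[index]] <- entry
  }
  out$groups <- c(positive = positive_group, negative = neg_group)
  out
}
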