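## Independent first-principles oracles used to cross-check the package
## implementations. These deliberately use loop-based, definitional
## computations rather than the package's vectorized code paths.

## Exhaustive between-class variance maximizer (definitional Otsu).
otsu_brute <- function(counts) {
  L <- length(counts); g <- 0:(L - 1); n <- sum(counts)
  best_t <- 0L; best_v <- -Inf
  for (t in 0:(L - 2)) {
    n0 <- sum(counts[1:(t + 1)]); n1 <- n - n0
    v <- if (n0 == 0 || n1 == 0) 0 else {
      mu0 <- sum(g[1:(t + 1)] * counts[1:(t + 1)]) / n0
      mu1 <- sum(g[(t + 2):L] * counts[(t + 2):L]) / n1
      (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

## Pairwise Mann-Whitney AUC: concordant pairs + half ties.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

## Two-way ANOVA mean squares from definitional sums of squares,
## then the ICC(2,1) absolute-agreement combination.
icc_brute <- function(pairs) {
  n <- nrow(pairs); k <- ncol(pairs)
  grand <- mean(pairs)
  row_m <- rowMeans(pairs); col_m <- colMeans(pairs)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((pairs - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  msr <- ss_r / (n - 1); msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

## Trapezoidal area under the (FPR, TPR) polygon, endpoints included.
auc_trapezoid <- function(roc) {
  fpr <- c(1, 1 - roc$specificity, 0)
  tpr <- c(1, roc$sensitivity, 0)
  sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

## A random small phantom spec with index ratios in a requested range.
random_phantom_spec <- function(seed, ratio_lo = 0.1, ratio_hi = 0.4,
                                noise_sigma = 0, bias_amplitude = 0) {
  set.seed(seed)
  a <- runif(1, 38, 44); b <- runif(1, 42, 46)
  ## target ratios drawn independently; spans derived from the geometry
  f_r <- runif(1, ratio_lo, ratio_hi)
  d_r <- runif(1, ratio_lo, ratio_hi)
  c_r <- runif(1, ratio_lo, min(ratio_hi, d_r))   # caudate narrower than body
  ## approximate same-level brain widths (exact rows depend on the raster;
  ## spans scaled off slightly-conservative widths keep geometry valid)
  phantom_spec(brain_semi_axes = c(a, b),
               frontal_horn_span = f_r * 2 * a * 0.9,
               body_outer_span = d_r * 2 * a * 0.95,
               caudate_span = c_r * 2 * a * 0.9,
               noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
               seed = seed)
}

## Quantization tolerance for a ratio num/den measured on a raster with
## pixel size sp: one pixel in the numerator and one in the denominator.
ratio_tol <- function(num, den, sp) sp / den + num * sp / den^2 + 1e-9

## Absolute comparison at one-pixel quantization (expect_equal's tolerance
## is relative, which is the wrong scale for ratio differences).
expect_ratio_close <- function(actual, expected, num, den, sp) {
  expect_lt(abs(actual - expected), ratio_tol(num, den, sp))
}
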