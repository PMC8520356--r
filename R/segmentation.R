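## Hybrid global/local Otsu threshold segmentation guided by Sobel-gradient
## pixel classification: gradient map -> detail/remainder pixel classes ->
## per-class Otsu thresholds -> merged binary map.

## 3x3 cross-correlation with replicate-padded borders.
conv3 <- function(m, k) {
  M <- nrow(m); N <- ncol(m)
  p <- m[c(1, seq_len(M), M), c(1, seq_len(N), N)]
  out <- matrix(0, M, N)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0) out <- out + w * p[(seq_len(M)) + dr + 1, (seq_len(N)) + dc + 1]
  }
  out
}

#' Sobel gradient map of a grayscale slice
#'
#' Computes the gradient magnitude `S = sqrt(Gx^2 + Gy^2)` with the standard
#' 3x3 Sobel kernels (borders by edge replication), its global mean `S_avg`,
#' and the 3x3 local window means `S_mu` of the magnitude map (also
#' edge-replicated).
#'
#' @param img a [gray_image()] (or plain integer matrix, at least 3 x 3).
#' @return a `gradient_map` object with fields `S`, `S_avg`, `S_mu`.
#' @export
sobel_gradient <- function(img) {
  m <- unclass(as.matrix(img))
  storage.mode(m) <- "double"
  if (nrow(m) < 3 || ncol(m) < 3) stop("image must be at least 3 x 3")
  kx <- outer(c(1, 2, 1), c(-1, 0, 1))    # column-direction derivative
  ky <- t(kx)                              # row-direction derivative
  gx <- conv3(m, kx)
  gy <- conv3(m, ky)
  S <- sqrt(gx^2 + gy^2)
  box <- matrix(1 / 9, 3, 3)
  structure(list(S = S, S_avg = mean(S), S_mu = conv3(S, box)),
            class = "gradient_map")
}

#' Classify pixels into detail and remainder classes
#'
#' A pixel belongs to the detail class (label 1) when both its gradient
#' magnitude and the 3x3 local mean gradient strictly exceed the global mean
#' gradient: `min(S(i,j), S_mu(i,j)) > S_avg`. Requiring the local window
#' mean as well suppresses isolated noise spikes, which have a high `S` but
#' a diluted `S_mu`; on a constant image (`S_avg = 0`) no pixel is labelled
#' detail, so the downstream segmentation reduces to plain global Otsu.
#'
#' @param grad a `gradient_map` from [sobel_gradient()].
#' @return a `label_map`: integer matrix with 1 = detail, 2 = remainder.
#' @export
classify_pixels <- function(grad) {
  stopifnot(inherits(grad, "gradient_map"))
  lab <- ifelse(pmin(grad$S, grad$S_mu) > grad$S_avg, 1L, 2L)
  structure(lab, class = c("label_map", "matrix"))
}

#' Otsu threshold by exhaustive between-class variance maximization
#'
#' Evaluates the between-class variance
#' `sigma_B^2(t) = w0(t) w1(t) (mu0(t) - mu1(t))^2` at every candidate
#' threshold `t` in `[0, L-2]`, with class 0 the pixels of gray level
#' `<= t`, and returns the smallest maximizing `t`. A histogram with a
#' single occupied bin is degenerate: the threshold returned is that gray
#' value and `degenerate` is set.
#'
#' @param x a [gray_image()], a numeric matrix/vector of gray values, or a
#'   histogram of counts over gray levels `0 .. L-1` (named `counts`).
#' @param gray_levels number of gray levels L.
#' @return list with `threshold`, `degenerate`, and the `between_var` curve
#'   (length L-1, index t+1).
#' @export
otsu_threshold <- function(x, gray_levels = 256L) {
  if (inherits(x, "gray_image")) {
    gray_levels <- attr(x, "gray_levels")
    counts <- tabulate(as.vector(x) + 1L, nbins = gray_levels)
  } else if (is.matrix(x) || (is.numeric(x) && length(x) > gray_levels)) {
    counts <- tabulate(as.vector(x) + 1L, nbins = gray_levels)
  } else {
    counts <- as.numeric(x)
    if (length(counts) != gray_levels) {
      ## short numeric vectors are gray values, not a histogram
      counts <- tabulate(as.vector(x) + 1L, nbins = gray_levels)
    }
  }
  if (sum(counts) == 0) stop("empty histogram")
  L <- gray_levels
  occupied <- which(counts > 0) - 1L
  if (length(occupied) == 1L) {
    return(list(threshold = occupied, degenerate = TRUE,
                between_var = rep(0, L - 1)))
  }
  p <- counts / sum(counts)
  g <- 0:(L - 1)
  w0 <- cumsum(p)[1:(L - 1)]
  mu_cum <- cumsum(p * g)[1:(L - 1)]
  mu_T <- sum(p * g)
  w1 <- 1 - w0
  num <- (mu_T * w0 - mu_cum)^2
  sigma_b <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), 0)
  t_best <- which.max(sigma_b) - 1L   # which.max takes the first maximum
  list(threshold = t_best, degenerate = FALSE, between_var = sigma_b)
}

#' Global threshold segmentation
#'
#' @param img gray image or matrix.
#' @param T gray-level threshold in `[0, L-1]`.
#' @param foreground `"above"` marks pixels with `f > T` as foreground (the
#'   default, for bright targets); `"below"` inverts the polarity for
#'   bright-CSF acquisitions where the target is dark.
#' @return logical matrix, TRUE = foreground.
#' @export
global_segment <- function(img, T, foreground = c("above", "below")) {
  foreground <- match.arg(foreground)
  m <- unclass(as.matrix(img))
  L <- gray_levels(img)
  if (T < 0 || T > L - 1) stop("threshold out of range [0, L-1]")
  if (foreground == "above") m > T else m <= T
}

#' Multi-threshold segmentation
#'
#' Partitions gray values into `n + 1` classes by `n` strictly ascending
#' thresholds: class `k` holds pixels with `T_k < f <= T_{k+1}` (with
#' `T_0 = -Inf`, `T_{n+1} = +Inf`).
#'
#' @param img gray image or matrix.
#' @param thresholds strictly ascending numeric vector.
#' @return integer matrix of class labels `0 .. n`.
#' @export
multi_segment <- function(img, thresholds) {
  if (length(thresholds) == 0) stop("at least one threshold is required")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  m <- unclass(as.matrix(img))
  k <- findInterval(m, thresholds, left.open = TRUE)
  matrix(as.integer(k), nrow(m), ncol(m))
}

#' Split an image into detail and remainder sub-images
#'
#' The detail sub-image `I1` is the set of pixels labelled detail by
#' [classify_pixels()]; `I2` is its complement. The whole-image Otsu
#' threshold is recorded alongside, as the fallback threshold for
#' degenerate sub-images.
#'
#' @param img gray image (unused beyond dimension checks; kept for the
#'   pipeline contract).
#' @param labels a `label_map`.
#' @param T_otsu whole-image Otsu threshold.
#' @return list `I1_mask`, `I2_mask`, `T_otsu`.
#' @export
decompose_subimages <- function(img, labels, T_otsu) {
  stopifnot(all(dim(as.matrix(img)) == dim(labels)))
  I1 <- unclass(labels) == 1L
  list(I1_mask = I1, I2_mask = !I1, T_otsu = T_otsu)
}

#' Threshold one sub-image
#'
#' Computes the Otsu threshold over the member pixels only and thresholds
#' those pixels; pixels outside the membership mask are zero. Degenerate
#' memberships (at most one distinct gray value) fall back to the
#' whole-image Otsu threshold; an empty membership returns an all-zero map
#' with a warning.
#'
#' @param img gray image.
#' @param member_mask logical matrix selecting the sub-image pixels.
#' @param T_otsu whole-image fallback threshold.
#' @param foreground polarity, as in [global_segment()].
#' @return list `threshold`, `binary` (zero outside the membership),
#'   `degenerate`.
#' @export
threshold_subimage <- function(img, member_mask, T_otsu,
                               foreground = c("above", "below")) {
  foreground <- match.arg(foreground)
  m <- unclass(as.matrix(img))
  member_mask <- as_mask(member_mask)
  L <- gray_levels(img)
  vals <- m[member_mask]
  if (length(vals) == 0) {
    warning("empty sub-image membership; falling back to whole-image threshold")
    return(list(threshold = T_otsu,
                binary = matrix(FALSE, nrow(m), ncol(m)), degenerate = TRUE))
  }
  if (length(unique(vals)) <= 1) {
    Tk <- T_otsu; degen <- TRUE
  } else {
    ot <- otsu_threshold(tabulate(vals + 1L, nbins = L), gray_levels = L)
    Tk <- ot$threshold; degen <- FALSE
  }
  B <- global_segment(img, Tk, foreground) & member_mask
  list(threshold = Tk, binary = B, degenerate = degen)
}

#' Merge per-sub-image binary maps
#'
#' `B(i,j) = B1(i,j)` for pixels of the detail sub-image and `B2(i,j)`
#' otherwise. The membership masks must partition the image: no overlap
#' between the segmented areas, and every pixel covered.
#'
#' @param B1,B2 binary maps from [threshold_subimage()].
#' @param I1_mask,I2_mask the membership masks.
#' @return logical matrix B.
#' @export
merge_masks <- function(B1, B2, I1_mask, I2_mask) {
  I1_mask <- as_mask(I1_mask); I2_mask <- as_mask(I2_mask)
  if (any(I1_mask & I2_mask)) stop("sub-image masks overlap")
  if (!all(I1_mask | I2_mask)) stop("sub-image masks do not cover the image")
  B1 <- as_mask(B1); B2 <- as_mask(B2)
  ifelse(I1_mask, B1, B2)
}

#' Adaptive hybrid threshold segmentation
#'
#' The full pipeline: Sobel gradient map, detail/remainder pixel
#' classification, whole-image Otsu threshold, sub-image decomposition,
#' per-sub-image Otsu thresholds, and the merged binary map. The detail
#' sub-image (edge-band pixels) receives its own threshold, which adapts to
#' local contrast at structure boundaries; the remainder behaves like
#' global Otsu. On images with no detail pixels the result reduces exactly
#' to global Otsu.
#'
#' @param img a [gray_image()] or integer matrix.
#' @param foreground polarity, as in [global_segment()].
#' @return an `hvs_segmentation` object retaining all intermediates:
#'   `gradient`, `label_map`, `T_otsu`, `T1`, `T2`, `I1_mask`, `I2_mask`,
#'   `B1`, `B2`, and the merged `B`.
#' @export
hvs_segment <- function(img, foreground = c("above", "below")) {
  foreground <- match.arg(foreground)
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  grad <- sobel_gradient(img)
  labels <- classify_pixels(grad)
  T_otsu <- otsu_threshold(img)$threshold
  dec <- decompose_subimages(img, labels, T_otsu)
  s1 <- threshold_subimage(img, dec$I1_mask, T_otsu, foreground)
  s2 <- threshold_subimage(img, dec$I2_mask, T_otsu, foreground)
  B <- merge_masks(s1$binary, s2$binary, dec$I1_mask, dec$I2_mask)
  structure(list(gradient = grad, label_map = labels, T_otsu = T_otsu,
                 T1 = s1$threshold, T2 = s2$threshold,
                 I1_mask = dec$I1_mask, I2_mask = dec$I2_mask,
                 B1 = s1$binary, B2 = s2$binary, B = B,
                 foreground = foreground),
            class = "hvs_segmentation")
}

#' @export
print.hvs_segmentation <- function(x, ...) {
  cat(sprintf("<hvs_segmentation> %d x %d; T_otsu = %d, T1 = %d (detail, %d px), T2 = %d\n",
              nrow(x$B), ncol(x$B), x$T_otsu, x$T1, sum(x$I1_mask), x$T2))
  cat(sprintf("foreground ('%s' threshold): %d px (%.1f%%)\n", x$foreground,
              sum(x$B), 100 * mean(x$B)))
  invisible(x)
}

#' Global Otsu segmentation (single-threshold baseline)
#'
#' @inheritParams hvs_segment
#' @return logical foreground map.
#' @export
otsu_segment <- function(img, foreground = c("above", "below")) {
  foreground <- match.arg(foreground)
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  global_segment(img, otsu_threshold(img)$threshold, foreground)
}

#' Uniformly tiled local Otsu segmentation (comparison baseline)
#'
#' Splits the image into k x k tiles and thresholds each tile with its own
#' Otsu threshold (degenerate tiles fall back to the whole-image
#' threshold). This is the classical fixed-tiling local threshold method,
#' provided for comparison with [hvs_segment()].
#'
#' @inheritParams hvs_segment
#' @param tile_size tile edge length in pixels.
#' @return logical foreground map.
#' @export
tiled_segment <- function(img, tile_size = 32L,
                          foreground = c("above", "below")) {
  foreground <- match.arg(foreground)
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  T_global <- otsu_threshold(img)$threshold
  M <- nrow(img); N <- ncol(img)
  out <- matrix(FALSE, M, N)
  for (r0 in seq(1, M, by = tile_size)) {
    for (c0 in seq(1, N, by = tile_size)) {
      rows <- r0:min(r0 + tile_size - 1, M)
      cols <- c0:min(c0 + tile_size - 1, N)
      mask <- matrix(FALSE, M, N); mask[rows, cols] <- TRUE
      out[rows, cols] <- threshold_subimage(img, mask, T_global,
                                            foreground)$binary[rows, cols]
    }
  }
  out
}
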