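#' @keywords internal
"_PACKAGE"

## RNG discipline: every stochastic entry point takes an explicit seed and
## restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical (or 0/1) matrices of identical dimension.
#' @return `2|A∩B| / (|A|+|B|)`; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Construct a grayscale slice object
#'
#' A `gray_image` is an integer matrix of gray levels in `[0, gray_levels - 1]`
#' carrying its pixel spacing (mm per pixel) and gray-level count as
#' attributes. Rows run anterior (top) to posterior (bottom).
#'
#' @param values numeric matrix (at least 3 x 3) of integer gray levels.
#' @param pixel_spacing mm per pixel, > 0.
#' @param gray_levels number of gray levels L (values must lie in `[0, L-1]`).
#' @return a `gray_image` object.
#' @export
gray_image <- function(values, pixel_spacing = 0.5, gray_levels = 256L) {
  values <- as.matrix(values)
  if (nrow(values) < 3 || ncol(values) < 3)
    stop("image must be at least 3 x 3")
  if (!is.numeric(values) || anyNA(values))
    stop("image values must be numeric and non-missing")
  if (any(values != round(values)))
    stop("image values must be integral gray levels")
  if (any(values < 0) || any(values > gray_levels - 1))
    stop("gray values must lie in [0, ", gray_levels - 1, "]")
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be > 0")
  storage.mode(values) <- "integer"
  structure(values,
            pixel_spacing = as.numeric(pixel_spacing),
            gray_levels = as.integer(gray_levels),
            class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, L = %d, spacing = %g mm/px, range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "gray_levels"),
              attr(x, "pixel_spacing"), min(x), max(x)))
  invisible(x)
}

pixel_spacing <- function(img) {
  sp <- attr(img, "pixel_spacing")
  if (is.null(sp)) stop("image has no pixel_spacing attribute")
  sp
}

gray_levels <- function(img) {
  L <- attr(img, "gray_levels")
  if (is.null(L)) 256L else L
}

as_mask <- function(m) {
  m <- as.matrix(m)
  if (is.logical(m)) return(m)
  m != 0
}
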