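## File I/O: grayscale slices and masks as PNG or single-slice NIfTI,
## cohort tables as CSV, reports as JSON.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a grayscale slice from PNG or NIfTI
#'
#' PNG (8- or 16-bit grayscale) values are mapped back to integer gray
#' levels; pixel spacing comes from the `spacing` argument. Single-slice
#' NIfTI files carry their spacing in the header. RGB PNGs and multi-slice
#' NIfTI volumes are rejected.
#'
#' @param path file path (`.png`, `.nii`, `.nii.gz`).
#' @param spacing mm per pixel, required for PNG; overrides the header if
#'   given for NIfTI.
#' @param gray_levels gray-level count for PNG decoding (256 for 8-bit,
#'   65536 for 16-bit).
#' @return a [gray_image()].
#' @export
read_slice <- function(path, spacing = NULL, gray_levels = 256L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is_nifti_path(path)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) > 2 && any(d[-(1:2)] > 1))
      stop("multi-slice NIfTI; supply a single-slice file")
    m <- if (length(d) > 2) vol[, , 1] else vol[, ]
    sp <- if (!is.null(spacing)) spacing else RNifti::pixdim(vol)[1]
    L <- max(256L, 2^ceiling(log2(max(m) + 1)))
    gray_image(round(m), pixel_spacing = sp, gray_levels = L)
  } else {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      if (dim(a)[3] > 2) stop("RGB PNG not supported; use grayscale")
      a <- a[, , 1]
    }
    if (is.null(spacing)) stop("pixel spacing must be supplied for PNG input")
    gray_image(round(a * (gray_levels - 1)), pixel_spacing = spacing,
               gray_levels = gray_levels)
  }
}

#' Write a grayscale slice or binary mask
#'
#' PNG output is 8-bit (masks as 0/255); NIfTI output keeps integer gray
#' levels (masks as 0/1) and stores the pixel spacing in the header.
#'
#' @param img a [gray_image()] or logical mask matrix.
#' @param path destination (`.png`, `.nii`, `.nii.gz`).
#' @param spacing mm per pixel; defaults to the image's own spacing.
#' @return `path`, invisibly.
#' @export
write_slice <- function(img, path, spacing = NULL) {
  is_mask <- is.logical(img)
  sp <- if (!is.null(spacing)) spacing
        else if (!is.null(attr(img, "pixel_spacing"))) attr(img, "pixel_spacing")
        else 1
  m <- unclass(as.matrix(img))
  if (is_nifti_path(path)) {
    vals <- if (is_mask) (m * 1L) else m
    storage.mode(vals) <- "integer"
    nii <- RNifti::asNifti(vals)
    RNifti::pixdim(nii) <- c(sp, sp)
    RNifti::writeNifti(nii, path)
  } else {
    L <- if (is_mask) 2 else gray_levels(img)
    scaled <- if (is_mask) m * 1 else m / (L - 1)
    png::writePNG(scaled, target = path)
  }
  invisible(path)
}

#' Read a binary mask from PNG or NIfTI
#'
#' Accepts PNG masks in 0/255 and NIfTI masks in 0/1 (any nonzero value is
#' foreground).
#'
#' @param path file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (is_nifti_path(path)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    m <- if (length(d) > 2) vol[, , 1] else vol[, ]
    m != 0
  } else {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    a > 0.5
  }
}

#' Write / read a cohort table as CSV
#'
#' Schema: `subject_id,group,f_ratio,d_ratio,c_ratio,evans[,rater1,rater2]`.
#'
#' @param cohort a cohort table data frame.
#' @param path CSV destination.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "f_ratio", "d_ratio", "c_ratio", "evans")
  if (!all(need %in% names(out)))
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  structure(out, class = c("cohort_table", "data.frame"))
}

#' Write a JSON analysis report
#'
#' The report embeds a schema version, the configuration echo, the seed,
#' and a hash of the configuration so a rerun with the same config + seed
#' is identifiable. Writing is atomic: on error no partial file remains.
#'
#' @param results named list of results (must be non-empty).
#' @param path JSON destination.
#' @param config configuration echoed into the report.
#' @param seed the seed used for the run.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = list(), seed = NULL) {
  if (length(results) == 0) stop("empty results; refusing to write a report")
  payload <- list(schema_version = "1.0",
                  seed = seed,
                  config = config,
                  config_hash = config_hash(config, seed),
                  results = results)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

config_hash <- function(config, seed = NULL) {
  s <- jsonlite::toJSON(list(config = config, seed = seed), auto_unbox = TRUE,
                        digits = NA)
  ## small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read back a JSON report
#'
#' @param path report path.
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
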