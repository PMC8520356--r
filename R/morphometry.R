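## Lateral-ventricle index measurement on one axial slice: anterior horn
## index F/F', body index D/D', caudate nucleus index C/C', Evans index.

#' Bundle the four ventricular indices
#'
#' @param F_ratio,D_ratio,C_ratio,evans dimensionless ratios in (0, 1).
#' @param landmarks optional list of the raw landmark rows and distances
#'   (mm) that produced the ratios.
#' @return an `index_measurements` object.
#' @export
index_measurements <- function(F_ratio, D_ratio, C_ratio, evans,
                               landmarks = NULL) {
  vals <- c(F_ratio = F_ratio, D_ratio = D_ratio,
            C_ratio = C_ratio, evans = evans)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 1))
    stop("all index ratios must be finite and in (0, 1)")
  structure(list(F_ratio = F_ratio, D_ratio = D_ratio,
                 C_ratio = C_ratio, evans = evans, landmarks = landmarks),
            class = "index_measurements")
}

#' @export
print.index_measurements <- function(x, ...) {
  cat(sprintf("F/F' = %.3f  D/D' = %.3f  C/C' = %.3f  Evans = %.3f\n",
              x$F_ratio, x$D_ratio, x$C_ratio, x$evans))
  invisible(x)
}

#' Horizontal extent of a mask on one row
#'
#' Width uses the outer-edge-to-outer-edge convention: each pixel is a cell
#' of edge `spacing`, so a run from column `l` to column `r` is
#' `(r - l + 1) * spacing` mm wide.
#'
#' @param mask logical matrix.
#' @param row 1-based row index.
#' @param spacing mm per pixel.
#' @return list `left`, `right` (1-based columns), `width` (mm), `empty`.
#' @export
row_extent <- function(mask, row, spacing) {
  mask <- as_mask(mask)
  if (row < 1 || row > nrow(mask)) stop("row out of range")
  cols <- which(mask[row, ])
  if (length(cols) == 0)
    return(list(left = NA_integer_, right = NA_integer_,
                width = NA_real_, empty = TRUE))
  l <- cols[1]; r <- cols[length(cols)]
  list(left = l, right = r, width = (r - l + 1) * spacing, empty = FALSE)
}

#' Measure the four ventricular indices from masks
#'
#' Landmark levels are found by the shared row-segment convention over the
#' ventricle row extent: the anterior-horn segment is the first `horn_frac`
#' of rows, the caudate band the next `caudate_frac`, the body segment the
#' remainder (a human rater picks these levels on clinical images; here
#' they are explicit, configurable windows).
#'
#' * F = widest ventricle outer span within the horn segment (ties to the
#'   most anterior row); F' = brain width at that row.
#' * D = minimal ventricle outer span over the body segment; D' = brain
#'   width at the minimizing row.
#' * C = ventricle outer span at the caudate row (middle of the caudate
#'   band, the level where the caudate head borders the ventricle); C' =
#'   brain width there.
#' * Evans = maximal ventricle outer span over all rows divided by the
#'   maximal brain width over all rows.
#'
#' @param ventricle_mask,brain_mask logical matrices; the ventricle mask
#'   must be contained in the brain mask and both must be non-empty.
#' @param spacing mm per pixel.
#' @param horn_frac,caudate_frac the row-segment fractions (defaults match
#'   [phantom_spec()]).
#' @return list with `landmarks` (rows, distances in mm) and `indices`
#'   (an [index_measurements()] object).
#' @export
measure_indices <- function(ventricle_mask, brain_mask, spacing,
                            horn_frac = 1/3, caudate_frac = 0.1) {
  vent <- as_mask(ventricle_mask); brain <- as_mask(brain_mask)
  if (!all(dim(vent) == dim(brain))) stop("mask dimensions differ")
  if (!any(vent)) stop("ventricle mask is empty")
  if (!any(brain)) stop("brain mask is empty")
  if (any(vent & !brain)) stop("ventricle mask is not contained in the brain mask")

  vrows <- which(rowSums(vent) > 0)
  seg <- ventricle_segments(vrows[1], vrows[length(vrows)],
                            horn_frac, caudate_frac)

  span_at <- function(mask, rows) {
    vapply(rows, function(r) {
      e <- row_extent(mask, r, spacing)
      if (e$empty) NA_real_ else e$width
    }, numeric(1))
  }

  horn_spans <- span_at(vent, seg$horn_rows)
  if (all(is.na(horn_spans))) stop("no ventricle pixels in the horn segment")
  i_f <- which.max(horn_spans)              # first maximum: most anterior row
  horn_row <- seg$horn_rows[i_f]
  F_mm <- horn_spans[i_f]
  Fp_mm <- row_extent(brain, horn_row, spacing)$width

  body_spans <- span_at(vent, seg$body_rows)
  if (all(is.na(body_spans))) stop("no ventricle pixels in the body segment")
  i_d <- which.min(body_spans)
  body_row <- seg$body_rows[i_d]
  D_mm <- body_spans[i_d]
  Dp_mm <- row_extent(brain, body_row, spacing)$width

  caud <- row_extent(vent, seg$caudate_row, spacing)
  if (caud$empty) stop("no ventricle pixels at the caudate row")
  C_mm <- caud$width
  Cp_mm <- row_extent(brain, seg$caudate_row, spacing)$width

  all_spans <- span_at(vent, vrows)
  evans_num <- max(all_spans, na.rm = TRUE)
  brain_rows <- which(rowSums(brain) > 0)
  evans_den <- max(span_at(brain, brain_rows), na.rm = TRUE)

  landmarks <- list(horn_row = horn_row, body_row = body_row,
                    caudate_row = seg$caudate_row,
                    F = F_mm, F_prime = Fp_mm, D = D_mm, D_prime = Dp_mm,
                    C = C_mm, C_prime = Cp_mm,
                    evans_num = evans_num, evans_den = evans_den)
  list(landmarks = landmarks,
       indices = index_measurements(F_ratio = F_mm / Fp_mm,
                                    D_ratio = D_mm / Dp_mm,
                                    C_ratio = C_mm / Cp_mm,
                                    evans = evans_num / evans_den,
                                    landmarks = landmarks))
}

#' Measure a batch of slices into a cohort-style table
#'
#' Per-slice failures (empty or inconsistent masks) are recorded in the
#' `status` column and do not abort the batch.
#'
#' @param slices list; each element a list with `ventricle_mask` and
#'   `brain_mask` (and optionally `subject_id`, `group`).
#' @param spacing mm per pixel.
#' @param ... passed to [measure_indices()].
#' @return data frame with one row per slice: `subject_id`, `group`,
#'   `f_ratio`, `d_ratio`, `c_ratio`, `evans`, `status` ("ok" or the error
#'   message).
#' @export
batch_measure <- function(slices, spacing, ...) {
  if (length(slices) == 0) stop("empty slice list")
  rows <- lapply(seq_along(slices), function(i) {
    sl <- slices[[i]]
    id <- if (!is.null(sl$subject_id)) sl$subject_id else sprintf("S%04d", i)
    grp <- if (!is.null(sl$group)) sl$group else NA_character_
    res <- tryCatch(
      measure_indices(sl$ventricle_mask, sl$brain_mask, spacing, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(subject_id = id, group = grp, f_ratio = NA_real_,
                 d_ratio = NA_real_, c_ratio = NA_real_, evans = NA_real_,
                 status = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      ix <- res$indices
      data.frame(subject_id = id, group = grp, f_ratio = ix$F_ratio,
                 d_ratio = ix$D_ratio, c_ratio = ix$C_ratio,
                 evans = ix$evans, status = "ok", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
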