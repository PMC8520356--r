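## Synthetic axial-slice phantoms with analytic ventricular ground truth,
## and cohort simulation from per-group normal distributions.

#' Specify a synthetic axial brain phantom
#'
#' The phantom is a single axial slice: a bright elliptical brain on a dark
#' background containing dark lateral-ventricle structures (paired anterior
#' horn wedges, a narrow caudate-level waist, and paired parallel body
#' bands), optionally modulated by a smooth multiplicative bias field and
#' additive Gaussian noise. All geometry is specified in mm; the true
#' morphometric indices follow in closed form.
#'
#' The maximal frontal-horn width is a single landmark: it is both the
#' anterior-horn index numerator F and the Evans-index numerator, so
#' `max_frontal_width` defaults to `frontal_horn_span` and the two must
#' agree.
#'
#' @param image_height,image_width image size in pixels.
#' @param pixel_spacing mm per pixel.
#' @param brain_semi_axes length-2 numeric, mm: transverse semi-axis (along
#'   columns) and anterior-posterior semi-axis (along rows).
#' @param frontal_horn_span outer-tip-to-outer-tip frontal horn width F, mm,
#'   attained at the anterior-horn measurement level.
#' @param body_outer_span outer-edge-to-outer-edge width of the ventricle
#'   bodies D, mm (constant over the body segment, hence also the minimal
#'   body-level span).
#' @param caudate_span wall-to-wall outer width C at the caudate level, mm.
#' @param max_frontal_width Evans-index numerator, mm; must equal
#'   `frontal_horn_span` (see Details).
#' @param tissue_intensity,csf_intensity,background_intensity gray levels;
#'   by default CSF is darker than tissue (T1-like polarity). Swap them for
#'   bright-CSF (T2-like) phantoms.
#' @param noise_sigma SD of additive zero-mean Gaussian noise, gray levels.
#' @param bias_amplitude relative amplitude of the smooth radial bias field
#'   (0.1 = about +/-10 percent shading).
#' @param vent_extent length-2 numeric: anterior and posterior ends of the
#'   ventricle system as fractions of the AP semi-axis (negative = anterior
#'   of center).
#' @param horn_frac,caudate_frac fractions of the ventricle row extent
#'   occupied by the anterior-horn segment and the caudate band; the rest is
#'   the body segment. Shared with [measure_indices()].
#' @param horn_thickness,caudate_wall,body_thickness wall thicknesses, mm.
#' @param horn_tip_frac horn span at the anterior tip as a fraction of F.
#' @param seed integer seed for the noise draw.
#' @return a `phantom_spec` object (validated list).
#' @seealso [make_phantom()], [measure_indices()]
#' @export
phantom_spec <- function(image_height = 192L, image_width = 192L,
                         pixel_spacing = 0.5,
                         brain_semi_axes = c(42, 45),
                         frontal_horn_span = 24,
                         body_outer_span = 19.5,
                         caudate_span = 10.4,
                         max_frontal_width = frontal_horn_span,
                         tissue_intensity = 180L,
                         csf_intensity = 60L,
                         background_intensity = 20L,
                         noise_sigma = 0,
                         bias_amplitude = 0,
                         vent_extent = c(-0.60, 0.30),
                         horn_frac = 1/3, caudate_frac = 0.1,
                         horn_thickness = 3, caudate_wall = 1.5,
                         body_thickness = 4, horn_tip_frac = 0.3,
                         seed = 1L) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               pixel_spacing = pixel_spacing,
               brain_semi_axes = brain_semi_axes,
               frontal_horn_span = frontal_horn_span,
               body_outer_span = body_outer_span,
               caudate_span = caudate_span,
               max_frontal_width = max_frontal_width,
               tissue_intensity = as.integer(tissue_intensity),
               csf_intensity = as.integer(csf_intensity),
               background_intensity = as.integer(background_intensity),
               noise_sigma = noise_sigma,
               bias_amplitude = bias_amplitude,
               vent_extent = vent_extent,
               horn_frac = horn_frac, caudate_frac = caudate_frac,
               horn_thickness = horn_thickness, caudate_wall = caudate_wall,
               body_thickness = body_thickness, horn_tip_frac = horn_tip_frac,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  if (s$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (length(s$brain_semi_axes) != 2 || any(s$brain_semi_axes <= 0))
    stop("brain_semi_axes must be two positive lengths (mm)")
  if (!isTRUE(all.equal(s$max_frontal_width, s$frontal_horn_span)))
    stop("max_frontal_width must equal frontal_horn_span: ",
         "both name the maximal frontal-horn width")
  if (s$csf_intensity == s$tissue_intensity)
    stop("csf_intensity must differ from tissue_intensity")
  for (f in c("frontal_horn_span", "body_outer_span", "caudate_span"))
    if (s[[f]] <= 0) stop(f, " must be > 0")
  a <- s$brain_semi_axes[1]; b <- s$brain_semi_axes[2]
  half_w <- (s$image_width - 1) / 2 * s$pixel_spacing
  half_h <- (s$image_height - 1) / 2 * s$pixel_spacing
  if (a > half_w || b > half_h)
    stop("brain ellipse does not fit inside the image")
  if (s$vent_extent[1] >= s$vent_extent[2])
    stop("vent_extent must be increasing")
  if (any(abs(s$vent_extent) >= 1))
    stop("vent_extent fractions must lie strictly inside (-1, 1)")
  if (s$horn_frac <= 0 || s$caudate_frac < 0 ||
      s$horn_frac + s$caudate_frac >= 1)
    stop("horn_frac + caudate_frac must be < 1")
  invisible(s)
}

## Shared row-segment convention for the ventricle extent: anterior-horn
## segment (first horn_frac of rows), caudate band (next caudate_frac),
## body segment (the remainder). Used identically by the generator and the
## measurement code so phantom ground truth is recoverable by construction.
ventricle_segments <- function(r_top, r_bot, horn_frac = 1/3,
                               caudate_frac = 0.1) {
  rows <- r_top:r_bot
  E <- length(rows)
  n_horn <- max(1L, ceiling(E * horn_frac))
  n_caud <- max(1L, round(E * caudate_frac))
  if (n_horn + n_caud >= E)
    stop("ventricle extent too short for the segment convention")
  horn <- rows[seq_len(n_horn)]
  caud <- rows[n_horn + seq_len(n_caud)]
  body <- rows[(n_horn + n_caud + 1):E]
  list(horn_rows = horn, caudate_rows = caud, body_rows = body,
       horn_row = horn[length(horn)],
       caudate_row = caud[ceiling(length(caud) / 2)])
}

## Ellipse half-width (mm) at AP offset y (mm) from center.
ellipse_half_width <- function(y, a, b) {
  ifelse(abs(y) >= b, 0, a * sqrt(1 - (y / b)^2))
}

#' Generate a phantom slice with ground-truth masks and indices
#'
#' Renders the slice described by a [phantom_spec()]: background, brain
#' ellipse at `tissue_intensity`, ventricle structures at `csf_intensity`,
#' multiplied by a smooth left-right-symmetric radial bias field and with
#' seeded additive Gaussian noise. Masks are the noise-free ground truth;
#' `true_indices` are the analytic ratios (e.g. D/D' = `body_outer_span` /
#' brain transverse diameter at the first body-segment row).
#'
#' @param spec a `phantom_spec`.
#' @return a `phantom` object: `image` (a [gray_image()]), `brain_mask`,
#'   `ventricle_mask`, `tissue_mask` (brain minus ventricles), `true_indices`,
#'   `landmark_rows` (1-based horn/caudate/first-body rows), and the
#'   originating `phantom_spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  s <- spec
  H <- s$image_height; W <- s$image_width; sp <- s$pixel_spacing
  a <- s$brain_semi_axes[1]; b <- s$brain_semi_axes[2]
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  y <- (seq_len(H) - 1 - cr) * sp   # mm, anterior negative
  x <- (seq_len(W) - 1 - cc) * sp

  brain <- outer((y / b)^2, (x / a)^2, `+`) <= 1

  ## ventricle rows from the AP extent fractions
  y_lo <- s$vent_extent[1] * b; y_hi <- s$vent_extent[2] * b
  vrows <- which(y >= y_lo & y <= y_hi)
  if (length(vrows) < 6) stop("ventricle extent spans too few rows")
  seg <- ventricle_segments(vrows[1], vrows[length(vrows)],
                            s$horn_frac, s$caudate_frac)

  ## per-row outer span (mm): linear horn taper, caudate waist, body bands
  span <- numeric(H); inner <- numeric(H)
  n_horn <- length(seg$horn_rows)
  tip <- s$horn_tip_frac * s$frontal_horn_span
  taper <- if (n_horn == 1) s$frontal_horn_span else
    tip + (s$frontal_horn_span - tip) * (seq_len(n_horn) - 1) / (n_horn - 1)
  span[seg$horn_rows] <- taper
  inner[seg$horn_rows] <- pmax(taper / 2 - s$horn_thickness, 0)
  span[seg$caudate_rows] <- s$caudate_span
  inner[seg$caudate_rows] <- pmax(s$caudate_span / 2 - s$caudate_wall, 0)
  span[seg$body_rows] <- s$body_outer_span
  inner[seg$body_rows] <- pmax(s$body_outer_span / 2 - s$body_thickness, 0)

  ## geometry check: every span must sit strictly inside the brain at its row
  for (r in c(seg$horn_rows, seg$caudate_rows, seg$body_rows)) {
    hw <- ellipse_half_width(y[r], a, b)
    if (span[r] / 2 >= hw) {
      off <- if (r %in% seg$horn_rows) "frontal_horn_span"
             else if (r %in% seg$caudate_rows) "caudate_span"
             else "body_outer_span"
      stop(off, " leaves the brain ellipse at row ", r)
    }
  }

  vent <- matrix(FALSE, H, W)
  for (r in which(span > 0)) {
    keep <- abs(x) <= span[r] / 2 & abs(x) >= inner[r]
    vent[r, keep] <- TRUE
  }
  vent <- vent & brain

  base <- matrix(as.numeric(s$background_intensity), H, W)
  base[brain] <- s$tissue_intensity
  base[vent] <- s$csf_intensity

  if (s$bias_amplitude != 0) {
    rho2 <- outer(((seq_len(H) - 1 - cr) / (H / 2))^2,
                  ((seq_len(W) - 1 - cc) / (W / 2))^2, `+`)
    base <- base * (1 + s$bias_amplitude * (0.5 - rho2))
  }
  if (s$noise_sigma > 0) {
    base <- base + with_seed(s$seed, matrix(stats::rnorm(H * W, 0, s$noise_sigma), H, W))
  }
  img <- gray_image(round(pmin(pmax(base, 0), 255)), pixel_spacing = sp)

  ## analytic ground truth (closed form from the phantom_spec geometry)
  Fp <- 2 * ellipse_half_width(y[seg$horn_row], a, b)
  Dp <- 2 * ellipse_half_width(y[seg$body_rows[1]], a, b)
  Cp <- 2 * ellipse_half_width(y[seg$caudate_row], a, b)
  evans_num <- max(s$frontal_horn_span, s$body_outer_span, s$caudate_span)
  landmarks <- list(horn_row = seg$horn_row, body_row = seg$body_rows[1],
                    caudate_row = seg$caudate_row,
                    F = s$frontal_horn_span, F_prime = Fp,
                    D = s$body_outer_span, D_prime = Dp,
                    C = s$caudate_span, C_prime = Cp,
                    evans_num = evans_num, evans_den = 2 * a)
  truth <- index_measurements(F_ratio = s$frontal_horn_span / Fp,
                              D_ratio = s$body_outer_span / Dp,
                              C_ratio = s$caudate_span / Cp,
                              evans = evans_num / (2 * a),
                              landmarks = landmarks)

  structure(list(image = img, brain_mask = brain, ventricle_mask = vent,
                 tissue_mask = brain & !vent, true_indices = truth,
                 landmark_rows = c(horn = seg$horn_row,
                                   caudate = seg$caudate_row,
                                   body = seg$body_rows[1]),
                 spec = s),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px @ %g mm/px; noise sd %g, bias %g\n",
              nrow(x$image), ncol(x$image), x$spec$pixel_spacing,
              x$spec$noise_sigma, x$spec$bias_amplitude))
  cat("true indices: ")
  print(x$true_indices)
  invisible(x)
}

#' Per-group distribution parameters for cohort simulation
#'
#' @param name group label.
#' @param n number of subjects (>= 2).
#' @param means,sds named numeric vectors over the four indices
#'   (`f_ratio`, `d_ratio`, `c_ratio`, `evans`); means in (0,1), sds > 0.
#' @return a `group_spec` object.
#' @export
group_spec <- function(name, n, means, sds) {
  idx <- c("f_ratio", "d_ratio", "c_ratio", "evans")
  if (!all(idx %in% names(means)) || !all(idx %in% names(sds)))
    stop("means and sds must be named over ", paste(idx, collapse = ", "))
  means <- means[idx]; sds <- sds[idx]
  if (n < 2) stop("n must be >= 2")
  if (any(sds <= 0)) stop("all SDs must be > 0")
  if (any(means <= 0 | means >= 1)) stop("all means must lie in (0, 1)")
  structure(list(name = as.character(name), n = as.integer(n),
                 means = means, sds = sds),
            class = "group_spec")
}

#' Reference cohort parameters: CHD and control groups
#'
#' The per-group means and SDs of the four ventricular indices for a
#' congenital-heart-disease group (n = 150) and a control group (n = 50):
#' F/F' 0.301+/-0.035 vs 0.296+/-0.031, D/D' 0.261+/-0.039 vs
#' 0.234+/-0.032, C/C' 0.138+/-0.018 vs 0.124+/-0.015, Evans
#' 0.239+/-0.052 vs 0.233+/-0.025.
#'
#' @return list of two [group_spec()] objects named `CHD` and `control`.
#' @export
table1_groups <- function() {
  list(
    CHD = group_spec("CHD", 150,
      means = c(f_ratio = 0.301, d_ratio = 0.261, c_ratio = 0.138, evans = 0.239),
      sds   = c(f_ratio = 0.035, d_ratio = 0.039, c_ratio = 0.018, evans = 0.052)),
    control = group_spec("control", 50,
      means = c(f_ratio = 0.296, d_ratio = 0.234, c_ratio = 0.124, evans = 0.233),
      sds   = c(f_ratio = 0.031, d_ratio = 0.032, c_ratio = 0.015, evans = 0.025))
  )
}

#' Simulate a cohort of per-subject index values
#'
#' Draws each index for each subject independently from that group's normal
#' distribution and clips the draws to the open unit interval (the indices
#' are ratios). Clipping events are counted in the `n_clipped` attribute;
#' at the reference parameters they are vanishingly rare.
#'
#' @param groups list of [group_spec()] objects.
#' @param seed integer seed.
#' @return a `cohort_table` data frame with columns `subject_id`, `group`,
#'   `f_ratio`, `d_ratio`, `c_ratio`, `evans`.
#' @export
sample_cohort <- function(groups = table1_groups(), seed = 1L) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  if (length(groups) == 0) stop("at least one group is required")
  for (g in groups) if (!inherits(g, "group_spec")) stop("groups must be group_spec objects")
  idx <- c("f_ratio", "d_ratio", "c_ratio", "evans")
  eps <- 1e-9
  n_clipped <- 0L
  out <- with_seed(seed, {
    parts <- lapply(groups, function(g) {
      vals <- sapply(idx, function(k) stats::rnorm(g$n, g$means[[k]], g$sds[[k]]))
      vals <- matrix(vals, nrow = g$n, dimnames = list(NULL, idx))
      n_clipped <<- n_clipped + sum(vals <= 0 | vals >= 1)
      vals <- pmin(pmax(vals, eps), 1 - eps)
      data.frame(group = g$name, vals, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  out <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  structure(out, n_clipped = n_clipped,
            class = c("cohort_table", "data.frame"))
}

#' Add two simulated rater measurements to a cohort
#'
#' Each rater's reading of the chosen index is the subject's true value plus
#' a fixed rater bias plus independent zero-mean Gaussian noise. With
#' between-subject variance `s_b^2` and rater noise variance `s_e^2` (and no
#' bias), the generating intraclass correlation is `s_b^2 / (s_b^2 + s_e^2)`.
#'
#' @param cohort a `cohort_table`.
#' @param index which index column the raters measure.
#' @param rater_noise_sd SD of each rater's measurement noise (>= 0).
#' @param rater_bias length-2 numeric, additive bias of each rater.
#' @param seed integer seed.
#' @return the cohort with `rater1` and `rater2` columns appended.
#' @export
simulate_raters <- function(cohort, index = "d_ratio", rater_noise_sd = 0,
                            rater_bias = c(0, 0), seed = 1L) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  if (rater_noise_sd < 0) stop("rater_noise_sd must be >= 0")
  if (length(rater_bias) == 1) rater_bias <- rep(rater_bias, 2)
  truth <- cohort[[index]]
  if (is.null(truth)) stop("no such index column: ", index)
  n <- length(truth)
  eps <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, rater_noise_sd), n, 2))
  cohort$rater1 <- truth + rater_bias[1] + eps[, 1]
  cohort$rater2 <- truth + rater_bias[2] + eps[, 2]
  cohort
}
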