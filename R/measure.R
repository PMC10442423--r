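# Quality control, standardization and geometric mJSW measurement from
# label masks.
#
# The minimum joint space width (mJSW) of a subject is the smaller of the
# two per-leg nine-point average femur-tibia gaps; gaps are measured
# vertically within raster columns. Raw measurements are in pixels and are
# placed on a common mm scale by regressing them on subject height within
# each image-resolution group (see fit_normalization).

#' Validate a scan's size and pad it to the standard frame
#'
#' Scans at or below the target size are zero-padded to exactly the target,
#' content centered (ties broken toward the top-left); larger scans are
#' resolution outliers and are rejected rather than resized.
#'
#' @param scan A `labeled_scan`.
#' @param target_width,target_height Standard frame (default 800 x 1000 px).
#' @return The padded `labeled_scan`, or an object of class `rejected_scan`
#'   with a `reason` field.
#' @export
validate_and_pad <- function(scan, target_width = 800, target_height = 1000) {
  stopifnot(inherits(scan, "labeled_scan"))
  h <- nrow(scan$mask)
  w <- ncol(scan$mask)
  if (h > target_height || w > target_width) {
    return(structure(
      list(subject_id = scan$subject_id, side = scan$side,
           reason = "resolution outlier",
           dims = c(height = h, width = w)),
      class = "rejected_scan"
    ))
  }
  if (h == target_height && w == target_width) return(scan)
  top <- floor((target_height - h) / 2)
  left <- floor((target_width - w) / 2)
  pad <- function(m) {
    out <- matrix(0L, nrow = target_height, ncol = target_width)
    out[top + seq_len(h), left + seq_len(w)] <- m
    out
  }
  out <- scan
  out$image <- pad(scan$image)
  out$mask <- pad(scan$mask)
  if (!is.null(scan$true_gap_profile)) {
    out$true_gap_profile$column <- scan$true_gap_profile$column + left
  }
  out
}

#' Per-column femur-tibia gap profile of a label mask
#'
#' For every column containing both femur (label 1) and tibia (label 2)
#' pixels, the gap is the count of rows strictly between the bottommost
#' femur pixel and the topmost tibia pixel, floored at 0 so that touching or
#' inverted labels give 0. Fibula pixels (label 3) are ignored.
#'
#' @param mask Integer label matrix (rows increase downward).
#' @param pixel_spacing mm/px carried into the profile.
#' @return A list of class `gap_profile` with `columns`, `gaps_px`,
#'   `pixel_spacing`.
#' @export
gap_profile <- function(mask, pixel_spacing = NA_real_) {
  femur <- mask == 1L
  tibia <- mask == 2L
  if (!any(femur) || !any(tibia)) stop("incomplete segmentation: missing bone")
  fcols <- which(colSums(femur) > 0)
  tcols <- which(colSums(tibia) > 0)
  cols <- intersect(fcols, tcols)
  if (length(cols) == 0) stop("no measurable joint: femur and tibia never share a column")
  nr <- nrow(mask)
  rows <- seq_len(nr)
  fbot <- apply(femur[, cols, drop = FALSE], 2, function(v) max(rows[v]))
  ttop <- apply(tibia[, cols, drop = FALSE], 2, function(v) min(rows[v]))
  gaps <- pmax(ttop - fbot - 1L, 0L)
  structure(
    list(columns = cols, gaps_px = as.integer(gaps),
         pixel_spacing = pixel_spacing),
    class = "gap_profile"
  )
}

# Indices (into the profile) of the nine sampled columns: the overlap range
# is split into three equal contiguous thirds and each third is sampled at
# the columns nearest its 25%, 50% and 75% positions.
nine_point_indices <- function(n) {
  if (n < 9) stop("joint too narrow to sample: need >= 9 overlap columns")
  b <- c(0, floor(n / 3), floor(2 * n / 3), n)
  unlist(lapply(1:3, function(k) {
    start <- b[k] + 1L
    len <- b[k + 1L] - b[k]
    start + round(c(0.25, 0.5, 0.75) * (len - 1))
  }))
}

#' Nine-point average joint space width of one leg
#'
#' The overlap is split into lateral, center and medial thirds; each third
#' contributes the gaps at its 25%, 50% and 75% positions, and the leg value
#' is the mean of the nine sampled gaps (px).
#'
#' @param profile A [gap_profile()].
#' @return The mean sampled gap in pixels, with the sampled profile indices
#'   as attribute `"sampled"`.
#' @export
nine_point_leg_jsw <- function(profile) {
  stopifnot(inherits(profile, "gap_profile"))
  ix <- nine_point_indices(length(profile$columns))
  structure(mean(profile$gaps_px[ix]), sampled = ix)
}

#' Per-subject minimum joint space width
#'
#' The smaller of the two per-leg averages; if only one leg was scanned that
#' leg's value is the phenotype.
#'
#' @param left_jsw,right_jsw Per-leg nine-point averages in px (`NA` if the
#'   leg is missing).
#' @export
subject_mjsw <- function(left_jsw = NA_real_, right_jsw = NA_real_) {
  v <- c(left_jsw, right_jsw)
  if (all(is.na(v))) stop("no leg measurement available")
  min(v, na.rm = TRUE)
}

#' Fit the height-regression resolution normalization
#'
#' Within each image-resolution group, raw pixel mJSW is regressed on
#' subject height by OLS. Because a physical slope in mm/cm appears in a
#' group's pixel units divided by that group's pixel spacing, the ratio
#' slope_reference / slope_group is a per-group scaling factor that places
#' all groups on the reference group's pixel scale; multiplying by the
#' reference pixel spacing then yields mm.
#'
#' @param records data.frame with columns `raw_px`, `height`, `group`,
#'   `pixel_spacing`.
#' @param reference_group Group id whose scale (factor 1) others are mapped
#'   onto; defaults to the first group.
#' @return A list of class `normalization_model` with per-group `slope`,
#'   `intercept`, `factor`, `valid`, plus `reference_group` and
#'   `pixel_spacing_reference`.
#' @export
fit_normalization <- function(records, reference_group = NULL) {
  stopifnot(all(c("raw_px", "height", "group", "pixel_spacing") %in% names(records)))
  if (any(records$height <= 0)) stop("heights must be positive")
  groups <- unique(records$group)
  reference_group <- reference_group %||% groups[1]
  if (!reference_group %in% groups) stop("reference group absent from records")

  fit_one <- function(g) {
    d <- records[records$group == g, ]
    if (stats::sd(d$height) == 0) stop("singular fit: constant height in group ", g)
    co <- stats::coef(stats::lm(raw_px ~ height, data = d))
    c(intercept = unname(co[1]), slope = unname(co[2]))
  }
  fits <- vapply(groups, fit_one, numeric(2))
  slopes <- fits["slope", ]
  if (length(groups) == 1L) {
    factors <- 1
  } else {
    factors <- slopes[[which(groups == reference_group)]] / slopes
  }
  valid <- slopes > 0
  spacing_ref <- unique(records$pixel_spacing[records$group == reference_group])
  if (length(spacing_ref) != 1L) {
    stop("reference group has inconsistent pixel spacing")
  }
  structure(
    list(
      groups = data.frame(
        group = groups,
        slope = unname(slopes),
        intercept = unname(fits["intercept", ]),
        factor = unname(factors),
        valid = unname(valid),
        stringsAsFactors = FALSE
      ),
      reference_group = reference_group,
      pixel_spacing_reference = spacing_ref
    ),
    class = "normalization_model"
  )
}

#' Apply a normalization model to raw pixel measurements
#'
#' `mjsw_norm = raw_px * factor_group * pixel_spacing_reference`, an
#' mm-equivalent that is order-preserving within each group.
#'
#' @param model A [fit_normalization()] model.
#' @param raw_px Raw per-subject mJSW in pixels.
#' @param group Resolution group of each measurement.
#' @export
apply_normalization <- function(model, raw_px, group) {
  stopifnot(inherits(model, "normalization_model"))
  ix <- match(group, model$groups$group)
  if (anyNA(ix)) stop("unknown resolution group: ",
                      paste(unique(group[is.na(ix)]), collapse = ", "))
  raw_px * model$groups$factor[ix] * model$pixel_spacing_reference
}

#' Measure one scan's leg JSW in pixels
#'
#' Convenience wrapper: gap profile then nine-point average.
#' @param scan A `labeled_scan`.
#' @export
measure_leg <- function(scan) {
  stopifnot(inherits(scan, "labeled_scan"))
  as.numeric(nine_point_leg_jsw(gap_profile(scan$mask, scan$pixel_spacing)))
}
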