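# Synthetic knee phantom generator.
#
# Phantoms emulate non-weight-bearing AP-view knee scans: an 8-bit grayscale
# raster plus a label mask (0 = background, 1 = femur, 2 = tibia, 3 = fibula)
# with a known femur-tibia gap profile, so that every downstream measurement
# can be checked against ground truth.

#' Default pixel-spacing / raster-size groups for phantom rendering
#'
#' Three resolution groups, all at or below the 800 x 1000 px standard frame.
#' Multiple pixel spacings exist so that the height-regression normalization
#' has something to normalize.
#'
#' @return A data.frame with columns `group`, `width`, `height`,
#'   `pixel_spacing` (mm/px).
#' @export
knee_resolutions <- function() {
  data.frame(
    group = c("res020", "res025", "res030"),
    width = c(750L, 640L, 540L),
    height = c(950L, 840L, 700L),
    pixel_spacing = c(0.20, 0.25, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Specify a knee phantom
#'
#' Bundles the geometry and rendering controls for one synthetic knee scan.
#' The joint gap is controlled in millimetres at the lateral, center and
#' medial reference positions (midpoints of the three thirds of the
#' femur-tibia overlap); the per-column profile is the quadratic through
#' those three points.
#'
#' @param image_width,image_height Raster size in px (must not exceed the
#'   800 x 1000 standard frame).
#' @param pixel_spacing mm per pixel.
#' @param side `"left"` or `"right"` knee. The fibula is drawn on the lateral
#'   side; by convention a right knee has its lateral side on the image
#'   right, a left knee on the image left.
#' @param gap_mm Named numeric vector with entries `lateral`, `center`,
#'   `medial`, all > 0 (mm).
#' @param condyle_depth_mm How much the femoral condyle curve rises towards
#'   the edges of the joint (mm); 0 gives a flat femur underside.
#' @param shaft_frac Fraction of the joint width occupied by the bone shafts.
#' @param tilt_px Linear tilt of the joint line across the overlap (px).
#' @param noise_sd Gaussian intensity noise added to the raster (not the
#'   mask), in 8-bit intensity units.
#' @param seed RNG seed; phantoms are a pure function of this
#'   specification object and seed.
#' @param subject_id Identifier carried through to measurement records.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_width = 640, image_height = 840,
                         pixel_spacing = 0.25,
                         side = c("right", "left"),
                         gap_mm = c(lateral = 4, center = 4, medial = 4),
                         condyle_depth_mm = 1.2,
                         shaft_frac = 0.45,
                         tilt_px = 0,
                         noise_sd = 6,
                         seed = 1L,
                         subject_id = "S1") {
  side <- match.arg(side)
  stopifnot(
    image_width >= 60, image_height >= 80,
    image_width <= 800, image_height <= 1000,
    pixel_spacing > 0
  )
  gap_mm <- gap_mm[c("lateral", "center", "medial")]
  if (anyNA(gap_mm) || any(gap_mm <= 0)) {
    stop("gap_mm must supply positive lateral, center and medial gaps")
  }
  structure(
    list(
      image_width = as.integer(image_width),
      image_height = as.integer(image_height),
      pixel_spacing = pixel_spacing,
      side = side,
      gap_mm = gap_mm,
      condyle_depth_mm = condyle_depth_mm,
      shaft_frac = shaft_frac,
      tilt_px = tilt_px,
      noise_sd = noise_sd,
      seed = seed,
      subject_id = subject_id
    ),
    class = "phantom_spec"
  )
}

# Quadratic (Lagrange) interpolation through three (x, y) control points,
# evaluated at xs. For equally spaced monotone controls this is linear.
lagrange3 <- function(x0, y0, xs) {
  stopifnot(length(x0) == 3, length(y0) == 3)
  l1 <- (xs - x0[2]) * (xs - x0[3]) / ((x0[1] - x0[2]) * (x0[1] - x0[3]))
  l2 <- (xs - x0[1]) * (xs - x0[3]) / ((x0[2] - x0[1]) * (x0[2] - x0[3]))
  l3 <- (xs - x0[1]) * (xs - x0[2]) / ((x0[3] - x0[1]) * (x0[3] - x0[2]))
  y0[1] * l1 + y0[2] * l2 + y0[3] * l3
}

#' Render a knee phantom from a specification
#'
#' Draws filled femur, tibia and fibula polygons into a label mask and a
#' matching grayscale raster. In every femur-tibia overlap column the femur
#' lies strictly above the tibia and the vertical pixel gap equals the
#' (discretized) requested gap profile; the exact profile is returned as
#' ground truth.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `labeled_scan`: a list with `image` and `mask`
#'   (height x width integer matrices), `pixel_spacing`, `side`,
#'   `subject_id`, and `true_gap_profile`, a data.frame of the overlap
#'   `column` indices with the rendered gap in `gap_px` and `gap_mm`.
#' @export
generate_knee_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- spec$image_width
  H <- spec$image_height
  sp <- spec$pixel_spacing

  # Overlap (joint) columns and the three reference columns.
  jx <- seq.int(round(0.22 * W), round(0.78 * W))
  n <- length(jx)
  b1 <- floor(n / 3)
  b2 <- floor(2 * n / 3)
  mids <- jx[c(ceiling((1 + b1) / 2), ceiling((b1 + 1 + b2) / 2),
               ceiling((b2 + 1 + n) / 2))]

  # Map anatomical lateral/medial onto image left/right: fibula marks the
  # lateral side; right knee -> lateral on image right.
  lateral_right <- spec$side == "right"
  g <- spec$gap_mm
  ctrl <- if (lateral_right) c(g[["medial"]], g[["center"]], g[["lateral"]])
          else c(g[["lateral"]], g[["center"]], g[["medial"]])

  gap_mm_profile <- lagrange3(mids, ctrl, jx)
  gap_px <- round(gap_mm_profile / sp)
  if (any(gap_px < 1)) {
    stop("unresolvable geometry: requested gap below 1 px at this pixel spacing")
  }

  xc <- mean(range(jx))
  hw <- (max(jx) - min(jx)) / 2
  u <- (jx - xc) / hw # -1 .. 1 across the joint

  depth_px <- spec$condyle_depth_mm / sp
  fbot <- round(0.45 * H - depth_px * u^2 + spec$tilt_px * u)
  ttop <- fbot + gap_px + 1L

  condyle_top <- round(0.30 * H)
  plateau_bot <- round(0.62 * H)
  shaft <- abs(u) <= spec$shaft_frac
  ftop <- ifelse(shaft, round(0.06 * H), condyle_top)
  tbot <- ifelse(shaft, round(0.94 * H), plateau_bot)

  ftop <- clamp(ftop, 1L, H)
  fbot <- clamp(fbot, 1L, H)
  ttop <- clamp(ttop, 1L, H)
  tbot <- clamp(tbot, 1L, H)
  if (any(ttop <= fbot) || any(tbot < ttop)) {
    stop("unresolvable geometry: joint does not fit in the raster")
  }

  mask <- matrix(0L, nrow = H, ncol = W)
  rows <- seq_len(H)
  for (i in seq_along(jx)) {
    x <- jx[i]
    mask[rows >= ftop[i] & rows <= fbot[i], x] <- 1L
    mask[rows >= ttop[i] & rows <= tbot[i], x] <- 2L
  }

  # Fibula: thin lateral polygon outside the overlap, clear of the gap.
  fib_w <- max(4L, round(0.06 * W))
  if (lateral_right) {
    fx <- seq.int(max(jx) + 3L, min(W - 1L, max(jx) + 2L + fib_w))
  } else {
    fx <- seq.int(max(2L, min(jx) - 2L - fib_w), min(jx) - 3L)
  }
  fib_top <- clamp(max(ttop) + round(0.04 * H), 1L, H)
  fib_bot <- clamp(round(0.88 * H), 1L, H)
  if (length(fx) > 0 && fib_bot > fib_top) {
    sel <- mask[fib_top:fib_bot, fx, drop = FALSE] == 0L
    block <- mask[fib_top:fib_bot, fx, drop = FALSE]
    block[sel] <- 3L
    mask[fib_top:fib_bot, fx] <- block
  }

  img <- with_seed(spec$seed, {
    base <- matrix(25, nrow = H, ncol = W)
    base[mask > 0L] <- 190
    if (spec$noise_sd > 0) base <- base + rnorm(H * W, sd = spec$noise_sd)
    matrix(as.integer(clamp(round(base), 0, 255)), nrow = H, ncol = W)
  })

  structure(
    list(
      image = img,
      mask = mask,
      pixel_spacing = sp,
      side = spec$side,
      subject_id = spec$subject_id,
      true_gap_profile = data.frame(
        column = jx,
        gap_px = as.integer(gap_px),
        gap_mm = gap_px * sp
      )
    ),
    class = "labeled_scan"
  )
}

#' @export
print.labeled_scan <- function(x, ...) {
  cat(sprintf(
    "<labeled_scan %s [%s]> %d x %d px @ %.2f mm/px, %d overlap columns\n",
    x$subject_id, x$side, nrow(x$mask), ncol(x$mask), x$pixel_spacing,
    nrow(x$true_gap_profile)
  ))
  invisible(x)
}

#' Write / read a labelled scan as PNG
#'
#' The raster is written as 8-bit grayscale; the mask as an 8-bit grayscale
#' PNG whose pixel values are exactly the labels {0,1,2,3}.
#'
#' @param scan A `labeled_scan`.
#' @param image_path,mask_path Output paths.
#' @export
write_scan_png <- function(scan, image_path, mask_path) {
  stopifnot(inherits(scan, "labeled_scan"))
  png::writePNG(scan$image / 255, target = image_path)
  png::writePNG(scan$mask / 255, target = mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

#' @rdname write_scan_png
#' @param path PNG path of a label mask written by [write_scan_png()].
#' @return `read_mask_png` returns an integer label matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  lab <- matrix(as.integer(round(m * 255)), nrow = nrow(m), ncol = ncol(m))
  if (!all(lab %in% 0:3)) stop("mask PNG contains values outside labels 0..3")
  lab
}
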