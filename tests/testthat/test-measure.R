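# Fixture masks built in code: small labelled rectangles with known gaps.
rect_mask <- function(H = 60, W = 40, femur_rows = 5:20, tibia_rows = 31:45,
                      cols = 8:32, fibula = NULL) {
  m <- matrix(0L, H, W)
  m[femur_rows, cols] <- 1L
  m[tibia_rows, cols] <- 2L
  if (!is.null(fibula)) m[fibula$rows, fibula$cols] <- 3L
  m
}

test_that("padding centers content, preserves it, and rejects outsized scans", {
  spec <- phantom_spec(image_width = 640, image_height = 900, noise_sd = 0)
  scan <- generate_knee_phantom(spec)
  out <- validate_and_pad(scan)
  expect_identical(dim(out$mask), c(1000L, 800L))
  expect_identical(sort(out$mask[out$mask > 0]), sort(scan$mask[scan$mask > 0]))
  expect_identical(sum(out$image), sum(scan$image)) # zero padding only
  # already-standard scans come back unchanged
  big <- scan
  big$mask <- matrix(0L, 1000, 800)
  big$image <- matrix(0L, 1000, 800)
  expect_identical(validate_and_pad(big), big)
  # oversized input is a resolution outlier
  over <- scan
  over$mask <- matrix(0L, 1100, 900)
  over$image <- matrix(0L, 1100, 900)
  rej <- validate_and_pad(over)
  expect_s3_class(rej, "rejected_scan")
  expect_identical(rej$reason, "resolution outlier")
})

test_that("gap profile measures separated, touching and fibula-bearing masks", {
  m <- rect_mask()
  gp <- gap_profile(m)
  expect_identical(gp$columns, 8:32)
  expect_true(all(gp$gaps_px == 10L))
  # touching bones floor at zero in that column only
  m2 <- rect_mask()
  m2[21:30, 15] <- 2L
  gp2 <- gap_profile(m2)
  expect_identical(gp2$gaps_px[gp2$columns == 15], 0L)
  expect_true(all(gp2$gaps_px[gp2$columns != 15] == 10L))
  # fibula pixels are ignored even inside the joint gap columns
  m3 <- rect_mask(fibula = list(rows = 25:28, cols = 30:34))
  expect_identical(gap_profile(m3)$gaps_px, gp$gaps_px)
  # errors
  expect_error(gap_profile(matrix(0L, 10, 10)), "incomplete")
  m4 <- matrix(0L, 10, 10)
  m4[1:3, 1:4] <- 1L
  m4[6:9, 6:10] <- 2L
  expect_error(gap_profile(m4), "no measurable joint")
})

test_that("nine-point sampling follows its definition and handles zeros", {
  const <- structure(list(columns = 1:30, gaps_px = rep(12L, 30),
                          pixel_spacing = 0.25), class = "gap_profile")
  expect_equal(as.numeric(nine_point_leg_jsw(const)), 12)
  # linear profile: value equals the mean at the oracle-enumerated indices
  gaps <- round(seq(6, 14, length.out = 90))
  lin <- structure(list(columns = 1:90, gaps_px = gaps, pixel_spacing = 0.2),
                   class = "gap_profile")
  want <- mean(gaps[oracle_nine_indices(90)])
  expect_equal(as.numeric(nine_point_leg_jsw(lin)), want)
  # one sampled zero among tens
  gaps0 <- rep(10L, 27)
  gaps0[oracle_nine_indices(27)[5]] <- 0L
  z <- structure(list(columns = 1:27, gaps_px = gaps0, pixel_spacing = 0.2),
                 class = "gap_profile")
  expect_equal(as.numeric(nine_point_leg_jsw(z)), (8 * 10 + 0) / 9)
  narrow <- structure(list(columns = 1:8, gaps_px = rep(5L, 8),
                           pixel_spacing = 0.2), class = "gap_profile")
  expect_error(nine_point_leg_jsw(narrow), "too narrow")
})

test_that("the subject minimum follows the two-leg rule", {
  expect_identical(subject_mjsw(4.2, 3.8), 3.8)
  expect_identical(subject_mjsw(NA, 5.1), 5.1)
  expect_identical(subject_mjsw(4.0, 4.0), 4.0)
  expect_error(subject_mjsw(NA, NA), "no leg")
})

test_that("normalization factors are slope ratios with closed-form behavior", {
  set.seed(21)
  h <- runif(40, 150, 190)
  a <- 0.5 * h + rnorm(40, sd = 0.01)
  recs <- data.frame(
    raw_px = c(a, 2 * a), height = c(h, h),
    group = rep(c("A", "B"), each = 40),
    pixel_spacing = rep(c(0.25, 0.125), each = 40)
  )
  m <- fit_normalization(recs, reference_group = "A")
  fb <- m$groups$factor[m$groups$group == "B"]
  expect_lt(abs(fb - 0.5), 1e-6)
  expect_identical(m$groups$factor[m$groups$group == "A"], 1)
  # single group: identity normalization
  solo <- fit_normalization(recs[recs$group == "A", ])
  expect_identical(solo$groups$factor, 1)
  # constant height is singular
  recs$height <- 170
  expect_error(fit_normalization(recs), "singular")
})

test_that("applying normalization converts units and preserves order", {
  m <- structure(
    list(groups = data.frame(group = "A", slope = 1, intercept = 0,
                             factor = 1, valid = TRUE),
         reference_group = "A", pixel_spacing_reference = 0.25),
    class = "normalization_model"
  )
  expect_equal(apply_normalization(m, 16, "A"), 4.0)
  two <- apply_normalization(m, c(10, 12), c("A", "A"))
  expect_true(two[1] < two[2])
  expect_error(apply_normalization(m, 10, "Z"), "unknown")
})

test_that("the same joint rendered at two resolutions normalizes within 2%", {
  # the scaling factor is a slope ratio, so the fixture must be large
  # enough that slope sampling error (the only noise beside pixel
  # rounding) is well below the 2% band
  res <- knee_resolutions()
  n <- 150
  heights <- seq(140, 200, length.out = n)
  rows <- list()
  for (i in seq_len(n)) {
    g <- 2.5 + 0.016 * heights[i]
    for (k in 1:2) {
      r <- res[k, ]
      spec <- phantom_spec(
        image_width = r$width, image_height = r$height,
        pixel_spacing = r$pixel_spacing,
        gap_mm = c(lateral = g + 0.4, center = g, medial = g - 0.4),
        noise_sd = 0, seed = i
      )
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, group = r$group, pixel_spacing = r$pixel_spacing,
        height = heights[i],
        raw_px = measure_leg(generate_knee_phantom(spec))
      )
    }
  }
  d <- do.call(rbind, rows)
  m <- fit_normalization(d, reference_group = res$group[1])
  d$norm <- apply_normalization(m, d$raw_px, d$group)
  wide <- reshape(d[, c("subject", "group", "norm")], idvar = "subject",
                  timevar = "group", direction = "wide")
  rel <- abs(wide[[2]] - wide[[3]]) / wide[[2]]
  expect_true(all(rel <= 0.02))
})

test_that("widening a phantom's gap strictly increases the raw measurement", {
  vals <- vapply(c(3, 3.5, 4, 4.5, 5), function(g) {
    spec <- phantom_spec(gap_mm = c(lateral = g, center = g, medial = g),
                         noise_sd = 0)
    measure_leg(generate_knee_phantom(spec))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
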