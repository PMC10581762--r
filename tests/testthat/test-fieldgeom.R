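test_that("infinity correction matches the stated geometry and its limits", {
  # zero separation is the identity at any radius
  th <- seq(-170, 170, by = 17)
  expect_equal(correct_to_infinity(th, "right", 0.5, 0), th)
  expect_equal(correct_to_infinity(th, "left", 2, 0), th)

  # direct evaluation for the right eye looking straight ahead
  expect_equal(correct_to_infinity(0, "right", 0.5, 0.02),
               atan2(-0.01, 0.5) * 180 / pi)
  expect_equal(correct_to_infinity(0, "right", 0.5, 0.02), -1.1457,
               tolerance = 1e-4)

  # ray-tracing oracle over a grid of angles, eyes, radii
  for (eye in c("left", "right")) {
    for (r in c(0.3, 0.5, 1)) {
      for (t in seq(-150, 150, by = 30)) {
        expect_equal(correct_to_infinity(t, eye, r, 0.03),
                     ray_trace_azimuth(t, eye, r, 0.03), tolerance = 1e-10)
      }
    }
  }

  # infinity limit: r = 1e6 x separation recovers the measured angle
  expect_equal(correct_to_infinity(-10, "left", 1e6 * 0.02, 0.02), -10,
               tolerance = 1e-3)

  expect_error(correct_to_infinity(0, "right", -1, 0.02), "positive")
  expect_error(correct_to_infinity(NaN, "right", 1, 0.02), "finite")
})

test_that("uncorrect_from_infinity inverts the correction exactly", {
  th <- seq(-80, 80, by = 7)
  for (eye in c("left", "right")) {
    meas <- uncorrect_from_infinity(th, eye, 0.5, 0.025)
    expect_equal(correct_to_infinity(meas, eye, 0.5, 0.025), th,
                 tolerance = 1e-10)
  }
})

test_that("binocular width clamps, mirrors, and reproduces the species maximum", {
  expect_equal(binocular_width(20, -20), 40)
  expect_equal(binocular_width(-5, 5), 0)
  expect_equal(binocular_width(27.25, -27.25), 54.5)
  # mirror antisymmetry of the margins leaves the width unchanged
  l <- runif(50, -30, 40)
  r <- runif(50, -40, 30)
  expect_equal(binocular_width(l, r), binocular_width(-r, -l))
  expect_true(all(binocular_width(l, r) >= 0))
})

test_that("sector decomposition obeys inclusion-exclusion", {
  set.seed(11)
  lm_ <- runif(200, -10, 40)
  rm_ <- runif(200, -40, 10)
  # lateral margins lie behind the other eye's medial margin, as in a real
  # head where each monocular field wraps past the front
  ll <- lm_ - runif(200, 100, 170)
  rl <- rm_ + runif(200, 100, 170)
  fc <- field_components(lm_, ll, rm_, rl)
  expect_equal(fc$cyclopean,
               fc$left_monocular + fc$right_monocular - fc$binocular)
  expect_equal(fc$blind, 360 - fc$cyclopean)
  expect_true(all(fc$binocular >= 0))
})

test_that("blocked-elevation interpolation averages neighbours and nothing else", {
  prof <- make_tent_profile(seq(-20, 0, 10), c(30, NA, 40))
  out <- interpolate_blocked(prof)
  expect_equal(out$binocular_width, c(30, 35, 40))
  expect_identical(out$interpolated, c(FALSE, TRUE, FALSE))
  # measured rows bit-identical
  expect_identical(out$binocular_width[c(1, 3)], prof$binocular_width[c(1, 3)])

  expect_equal(interpolate_blocked(
    make_tent_profile(seq(-20, 0, 10), c(40, NA, 40)))$binocular_width[2], 40)
  expect_equal(interpolate_blocked(
    make_tent_profile(seq(-20, 0, 10), c(0, NA, 10)))$binocular_width[2], 5)
  # no measured neighbour below -> error
  expect_error(interpolate_blocked(
    make_tent_profile(seq(-20, 0, 10), c(NA, 30, 40))), "neighbour")
})

test_that("field summaries: maximum, tie-break, vertical extent", {
  tri <- make_tent_profile(c(-30, 0, 30), c(0, 50, 0))
  s <- summarize_field(tri, bill_tip_elevation = -20)
  expect_equal(s$max_binocular_overlap, 50)
  expect_equal(s$elevation_of_max, 0)
  expect_equal(s$vertical_extent, 60)
  expect_equal(s$max_overlap_offset, 20)

  # flat 10-degree profile spanning -20..80 reproduces a 100-degree extent
  flat <- make_tent_profile(seq(-20, 80, 10), rep(10, 11))
  expect_equal(summarize_field(flat)$vertical_extent, 100)

  # plateau ties break toward the lowest elevation (exhaustive scan oracle)
  pl <- make_tent_profile(c(-10, 0, 10, 20), c(10, 20, 20, 10))
  sp <- summarize_field(pl)
  w <- pl$binocular_width
  expect_equal(sp$elevation_of_max,
               min(pl$elevation[w == max(w)]))
  expect_equal(sp$elevation_of_max, 0)

  # off-grid zero crossing from signed margins is interpolated linearly
  cross <- tibble::tibble(
    species = "toy", individual = "i", elevation = c(-30, -20, -10, 0, 10),
    left_margin = c(-5, 5, 10, 5, -5) / 2,
    right_margin = -c(-5, 5, 10, 5, -5) / 2,
    binocular_width = pmax(0, c(-5, 5, 10, 5, -5)),
    interpolated = FALSE, estimated_lower_bound = FALSE
  )
  sc <- summarize_field(cross)
  expect_equal(sc$vertical_extent, (5 - (-25))) # crossings at -25 and +5

  # degenerate all-zero profile
  z <- summarize_field(make_tent_profile(c(-10, 0, 10), c(0, 0, 0)))
  expect_true(z$degenerate)
  expect_equal(z$max_binocular_overlap, 0)
  expect_equal(z$vertical_extent, 0)
})

test_that("vertical extent ignores zero rows beyond the field limits", {
  base <- make_tent_profile()
  ext <- make_tent_profile(seq(-50, 50, 10),
                           c(0, 0, base$binocular_width, 0, 0))
  expect_equal(summarize_field(ext)$vertical_extent,
               summarize_field(base)$vertical_extent)
})

test_that("outlines close correctly and their area equals the width integral", {
  diamond <- outline_from_profile(
    make_tent_profile(c(-10, 0, 10), c(0, 40, 0)))
  expect_closed(diamond)
  verts <- unique(diamond[-nrow(diamond), ])
  expect_equal(nrow(verts), 4)
  expect_true(all(c(20, -20) %in% verts$x))

  # rectangle from an all-equal profile
  rect <- outline_from_profile(make_tent_profile(c(0, 10, 20), c(30, 30, 30)))
  expect_equal(sort(unique(rect$x)), c(-15, 15))
  expect_equal(abs(outline_area(rect)), 30 * 20)

  # area property on random tent profiles
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    w <- c(0, runif(n, 5, 60), 0)
    e <- seq(-30, by = 10, length.out = n + 2)
    prof <- make_tent_profile(e, w)
    a <- abs(outline_area(outline_from_profile(prof)))
    trap <- sum(diff(e) * (w[-1] + w[-length(w)]) / 2)
    expect_equal(a, trap, tolerance = 1e-10)
  }

  expect_error(outline_from_profile(
    make_tent_profile(c(0, 10), c(0, 0))), "degenerate")
})

test_that("lower-bound estimation extrapolates the last two widths to zero", {
  prof <- make_tent_profile(seq(-50, 0, 10), c(10, 20, 40, 50, 40, 30))
  out <- estimate_lower_bounds(prof)
  expect_equal(min(out$elevation), -60) # zero crossing of the 10->20 trend
  expect_equal(out$binocular_width[out$elevation == -60], 0)
  expect_true(all(out$estimated_lower_bound[out$elevation < -50]))
  expect_identical(out[out$elevation >= -50, c("elevation", "binocular_width")],
                   prof[, c("elevation", "binocular_width")])

  # untruncated profile is a no-op
  tent <- make_tent_profile()
  expect_identical(estimate_lower_bounds(tent), tent)

  # flat trend cannot terminate: warn and close one grid step below
  flat <- make_tent_profile(seq(-20, 0, 10), c(15, 15, 20))
  expect_warning(out2 <- estimate_lower_bounds(flat), "closure")
  expect_equal(min(out2$elevation), -30)
  expect_equal(out2$binocular_width[1], 0)

  expect_error(estimate_lower_bounds(make_tent_profile(0, 10)), "two")
})

test_that("orthographic projection maps the sphere to the unit disc", {
  expect_equal(orthographic_project(0, 0)[, c("x", "y")],
               tibble::tibble(x = 0, y = 0))
  rim <- orthographic_project(0, 90)
  expect_equal(c(rim$x, rim$y), c(1, 0))
  expect_false(rim$hidden)
  expect_true(orthographic_project(0, 135)$hidden)

  set.seed(9)
  pts <- orthographic_project(runif(500, -90, 90), runif(500, -180, 180),
                              view_lat = 20, view_lon = -45)
  expect_true(all(pts$x^2 + pts$y^2 <= 1 + 1e-12))
  expect_error(orthographic_project(91, 0), "latitude")
})

test_that("record-to-profile pipeline corrects margins and flags blocked rows", {
  rec <- tibble::tibble(
    species = "sp", individual = "i1",
    eye = rep(c("left", "right"), each = 3),
    eye_state = "converged",
    elevation = rep(c(-10, 0, 10), 2),
    margin_azimuth = c(10, NA, 12, -10, NA, -12),
    apparatus_radius = 0.5, eye_separation = 0.02,
    blocked = rep(c(FALSE, TRUE, FALSE), 2)
  )
  prof <- profiles_from_records(rec)
  expect_equal(nrow(prof), 3)
  expect_true(is.na(prof$binocular_width[2]))
  expect_equal(prof$left_margin[1],
               correct_to_infinity(10, "left", 0.5, 0.02))
  filled <- interpolate_blocked(prof)
  expect_equal(filled$binocular_width[2],
               mean(filled$binocular_width[c(1, 3)]))
})
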