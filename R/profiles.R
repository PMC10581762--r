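#' Fill widths at elevations blocked by the bill holder
#'
#' At some elevations the bill holder obstructs the ophthalmoscope's view of
#' the eyes and no margin can be read. The binocular width at such an
#' elevation is estimated as the arithmetic mean of the widths at the nearest
#' measured elevations immediately above and below. Measured rows are never
#' altered.
#'
#' @param profile A single-individual field profile (tibble with `elevation`,
#'   `binocular_width`, flag columns), sorted by elevation.
#' @param blocked_elevations Elevations to fill. Defaults to all rows whose
#'   `binocular_width` is `NA`.
#' @return The profile with blocked widths filled and their `interpolated`
#'   flag set.
#' @export
interpolate_blocked <- function(profile, blocked_elevations = NULL) {
  profile <- check_profile(profile)
  if (is.null(blocked_elevations)) {
    blocked_elevations <- profile$elevation[is.na(profile$binocular_width)]
  }
  if (!length(blocked_elevations)) return(profile)
  if (!all(blocked_elevations %in% profile$elevation)) {
    abort("blocked elevations must be rows of the profile.")
  }
  measured <- which(!is.na(profile$binocular_width) &
                      !(profile$elevation %in% blocked_elevations))
  for (e in blocked_elevations) {
    i <- which(profile$elevation == e)
    below <- measured[measured < i]
    above <- measured[measured > i]
    if (!length(below) || !length(above)) {
      abort(sprintf(
        "blocked elevation %g has no measured neighbour on one side; %s",
        e, "use estimate_lower_bounds() for truncated profile ends."))
    }
    profile$binocular_width[i] <-
      mean(c(profile$binocular_width[max(below)],
             profile$binocular_width[min(above)]))
    profile$interpolated[i] <- TRUE
  }
  profile
}

check_profile <- function(profile) {
  profile <- tibble::as_tibble(profile)
  if (!all(c("elevation", "binocular_width") %in% names(profile))) {
    abort("a field profile needs `elevation` and `binocular_width` columns.")
  }
  if (is.unsorted(profile$elevation, strictly = TRUE)) {
    profile <- dplyr::arrange(profile, .data$elevation)
    if (anyDuplicated(profile$elevation)) {
      abort("profile elevations must be unique.")
    }
  }
  for (fl in c("interpolated", "estimated_lower_bound")) {
    if (!fl %in% names(profile)) profile[[fl]] <- FALSE
  }
  profile
}

# Signed binocular width: left - right margins where both are available
# (can be negative when a frontal gap exists), otherwise the clamped width.
signed_width <- function(profile) {
  w <- profile$binocular_width
  if (all(c("left_margin", "right_margin") %in% names(profile))) {
    s <- profile$left_margin - profile$right_margin
    ifelse(is.na(s), w, s)
  } else {
    w
  }
}

#' Summary statistics of one binocular-field profile
#'
#' Computes the three scalar descriptors used to compare species: the width
#' of the maximum binocular overlap, the elevation at which it occurs
#' (relative to the projection of the eye-bill tip direction), and the
#' vertical extent of the binocular field.
#'
#' The vertical extent is the angular distance between the lower and upper
#' limits of the region of positive binocular width. Where the signed width
#' (left minus right margin) changes sign between two grid rows, the limit is
#' placed at the linearly interpolated zero crossing; if the profile simply
#' ends with positive width (a truncated measurement), the end row is taken
#' as the limit. Ties in the maximum are broken toward the lowest elevation.
#'
#' @param profile A field profile for one individual or one species (no `NA`
#'   widths; interpolate or edit first).
#' @param bill_tip_elevation Elevation (degrees) of the eye-bill-tip
#'   projection, the anatomical reference direction.
#' @return A one-row tibble: `max_binocular_overlap`, `elevation_of_max`,
#'   `vertical_extent`, `bill_tip_elevation`, `max_overlap_offset`
#'   (the magnitude of `elevation_of_max - bill_tip_elevation`), and a
#'   `degenerate` flag for all-zero profiles.
#' @export
summarize_field <- function(profile, bill_tip_elevation = 0) {
  profile <- check_profile(profile)
  w <- profile$binocular_width
  if (anyNA(w)) abort("profile has NA widths; call interpolate_blocked() first.")
  if (any(w < 0)) abort("binocular widths must be non-negative.")
  e <- profile$elevation
  if (!any(w > 0)) {
    return(tibble::tibble(
      max_binocular_overlap = 0, elevation_of_max = NA_real_,
      vertical_extent = 0, bill_tip_elevation = bill_tip_elevation,
      max_overlap_offset = NA_real_, degenerate = TRUE
    ))
  }
  wmax <- max(w)
  emax <- min(e[w == wmax]) # ties broken toward the lowest elevation
  s <- signed_width(profile)
  pos <- which(w > 0)
  lo_i <- min(pos)
  hi_i <- max(pos)
  lower <- if (lo_i == 1) e[1] else zero_cross(e[lo_i - 1], s[lo_i - 1], e[lo_i], s[lo_i])
  upper <- if (hi_i == length(e)) e[hi_i] else zero_cross(e[hi_i], s[hi_i], e[hi_i + 1], s[hi_i + 1])
  tibble::tibble(
    max_binocular_overlap = wmax,
    elevation_of_max = emax,
    vertical_extent = upper - lower,
    bill_tip_elevation = bill_tip_elevation,
    max_overlap_offset = abs(emax - bill_tip_elevation),
    degenerate = FALSE
  )
}

# Linear zero crossing between (e0, s0) with s0 <= 0 and (e1, s1) with s1 > 0
# (or the mirror image). Falls back to the non-positive end when flat.
zero_cross <- function(e0, s0, e1, s1) {
  if (s0 == s1) return(if (s0 <= 0) e0 else e1)
  e0 + (0 - s0) * (e1 - e0) / (s1 - s0)
}

#' Extrapolate the unmeasured bottom of a truncated field profile
#'
#' For species whose lowest elevations could not be observed, the bottom of
#' the binocular field is reconstructed by extending the trend of the last
#' two measured widths linearly downward, on the measurement grid, until the
#' width reaches zero. Appended rows carry the `estimated_lower_bound` flag.
#' If the width is not decreasing toward the bottom the extrapolation never
#' terminates; a warning is issued and the field is closed one grid step
#' below the last measurement.
#'
#' @param profile A field profile whose lowest row has positive width
#'   (a profile already reaching zero width is returned unchanged).
#' @return The extended profile.
#' @export
estimate_lower_bounds <- function(profile) {
  profile <- check_profile(profile)
  w <- profile$binocular_width
  if (anyNA(w)) abort("interpolate blocked rows before estimating lower bounds.")
  if (nrow(profile) < 2) abort("need at least two measured rows to extrapolate.")
  if (w[1] <= 0) return(profile) # untruncated: nothing to do
  e <- profile$elevation
  step <- min(diff(e))
  e1 <- e[1]; w1 <- w[1]
  e2 <- e[2]; w2 <- w[2]
  slope <- (w2 - w1) / (e2 - e1) # width change per degree of elevation
  if (slope <= 0) {
    warn("width does not decrease toward the lowest measured elevation; forcing closure one grid step below.")
    new_e <- e1 - step
    new_w <- 0
  } else {
    e0 <- e1 - w1 / slope # linear zero crossing below the profile
    grid_e <- seq(e1 - step, by = -step, length.out = ceiling((e1 - e0) / step))
    grid_e <- grid_e[grid_e > e0 + 1e-9]
    new_e <- c(grid_e, e0)
    new_w <- pmax(0, w1 + slope * (new_e - e1))
  }
  extra <- profile[rep(1, length(new_e)), ]
  extra$elevation <- new_e
  extra$binocular_width <- new_w
  for (cl in intersect(c("left_margin", "right_margin"), names(extra))) {
    extra[[cl]] <- NA_real_
  }
  extra$interpolated <- FALSE
  extra$estimated_lower_bound <- TRUE
  dplyr::arrange(dplyr::bind_rows(profile, extra), .data$elevation)
}

#' Closed outline of the binocular field on a Cartesian plane
#'
#' Projects the binocular field onto a plane with x the horizontal overlap
#' (symmetric about the median plane, so the outline runs from `-width/2` to
#' `+width/2`) and y the elevation. The polygon is traversed up the right
#' limb and down the left limb and closed on its first vertex.
#'
#' @param profile A field profile with at least two rows of positive width.
#' @return A tibble of outline vertices `x`, `y`, closed (first row repeated
#'   last).
#' @export
outline_from_profile <- function(profile) {
  profile <- check_profile(profile)
  w <- profile$binocular_width
  if (anyNA(w)) abort("profile has NA widths.")
  if (nrow(profile) < 2 || !any(w > 0)) {
    abort("degenerate profile: need >= 2 rows with some positive width.")
  }
  e <- profile$elevation
  right <- tibble::tibble(x = w / 2, y = e)
  keep <- rev(which(w > 0))
  left <- tibble::tibble(x = -w[keep] / 2, y = e[keep])
  out <- dplyr::bind_rows(right, left)
  out <- dplyr::bind_rows(out, out[1, ])
  out
}

#' Signed area of a closed outline (shoelace formula)
#'
#' @param outline A closed outline tibble with `x`, `y` (first vertex
#'   repeated last, as produced by [outline_from_profile()]).
#' @return Area enclosed, positive for counter-clockwise traversal.
#' @export
outline_area <- function(outline) {
  x <- outline$x
  y <- outline$y
  n <- length(x)
  if (n < 4) abort("a closed outline needs at least 3 distinct vertices.")
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Orthographic projection of latitude/longitude points
#'
#' Standard orthographic map projection onto the plane tangent to the unit
#' sphere at the view direction, used to draw visual-field maps as seen from
#' outside the head (elevation plays latitude, azimuth longitude). Points on
#' the far hemisphere are flagged `hidden`.
#'
#' @param latitude,longitude Point coordinates in degrees; `|latitude| <= 90`.
#' @param view_lat,view_lon View direction (degrees); the default looks at
#'   the point straight ahead of the bird.
#' @return A tibble with `x`, `y` on the unit disc and logical `hidden`.
#' @export
orthographic_project <- function(latitude, longitude,
                                 view_lat = 0, view_lon = 0) {
  check_finite(latitude, "latitude")
  check_finite(longitude, "longitude")
  if (any(abs(latitude) > 90)) abort("`latitude` must lie in [-90, 90].")
  phi <- deg2rad(latitude)
  lam <- deg2rad(longitude)
  phi0 <- deg2rad(view_lat)
  lam0 <- deg2rad(view_lon)
  x <- cos(phi) * sin(lam - lam0)
  y <- cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  tibble::tibble(x = x, y = y, hidden = cosc < 0)
}
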