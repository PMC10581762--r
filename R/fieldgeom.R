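#' Correct a perimeter margin for viewing from infinity
#'
#' Perimeter measurements locate each eye's retinal-field margin as an angle
#' read off the apparatus arc, i.e. as seen from the centre of the bird's
#' head. Because the two eyes sit a finite distance apart and the apparatus
#' has a finite radius, that angle differs from the direction of the same
#' margin as seen *from the eye itself*, which is what the visual field at
#' infinity is defined by. With the head centre at the origin, the forward
#' axis along +y and the bird's right along +x, the eye sits at
#' `(+s/2, 0)` (right eye) or `(-s/2, 0)` (left eye) and the ophthalmoscope
#' viewing point at `(r sin(theta), r cos(theta))`. The corrected azimuth is
#' the direction from the eye to that viewing point,
#'
#'   `theta' = atan2(r sin(theta) -/+ s/2, r cos(theta))`
#'
#' (minus for the right eye, plus for the left). As `r -> Inf` or `s -> 0`
#' the correction vanishes.
#'
#' @param azimuth_deg Measured margin azimuth in degrees, signed, positive
#'   toward the bird's right side of the median sagittal plane.
#' @param eye `"left"` or `"right"` (vectorised).
#' @param radius Apparatus radius, in the same length unit as
#'   `eye_separation`. Must be positive.
#' @param eye_separation Horizontal separation between the centres of the two
#'   eyes. Must be non-negative.
#' @return Corrected azimuth in degrees, same sign convention.
#' @examples
#' correct_to_infinity(0, "right", radius = 0.5, eye_separation = 0.02)
#' @export
correct_to_infinity <- function(azimuth_deg, eye, radius, eye_separation) {
  check_finite(azimuth_deg, "azimuth_deg")
  check_finite(radius, "radius")
  check_finite(eye_separation, "eye_separation")
  if (any(radius <= 0)) abort("`radius` must be positive.")
  if (any(eye_separation < 0)) abort("`eye_separation` must be non-negative.")
  eye <- match_eye(eye, length(azimuth_deg))
  th <- deg2rad(azimuth_deg)
  # eye x-offset: +s/2 for the right eye, -s/2 for the left
  ex <- ifelse(eye == "right", 1, -1) * eye_separation / 2
  rad2deg(atan2(radius * sin(th) - ex, radius * cos(th)))
}

#' Invert the infinity correction (apparatus-frame azimuth from eye-frame)
#'
#' Given the direction of a field margin from the eye itself, returns the
#' azimuth at which the ophthalmoscope would sit on an apparatus of radius
#' `radius`: the viewing point is the intersection of the ray leaving the eye
#' at `azimuth_deg` with the apparatus circle. Used by the synthetic
#' measurement generator and as a geometric self-check.
#'
#' @inheritParams correct_to_infinity
#' @param azimuth_deg Eye-frame (corrected) azimuth in degrees.
#' @return Apparatus-frame (measured) azimuth in degrees.
#' @export
uncorrect_from_infinity <- function(azimuth_deg, eye, radius, eye_separation) {
  check_finite(azimuth_deg, "azimuth_deg")
  if (any(radius <= 0)) abort("`radius` must be positive.")
  eye <- match_eye(eye, length(azimuth_deg))
  th <- deg2rad(azimuth_deg)
  ex <- ifelse(eye == "right", 1, -1) * eye_separation / 2
  # eye at (ex, 0); ray direction (sin th, cos th); solve |P|^2 = r^2 for t > 0
  b <- ex * sin(th)                      # dot(eye, dir)
  disc <- b^2 - (ex^2 - radius^2)
  t <- -b + sqrt(disc)
  rad2deg(atan2(ex + t * sin(th), t * cos(th)))
}

match_eye <- function(eye, n) {
  eye <- as.character(eye)
  if (length(eye) == 1) eye <- rep(eye, n)
  if (!all(eye %in% c("left", "right"))) {
    abort('`eye` must be "left" or "right".')
  }
  eye
}

#' Binocular overlap width from the two medial margins
#'
#' The binocular field at a given elevation is the horizontal sector seen by
#' both eyes: it extends from the right eye's medial (frontal) margin to the
#' left eye's medial margin. With azimuths signed positive toward the bird's
#' right, the left eye's medial margin normally lies to the right of the
#' median plane and the right eye's to the left, so the overlap is
#' `left_margin - right_margin`, clamped at zero when the monocular fields do
#' not meet.
#'
#' @param left_margin,right_margin Corrected medial-margin azimuths (degrees)
#'   of the left and right eye.
#' @return Overlap width in degrees (never negative). The signed difference,
#'   which is negative when a frontal blind gap exists, is recoverable as
#'   `left_margin - right_margin`.
#' @examples
#' binocular_width(27.25, -27.25) # 54.5
#' @export
binocular_width <- function(left_margin, right_margin) {
  check_finite(left_margin, "left_margin")
  check_finite(right_margin, "right_margin")
  pmax(0, left_margin - right_margin)
}

#' Decompose a horizontal slice of the visual field into its sectors
#'
#' Given the medial and lateral margins of both eyes at one elevation,
#' computes the monocular field widths, the binocular overlap, the cyclopean
#' field (union of the two monocular fields) and the blind sector behind the
#' head. The cyclopean width is computed independently as the measure of the
#' union of the two angular intervals, so that the inclusion-exclusion
#' identity `cyclopean = left + right - binocular` can be verified rather
#' than assumed.
#'
#' @param left_medial,left_lateral Left-eye medial and lateral margin
#'   azimuths in degrees; the left monocular field spans from `left_lateral`
#'   (typically strongly negative, i.e. far to the bird's left or behind)
#'   up to `left_medial`.
#' @param right_medial,right_lateral Right-eye margins; the right monocular
#'   field spans from `right_medial` up to `right_lateral`.
#' @return A tibble with columns `left_monocular`, `right_monocular`,
#'   `binocular`, `cyclopean`, `blind`, all in degrees.
#' @export
field_components <- function(left_medial, left_lateral,
                             right_medial, right_lateral) {
  if (any(left_lateral > left_medial) || any(right_lateral < right_medial)) {
    abort("lateral margins must lie outside medial margins for each eye.")
  }
  left_w <- left_medial - left_lateral
  right_w <- right_lateral - right_medial
  if (any(left_w > 360) || any(right_w > 360)) {
    abort("a monocular field cannot exceed 360 degrees.")
  }
  bino <- binocular_width(left_medial, right_medial)
  # union of [left_lateral, left_medial] and [right_medial, right_lateral]
  inter <- pmax(0, pmin(left_medial, right_lateral) -
                  pmax(left_lateral, right_medial))
  cyclo <- pmin(360, left_w + right_w - inter)
  tibble::tibble(
    left_monocular = left_w,
    right_monocular = right_w,
    binocular = bino,
    cyclopean = cyclo,
    blind = 360 - cyclo
  )
}

#' Apply the infinity correction to a table of perimeter records
#'
#' @param records A data frame of perimeter measurements with columns
#'   `species`, `individual`, `eye` (`"left"`/`"right"`), `elevation`
#'   (degrees on the measurement grid), `margin_azimuth` (degrees, apparatus
#'   frame), `apparatus_radius` and `eye_separation` (same length unit).
#'   An optional logical `blocked` column flags elevations at which the bill
#'   holder obstructed the view (their `margin_azimuth` may be `NA`).
#' @return The same tibble with a `corrected_azimuth` column appended.
#' @export
correct_perimeter <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("species", "individual", "eye", "elevation", "margin_azimuth",
            "apparatus_radius", "eye_separation")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ok <- !is.na(records$margin_azimuth)
  out <- rep(NA_real_, nrow(records))
  out[ok] <- correct_to_infinity(
    records$margin_azimuth[ok], records$eye[ok],
    records$apparatus_radius[ok], records$eye_separation[ok]
  )
  records$corrected_azimuth <- out
  records
}

#' Build per-individual visual-field profiles from perimeter records
#'
#' Corrects each margin for viewing from infinity, pairs the left and right
#' medial margins at each elevation and derives the binocular width. Rows
#' flagged `blocked` (or with missing margins) get `NA` widths to be filled
#' by [interpolate_blocked()].
#'
#' @inheritParams correct_perimeter
#' @return A tibble with one row per species, individual and elevation:
#'   `left_margin`, `right_margin` (corrected, degrees), `binocular_width`,
#'   and logical flags `interpolated` and `estimated_lower_bound` (all
#'   `FALSE` here).
#' @export
profiles_from_records <- function(records) {
  corrected <- correct_perimeter(records)
  if (!"blocked" %in% names(corrected)) corrected$blocked <- FALSE
  wide <- corrected |>
    dplyr::select(dplyr::all_of(c("species", "individual", "elevation",
                                  "eye", "corrected_azimuth", "blocked"))) |>
    tidyr::pivot_wider(names_from = "eye",
                       values_from = c("corrected_azimuth", "blocked")) |>
    dplyr::arrange(.data$species, .data$individual, .data$elevation)
  blk_l <- wide[["blocked_left"]] %||% FALSE
  blk_r <- wide[["blocked_right"]] %||% FALSE
  blocked <- (blk_l | blk_r) %in% TRUE
  left <- wide[["corrected_azimuth_left"]]
  right <- wide[["corrected_azimuth_right"]]
  ok <- !blocked & !is.na(left) & !is.na(right)
  width <- rep(NA_real_, length(left))
  width[ok] <- binocular_width(left[ok], right[ok])
  tibble::tibble(
    species = wide$species,
    individual = wide$individual,
    elevation = wide$elevation,
    left_margin = ifelse(blocked, NA_real_, left),
    right_margin = ifelse(blocked, NA_real_, right),
    binocular_width = width,
    interpolated = FALSE,
    estimated_lower_bound = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
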