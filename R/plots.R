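#' Plot a binocular-width profile
#'
#' Width of the binocular field against elevation, with interpolated and
#' extrapolated rows marked.
#'
#' @param profile A field profile tibble.
#' @return A ggplot object.
#' @export
plot_field_profile <- function(profile) {
  profile <- check_profile(profile)
  profile$row_type <- dplyr::case_when(
    profile$estimated_lower_bound ~ "estimated lower bound",
    profile$interpolated ~ "interpolated",
    TRUE ~ "measured"
  )
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$binocular_width,
                               y = .data$elevation)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$row_type)) +
    ggplot2::labs(x = "binocular width (deg)", y = "elevation (deg)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one or more binocular-field outlines
#'
#' @param outlines A single outline tibble or a named list of them.
#' @return A ggplot object.
#' @export
plot_outlines <- function(outlines) {
  if (is.data.frame(outlines)) outlines <- list(outline = outlines)
  df <- purrr::imap_dfr(outlines, function(o, nm) {
    dplyr::mutate(tibble::as_tibble(o), species = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$species,
                                   colour = .data$species)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Orthographic map of visual-field sectors
#'
#' Projects field margins given in elevation/azimuth onto an orthographic
#' view of the head-centred sphere, drawing the visible hemisphere's grid.
#'
#' @param margins Tibble with `elevation`, `azimuth` columns and optionally
#'   a `part` column distinguishing curves.
#' @param view_lat,view_lon View direction in degrees.
#' @return A ggplot object.
#' @export
plot_field_map <- function(margins, view_lat = 0, view_lon = 0) {
  pr <- orthographic_project(margins$elevation, margins$azimuth,
                             view_lat, view_lon)
  df <- dplyr::bind_cols(tibble::as_tibble(margins), pr)
  df <- df[!df$hidden, ]
  if (!"part" %in% names(df)) df$part <- "margin"
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 181))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$part)) +
    ggplot2::geom_path(data = tibble::tibble(x = cos(circ$t),
                                             y = sin(circ$t), part = "rim"),
                       colour = "grey70") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
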