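#' Build the four-petal tracing track
#'
#' Constructs the tracing pattern used for the motor-skill task: eight
#' axis-aligned quarter-ellipse sections arranged into a four-petal
#' curved pattern. Each petal lies in one quadrant and is bounded by two
#' quarter-ellipses that join the central vertex to the petal tip, so
#' the union of all section endpoints is five vertices (center plus four
#' tips). The pattern is symmetric about both screen axes. Tips are at
#' (+-extent_x/2, +-extent_y/2) relative to the center, so opposing tips
#' are `extent_x_px` apart horizontally and `extent_y_px` vertically.
#'
#' @param extent_x_px,extent_y_px horizontal/vertical distance in screen
#'   pixels between opposing petal tips; must be positive.
#' @param n_points number of polyline vertices per section.
#' @param pixel_area_cm2 physical area covered by one pixel; the default
#'   0.0025 cm^2 corresponds to 0.25 mm^2 per pixel.
#' @param center_px screen coordinates of the central vertex.
#' @return An object of class `track_pattern`: list with `sections` (list
#'   of 8 two-column matrices, ordered petal by petal, each running from
#'   its start vertex to its end vertex), `section_vertices` (data.frame
#'   of start/end vertex ids), `vertices` (5 x 2 matrix: center, then the
#'   4 tips), `extent_px`, `pixel_area_cm2`.
#' @export
build_track <- function(extent_x_px, extent_y_px, n_points = 181L,
                        pixel_area_cm2 = 0.0025, center_px = c(0, 0)) {
  if (!is.numeric(extent_x_px) || !is.numeric(extent_y_px) ||
      extent_x_px <= 0 || extent_y_px <= 0)
    stop("track extents must be positive")
  if (n_points < 2L) stop("n_points must be at least 2")
  a <- extent_x_px / 2
  b <- extent_y_px / 2
  u <- seq(0, pi / 2, length.out = n_points)
  # petal in quadrant (sx, sy): two quarter-ellipses center -> tip.
  # arc "y-first" rises along y then bends to the tip; "x-first" runs
  # along x first. Both are quarters of axis-aligned ellipses with
  # semi-axes (a, b) centered at (0, sy*b) and (sx*a, 0) respectively.
  arc_yfirst <- function(sx, sy)
    cbind(x = sx * a * sin(u), y = sy * b * (1 - cos(u)))
  arc_xfirst <- function(sx, sy)
    cbind(x = sx * a * (1 - cos(u)), y = sy * b * sin(u))
  quadrants <- list(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  sections <- vector("list", 8L)
  sv <- data.frame(section = 1:8, start_vertex = NA_integer_,
                   end_vertex = NA_integer_)
  for (q in seq_along(quadrants)) {
    s <- quadrants[[q]]
    out_arc <- arc_yfirst(s[1], s[2])               # center -> tip
    back_arc <- arc_xfirst(s[1], s[2])[n_points:1, ] # tip -> center
    sections[[2 * q - 1]] <- sweep(out_arc, 2L, center_px, "+")
    sections[[2 * q]] <- sweep(back_arc, 2L, center_px, "+")
    sv$start_vertex[2 * q - 1] <- 1L
    sv$end_vertex[2 * q - 1] <- q + 1L
    sv$start_vertex[2 * q] <- q + 1L
    sv$end_vertex[2 * q] <- 1L
  }
  tips <- t(vapply(quadrants, function(s) center_px + c(s[1] * a, s[2] * b),
                   numeric(2)))
  vertices <- rbind(center = center_px, tips)
  rownames(vertices) <- c("center", "tip_q1", "tip_q2", "tip_q3", "tip_q4")
  colnames(vertices) <- c("x", "y")
  structure(
    list(sections = sections, section_vertices = sv, vertices = vertices,
         extent_px = c(x = extent_x_px, y = extent_y_px),
         pixel_area_cm2 = pixel_area_cm2),
    class = "track_pattern"
  )
}

#' @export
print.track_pattern <- function(x, ...) {
  cat("<track_pattern> 8 quarter-ellipse sections,",
      sprintf("extent %g x %g px, %g cm^2/px\n",
              x$extent_px["x"], x$extent_px["y"], x$pixel_area_cm2))
  invisible(x)
}

#' Polyline of one track section, oriented by tracing direction
#'
#' @param track a `track_pattern`.
#' @param section section id in 1..8.
#' @param direction `"forward"` (start vertex to end vertex) or
#'   `"reverse"`.
#' @return two-column matrix of pixel coordinates.
#' @export
track_section <- function(track, section, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(track, "track_pattern"),
            section %in% 1:8)
  p <- track$sections[[section]]
  if (direction == "reverse") p <- p[nrow(p):1, , drop = FALSE]
  p
}

#' Arc length of a quarter-ellipse by numerical quadrature
#'
#' Dense-grid quadrature of the quarter-ellipse perimeter integrand;
#' used as the reference for polyline arc lengths.
#'
#' @param a,b semi-axes.
#' @param n quadrature points.
#' @return arc length (same units as the semi-axes).
#' @export
quarter_ellipse_length <- function(a, b, n = 20000L) {
  u <- seq(0, pi / 2, length.out = n)
  f <- sqrt((a * cos(u))^2 + (b * sin(u))^2)
  sum((f[-1] + f[-n]) / 2) * (pi / 2) / (n - 1)
}
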