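#' Digitized glacier-lake boundary
#'
#' Stores one epoch's glacier-lake boundary as an ordered set of pixel
#' coordinates together with the image scale. Coordinates follow the image
#' convention: 0-based pixels, y increasing downward (toward the lake axis,
#' so a growing mean y means retreat). Lengths and areas are converted to
#' meters only through `pixel_scale`.
#'
#' @param year Calendar year of the image the boundary was digitized from.
#' @param points Two-column matrix (or data.frame) of x, y pixel
#'   coordinates, ordered along the boundary. At least two points.
#' @param pixel_scale Meters per pixel, > 0.
#' @return An object of class `glacier_boundary`.
#' @examples
#' b <- glacier_boundary(1939, cbind(x = 0:10, y = rep(100, 11)), 0.5)
#' polyline_length(b)
#' @export
glacier_boundary <- function(year, points, pixel_scale) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2)
    stop("`points` must be a numeric two-column (x, y) matrix")
  if (nrow(points) < 2)
    stop("a boundary needs at least 2 points")
  if (anyNA(points)) stop("boundary points contain NA")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1 || pixel_scale <= 0)
    stop("`pixel_scale` must be a single positive number (m/px)")
  colnames(points) <- c("x", "y")
  # orientation normalization: order along increasing x
  if (points[1, "x"] > points[nrow(points), "x"]) points <- points[nrow(points):1, , drop = FALSE]
  structure(list(year = year, points = points, pixel_scale = pixel_scale),
            class = "glacier_boundary")
}

#' @export
print.glacier_boundary <- function(x, ...) {
  cat(sprintf("<glacier_boundary %s: %d points, %.3g m/px>\n",
              x$year, nrow(x$points), x$pixel_scale))
  invisible(x)
}

check_boundary_pair <- function(b_ref, b_new) {
  stopifnot(inherits(b_ref, "glacier_boundary"),
            inherits(b_new, "glacier_boundary"))
  if (!isTRUE(all.equal(b_ref$pixel_scale, b_new$pixel_scale)))
    stop("boundaries have mismatched pixel_scale; they must share one image frame")
}

#' Mean boundary offset between two epochs
#'
#' The retreat signal is measured along the image y-axis: the mean of each
#' boundary's y coordinates is taken and the difference converted to meters.
#' Positive values mean the newer boundary has moved toward the lake axis
#' (downward in image coordinates).
#'
#' @param b_ref,b_new [glacier_boundary()] objects sharing a pixel frame.
#' @return Offset in meters (scalar).
#' @export
mean_boundary_offset <- function(b_ref, b_new) {
  check_boundary_pair(b_ref, b_new)
  (mean(b_new$points[, "y"]) - mean(b_ref$points[, "y"])) * b_ref$pixel_scale
}

#' Retreat rate between two digitized boundaries
#'
#' @inheritParams mean_boundary_offset
#' @return A list of class `retreat_estimate` with `year_from`, `year_to`,
#'   `mean_offset_m` and `rate_m_per_a`.
#' @examples
#' b1 <- glacier_boundary(1939, cbind(0:9, 100), 1)
#' b2 <- glacier_boundary(1995, cbind(0:9, 164.96), 1)
#' retreat_rate(b1, b2)$rate_m_per_a  # 1.16 m/a
#' @export
retreat_rate <- function(b_ref, b_new) {
  check_boundary_pair(b_ref, b_new)
  dy <- b_new$year - b_ref$year
  if (!is.finite(dy) || dy <= 0)
    stop("`b_new` must postdate `b_ref` (zero or negative year span)")
  off <- mean_boundary_offset(b_ref, b_new)
  structure(list(year_from = b_ref$year, year_to = b_new$year,
                 mean_offset_m = off, rate_m_per_a = off / dy),
            class = "retreat_estimate")
}

#' @export
print.retreat_estimate <- function(x, ...) {
  cat(sprintf("Retreat %d-%d: %.2f m total, %.2f m/a\n",
              x$year_from, x$year_to, x$mean_offset_m, x$rate_m_per_a))
  invisible(x)
}

#' Length of a digitized boundary polyline
#'
#' Sum of segment lengths times the pixel scale. Always at least the
#' straight-line endpoint distance.
#'
#' @param b A [glacier_boundary()].
#' @return Length in meters.
#' @export
polyline_length <- function(b) {
  stopifnot(inherits(b, "glacier_boundary"))
  d <- diff(b$points)
  sum(sqrt(rowSums(d^2))) * b$pixel_scale
}

# Check a closed polygon ring (n x 2, open form) for self-intersection of
# non-adjacent edges. O(n^2); digitized boundaries are small.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j <= i) next
      j2 <- if (j == n) 1L else j + 1L
      # skip adjacent edges (share a vertex)
      if (i2 == j || j2 == i || (i == 1L && j == n)) next
      if (segments_cross(poly[i, ], poly[i2, ], poly[j, ], poly[j2, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Planar region swept between two boundary positions
#'
#' Builds the simple polygon bounded by the two epoch boundaries, in meters.
#' Under `mode = "chord"` each digitized curve is replaced by its endpoint
#' chord (the "straight wall" scenario); `mode = "polyline"` keeps the
#' digitized surface shape. The two scenarios bracket the unknown true
#' subaqueous geometry of the ice front.
#'
#' @inheritParams mean_boundary_offset
#' @param mode `"chord"` or `"polyline"`.
#' @return A list of class `swept_region` with `vertices` (n x 2 matrix,
#'   meters) and `area_m2`.
#' @export
swept_region <- function(b_ref, b_new, mode = c("polyline", "chord")) {
  mode <- match.arg(mode)
  check_boundary_pair(b_ref, b_new)
  take <- function(b) {
    p <- b$points * b$pixel_scale
    if (mode == "chord") p[c(1, nrow(p)), , drop = FALSE] else p
  }
  p_ref <- take(b_ref)
  p_new <- take(b_new)
  poly <- rbind(p_ref, p_new[nrow(p_new):1, , drop = FALSE])
  area <- abs(pracma::polyarea(poly[, 1], poly[, 2]))
  if (area > 0 && polygon_self_intersects(poly))
    stop("swept region is self-intersecting: the two boundaries cross; ",
         "check digitization order/orientation")
  structure(list(vertices = poly, area_m2 = area, mode = mode,
                 year_from = b_ref$year, year_to = b_new$year),
            class = "swept_region")
}

#' @export
print.swept_region <- function(x, ...) {
  cat(sprintf("<swept_region %s-%s (%s): area %.4g m2>\n",
              x$year_from, x$year_to, x$mode, x$area_m2))
  invisible(x)
}
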