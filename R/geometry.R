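#' Screen geometry
#'
#' Describes the physical display the participant views: its pixel
#' resolution, its physical size, and the nominal viewing distance used
#' whenever no per-sample 3D eye position is available.
#'
#' The screen is modeled as a planar rectangle. Coordinates on it are
#' expressed in normalized units in \code{[0, 1]^2} with the origin at the
#' top-left corner, x increasing rightward and y increasing downward.
#' Off-screen positions are representable (values outside \code{[0, 1]}).
#' The 3D frame used for angular computations places the screen center at
#' the origin with the participant's eye on the positive z axis; eye
#' origins reported by a tracker in its user coordinate system (UCS,
#' millimeters, z toward the participant) map directly into this frame.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_mm,height_mm physical screen size in millimeters.
#' @param viewing_distance_mm nominal eye-to-screen-center distance in
#'   millimeters, used when a sample carries no 3D eye origin.
#' @return an object of class \code{screen_geometry}.
#' @examples
#' g <- screen_geometry(1920, 1080, 531, 299)
#' normalized_to_px(c(0.5, 0.5), g)
#' @export
screen_geometry <- function(width_px, height_px, width_mm, height_mm,
                            viewing_distance_mm = 600) {
  vals <- c(width_px, height_px, width_mm, height_mm, viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry quantities must be finite and strictly positive")
  }
  ar_px <- width_px / height_px
  ar_mm <- width_mm / height_mm
  if (abs(ar_px / ar_mm - 1) > 0.05) {
    warning(sprintf(
      "pixel aspect ratio (%.3f) and physical aspect ratio (%.3f) differ by more than 5%%",
      ar_px, ar_mm))
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_mm = width_mm, height_mm = height_mm,
         viewing_distance_mm = viewing_distance_mm),
    class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen %d x %d px, %.0f x %.0f mm, viewing distance %.0f mm>\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$viewing_distance_mm))
  invisible(x)
}

#' Construct a normalized screen point
#'
#' @param x,y normalized screen coordinates (origin top-left; may lie
#'   outside \code{[0,1]} for off-screen gaze).
#' @return numeric vector \code{c(x, y)}.
#' @export
screen_point <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  c(x = x, y = y)
}

#' Construct a 3D point in the user coordinate system
#'
#' @param x,y,z millimeters; z points toward the participant.
#' @return numeric vector \code{c(x, y, z)}.
#' @export
ucs_point <- function(x, y, z) {
  stopifnot(is.finite(x), is.finite(y), is.finite(z))
  c(x = x, y = y, z = z)
}

#' Is a screen point on the screen?
#'
#' @param p a screen point (or n x 2 matrix of points) in normalized
#'   coordinates.
#' @return logical; TRUE where the point lies within \code{[0,1]^2}.
#' @export
on_screen <- function(p) {
  p <- as_point_matrix(p)
  p[, 1] >= 0 & p[, 1] <= 1 & p[, 2] >= 0 & p[, 2] <= 1
}

# coerce c(x, y) or an n x 2 matrix / data.frame to an n x 2 matrix
as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    matrix(as.numeric(p), ncol = 2)
  } else {
    m <- as.matrix(p)
    storage.mode(m) <- "double"
    m
  }
}

#' Convert normalized screen coordinates to pixels
#'
#' @param p screen point(s), normalized.
#' @param g a \code{\link{screen_geometry}}.
#' @return pixel coordinates, same shape as the input.
#' @export
normalized_to_px <- function(p, g) {
  m <- as_point_matrix(p)
  out <- cbind(m[, 1] * g$width_px, m[, 2] * g$height_px)
  if (is.null(dim(p))) drop(out) else out
}

#' Convert pixel coordinates to normalized screen coordinates
#'
#' @inheritParams normalized_to_px
#' @export
px_to_normalized <- function(p, g) {
  m <- as_point_matrix(p)
  out <- cbind(m[, 1] / g$width_px, m[, 2] / g$height_px)
  if (is.null(dim(p))) drop(out) else out
}

# normalized screen coords -> physical mm in the screen-centered frame
# (x rightward, y downward, z toward participant; screen plane z = 0)
normalized_to_mm <- function(p, g) {
  m <- as_point_matrix(p)
  cbind((m[, 1] - 0.5) * g$width_mm, (m[, 2] - 0.5) * g$height_mm)
}

# default eye position: on the screen-center normal at the nominal distance
nominal_eye <- function(g) c(0, 0, g$viewing_distance_mm)

#' Angular offset between two screen points as seen from the eye
#'
#' The angle (degrees of visual angle) subtended at the eye between the
#' physical locations of two on-screen points. This is the quantity behind
#' the accuracy ("offset") metric.
#'
#' @param a,b screen points in normalized coordinates; either may be an
#'   n x 2 matrix (recycled against the other).
#' @param g a \code{\link{screen_geometry}}.
#' @param eye 3D eye position in millimeters in the screen-centered frame
#'   (\code{\link{ucs_point}}); \code{NULL} uses the nominal viewing
#'   distance on the screen-center normal.
#' @return angle(s) in degrees.
#' @examples
#' g <- screen_geometry(1920, 1080, 531, 299)
#' angular_offset(c(0.4, 0.5), c(0.6, 0.5), g)
#' @export
angular_offset <- function(a, b, g, eye = NULL) {
  if (is.null(eye)) eye <- nominal_eye(g)
  if (abs(eye[3]) < 1e-9) stop("degenerate geometry: eye lies in the screen plane")
  am <- normalized_to_mm(a, g)
  bm <- normalized_to_mm(b, g)
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1 && n > 1) am <- am[rep(1, n), , drop = FALSE]
  if (nrow(bm) == 1 && n > 1) bm <- bm[rep(1, n), , drop = FALSE]
  ux <- am[, 1] - eye[1]; uy <- am[, 2] - eye[2]; uz <- -eye[3]
  vx <- bm[, 1] - eye[1]; vy <- bm[, 2] - eye[2]; vz <- -eye[3]
  dot <- ux * vx + uy * vy + uz * vz
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  cr <- sqrt(cx^2 + cy^2 + cz^2)
  atan2(cr, dot) * 180 / pi
}

# angular position (azimuth, elevation in degrees) of screen points as
# seen from the eye; used for the STD precision metric
screen_to_angles <- function(p, g, eye = NULL) {
  if (is.null(eye)) eye <- nominal_eye(g)
  if (abs(eye[3]) < 1e-9) stop("degenerate geometry: eye lies in the screen plane")
  m <- normalized_to_mm(p, g)
  vx <- m[, 1] - eye[1]; vy <- m[, 2] - eye[2]; vz <- eye[3]
  az <- atan2(vx, vz) * 180 / pi
  el <- atan2(vy, sqrt(vx^2 + vz^2)) * 180 / pi
  cbind(az = az, el = el)
}

#' Screen offset corresponding to a visual angle
#'
#' Converts an angle in degrees into a normalized on-screen displacement
#' about the screen center at the nominal viewing distance. Used by the
#' simulator to apply angular fixation noise, and handy for constructing
#' test fixtures at known angular offsets.
#'
#' @param deg angle in degrees.
#' @param g a \code{\link{screen_geometry}}.
#' @param axis \code{"x"} or \code{"y"}.
#' @return normalized screen displacement along the chosen axis.
#' @export
angle_to_norm_offset <- function(deg, g, axis = c("x", "y")) {
  axis <- match.arg(axis)
  mm <- g$viewing_distance_mm * tan(deg * pi / 180)
  if (axis == "x") mm / g$width_mm else mm / g$height_mm
}

#' Head position relative to the desired position
#'
#' Compares the midpoint of the valid eye origins in a gaze sample with a
#' configured desired head position and reports per-axis offsets plus the
#' Euclidean distance, flagging when only one eye is tracked.
#'
#' @param sample a single-row gaze stream data frame (see
#'   \code{\link{gaze_stream}}) carrying eye-origin columns.
#' @param desired desired head position, \code{\link{ucs_point}}.
#' @return a list with \code{status} ("ok", "single_eye" or
#'   "head not detected"), \code{offset_mm} (x, y, z), \code{distance_mm},
#'   and \code{eyes} used.
#' @export
head_position_status <- function(sample, desired) {
  stopifnot(length(desired) == 3)
  lo <- c(sample$left_origin_x, sample$left_origin_y, sample$left_origin_z)
  ro <- c(sample$right_origin_x, sample$right_origin_y, sample$right_origin_z)
  l_ok <- length(lo) == 3 && all(is.finite(lo)) && isTRUE(sample$left_valid > 0)
  r_ok <- length(ro) == 3 && all(is.finite(ro)) && isTRUE(sample$right_valid > 0)
  if (!l_ok && !r_ok) {
    return(list(status = "head not detected", offset_mm = rep(NA_real_, 3),
                distance_mm = NA_real_, eyes = character(0)))
  }
  mid <- if (l_ok && r_ok) (lo + ro) / 2 else if (l_ok) lo else ro
  off <- unname(mid - desired)
  list(status = if (l_ok && r_ok) "ok" else "single_eye",
       offset_mm = off,
       distance_mm = sqrt(sum(off^2)),
       eyes = c("left", "right")[c(l_ok, r_ok)])
}
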