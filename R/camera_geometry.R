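#' Construct a pinhole camera
#'
#' The camera is a pinhole model with square pixels: the vertical field of view
#' spans the image height. Orientation is built from a look-at target and an up
#' vector. Pixel convention (documented because downstream keypoint datasets
#' depend on it): origin at the top-left image corner, `u` grows rightward,
#' `v` grows downward; continuous coordinates lie in `[0, W) x [0, H)` when a
#' point is inside the frame.
#'
#' @param position camera position (3-vector, meters).
#' @param target look-at point (3-vector).
#' @param up approximate up direction (must not be parallel to the view
#'   direction), default +Y.
#' @param fov vertical field of view in degrees, in (0, 180).
#' @param width,height image size in pixels (default 1024 x 1024).
#' @return an object of class `camera` with fields `position`, `R` (world to
#'   camera rotation; camera axes are right / down / forward), `fov`, `width`,
#'   `height`, `focal` (pixels).
#' @export
camera <- function(position, target, up = c(0, 1, 0), fov = 60,
                   width = 1024, height = 1024) {
  position <- as.numeric(position)
  if (fov <= 0 || fov >= 180) stop("fov must be in (0, 180) degrees")
  if (width < 1 || height < 1) stop("image size must be >= 1 pixel")
  fwd <- target - position
  if (vnorm(fwd) < 1e-12) stop("camera target coincides with position")
  fwd <- unit(fwd)
  if (abs(sum(fwd * unit(up))) > 1 - 1e-9)
    stop("up vector is parallel to the view direction")
  right <- unit(cross3(unit(up), fwd))
  down <- cross3(fwd, right)
  R <- rbind(right, down, fwd)
  rownames(R) <- NULL
  structure(list(position = position, R = R, fov = fov,
                 width = as.integer(width), height = as.integer(height),
                 focal = (height / 2) / tan(fov * pi / 360)),
            class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("<camera> %dx%d px, fov %.1f deg, at (%.2f, %.2f, %.2f)\n",
              x$width, x$height, x$fov, x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

camera_space <- function(cam, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  sweep(pts, 2, cam$position) %*% t(cam$R)
}

#' Project 3D points to pixel coordinates
#'
#' Perspective projection. Points with non-positive view-space depth are
#' flagged `behind_camera`; their (extrapolated) coordinates are still
#' returned so that annotation records stay complete.
#'
#' @param cam a `camera`.
#' @param pts 3-vector or N x 3 matrix of world points.
#' @return data.frame with columns `u`, `v` (pixels) and `behind_camera`.
#' @export
project <- function(cam, pts) {
  pc <- camera_space(cam, pts)
  z <- pc[, 3]
  behind <- z <= 0
  zsafe <- ifelse(abs(z) < 1e-12, 1e-12, z)
  data.frame(u = cam$width / 2 + cam$focal * pc[, 1] / zsafe,
             v = cam$height / 2 + cam$focal * pc[, 2] / zsafe,
             behind_camera = behind)
}

#' Keypoint depth: Euclidean camera-to-point distance
#'
#' Depth labels are the Euclidean distance between the camera position and the
#' landmark, in meters (not the view-space z).
#'
#' @param cam a `camera`.
#' @param pts 3-vector or N x 3 matrix.
#' @return numeric vector of distances (m).
#' @export
point_depth <- function(cam, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  sqrt(rowSums(sweep(pts, 2, cam$position)^2))
}

#' Unproject a pixel to a world point at a given Euclidean distance
#'
#' Inverse of [project()] along the pixel ray, scaled so that the result lies
#' at Euclidean distance `d` from the camera. Pixels outside the frame simply
#' extrapolate the ray.
#'
#' @param cam a `camera`.
#' @param uv length-2 vector or N x 2 matrix of pixel coordinates.
#' @param d Euclidean distance(s) in meters, > 0.
#' @return N x 3 matrix of world points.
#' @export
unproject <- function(cam, uv, d) {
  if (!is.matrix(uv)) uv <- matrix(uv, ncol = 2)
  if (any(d <= 0)) stop("d must be positive")
  dirs <- cbind((uv[, 1] - cam$width / 2) / cam$focal,
                (uv[, 2] - cam$height / 2) / cam$focal,
                1)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  world_dirs <- dirs %*% cam$R   # rows times R == t(R) %*% dir per row
  sweep(world_dirs * d, 2, cam$position, "+")
}

#' Camera sampling ranges
#'
#' Defaults define the randomized-camera protocol: position on a spherical
#' shell around the look-at target (radius 2.5-5 m, azimuth full circle,
#' elevation -20..60 degrees), look-at jitter of +-0.1 m per axis, and
#' vertical FOV uniform on 30-120 degrees.
#'
#' @param radius length-2 range (m). @param azimuth,elevation length-2 ranges
#'   (degrees). @param fov length-2 FOV range (degrees). @param jitter look-at
#'   jitter half-width (m). @param width,height image size.
#' @return list of ranges for [sample_camera()].
#' @export
camera_ranges <- function(radius = c(2.5, 5), azimuth = c(0, 360),
                          elevation = c(-20, 60), fov = c(30, 120),
                          jitter = 0.1, width = 1024, height = 1024) {
  list(radius = radius, azimuth = azimuth, elevation = elevation, fov = fov,
       jitter = jitter, width = width, height = height)
}

#' Sample a randomized camera
#'
#' Draws a camera on a spherical shell around `target_point` per the ranges
#' (see [camera_ranges()]). Uses the current R RNG stream.
#'
#' @param target_point scene point the camera looks at (e.g. avatar centroid).
#' @param ranges a [camera_ranges()] list.
#' @return a `camera`.
#' @export
sample_camera <- function(target_point, ranges = camera_ranges()) {
  r <- stats::runif(1, ranges$radius[1], ranges$radius[2])
  az <- stats::runif(1, ranges$azimuth[1], ranges$azimuth[2]) * pi / 180
  el <- stats::runif(1, ranges$elevation[1], ranges$elevation[2]) * pi / 180
  fov <- stats::runif(1, ranges$fov[1], ranges$fov[2])
  jit <- stats::runif(3, -ranges$jitter, ranges$jitter)
  pos <- target_point + r * c(cos(el) * sin(az), sin(el), cos(el) * cos(az))
  camera(position = pos, target = target_point + jit, fov = fov,
         width = ranges$width, height = ranges$height)
}
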