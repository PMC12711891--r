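# Software rendering: RGB images with flat Lambertian shading, whole-body
# silhouettes and per-segment masks, all through one z-buffered rasterizer.

#' Render settings
#'
#' @param width,height output resolution in pixels (default 1024 x 1024).
#' @param background either an RGB 3-vector in [0,1] (solid), a list
#'   `list(type = "gradient", top =, bottom =)` for a vertical gradient, or
#'   `list(type = "image", path =)` for a PNG/JPEG backdrop (nearest-neighbor
#'   resampled).
#' @param light_direction unit 3-vector pointing toward the light.
#' @param segment_threshold skinning-weight cutoff for segment masks: vertices
#'   with weight below this are hidden (a vertex at exactly the threshold is
#'   shown). Default 0.5.
#' @param triangle_rule `"all"` (a triangle of a segment mask is drawn only
#'   when all three vertices are shown; default) or `"any"`.
#' @param rgb_format `"jpeg"` (default) or `"png"`; masks are always PNG so
#'   that lossy compression cannot corrupt labels.
#' @param jpeg_quality JPEG quality in (0, 1], default 0.9.
#' @return a `render_settings` list.
#' @export
render_settings <- function(width = 1024, height = 1024,
                            background = c(0.35, 0.45, 0.55),
                            light_direction = c(0.4, 0.8, 0.45),
                            segment_threshold = 0.5,
                            triangle_rule = c("all", "any"),
                            rgb_format = c("jpeg", "png"),
                            jpeg_quality = 0.9) {
  if (width < 16 || height < 16) stop("resolution must be >= 16 pixels")
  if (segment_threshold <= 0 || segment_threshold >= 1)
    stop("segment_threshold must be in (0, 1)")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background,
                 light_direction = unit(as.numeric(light_direction)),
                 segment_threshold = segment_threshold,
                 triangle_rule = match.arg(triangle_rule),
                 rgb_format = match.arg(rgb_format),
                 jpeg_quality = jpeg_quality),
            class = "render_settings")
}

background_image <- function(settings) {
  H <- settings$height; W <- settings$width
  bg <- settings$background
  img <- array(0, c(H, W, 3))
  if (is.numeric(bg) && length(bg) == 3) {
    for (c in 1:3) img[, , c] <- bg[c]
  } else if (is.list(bg) && identical(bg$type, "gradient")) {
    tvec <- (seq_len(H) - 1) / max(1, H - 1)
    for (c in 1:3) img[, , c] <- matrix((1 - tvec) * bg$top[c] + tvec * bg$bottom[c], H, W)
  } else if (is.list(bg) && identical(bg$type, "image")) {
    src <- if (grepl("\\.png$", bg$path, ignore.case = TRUE)) png::readPNG(bg$path)
           else jpeg::readJPEG(bg$path)
    if (length(dim(src)) == 2) src <- array(rep(src, 3), c(dim(src), 3))
    ri <- pmax(1, round(seq_len(H) / H * dim(src)[1]))
    ci <- pmax(1, round(seq_len(W) / W * dim(src)[2]))
    for (c in 1:3) img[, , c] <- src[ri, ci, c]
  } else stop("unsupported background spec")
  img
}

# Project vertices, drop faces touching the near plane, rasterize.
# The focal length is recomputed from the camera FOV at the render resolution,
# so settings may render at a different size than the camera's annotation
# resolution while keeping the same field of view.
rasterize_mesh <- function(mesh, cam, width, height, face_rgb = NULL,
                           keep_faces = NULL) {
  pc <- camera_space(cam, mesh$vertices)
  z <- pc[, 3]
  focal <- (height / 2) / tan(cam$fov * pi / 360)
  uv <- cbind(width / 2 + focal * pc[, 1] / ifelse(z > 0, z, 1),
              height / 2 + focal * pc[, 2] / ifelse(z > 0, z, 1))
  faces <- mesh$faces
  ok <- z[faces[, 1]] > 1e-6 & z[faces[, 2]] > 1e-6 & z[faces[, 3]] > 1e-6
  if (!is.null(keep_faces)) ok <- ok & keep_faces
  faces <- faces[ok, , drop = FALSE]
  if (is.null(face_rgb)) {
    face_rgb <- matrix(1, nrow(faces), 3)
  } else {
    face_rgb <- face_rgb[ok, , drop = FALSE]
  }
  if (nrow(faces) == 0) {
    return(list(rgb = array(0, c(height, width, 3)),
                hit = matrix(0L, height, width),
                zbuf = matrix(0, height, width)))
  }
  rasterize_cpp(uv, 1 / pmax(z, 1e-12), faces - 1L, face_rgb,
                as.integer(width), as.integer(height))
}

face_shaded_colors <- function(mesh, settings, colors) {
  F <- mesh$faces
  a <- mesh$vertices[F[, 1], , drop = FALSE]
  e1 <- mesh$vertices[F[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[F[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(n^2))
  n <- n / ifelse(nn > 1e-18, nn, 1)
  lambert <- 0.3 + 0.7 * pmax(0, abs(n %*% settings$light_direction))
  base <- (colors[F[, 1], , drop = FALSE] + colors[F[, 2], , drop = FALSE] +
             colors[F[, 3], , drop = FALSE]) / 3
  shaded <- base * as.numeric(lambert)
  shaded[] <- pmin(1, pmax(0, shaded))
  shaded
}

#' Render an RGB image of the avatar
#'
#' Z-buffered rasterization with flat Lambertian shading (ambient 0.3 plus 0.7
#' times the diffuse term) over the configured background. Deterministic for
#' fixed inputs.
#'
#' @param mesh a `triangle_mesh` (deformed frame mesh).
#' @param cam a `camera` (its resolution is overridden by `settings`).
#' @param settings a [render_settings()] list.
#' @param colors optional N x 3 per-vertex RGB; defaults to `mesh$colors` or a
#'   uniform skin tone.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
render_rgb <- function(mesh, cam, settings = render_settings(), colors = NULL) {
  if (is.null(colors)) colors <- mesh$colors
  if (is.null(colors))
    colors <- matrix(rep(c(0.87, 0.67, 0.53), each = nrow(mesh$vertices)),
                     ncol = 3)
  img <- background_image(settings)
  if (nrow(mesh$faces) == 0) return(img)
  face_rgb <- face_shaded_colors(mesh, settings, colors)
  ras <- rasterize_mesh(mesh, cam, settings$width, settings$height, face_rgb)
  m <- ras$hit == 1L
  for (c in 1:3) {
    plane <- img[, , c]
    plane[m] <- ras$rgb[, , c][m]
    img[, , c] <- plane
  }
  img
}

#' Render the whole-body silhouette mask
#'
#' Same rasterization coverage as [render_rgb()] (identical z-buffer hits), no
#' shading or anti-aliasing: foreground 255 on background 0, exactly binary.
#'
#' @inheritParams render_rgb
#' @return H x W integer matrix with values 0 / 255.
#' @export
render_silhouette <- function(mesh, cam, settings = render_settings()) {
  if (nrow(mesh$faces) == 0)
    return(matrix(0L, settings$height, settings$width))
  ras <- rasterize_mesh(mesh, cam, settings$width, settings$height)
  ras$hit * 255L
}

#' Render the mask of one body segment
#'
#' Vertices whose skinning weight to the segment's bone is below the threshold
#' are hidden (a vertex at exactly the threshold is shown); a triangle is
#' rasterized only when all three of its vertices are shown (switchable to
#' "any vertex shown" via `settings$triangle_rule`). Because the drawn faces
#' are a subset of the full mesh, every segment-mask pixel is also a
#' silhouette pixel.
#'
#' @param mesh a `triangle_mesh`.
#' @param weights a `weight_matrix`.
#' @param segment a body name (requires `armature`) or a segment-bone column
#'   name of `weights`.
#' @param cam a `camera`.
#' @param settings a [render_settings()] list.
#' @param armature optional `armature` for body-name lookup.
#' @return H x W integer matrix with values 0 / 255.
#' @export
render_segment_mask <- function(mesh, weights, segment, cam,
                                settings = render_settings(), armature = NULL) {
  col <- segment
  if (!is.null(armature) && segment %in% names(armature$body_to_segment))
    col <- armature$body_to_segment[[segment]]
  if (!(col %in% colnames(weights)))
    stop(sprintf("unknown segment '%s'", segment))
  shown <- weights[, col] >= settings$segment_threshold
  F <- mesh$faces
  keep <- if (settings$triangle_rule == "all") {
    shown[F[, 1]] & shown[F[, 2]] & shown[F[, 3]]
  } else {
    shown[F[, 1]] | shown[F[, 2]] | shown[F[, 3]]
  }
  if (!any(keep)) return(matrix(0L, settings$height, settings$width))
  ras <- rasterize_mesh(mesh, cam, settings$width, settings$height,
                        keep_faces = keep)
  ras$hit * 255L
}

#' Write an image array or mask to disk
#'
#' RGB arrays go to JPEG (default, quality per settings) or PNG; binary masks
#' always to PNG.
#'
#' @param img H x W x 3 array in [0,1], or an H x W mask matrix (0/255).
#' @param path output path (extension chosen by the caller).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) == 2) {
    png::writePNG(img / 255, path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    jpeg::writeJPEG(img, path, quality = 0.9)
  }
  invisible(path)
}
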