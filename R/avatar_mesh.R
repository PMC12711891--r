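#' Construct a triangle mesh
#'
#' @param vertices N x 3 numeric matrix of vertex positions (meters).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param colors optional N x 3 matrix of per-vertex RGB colors in [0, 1].
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be N x 3")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite coordinates")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range")
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    if (any(degen)) stop(sprintf("%d degenerate faces (repeated vertex index)", sum(degen)))
  }
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3)
      stop("colors must be N x 3")
  }
  structure(list(vertices = vertices, faces = faces, colors = colors),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", per-vertex colors"))
  invisible(x)
}

#' Morphology parameters for avatar generation
#'
#' `shape` is a single scalar in [-2, 2] scaling segment girth, a stand-in for
#' the ten shape parameters of statistical body models (which the source
#' datasets sweep over the same -2..2 range); `sex_tag` selects shoulder/hip
#' girth presets.
#'
#' @param sex_tag `"female"` or `"male"`.
#' @param shape girth scale in [-2, 2]; radius multiplier is `1 + 0.15 * shape`.
#' @param mesh_resolution target vertex count of the generated mesh (>= 500).
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(sex_tag = c("female", "male"), shape = 0,
                              mesh_resolution = 7500) {
  sex_tag <- match.arg(sex_tag)
  if (shape < -2 || shape > 2) stop("shape must be in [-2, 2]")
  if (mesh_resolution < 500) stop("mesh_resolution must be >= 500")
  structure(list(sex_tag = sex_tag, shape = shape,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "morphology_params")
}

# Base segment radii (m) by body-name keyword, before morphology scaling.
segment_base_radius <- function(body, morphology) {
  base <- c(pelvis = 0.115, torso = 0.140, femur = 0.070, tibia = 0.050,
            foot = 0.040, humerus = 0.046, ulna = 0.036, radius = 0.036,
            hand = 0.035, head = 0.095)
  hit <- names(base)[vapply(names(base), function(k) grepl(k, body, fixed = TRUE), NA)]
  r <- if (length(hit) > 0) base[[hit[1]]] else 0.05
  if (morphology$sex_tag == "male") {
    if (grepl("torso", body)) r <- r * 1.08
    if (grepl("pelvis", body)) r <- r * 0.95
  } else {
    if (grepl("torso", body)) r <- r * 0.92
    if (grepl("pelvis", body)) r <- r * 1.08
  }
  r * (1 + 0.15 * morphology$shape)
}

# Tessellate a capsule from `head` to `tail` with radius r.
# sectors must be even; with the canonical frame (e0 = sagittal-plane-free
# x axis component) and half-phase azimuths the tessellation is symmetric
# under x -> -x whenever the axis lies in the x = 0 plane.
capsule_mesh <- function(head, tail, r, sectors, rings_total, m_cap) {
  axis <- tail - head
  L <- vnorm(axis)
  e2 <- if (L > 1e-12) axis / L else c(0, 1, 0)
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * e2) * e2
  e0 <- if (vnorm(ex) > 1e-6) ex / vnorm(ex) else {
    ez <- c(0, 0, 1) - sum(c(0, 0, 1) * e2) * e2
    ez / vnorm(ez)
  }
  e1 <- cross3(e2, e0)
  center <- (head + tail) / 2
  m_cyl <- max(1L, rings_total + 1L - 2L * m_cap)
  rings_total <- 2L * m_cap + m_cyl - 1L
  # ring profile from tail(+) cap over the wall to head(-) cap, top to bottom
  ys <- numeric(0); rads <- numeric(0)
  for (i in seq_len(m_cap)) {
    phi <- i * (pi / 2) / m_cap
    ys <- c(ys, L / 2 + r * cos(phi)); rads <- c(rads, r * sin(phi))
  }
  if (m_cyl > 1) for (j in seq_len(m_cyl - 1)) {
    ys <- c(ys, L / 2 - j * L / m_cyl); rads <- c(rads, r)
  }
  for (i in seq(m_cap, 1)) {
    phi <- i * (pi / 2) / m_cap
    ys <- c(ys, -L / 2 - r * cos(phi)); rads <- c(rads, r * sin(phi))
  }
  theta <- 2 * pi * (seq_len(sectors) - 0.5) / sectors
  nv <- 2L + sectors * rings_total
  V <- matrix(0, nv, 3)
  V[1, ] <- center + (L / 2 + r) * e2          # top pole (tail side)
  V[nv, ] <- center - (L / 2 + r) * e2         # bottom pole (head side)
  k <- 1L
  for (i in seq_along(ys)) {
    ring <- outer(cos(theta), e0) * rads[i] + outer(sin(theta), e1) * rads[i]
    ring <- sweep(ring, 2, center + ys[i] * e2, "+")
    V[(k + 1):(k + sectors), ] <- ring
    k <- k + sectors
  }
  ring_idx <- function(i) 1L + (i - 1L) * sectors + seq_len(sectors)
  F <- list()
  top <- ring_idx(1)
  F[[1]] <- cbind(1L, top, c(top[-1], top[1]))
  for (i in seq_len(rings_total - 1)) {
    a <- ring_idx(i); b <- ring_idx(i + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    F[[length(F) + 1]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  bot <- ring_idx(rings_total)
  F[[length(F) + 1]] <- cbind(nv, c(bot[-1], bot[1]), bot)
  triangle_mesh(V, do.call(rbind, F))
}

round_even <- function(x) max(6L, 2L * as.integer(round(x / 2)))

#' Generate a procedural human-like avatar mesh
#'
#' Builds one watertight capsule shell per body segment, sized from the
#' segment-bone length (see [build_armature()]) and a morphology-scaled radius
#' preset, and merges them into a single triangle mesh. The mesh is generated
#' in the rest (T-) pose so that it matches the skeleton by construction; the
#' default resolution (~7,500 vertices) matches the vertex count scale of
#' typical statistical body meshes. For a left/right-symmetric skeleton the
#' mesh is symmetric about the sagittal (x = 0) plane: left-side (`_l`)
#' capsules are exact mirrors of their right-side counterparts and mid-line
#' capsules use a mirror-symmetric tessellation.
#'
#' @param model a `skeletal_model`.
#' @param morphology a [morphology_params()] object.
#' @param rest rest-pose `body_transforms` (default [rest_transforms()]).
#' @return a `triangle_mesh` with attribute `vertex_body` (character vector
#'   naming the generating body segment of every vertex).
#' @export
generate_avatar <- function(model, morphology = morphology_params(),
                            rest = rest_transforms(model)) {
  arm <- build_armature(model, rest)
  bn <- body_names(model)
  seg <- lapply(bn, function(b) arm$bones[[arm$body_to_segment[[b]]]])
  names(seg) <- bn
  radii <- vapply(bn, segment_base_radius, 0, morphology = morphology)
  lens <- vapply(seg, function(s) vnorm(s$tail - s$head), 0)
  if (any(lens + radii < 1e-6)) stop("unresolvable zero-size segment")
  area <- 2 * pi * radii * (2 * radii + lens)
  quota <- morphology$mesh_resolution * area / sum(area)

  build_one <- function(b) {
    h <- lens[[b]] + pi * radii[[b]]          # unrolled height
    w <- 2 * pi * radii[[b]]                  # unrolled circumference
    S <- round_even(sqrt(quota[[b]] * w / h))
    rings <- max(3L, as.integer(round(quota[[b]] / S)))
    m_cap <- max(1L, as.integer(round(rings * (pi * radii[[b]] / 2) / h)))
    capsule_mesh(seg[[b]]$head, seg[[b]]$tail, radii[[b]], S, rings, m_cap)
  }

  parts <- list()
  for (b in bn) {
    if (grepl("_l$", b)) {
      rb <- sub("_l$", "_r", b)
      mir <- function(v) v * c(-1, 1, 1)
      if (rb %in% bn &&
          vnorm(mir(seg[[rb]]$head) - seg[[b]]$head) < 1e-9 &&
          vnorm(mir(seg[[rb]]$tail) - seg[[b]]$tail) < 1e-9 &&
          abs(radii[[rb]] - radii[[b]]) < 1e-12) {
        rm <- parts[[rb]]
        if (is.null(rm)) { rm <- build_one(rb); parts[[rb]] <- rm }
        V <- rm$vertices; V[, 1] <- -V[, 1]
        parts[[b]] <- triangle_mesh(V, rm$faces[, c(1, 3, 2)])  # mirrored, winding flipped
        next
      }
    }
    if (is.null(parts[[b]])) parts[[b]] <- build_one(b)
  }
  parts <- parts[bn]
  counts <- vapply(parts, function(p) nrow(p$vertices), 0L)
  offs <- cumsum(c(0L, counts[-length(counts)]))
  V <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  F <- do.call(rbind, lapply(seq_along(parts), function(i) parts[[i]]$faces + offs[i]))
  mesh <- triangle_mesh(V, F)
  attr(mesh, "vertex_body") <- rep(bn, counts)
  mesh
}

#' Summarize a triangle mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `n_vertices`, `n_faces` and `extents` (3 x 2 matrix of
#'   per-axis min/max).
#' @export
mesh_summary <- function(mesh) {
  if (nrow(mesh$vertices) == 0) stop("empty mesh")
  ext <- cbind(min = apply(mesh$vertices, 2, min),
               max = apply(mesh$vertices, 2, max))
  rownames(ext) <- c("x", "y", "z")
  list(n_vertices = nrow(mesh$vertices), n_faces = nrow(mesh$faces), extents = ext)
}

#' Write a mesh as ASCII OBJ
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read an ASCII OBJ mesh (positions and faces only)
#'
#' Loader hook for users bringing externally generated body meshes; polygon
#' faces are fan-triangulated, texture/normal indices are ignored.
#'
#' @param path OBJ file path.
#' @return a `triangle_mesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "[ \t]+"), function(x) as.numeric(x[2:4])))
  F <- list()
  for (ln in fl) {
    idx <- vapply(strsplit(ln, "[ \t]+")[[1]][-1],
                  function(tok) as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1]), 0L)
    for (k in seq_len(length(idx) - 2))
      F[[length(F) + 1]] <- c(idx[1], idx[k + 1], idx[k + 2])
  }
  triangle_mesh(V, do.call(rbind, F))
}
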