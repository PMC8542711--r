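#' Fit a third-order polynomial midline to a skeleton
#'
#' The six skeleton points are rotated into a fish-aligned frame (x-axis =
#' head-to-tail direction) and a cubic `y = c0 + c1 x + c2 x^2 + c3 x^3` is
#' fitted by least squares, capturing the bend of the body posture.
#'
#' @param pose Long pose tibble (`node`, `x_cm`, `y_cm`), nodes ordered
#'   head to tail; at least 4 visible (finite) nodes are required.
#'
#' @return A `midline_curve`: `coefficients` (c0..c3), `frame` (rotation
#'   angle and origin mapping fish frame to tank coordinates), `x_range`,
#'   `arc_length`, `residuals` at the skeleton nodes.
#' @export
fit_midline <- function(pose) {
  if (all(c("node", "x_cm") %in% names(pose))) {
    pose <- pose[match(skeleton_nodes, pose$node), ]
  }
  ok <- is.finite(pose$x_cm) & is.finite(pose$y_cm)
  if (sum(ok) < 4) {
    abort_pulseid("need at least 4 visible nodes for a third-order fit",
                  "pulseid_insufficient_points")
  }
  px <- pose$x_cm[ok]; py <- pose$y_cm[ok]
  origin <- c(px[1], py[1])
  axis <- c(px[length(px)] - px[1], py[length(py)] - py[1])
  theta <- atan2(axis[2], axis[1])
  # rotate into the fish frame: head at the origin, tail on the +x axis
  ct <- cos(-theta); st <- sin(-theta)
  u <- ct * (px - origin[1]) - st * (py - origin[2])
  v <- st * (px - origin[1]) + ct * (py - origin[2])
  fit <- stats::lm(v ~ poly(u, 3, raw = TRUE))
  cf <- unname(stats::coef(fit))
  cf[is.na(cf)] <- 0
  xr <- range(u)
  uu <- seq(xr[1], xr[2], length.out = 512)
  vv <- cf[1] + cf[2] * uu + cf[3] * uu^2 + cf[4] * uu^3
  arc <- sum(sqrt(diff(uu)^2 + diff(vv)^2))
  structure(
    list(coefficients = cf, frame = list(theta = theta, origin = origin),
         x_range = xr, arc_length = arc,
         residuals = unname(stats::residuals(fit))),
    class = "midline_curve"
  )
}

#' @export
print.midline_curve <- function(x, ...) {
  cat(sprintf("<midline_curve> c = (%s), arc length %.2f cm\n",
              paste(signif(x$coefficients, 3), collapse = ", "),
              x$arc_length))
  invisible(x)
}

midline_eval <- function(curve, u) {
  cf <- curve$coefficients
  v <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
  th <- curve$frame$theta; o <- curve$frame$origin
  cbind(x = cos(th) * u - sin(th) * v + o[1],
        y = sin(th) * u + cos(th) * v + o[2])
}

midline_tangent <- function(curve, u) {
  cf <- curve$coefficients
  dv <- cf[2] + 2 * cf[3] * u + 3 * cf[4] * u^2
  th <- curve$frame$theta
  tx <- cos(th) - sin(th) * dv
  ty <- sin(th) + cos(th) * dv
  n <- sqrt(tx^2 + ty^2)
  cbind(tx / n, ty / n)
}

#' Default body profile table
#'
#' Relative semi-axes of the elliptical cross-sections for a slender
#' mormyrid-like body: deepest just behind the head, tapering smoothly to
#' the snout and the narrow caudal peduncle. Values are fractions of body
#' length; the profile is not taken from measurements and can be replaced
#' by a user table (`ring_index, semi_width_rel, semi_height_rel`).
#'
#' @param n_rings Number of cross-sections (default 49).
#' @return Tibble: `ring_index`, `s` (fraction of arc length),
#'   `semi_width_rel`, `semi_height_rel`.
#' @export
body_profile <- function(n_rings = 49) {
  s <- seq_len(n_rings) / (n_rings + 1)
  tibble::tibble(
    ring_index = seq_len(n_rings), s = s,
    semi_width_rel = 0.045 * sin(pi * s^0.8)^0.9,
    semi_height_rel = 0.095 * sin(pi * s^0.7)^0.8
  )
}

#' Build a closed triangulated fish surface from a midline
#'
#' Places `n_rings` elliptical cross-sections (default 49, of `n_nodes`
#' nodes each, default 17) along the midline at uniform arc-length spacing,
#' re-orients each ring perpendicular to the local midline tangent (first
#' derivative of the fitted polynomial), stitches adjacent rings with
#' triangle strips and closes the snout and tail with apex fans. At the
#' default resolution this yields 49 x 17 + 2 = 835 vertices and 1,666
#' triangles.
#'
#' @param curve A [fit_midline()] result, or NULL for a straight midline.
#' @param length_cm Fish length (sets the absolute profile scale and, for a
#'   straight midline, the mesh extent).
#' @param profile Body profile table (see [body_profile()]); must have one
#'   row per ring.
#' @param n_nodes Nodes per ring.
#' @param z_center Vertical position of the midline plane, cm (default half
#'   a 20 cm water depth).
#' @param bend_limit Maximum tangent-direction change between adjacent
#'   rings, radians, above which a geometry warning is issued.
#'
#' @return A `fish_mesh`: list with `vertices` (V x 3), `triangles`
#'   (F x 3, 1-based, outward-oriented), `length_cm`, `n_rings`, `n_nodes`.
#' @export
build_mesh <- function(curve = NULL, length_cm = 12,
                       profile = body_profile(), n_nodes = 17,
                       z_center = 10, bend_limit = pi / 3) {
  if (length_cm <= 0) {
    abort_pulseid("length_cm must be positive", "pulseid_parameter_error")
  }
  n_rings <- nrow(profile)
  if (is.null(curve)) {
    pose <- tibble::tibble(node = skeleton_nodes,
                           x_cm = node_fractions * length_cm, y_cm = 0)
    curve <- fit_midline(pose)
  }
  # uniform arc-length stations for the rings plus the two apexes
  uu <- seq(curve$x_range[1], curve$x_range[2], length.out = 2048)
  pts <- midline_eval(curve, uu)
  seg <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  total <- seg[length(seg)]
  s_stations <- profile$s %||% (seq_len(n_rings) / (n_rings + 1))
  u_at <- function(s) stats::approx(seg, uu, xout = s * total)$y
  u_rings <- u_at(s_stations)
  centers <- midline_eval(curve, u_rings)
  tangents <- midline_tangent(curve, u_rings)
  bend <- abs(diff(atan2(tangents[, 2], tangents[, 1])))
  if (any(pmin(bend, 2 * pi - bend) > bend_limit)) {
    warning("midline curvature exceeds the bend limit; mesh may self-intersect",
            call. = FALSE)
  }
  phi <- 2 * pi * (seq_len(n_nodes) - 1) / n_nodes
  verts <- matrix(0, n_rings * n_nodes + 2, 3)
  for (i in seq_len(n_rings)) {
    sw <- profile$semi_width_rel[i] * length_cm
    sh <- profile$semi_height_rel[i] * length_cm
    h <- c(-tangents[i, 2], tangents[i, 1])  # horizontal normal
    idx <- (i - 1) * n_nodes + seq_len(n_nodes)
    verts[idx, 1] <- centers[i, 1] + sw * cos(phi) * h[1]
    verts[idx, 2] <- centers[i, 2] + sw * cos(phi) * h[2]
    verts[idx, 3] <- z_center + sh * sin(phi)
  }
  nose <- n_rings * n_nodes + 1L
  tail <- n_rings * n_nodes + 2L
  ends <- midline_eval(curve, curve$x_range)
  verts[nose, ] <- c(ends[1, ], z_center)
  verts[tail, ] <- c(ends[2, ], z_center)

  tri <- triangulate_rings(n_rings, n_nodes, nose, tail)
  mesh <- structure(list(vertices = verts, triangles = tri,
                         length_cm = length_cm, n_rings = n_rings,
                         n_nodes = n_nodes),
                    class = "fish_mesh")
  if (mesh_volume(mesh) < 0) mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

# Triangle index table for a stack of rings closed by two apex fans.
triangulate_rings <- function(n_rings, n_nodes, nose, tail) {
  tri <- matrix(0L, 0, 3)
  nxt <- function(k) k %% n_nodes + 1L
  for (k in seq_len(n_nodes)) {
    tri <- rbind(tri, c(nose, k, nxt(k)))
  }
  for (i in seq_len(n_rings - 1)) {
    a <- (i - 1) * n_nodes; b <- i * n_nodes
    for (k in seq_len(n_nodes)) {
      tri <- rbind(tri,
                   c(a + k, b + k, a + nxt(k)),
                   c(a + nxt(k), b + k, b + nxt(k)))
    }
  }
  off <- (n_rings - 1) * n_nodes
  for (k in seq_len(n_nodes)) {
    tri <- rbind(tri, c(tail, off + nxt(k), off + k))
  }
  tri
}

#' Sphere mesh with the ring-and-apex topology
#'
#' A sphere discretized exactly like the fish surface (rings of nodes plus
#' two apexes), used to validate the boundary element solver against
#' classical analytic results.
#'
#' @param radius Sphere radius, cm.
#' @param n_rings,n_nodes Ring/nodes-per-ring counts (defaults 49 and 17,
#'   the fish-surface resolution).
#' @param center Sphere centre (x, y, z), cm.
#' @return A `fish_mesh`.
#' @export
sphere_mesh <- function(radius = 1, n_rings = 49, n_nodes = 17,
                        center = c(0, 0, 0)) {
  theta <- pi * seq_len(n_rings) / (n_rings + 1)
  phi <- 2 * pi * (seq_len(n_nodes) - 1) / n_nodes
  verts <- matrix(0, n_rings * n_nodes + 2, 3)
  for (i in seq_len(n_rings)) {
    idx <- (i - 1) * n_nodes + seq_len(n_nodes)
    verts[idx, 1] <- center[1] - radius * cos(theta[i])
    verts[idx, 2] <- center[2] + radius * sin(theta[i]) * cos(phi)
    verts[idx, 3] <- center[3] + radius * sin(theta[i]) * sin(phi)
  }
  nose <- n_rings * n_nodes + 1L
  tail <- n_rings * n_nodes + 2L
  verts[nose, ] <- center - c(radius, 0, 0)
  verts[tail, ] <- center + c(radius, 0, 0)
  mesh <- structure(list(vertices = verts,
                         triangles = triangulate_rings(n_rings, n_nodes,
                                                       nose, tail),
                         length_cm = 2 * radius, n_rings = n_rings,
                         n_nodes = n_nodes),
                    class = "fish_mesh")
  if (mesh_volume(mesh) < 0) mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' @export
print.fish_mesh <- function(x, ...) {
  cat(sprintf("<fish_mesh> %d vertices, %d triangles, length %.1f cm\n",
              nrow(x$vertices), nrow(x$triangles), x$length_cm))
  invisible(x)
}

#' Mesh quantities
#'
#' Signed volume (positive for outward-oriented closed surfaces), total
#' surface area, per-triangle areas, centroids and outward normals.
#'
#' @param mesh A `fish_mesh`.
#' @return `mesh_volume`/`mesh_area`: scalars. `mesh_triangle_data`: tibble
#'   with per-triangle centroid, area and unit normal.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  sum(mesh_triangle_data(mesh)$area)
}

#' @rdname mesh_volume
#' @export
mesh_triangle_data <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  tibble::tibble(
    triangle = seq_len(nrow(tr)),
    cx = (a[, 1] + b[, 1] + cc[, 1]) / 3,
    cy = (a[, 2] + b[, 2] + cc[, 2]) / 3,
    cz = (a[, 3] + b[, 3] + cc[, 3]) / 3,
    area = nrm / 2,
    nx = nx / nrm, ny = ny / nrm, nz = nz / nrm
  )
}

#' Edge table of a mesh
#'
#' @param mesh A `fish_mesh`.
#' @return Tibble of undirected edges with the count of incident triangles
#'   (2 everywhere on a closed surface).
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  tibble::tibble(edge = names(tab), n_triangles = as.integer(tab))
}

#' Uniformly scale a mesh to a new body length
#'
#' Scales about the mesh centroid; vertex and triangle counts are
#' unchanged, areas scale with the square and volume with the cube of the
#' factor.
#'
#' @param mesh A `fish_mesh`.
#' @param new_length_cm Target length, cm.
#' @return The scaled `fish_mesh`.
#' @export
scale_mesh <- function(mesh, new_length_cm) {
  if (new_length_cm <= 0) {
    abort_pulseid("new_length_cm must be positive", "pulseid_parameter_error")
  }
  f <- new_length_cm / mesh$length_cm
  ctr <- colMeans(mesh$vertices)
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, ctr), 2, rep(f, 3), "*")
  mesh$vertices <- sweep(mesh$vertices, 2, ctr, "+")
  mesh$length_cm <- new_length_cm
  mesh
}

#' Translate a mesh
#' @param mesh A `fish_mesh`.
#' @param offset Numeric length-3 translation (cm).
#' @return Translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

#' Export a mesh as OBJ or PLY (ASCII)
#'
#' @param mesh A `fish_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Write the body-profile table as CSV
#' @param profile Profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
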