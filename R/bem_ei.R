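#' Conductivity scene for the boundary element solver
#'
#' The electrostatic model: ohmic media everywhere (current density
#' proportional to the field), no charge accumulation, piecewise-homogeneous
#' conductivity — fish bodies immersed in an infinite water volume, each
#' covered by a thin resistive skin. The discharging fish carries internal
#' current poles that must sum to zero (charge conservation).
#'
#' Internally the solver works in cm, S/cm and uA, so surface potentials
#' come out in uV and current densities in uA/cm^2; skin resistivity in
#' Ohm cm^2 enters without conversion.
#'
#' @param bodies List of bodies, each a list with `mesh` (a `fish_mesh`),
#'   `id` (character), `body_sigma_S_m` (default 2) and `skin_ohm_cm2`
#'   (default 3000; large values make the body effectively insulating).
#' @param water_uS_cm Water conductivity, uS/cm (measured 120 in the
#'   experimental tank).
#' @param sources Tibble with `x`, `y`, `z` (cm), `current_uA` and
#'   `body_id`; poles must lie inside their body and sum to zero per body.
#' @param discharging Id of the discharging body (`NA` for none, e.g. a
#'   pure background-field scene).
#' @param background_E Optional uniform applied field, numeric length-3
#'   (uV/cm), used mainly for verification against analytic solutions.
#'
#' @return A `conductivity_scene`.
#' @export
conductivity_scene <- function(bodies, water_uS_cm = 120, sources = NULL,
                               discharging = NA_character_,
                               background_E = NULL) {
  ids <- vapply(bodies, function(b) b$id %||% NA_character_, character(1))
  if (anyNA(ids) || anyDuplicated(ids)) {
    abort_pulseid("every body needs a unique id", "pulseid_scene_error")
  }
  if (!is.null(sources)) {
    for (id in unique(sources$body_id)) {
      tot <- sum(sources$current_uA[sources$body_id == id])
      if (abs(tot) > 1e-9 * max(abs(sources$current_uA))) {
        abort_pulseid("source currents must sum to zero within each body",
                      "pulseid_scene_error")
      }
    }
    if (!is.na(discharging) && !all(sources$body_id == discharging)) {
      abort_pulseid("exactly one body discharges per solve",
                    "pulseid_scene_error")
    }
  }
  structure(
    list(bodies = purrr::map(bodies, function(b) {
      list(mesh = b$mesh, id = b$id,
           body_sigma_S_m = b$body_sigma_S_m %||% 2,
           skin_ohm_cm2 = b$skin_ohm_cm2 %||% 3000)
    }),
    water_uS_cm = water_uS_cm, sources = sources,
    discharging = discharging, background_E = background_E),
    class = "conductivity_scene"
  )
}

#' Dipole source poles in the caudal peduncle of a fish mesh
#'
#' The electric organ of mormyrids sits in the caudal peduncle; the default
#' source model is a pole pair (+I at the rostral-ward pole, -I caudal) at
#' 80% and 95% of the ring sequence, on the mesh midline.
#'
#' @param mesh A `fish_mesh`.
#' @param body_id Id the poles belong to.
#' @param current_uA Pole current I, uA (default 1000: a
#'   milliamp-scale discharge, so that near-contact electric images sit
#'   well above the 0.1 uA model noise floor).
#' @param fractions Ring-sequence fractions for the two poles.
#' @return Source tibble for [conductivity_scene()].
#' @export
tail_dipole_sources <- function(mesh, body_id, current_uA = 1000,
                                fractions = c(0.80, 0.95)) {
  ring_center <- function(fr) {
    i <- max(1L, min(mesh$n_rings, round(fr * mesh$n_rings)))
    idx <- (i - 1) * mesh$n_nodes + seq_len(mesh$n_nodes)
    colMeans(mesh$vertices[idx, , drop = FALSE])
  }
  p1 <- ring_center(fractions[1]); p2 <- ring_center(fractions[2])
  tibble::tibble(x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                 z = c(p1[3], p2[3]),
                 current_uA = c(current_uA, -current_uA),
                 body_id = body_id)
}

# Equal-area sub-centroids (barycentric) after repeated midpoint
# subdivision, used for near-singular quadrature (16 and 64 points).
bary_centroids <- function(levels) {
  subdiv <- function(tri) {
    a <- tri[1, ]; b <- tri[2, ]; cc <- tri[3, ]
    ab <- (a + b) / 2; bc <- (b + cc) / 2; ca <- (cc + a) / 2
    list(rbind(a, ab, ca), rbind(ab, b, bc), rbind(ca, bc, cc),
         rbind(ab, bc, ca))
  }
  tris <- list(diag(3))
  for (lev in seq_len(levels)) {
    tris <- unlist(lapply(tris, subdiv), recursive = FALSE)
  }
  t(vapply(tris, colMeans, numeric(3)))
}
sub_bary <- bary_centroids(2)    # 16 x 3
sub_bary3 <- bary_centroids(3)   # 64 x 3

# Geometry tables for the BEM system: one row per triangle.
scene_geometry <- function(scene) {
  geo <- purrr::imap_dfr(scene$bodies, function(b, bi) {
    td <- mesh_triangle_data(b$mesh)
    td$body <- b$id
    td$body_index <- bi
    td$sigma_in <- b$body_sigma_S_m / 100     # S/cm
    td$rho <- b$skin_ohm_cm2
    td
  })
  geo
}

# Per-triangle 16-point sub-centroids for all meshes, as an (N*16) x 3
# matrix aligned with the geometry table.
scene_subpoints <- function(scene) {
  do.call(rbind, purrr::map(scene$bodies, function(b) {
    v <- b$mesh$vertices; tr <- b$mesh$triangles
    a <- v[tr[, 1], , drop = FALSE]
    bb <- v[tr[, 2], , drop = FALSE]
    cc <- v[tr[, 3], , drop = FALSE]
    out <- matrix(0, nrow(tr) * 16, 3)
    for (k in 1:16) {
      w <- sub_bary[k, ]
      out[seq_len(nrow(tr)) + (k - 1) * nrow(tr), ] <-
        w[1] * a + w[2] * bb + w[3] * cc
    }
    # reorder so each triangle's 16 points are contiguous
    idx <- as.vector(t(matrix(seq_len(nrow(tr) * 16), nrow(tr), 16)))
    out[idx, , drop = FALSE]
  }))
}

# Analytic integral of 1/(4 pi r) over a flat triangle, observed from its
# own centroid: split at the centroid into three sub-triangles with the
# observation point at a vertex; for each, integral of 1/r dS =
# h * (asinh(t2/h) - asinh(t1/h)) with h the distance to the opposite edge.
self_single_layer <- function(va, vb, vc) {
  ctr <- (va + vb + vc) / 3
  one <- function(p, a, b) {
    e <- b - a
    le <- sqrt(sum(e^2))
    eh <- e / le
    pa <- a - p
    tpar <- sum(pa * eh)
    foot <- a - tpar * eh
    h <- sqrt(sum((foot - p)^2))
    t1 <- sum((a - foot) * eh); t2 <- sum((b - foot) * eh)
    h * (asinh(t2 / h) - asinh(t1 / h))
  }
  (one(ctr, va, vb) + one(ctr, vb, vc) + one(ctr, vc, va)) / (4 * pi)
}

# Integral of 1/(4 pi r) over a triangle observed from one of its own
# vertices p (a and b are the other two vertices).
vertex_single_layer <- function(p, a, b) {
  e <- b - a
  le <- sqrt(sum(e^2))
  eh <- e / le
  pa <- a - p
  tpar <- sum(pa * eh)
  foot <- a - tpar * eh
  h <- sqrt(sum((foot - p)^2))
  t1 <- sum((a - foot) * eh); t2 <- sum((b - foot) * eh)
  h * (asinh(t2 / h) - asinh(t1 / h)) / (4 * pi)
}

#' Assemble and solve the boundary element system
#'
#' Collocation at triangle centroids with piecewise-constant single-layer
#' densities: one interior and one exterior density per triangle, coupled
#' by current continuity through the skin and the resistive-skin potential
#' jump `phi_in - phi_out = rho * J`. Self-terms of the single-layer
#' operator are integrated analytically; neighbouring triangles use a
#' 16-point subdivided quadrature. Solves one dense linear system of
#' 2 x (total triangles) equations.
#'
#' @param scene A [conductivity_scene()].
#' @param near_factor Distance cutoff (in units of triangle diameter) below
#'   which the refined quadrature is used.
#'
#' @return A `boundary_solution`: tibble `values` with per-triangle `body`,
#'   `triangle`, `J_uA_cm2` (outward transcutaneous current density),
#'   `phi_out_uV`; plus `node_values` (per mesh node, area-weighted from
#'   incident triangles), `conservation` (net outward current per body,
#'   uA) and the scene.
#' @export
assemble_and_solve <- function(scene, near_factor = 2) {
  stopifnot(inherits(scene, "conductivity_scene"))
  geo <- scene_geometry(scene)
  n <- nrow(geo)
  sigma_w <- scene$water_uS_cm * 1e-6  # S/cm
  C <- cbind(geo$cx, geo$cy, geo$cz)
  NM <- cbind(geo$nx, geo$ny, geo$nz)
  A <- geo$area
  same_body <- outer(geo$body_index, geo$body_index, "==")

  dx <- outer(C[, 1], C[, 1], "-")  # x_i - x_j
  dy <- outer(C[, 2], C[, 2], "-")
  dz <- outer(C[, 3], C[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  diag(r) <- 1
  S <- sweep(1 / (4 * pi * r), 2, A, "*")
  # K_ij = d/dn_i int_Tj G = A_j ((c_j - x_i) . n_i) / (4 pi r^3)
  dot_n <- -(dx * NM[, 1] + dy * NM[, 2] + dz * NM[, 3])
  K <- sweep(dot_n / (4 * pi * r^3), 2, A, "*")
  diag(K) <- 0

  # refined quadrature for near pairs, analytic for self
  sub <- scene_subpoints(scene)
  diam <- 2 * sqrt(A / pi)
  near <- which(r < near_factor * matrix(diam, n, n, byrow = TRUE) &
                  row(S) != col(S), arr.ind = TRUE)
  if (nrow(near) > 0) {
    for (ii in seq_len(nrow(near))) {
      i <- near[ii, 1]; j <- near[ii, 2]
      q <- sub[(j - 1) * 16 + 1:16, , drop = FALSE]
      dv <- sweep(-q, 2, C[i, ], "+")  # x_i - q
      rr <- sqrt(rowSums(dv^2))
      S[i, j] <- sum(A[j] / 16 / (4 * pi * rr))
      K[i, j] <- sum(A[j] / 16 * (-(dv %*% NM[i, ])) / (4 * pi * rr^3))
    }
  }
  # enforce the discrete solid-angle identity per closed surface:
  # sum_i A_i K_ij over the rows of body(j) must equal -A_j / 2 (the flat
  # self-panel term vanishes; the defect is absorbed into the diagonal)
  for (bix in unique(geo$body_index)) {
    rows <- which(geo$body_index == bix)
    colsum <- colSums(K[rows, rows, drop = FALSE] * A[rows])
    K[cbind(rows, rows)] <- (-A[rows] / 2 - colsum) / A[rows]
  }

  vert_all <- purrr::map(scene$bodies, ~ .x$mesh$vertices)
  tri_off <- 0L
  for (b in seq_along(scene$bodies)) {
    tr <- scene$bodies[[b]]$mesh$triangles
    v <- vert_all[[b]]
    for (t in seq_len(nrow(tr))) {
      i <- tri_off + t
      S[i, i] <- self_single_layer(v[tr[t, 1], ], v[tr[t, 2], ], v[tr[t, 3], ])
    }
    tri_off <- tri_off + nrow(tr)
  }

  # triangle vertex arrays (global panel order) for refined quadrature
  tri_verts <- purrr::map(1:3, function(cix) {
    do.call(rbind, purrr::map(scene$bodies,
      ~ .x$mesh$vertices[.x$mesh$triangles[, cix], , drop = FALSE]))
  })

  # primary fields at the collocation points; panels close to a pole get a
  # 64-point panel-averaged evaluation (the poles sit just under the skin)
  Psrc <- numeric(n); Dsrc <- numeric(n)
  if (!is.null(scene$sources) && nrow(scene$sources) > 0) {
    for (k in seq_len(nrow(scene$sources))) {
      src <- scene$sources[k, ]
      own <- geo$body == src$body_id
      sig <- geo$sigma_in[own][1]
      p <- c(src$x, src$y, src$z)
      dvx <- C[own, 1] - p[1]; dvy <- C[own, 2] - p[2]
      dvz <- C[own, 3] - p[3]
      rr <- sqrt(dvx^2 + dvy^2 + dvz^2)
      pk <- src$current_uA / (4 * pi * sig * rr)
      ddn <- dvx * NM[own, 1] + dvy * NM[own, 2] + dvz * NM[own, 3]
      dk <- -src$current_uA * ddn / (4 * pi * sig * rr^3)
      near_src <- which(rr < 4 * diam[own])
      own_idx <- which(own)
      for (jj in near_src) {
        j <- own_idx[jj]
        q <- sub_bary3 %*% rbind(tri_verts[[1]][j, ], tri_verts[[2]][j, ],
                                 tri_verts[[3]][j, ])
        dv <- sweep(q, 2, p)
        r3 <- sqrt(rowSums(dv^2))
        pk[jj] <- src$current_uA * mean(1 / r3) / (4 * pi * sig)
        dk[jj] <- -src$current_uA *
          mean((dv %*% NM[j, ]) / r3^3) / (4 * pi * sig)
      }
      Psrc[own] <- Psrc[own] + pk
      Dsrc[own] <- Dsrc[own] + dk
    }
  }
  Pbg <- numeric(n); Dbg <- numeric(n)
  if (!is.null(scene$background_E)) {
    E0 <- scene$background_E
    Pbg <- -(C %*% E0)[, 1]
    Dbg <- -(NM %*% E0)[, 1]
  }

  sig_b <- geo$sigma_in
  rho <- geo$rho
  K_own <- K * same_body
  S_own <- S * same_body
  Imh <- diag(n) / 2
  # continuity: sigma_b (I/2 + K_own) mu - sigma_w (-I/2 + K) nu = rhs1
  M11 <- sig_b * (Imh + K_own)
  M12 <- -sigma_w * (-Imh + K)
  rhs1 <- sigma_w * Dbg - sig_b * Dsrc
  # skin jump: (S_own - rho sigma_b (I/2 + K_own)) mu - S nu = rhs2
  M21 <- S_own - rho * sig_b * (Imh + K_own)
  M22 <- -S
  rhs2 <- Pbg - Psrc + rho * sig_b * Dsrc
  M <- rbind(cbind(M11, M12), cbind(M21, M22))
  x <- tryCatch(solve(M, c(rhs1, rhs2)),
                error = function(e) abort_pulseid(
                  paste("BEM system solve failed:", conditionMessage(e)),
                  "pulseid_solver_error"))
  mu <- x[seq_len(n)]; nu <- x[n + seq_len(n)]

  J <- sig_b * (Dsrc + (mu / 2 + as.numeric(K_own %*% mu)))
  phi_out <- Pbg + as.numeric(S %*% nu)

  values <- tibble::tibble(body = geo$body,
                           triangle = unlist(purrr::map(scene$bodies,
                             ~ seq_len(nrow(.x$mesh$triangles)))),
                           area = A, J_uA_cm2 = J, phi_out_uV = phi_out)

  # nodal exterior potential evaluated directly from the single layers
  # (continuous across the surface); nodal current density by area-weighted
  # interpolation from the incident triangles.
  tri_off <- c(0L, cumsum(purrr::map_int(scene$bodies,
                                         ~ nrow(.x$mesh$triangles))))
  node_values <- purrr::imap_dfr(scene$bodies, function(b, bi) {
    verts <- b$mesh$vertices
    tr <- b$mesh$triangles
    m <- nrow(verts)
    ndx <- outer(verts[, 1], C[, 1], "-")
    ndy <- outer(verts[, 2], C[, 2], "-")
    ndz <- outer(verts[, 3], C[, 3], "-")
    nr <- sqrt(ndx^2 + ndy^2 + ndz^2)
    nr[nr == 0] <- 1e-12
    Sn <- sweep(1 / (4 * pi * nr), 2, A, "*")
    near_n <- which(nr < near_factor * matrix(diam, m, n, byrow = TRUE),
                    arr.ind = TRUE)
    if (nrow(near_n) > 0) {
      for (ii in seq_len(nrow(near_n))) {
        vtx <- near_n[ii, 1]; j <- near_n[ii, 2]
        jl <- j - tri_off[bi]  # local triangle index if on this body
        if (jl >= 1 && jl <= nrow(tr) && vtx %in% tr[jl, ]) {
          oth <- setdiff(tr[jl, ], vtx)
          if (length(oth) == 2) {
            Sn[vtx, j] <- vertex_single_layer(verts[vtx, ],
                                              verts[oth[1], ],
                                              verts[oth[2], ])
            next
          }
        }
        q <- sub[(j - 1) * 16 + 1:16, , drop = FALSE]
        rr <- sqrt(rowSums(sweep(-q, 2, verts[vtx, ], "+")^2))
        Sn[vtx, j] <- sum(A[j] / 16 / (4 * pi * rr))
      }
    }
    phi_n <- as.numeric(Sn %*% nu)
    if (!is.null(scene$background_E)) {
      phi_n <- phi_n - as.numeric(verts %*% scene$background_E)
    }
    sel <- values[values$body == b$id, ]
    nv <- numeric(m); wt <- numeric(m)
    for (cix in 1:3) {
      add <- tapply(sel$J_uA_cm2 * sel$area, tr[, cix], sum)
      aw <- tapply(sel$area, tr[, cix], sum)
      ids <- as.integer(names(add))
      nv[ids] <- nv[ids] + add
      wt[ids] <- wt[ids] + aw
    }
    tibble::tibble(body = b$id, node = seq_len(m),
                   J_uA_cm2 = nv / wt, phi_out_uV = phi_n,
                   x = verts[, 1], y = verts[, 2], z = verts[, 3])
  })
  conservation <- values |>
    dplyr::group_by(.data$body) |>
    dplyr::summarise(net_current_uA = sum(.data$J_uA_cm2 * .data$area),
                     .groups = "drop")
  structure(list(values = values, node_values = node_values,
                 conservation = conservation, scene = scene),
            class = "boundary_solution")
}

#' @export
print.boundary_solution <- function(x, ...) {
  cat(sprintf("<boundary_solution> %d triangles over %d body(ies)\n",
              nrow(x$values), length(x$scene$bodies)))
  print(x$conservation)
  invisible(x)
}

new_electric_image <- function(node_values, modality, emitter, perceiver) {
  structure(
    list(node_values = node_values, modality = modality,
         emitter_id = emitter, perceiver_id = perceiver,
         summary = list(max = max(abs(node_values$value)),
                        rms = sqrt(mean(node_values$value^2)))),
    class = "electric_image"
  )
}

#' @export
print.electric_image <- function(x, ...) {
  cat(sprintf("<electric_image> %s, emitter %s -> perceiver %s: max %.4g, rms %.4g uA/cm2\n",
              x$modality, x$emitter_id, x$perceiver_id,
              x$summary$max, x$summary$rms))
  invisible(x)
}

#' @method tidy electric_image
#' @export
tidy.electric_image <- function(x, ...) x$node_values

#' @method glance electric_image
#' @export
glance.electric_image <- function(x, ...) {
  tibble::tibble(modality = x$modality, emitter = x$emitter_id,
                 perceiver = x$perceiver_id, max_uA_cm2 = x$summary$max,
                 rms_uA_cm2 = x$summary$rms)
}

#' @method autoplot electric_image
#' @export
autoplot.electric_image <- function(object, ...) {
  ggplot2::ggplot(object$node_values,
                  ggplot2::aes(.data$x, .data$z, colour = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = "uA/cm2") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s electric image (%s)", object$modality,
                                  object$emitter_id),
                  x = "x (cm)", y = "z (cm)")
}

scene_subset <- function(scene, keep_ids, discharging = scene$discharging) {
  conductivity_scene(
    bodies = purrr::keep(scene$bodies, ~ .x$id %in% keep_ids),
    water_uS_cm = scene$water_uS_cm,
    sources = if (!is.null(scene$sources))
      scene$sources[scene$sources$body_id %in% keep_ids, ],
    discharging = if (discharging %in% keep_ids) discharging else
      NA_character_,
    background_E = scene$background_E
  )
}

#' Basal, active and passive electric images
#'
#' `basal_image()` is the self-generated image of the discharging fish
#' alone in the water (per-node transcutaneous current density).
#' `active_image()` is the nodewise difference between the full-scene image
#' at the discharging fish's skin and the basal image: the modulation caused
#' by the second fish. `passive_image()` is the full-scene stimulus at the
#' skin of the non-discharging fish.
#'
#' @param scene A two-fish (or one-fish, for basal) [conductivity_scene()]
#'   with `discharging` set.
#' @param solution Optional precomputed [assemble_and_solve()] result for
#'   the full scene.
#' @return An `electric_image` (per-node values in uA/cm^2, plus max/rms
#'   summary).
#' @export
basal_image <- function(scene) {
  em <- scene$discharging
  if (is.na(em)) abort_pulseid("no discharging body", "pulseid_modality_error")
  sol <- assemble_and_solve(scene_subset(scene, em))
  nv <- sol$node_values[sol$node_values$body == em, ]
  nv$value <- nv$J_uA_cm2
  new_electric_image(nv[, c("node", "x", "y", "z", "value")],
                     "active-basal", em, em)
}

#' @rdname basal_image
#' @export
active_image <- function(scene, solution = NULL) {
  em <- scene$discharging
  if (is.na(em)) abort_pulseid("no discharging body", "pulseid_modality_error")
  if (length(scene$bodies) < 2) {
    abort_pulseid("active image needs the full two-fish scene",
                  "pulseid_scene_error")
  }
  solution <- solution %||% assemble_and_solve(scene)
  bas <- basal_image(scene)
  nv <- solution$node_values[solution$node_values$body == em, ]
  if (nrow(nv) != nrow(bas$node_values)) {
    abort_pulseid("scene and basal meshes do not match",
                  "pulseid_consistency_error")
  }
  nv$value <- nv$J_uA_cm2 - bas$node_values$value
  other <- setdiff(purrr::map_chr(scene$bodies, "id"), em)
  new_electric_image(nv[, c("node", "x", "y", "z", "value")],
                     "active", em, em)
}

#' @rdname basal_image
#' @param receiver Id of the non-discharging fish.
#' @export
passive_image <- function(scene, receiver, solution = NULL) {
  em <- scene$discharging
  if (is.na(em)) abort_pulseid("no discharging body", "pulseid_modality_error")
  if (receiver == em) {
    abort_pulseid("receiver must not be the discharging fish",
                  "pulseid_modality_error")
  }
  solution <- solution %||% assemble_and_solve(scene)
  nv <- solution$node_values[solution$node_values$body == receiver, ]
  nv$value <- nv$J_uA_cm2
  new_electric_image(nv[, c("node", "x", "y", "z", "value")],
                     "passive", em, receiver)
}

#' Tangential surface field from a boundary solution
#'
#' The exterior surface potential is linearly interpolated over each
#' triangle; its in-plane gradient gives the tangential electric field just
#' outside the skin (uV/cm).
#'
#' @param solution A [assemble_and_solve()] result.
#' @param body_id Body whose surface field to compute.
#' @return Tibble: `triangle`, centroid `cx/cy/cz`, field components
#'   `Ex/Ey/Ez` and `magnitude`.
#' @export
surface_field <- function(solution, body_id) {
  bi <- which(purrr::map_chr(solution$scene$bodies, "id") == body_id)
  mesh <- solution$scene$bodies[[bi]]$mesh
  nv <- solution$node_values[solution$node_values$body == body_id, ]
  phi <- nv$phi_out_uV
  tr <- mesh$triangles; v <- mesh$vertices
  td <- mesh_triangle_data(mesh)
  out <- matrix(0, nrow(tr), 3)
  for (t in seq_len(nrow(tr))) {
    v1 <- v[tr[t, 1], ]; v2 <- v[tr[t, 2], ]; v3 <- v[tr[t, 3], ]
    p <- phi[tr[t, ]]
    A3 <- rbind(v2 - v1, v3 - v1, c(td$nx[t], td$ny[t], td$nz[t]))
    g <- solve(A3, c(p[2] - p[1], p[3] - p[1], 0))
    out[t, ] <- -g
  }
  tibble::tibble(triangle = seq_len(nrow(tr)), cx = td$cx, cy = td$cy,
                 cz = td$cz, Ex = out[, 1], Ey = out[, 2], Ez = out[, 3],
                 magnitude = sqrt(rowSums(out^2)))
}

#' First-detection criterion
#'
#' Given the time series of electric-image amplitudes received by each
#' fish, finds the earliest moment where one fish's amplitude exceeds the
#' other's by `factor` (default 2) while also exceeding the model's internal
#' noise floor (default 0.1 uA). The two series are merged on the union of
#' their EOD times; the other fish's value at an instant is its most recent
#' amplitude.
#'
#' @param series_a,series_b Tibbles with `time_s` and `amp` (uA or
#'   uA/cm^2), time-ordered, for fish A and B.
#' @param factor Detection ratio (default 2).
#' @param floor Amplitude floor (default 0.1).
#' @param ids Ids reported for the two fish.
#'
#' @return One-row tibble `fish_id`, `time_s`, or a 0-row tibble if the
#'   criterion is never met.
#' @export
first_detection <- function(series_a, series_b, factor = 2, floor = 0.1,
                            ids = c("A", "B")) {
  if (nrow(series_a) == 0 || nrow(series_b) == 0) {
    abort_pulseid("empty amplitude series", "pulseid_data_error")
  }
  tt <- sort(union(series_a$time_s, series_b$time_s))
  locf <- function(s) {
    idx <- findInterval(tt, s$time_s)
    ifelse(idx == 0, NA_real_, s$amp[pmax(idx, 1)])
  }
  a <- locf(series_a); b <- locf(series_b)
  a_wins <- !is.na(a) & !is.na(b) & a > factor * b & a > floor
  b_wins <- !is.na(a) & !is.na(b) & b > factor * a & b > floor
  hit <- which(a_wins | b_wins)
  if (length(hit) == 0) {
    return(tibble::tibble(fish_id = character(), time_s = numeric()))
  }
  h <- hit[1]
  tibble::tibble(fish_id = ids[if (a_wins[h]) 1 else 2], time_s = tt[h])
}
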