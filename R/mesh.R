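#' Reconstruction configuration
#'
#' @param d_max Maximum association distance between vertices of successive
#'   slice contours, in micrometres (default 1.0, about three pixels at the
#'   0.16 um lateral resolution used here, relative to the 0.3 um axial
#'   step).
#' @param taubin_lambda,taubin_mu,taubin_iters Taubin smoothing parameters;
#'   stability requires `mu < -lambda < 0`.
#' @param remesh_target_vertices Target vertex count for the uniform
#'   remeshing step, or `NULL` to skip remeshing.
#' @param axial_spacing Distance between slices in micrometres.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param lumen_direction Side of the image on which the (aortic) lumen
#'   lies, used to label the two arcs of each membrane contour: one of
#'   `"up"`, `"down"`, `"left"`, `"right"` (image coordinates; `"up"` means
#'   decreasing row). Set to `NULL` to require explicit configuration.
#' @param max_slice_gap Largest number of slice steps that may separate two
#'   segmented slices and still be tiled across (default 2: one missing
#'   slice). Larger gaps split the surface.
#' @return A `recon_config` list.
#' @export
recon_config <- function(d_max = 1.0,
                         taubin_lambda = 0.5, taubin_mu = -0.53,
                         taubin_iters = 10L,
                         remesh_target_vertices = NULL,
                         axial_spacing = 0.3, pixel_size = 0.16,
                         lumen_direction = "up",
                         max_slice_gap = 2L) {
  if (d_max <= 0) stop("'d_max' must be positive")
  if (!(taubin_mu < -taubin_lambda && taubin_lambda > 0))
    stop("Taubin stability requires mu < -lambda < 0")
  if (axial_spacing <= 0 || pixel_size <= 0) stop("spacings must be positive")
  structure(list(d_max = d_max, taubin_lambda = taubin_lambda,
                 taubin_mu = taubin_mu, taubin_iters = as.integer(taubin_iters),
                 remesh_target_vertices = remesh_target_vertices,
                 axial_spacing = axial_spacing, pixel_size = pixel_size,
                 lumen_direction = lumen_direction,
                 max_slice_gap = as.integer(max_slice_gap)),
            class = "recon_config")
}

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix (x, y, z) in micrometres.
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @param role Optional integer vector per vertex: 1 = luminal, 2 = basal,
#'   3 = cavity, 0 = unassigned.
#' @return A `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, role = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (nrow(triangles) &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("degenerate triangle (repeated vertex index)")
  if (is.null(role)) role <- integer(nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 role = as.integer(role)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles, %d component(s)\n",
              nrow(x$vertices), nrow(x$triangles), mesh_component_count(x)))
  invisible(x)
}

# Lift a 2D contour to a z = const polygon in physical micrometre
# coordinates: (x, y, z) = (col * pixel_size, row * pixel_size,
# (slice - 1) * axial_spacing).
lift_contour <- function(contour, slice_index, pixel_size, axial_spacing,
                         role = "membrane", cavity_id = NA_integer_) {
  v <- contour$vertices
  structure(list(vertices = cbind(x = v[, 2] * pixel_size,
                                  y = v[, 1] * pixel_size,
                                  z = (slice_index - 1) * axial_spacing),
                 closed = TRUE, role = role, cavity_id = cavity_id),
            class = "contour3d")
}

# signed area in the (x, y) plane; used to normalize orientation so the
# successor direction is consistent between slices
contour_signed_area <- function(v) {
  n <- nrow(v); nxt <- c(2:n, 1L)
  sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2]) / 2
}

orient_ccw <- function(c3) {
  if (contour_signed_area(c3$vertices) < 0)
    c3$vertices <- c3$vertices[rev(seq_len(nrow(c3$vertices))), , drop = FALSE]
  c3
}

#' Split a membrane contour into luminal and basal arcs
#'
#' Partitions a closed contour into two open arcs at its two extremal
#' vertices along the axis perpendicular to the configured lumen direction
#' (for a lumen lying above the cell, the split points are the extreme
#' columns). The arc facing the lumen is labelled luminal, the other basal.
#' Cavity contours are never split: each cavity is attached whole to the
#' luminal side by the caller.
#'
#' @param contour A `contour3d` (closed).
#' @param lumen_direction `"up"`, `"down"`, `"left"` or `"right"`; an error
#'   asks the user to set it when `NULL`.
#' @return List with `luminal` and `basal` open polylines (vertex
#'   matrices), each including both split vertices.
#' @export
split_basal_luminal <- function(contour, lumen_direction) {
  if (is.null(lumen_direction))
    stop("the lumen side is not configured: set 'lumen_direction' ",
         "(\"up\", \"down\", \"left\" or \"right\") in recon_config()")
  if (identical(contour$role, "cavity"))   # holes belong to the luminal side
    return(list(luminal = contour$vertices,
                basal = contour$vertices[0, , drop = FALSE]))
  v <- contour$vertices
  # y = row * pixel_size grows downward in image coordinates
  lum_axis <- switch(lumen_direction,
                     up = c(0, -1), down = c(0, 1),
                     left = c(-1, 0), right = c(1, 0),
                     stop("unknown lumen_direction"))
  perp <- v[, 1] * lum_axis[2] - v[, 2] * lum_axis[1]
  i1 <- which.min(perp); i2 <- which.max(perp)
  lo <- min(i1, i2); hi <- max(i1, i2)
  arc_a <- v[lo:hi, , drop = FALSE]
  arc_b <- v[c(hi:nrow(v), 1:lo), , drop = FALSE]
  proj_a <- mean(arc_a[, 1] * lum_axis[1] + arc_a[, 2] * lum_axis[2])
  proj_b <- mean(arc_b[, 1] * lum_axis[1] + arc_b[, 2] * lum_axis[2])
  if (proj_a >= proj_b) list(luminal = arc_a, basal = arc_b)
  else list(luminal = arc_b, basal = arc_a)
}

#' Tile two contours on adjacent slices
#'
#' Solves the double association problem between two polylines on
#' neighbouring slices: each vertex is associated with its successor on its
#' own contour and with the nearest vertex on the other contour, and the
#' triple forms a triangle when that nearest partner lies within `d_max`
#' (the admissible partner lives in a ball of that radius). A symmetric
#' pass from the second contour fills the complementary triangles. Vertices
#' with no admissible partner generate no triangle, leaving open rims —
#' which is what prevents a hole on one slice from being welded to the
#' plain membrane curve on the next. ([reconstruct_mesh()] additionally
#' drops triangles whose successor diagonal crosses slices at more than
#' `d_max`, so the assembled surface honours the distance contract on every
#' edge.)
#'
#' @param A,B Vertex matrices (n x 3) or `contour3d` objects.
#' @param d_max Maximum admissible edge length across slices (um).
#' @param closed_a,closed_b Whether each polyline wraps around (overridden
#'   by the `closed` field of `contour3d` inputs).
#' @return m x 3 integer matrix of triangles indexing `rbind(A, B)`;
#'   possibly zero rows.
#' @export
tile_adjacent_contours <- function(A, B, d_max, closed_a = TRUE, closed_b = TRUE) {
  if (inherits(A, "contour3d")) { closed_a <- A$closed; A <- A$vertices }
  if (inherits(B, "contour3d")) { closed_b <- B$closed; B <- B$vertices }
  nA <- nrow(A); nB <- nrow(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  lim <- d_max^2
  nnB <- apply(d2, 1, which.min); nnB_d <- d2[cbind(seq_len(nA), nnB)]
  nnA <- apply(d2, 2, which.min); nnA_d <- d2[cbind(nnA, seq_len(nB))]
  succ_a <- if (closed_a) c(seq_len(nA)[-1], 1L) else c(seq_len(nA)[-1], NA)
  succ_b <- if (closed_b) c(seq_len(nB)[-1], 1L) else c(seq_len(nB)[-1], NA)
  ia <- which(!is.na(succ_a))
  ok <- nnB_d[ia] <= lim
  t1 <- cbind(ia, succ_a[ia], nA + nnB[ia])[ok, , drop = FALSE]
  # the complementary pass anchors at the successor's nearest partner, so
  # that aligned contours produce a properly split (closed) quad strip
  ib <- which(!is.na(succ_b))
  ok <- nnA_d[succ_b[ib]] <= lim
  t2 <- cbind(nA + ib, nA + succ_b[ib], nnA[succ_b[ib]])[ok, , drop = FALSE]
  tri <- rbind(t1, t2)
  storage.mode(tri) <- "integer"
  dimnames(tri) <- NULL
  tri
}

#' Reconstruct a triangulated surface from slice segmentations
#'
#' Lifts every membrane and cavity contour to physical coordinates, splits
#' each membrane profile into luminal and basal arcs, and tiles each role
#' independently across consecutive segmented slices under the `d_max`
#' association rule. Cavity contours are tiled only against cavity contours
#' of the neighbouring slice whose projected interiors overlap by at least
#' one pixel; unmatched cavities terminate with an open rim. Slices
#' separated by more than `max_slice_gap` steps are not tiled together, so
#' the surface splits there. Duplicate vertices (the shared arc endpoints)
#' are merged.
#'
#' @param segmentations List of `slice_segmentation` objects (at least 2).
#' @param config A [recon_config()].
#' @return A [triangle_mesh()] with per-vertex roles.
#' @export
reconstruct_mesh <- function(segmentations, config = recon_config()) {
  if (length(segmentations) < 2L)
    stop("surface reconstruction needs at least 2 segmented slices")
  ps <- config$pixel_size; az <- config$axial_spacing
  verts <- NULL; roles <- integer(0); tris <- NULL
  add_vertices <- function(v, role_id) {
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <<- rbind(verts, v)
    roles <<- c(roles, rep(role_id, nrow(v)))
    off
  }
  pieces <- lapply(segmentations, function(seg) {
    g <- orient_ccw(lift_contour(seg$membrane, seg$slice_index, ps, az))
    arcs <- split_basal_luminal(g, config$lumen_direction)
    cavs <- lapply(seg$cavities, function(cv)
      orient_ccw(lift_contour(cv, seg$slice_index, ps, az, role = "cavity")))
    list(slice = seg$slice_index,
         luminal = arcs$luminal, basal = arcs$basal,
         cavities = cavs,
         cavity_interiors = lapply(seg$cavities, `[[`, "interior"))
  })
  offs <- lapply(pieces, function(p) {
    list(luminal = add_vertices(p$luminal, 1L),
         basal = add_vertices(p$basal, 2L),
         cavities = lapply(p$cavities, function(cv) add_vertices(cv$vertices, 3L)))
  })
  add_tris <- function(tri, offA, offB) {
    if (!nrow(tri)) return(invisible())
    nA <- attr(tri, "nA")
    local <- tri
    local[tri <= nA] <- tri[tri <= nA] + offA
    local[tri > nA] <- tri[tri > nA] - nA + offB
    tris <<- rbind(tris, local)
  }
  for (k in seq_len(length(pieces) - 1L)) {
    a <- pieces[[k]]; b <- pieces[[k + 1L]]
    if (b$slice - a$slice > config$max_slice_gap) next
    for (role in c("luminal", "basal")) {
      tri <- tile_adjacent_contours(a[[role]], b[[role]], config$d_max,
                                    closed_a = FALSE, closed_b = FALSE)
      attr(tri, "nA") <- nrow(a[[role]])
      add_tris(tri, offs[[k]][[role]], offs[[k + 1L]][[role]])
    }
    if (length(a$cavities) && length(b$cavities)) {
      used_b <- logical(length(b$cavities))
      for (i in seq_along(a$cavities)) {
        ov <- vapply(seq_along(b$cavities), function(j)
          if (used_b[j]) 0L else sum(a$cavity_interiors[[i]] &
                                     b$cavity_interiors[[j]]), integer(1))
        if (!any(ov >= 1L)) next
        j <- which.max(ov)
        used_b[j] <- TRUE
        tri <- tile_adjacent_contours(a$cavities[[i]], b$cavities[[j]],
                                      config$d_max)
        attr(tri, "nA") <- nrow(a$cavities[[i]]$vertices)
        add_tris(tri, offs[[k]]$cavities[[i]], offs[[k + 1L]]$cavities[[j]])
      }
    }
  }
  if (is.null(tris)) tris <- matrix(integer(0), 0, 3)
  # enforce the d_max contract on every cross-slice edge of every triangle
  # (the association rule only bounds the nearest-partner edge; the successor
  # diagonal can slightly exceed it and is dropped here)
  if (nrow(tris)) {
    ok <- rep(TRUE, nrow(tris))
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tris[, pair[1]]; b <- tris[, pair[2]]
      cross <- verts[a, 3] != verts[b, 3]
      len2 <- rowSums((verts[a, , drop = FALSE] - verts[b, , drop = FALSE])^2)
      ok <- ok & (!cross | len2 <= config$d_max^2 + 1e-12)
    }
    tris <- tris[ok, , drop = FALSE]
  }
  merge_mesh_vertices(verts, tris, roles)
}

# merge exactly-coincident vertices of the same role (so the luminal and
# basal sheets remain distinct components at their shared split points)
# and drop degenerate or duplicate triangles
merge_mesh_vertices <- function(verts, tris, roles, digits = 9L) {
  key <- paste(roles, apply(round(verts, digits), 1, paste, collapse = "/"))
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_verts <- verts[first, , drop = FALSE]
  new_roles <- roles[first]
  if (nrow(tris)) {
    tris <- matrix(map[tris], ncol = 3)
    good <- tris[, 1] != tris[, 2] & tris[, 1] != tris[, 3] &
      tris[, 2] != tris[, 3]
    tris <- tris[good, , drop = FALSE]
    tris <- tris[!duplicated(t(apply(tris, 1, sort))), , drop = FALSE]
  }
  triangle_mesh(new_verts, tris, new_roles)
}
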