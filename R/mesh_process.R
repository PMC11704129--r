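mesh_edges <- function(mesh) {
  t <- mesh$triangles
  if (!nrow(t)) return(matrix(integer(0), 0, 2))
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Taubin mesh smoothing
#'
#' Alternates a shrinking uniform-weight Laplacian step of factor `lambda`
#' with an inflating step of factor `mu` for `iters` rounds. With the
#' classical stable pair (0.5, -0.53) this removes curvature artifacts
#' introduced by slightly different segmentations on successive slices
#' while approximately preserving the enclosed volume. Connectivity is
#' unchanged; isolated vertices stay in place.
#'
#' @param mesh A [triangle_mesh()].
#' @param lambda Positive shrink factor.
#' @param mu Negative inflate factor, `mu < -lambda`.
#' @param iters Number of lambda/mu rounds; 0 returns the mesh unchanged.
#' @return The smoothed [triangle_mesh()].
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iters = 10L) {
  if (!(mu < -lambda && lambda > 0))
    stop("Taubin stability requires mu < -lambda < 0")
  if (iters == 0L) return(mesh)
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  src <- c(e[, 1], e[, 2]); dst <- c(e[, 2], e[, 1])
  deg <- tabulate(src, n)
  free <- deg > 0
  V <- mesh$vertices
  lap_step <- function(V, f) {
    nb <- rowsum(V[dst, , drop = FALSE], src, reorder = TRUE)
    idx <- as.integer(rownames(nb))
    L <- V
    L[idx, ] <- nb / deg[idx]
    V[free, ] <- V[free, ] + f * (L[free, , drop = FALSE] - V[free, , drop = FALSE])
    V
  }
  for (k in seq_len(iters)) {
    V <- lap_step(V, lambda)
    V <- lap_step(V, mu)
  }
  mesh$vertices <- V
  mesh
}

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem volume (sum of signed tetrahedra against the
#' origin). Meaningful for closed, consistently oriented surfaces; use
#' `abs()` if the orientation convention is unknown.
#'
#' @param mesh A [triangle_mesh()].
#' @return Scalar volume in cubic micrometres (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  if (!nrow(t)) return(0)
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  cc <- v[t[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Triangle areas of a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @return Numeric vector of areas (square micrometres).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  if (!nrow(t)) return(numeric(0))
  u <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  w <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# connected components over vertices that appear in at least one triangle;
# returns a component id per vertex (NA for unused vertices)
mesh_vertex_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- mesh_edges(mesh)
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a != b) parent[b] <- a
  }
  used <- sort(unique(as.integer(mesh$triangles)))
  comp <- rep(NA_integer_, n)
  if (length(used)) {
    roots <- vapply(used, find, integer(1))
    comp[used] <- match(roots, unique(roots))
  }
  comp
}

#' Number of connected components of a mesh
#'
#' Counts components over the vertices used by at least one triangle.
#'
#' @param mesh A [triangle_mesh()].
#' @return Integer count.
#' @export
mesh_component_count <- function(mesh) {
  comp <- mesh_vertex_components(mesh)
  length(unique(comp[!is.na(comp)]))
}

#' Audit the reconstruction contracts of a mesh
#'
#' Checks that no edge joining vertices of different z exceeds `d_max` and
#' that no triangle edge connects a cavity-role vertex to a membrane-role
#' vertex (no welding between cavity surfaces and the membrane sheets).
#'
#' @param mesh A [triangle_mesh()] from [reconstruct_mesh()].
#' @param d_max The association bound used at reconstruction, in um.
#' @param tol Numerical slack on the edge-length comparison.
#' @return List with `max_interslice_edge`, `d_max_ok`, `welding_ok`,
#'   `components`.
#' @export
audit_mesh <- function(mesh, d_max, tol = 1e-9) {
  e <- mesh_edges(mesh)
  v <- mesh$vertices
  res <- list(max_interslice_edge = 0, d_max_ok = TRUE, welding_ok = TRUE,
              components = mesh_component_count(mesh))
  if (!nrow(e)) return(res)
  dz <- v[e[, 1], 3] != v[e[, 2], 3]
  if (any(dz)) {
    len <- sqrt(rowSums((v[e[dz, 1], , drop = FALSE] -
                         v[e[dz, 2], , drop = FALSE])^2))
    res$max_interslice_edge <- max(len)
    res$d_max_ok <- all(len <= d_max + tol)
  }
  r <- mesh$role
  cav <- r[e[, 1]] == 3L | r[e[, 2]] == 3L
  mem <- r[e[, 1]] %in% c(1L, 2L) | r[e[, 2]] %in% c(1L, 2L)
  res$welding_ok <- !any(cav & mem)
  res
}

#' Midpoint subdivision of a mesh
#'
#' Splits the selected triangles into four through their edge midpoints
#' (midpoints are shared wherever both incident triangles split, so a full
#' subdivision is conforming; a partial one leaves harmless T-vertices on
#' the selection boundary). The geometry is unchanged. Midpoint roles are
#' inherited from an endpoint.
#'
#' @param mesh A [triangle_mesh()].
#' @param only Indices of the triangles to split (default: all).
#' @return The refined [triangle_mesh()].
#' @export
subdivide_mesh <- function(mesh, only = seq_len(nrow(mesh$triangles))) {
  v <- mesh$vertices
  t <- mesh$triangles[only, , drop = FALSE]
  keep <- mesh$triangles[-only, , drop = FALSE]
  if (!nrow(t)) return(mesh)
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(ekey)
  eidx <- match(ekey, uk)
  ue <- e[!duplicated(ekey), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mid_id <- nrow(v) + seq_len(nrow(ue))
  m_ab <- mid_id[eidx[seq_len(nrow(t))]]
  m_bc <- mid_id[eidx[nrow(t) + seq_len(nrow(t))]]
  m_ca <- mid_id[eidx[2L * nrow(t) + seq_len(nrow(t))]]
  nt <- rbind(keep,
              cbind(t[, 1], m_ab, m_ca),
              cbind(t[, 2], m_bc, m_ab),
              cbind(t[, 3], m_ca, m_bc),
              cbind(m_ab, m_bc, m_ca))
  triangle_mesh(rbind(v, mids), nt, c(mesh$role, mesh$role[ue[, 1]]))
}

#' Uniform remeshing by vertex clustering
#'
#' Area-weighted centroidal clustering in the style of approximated
#' centroidal Voronoi diagrams. The mesh is first refined by conforming
#' midpoint subdivision until no triangle exceeds twice the target cluster
#' area (clustering cannot exceed the input vertex density, so coarse
#' regions are pre-refined exactly as clustering-based remeshers
#' prescribe). Cluster seeds are then spread with deterministic
#' farthest-point sampling, refined by weighted Lloyd iterations where each
#' vertex carries one third of its incident triangle area, and each cluster
#' collapses to its weighted centroid. Triangles are re-indexed through the
#' clusters; degenerate and duplicate triangles are dropped. Clustering is
#' performed independently per connected component (with seats allocated
#' proportionally to component area), so the component count is preserved.
#'
#' @param mesh A [triangle_mesh()].
#' @param target_vertices Desired output vertex count (at least 4). If it
#'   exceeds what the input resolution allows, a warning is issued and the
#'   input vertices are kept.
#' @param lloyd_iters Number of Lloyd refinement passes.
#' @return The remeshed [triangle_mesh()] (roles are taken from the
#'   dominant role of each cluster).
#' @export
remesh_uniform <- function(mesh, target_vertices, lloyd_iters = 10L) {
  if (target_vertices < 4) stop("'target_vertices' must be at least 4")
  if (target_vertices > nrow(mesh$vertices)) {
    warning("target exceeds the input vertex count; keeping input resolution")
    return(mesh)
  }
  target_area <- sum(triangle_areas(mesh)) / target_vertices
  longest_edge <- function(m) {
    v <- m$vertices; t <- m$triangles
    pmax(sqrt(rowSums((v[t[, 1], , drop = FALSE] - v[t[, 2], , drop = FALSE])^2)),
         sqrt(rowSums((v[t[, 2], , drop = FALSE] - v[t[, 3], , drop = FALSE])^2)),
         sqrt(rowSums((v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE])^2)))
  }
  lim <- 1.5 * sqrt(target_area)
  for (round in 1:8) {   # refine coarse regions to resolve the cluster spacing
    big <- which(longest_edge(mesh) > lim)
    if (!length(big)) break
    mesh <- subdivide_mesh(mesh, only = big)
  }
  n <- nrow(mesh$vertices)
  comp <- mesh_vertex_components(mesh)
  used <- which(!is.na(comp))
  areas <- triangle_areas(mesh)
  w <- numeric(n)
  for (c_ in 1:3) {
    s <- rowsum(areas / 3, mesh$triangles[, c_], reorder = TRUE)
    idx <- as.integer(rownames(s))
    w[idx] <- w[idx] + s
  }
  w[w <= 0] <- min(w[w > 0], na.rm = TRUE) * 1e-3

  comps <- sort(unique(comp[used]))
  comp_area <- vapply(comps, function(cc) sum(w[which(comp == cc)]), numeric(1))
  seats <- pmax(1L, round(target_vertices * comp_area / sum(comp_area)))
  # adjust rounding drift toward the requested total
  while (sum(seats) > target_vertices && any(seats > 1L)) {
    k <- which.max(seats); seats[k] <- seats[k] - 1L
  }
  while (sum(seats) < target_vertices) {
    k <- which.max(comp_area / seats); seats[k] <- seats[k] + 1L
  }

  cluster_of <- rep(NA_integer_, n)
  centers_all <- NULL
  n_done <- 0L
  for (ci in seq_along(comps)) {
    vs <- which(comp == comps[ci])
    k <- min(seats[ci], length(vs))
    P <- mesh$vertices[vs, , drop = FALSE]
    wi <- w[vs]
    # farthest-point seeding, starting from the heaviest vertex
    seed <- integer(k)
    seed[1] <- which.max(wi)
    mind <- rowSums((P - matrix(P[seed[1], ], nrow(P), 3, byrow = TRUE))^2)
    if (k > 1) for (s_ in 2:k) {
      seed[s_] <- which.max(mind)
      d <- rowSums((P - matrix(P[seed[s_], ], nrow(P), 3, byrow = TRUE))^2)
      mind <- pmin(mind, d)
    }
    C <- P[seed, , drop = FALSE]
    for (it in seq_len(lloyd_iters)) {
      d2 <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
      asg <- max.col(-d2, ties.method = "first")
      for (j in which(tabulate(asg, k) == 0L)) {   # reseed empty clusters
        far <- which.max(d2[cbind(seq_len(nrow(P)), asg)])
        asg[far] <- j
      }
      C <- rowsum(P * wi, asg, reorder = TRUE) / rowsum(wi, asg, reorder = TRUE)[, 1]
      if (nrow(C) < k) k <- nrow(C)
    }
    d2 <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
    asg <- max.col(-d2, ties.method = "first")
    cluster_of[vs] <- n_done + asg
    centers_all <- rbind(centers_all, C)
    n_done <- n_done + nrow(C)
  }

  tri <- matrix(cluster_of[mesh$triangles], ncol = 3)
  good <- !is.na(tri[, 1]) & tri[, 1] != tri[, 2] & tri[, 1] != tri[, 3] &
    tri[, 2] != tri[, 3]
  tri <- tri[good, , drop = FALSE]
  tri <- tri[!duplicated(t(apply(tri, 1, sort))), , drop = FALSE]
  role <- vapply(seq_len(n_done), function(j) {
    rr <- mesh$role[which(cluster_of == j)]
    if (!length(rr)) 0L else as.integer(names(sort(table(rr), decreasing = TRUE))[1])
  }, integer(1))
  triangle_mesh(centers_all, tri, role)
}

#' Synthetic icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; a closed, consistently
#' oriented synthetic mesh used to exercise smoothing and remeshing.
#'
#' @param subdiv Number of 4-to-1 subdivisions (0 = icosahedron).
#' @param radius Sphere radius.
#' @return A [triangle_mesh()].
#' @export
icosphere_mesh <- function(subdiv = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  t <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    nv <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      nv <<- rbind(nv, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(nv)
      nrow(nv)
    }
    nt <- NULL
    for (r in seq_len(nrow(t))) {
      a <- t[r, 1]; b <- t[r, 2]; cc <- t[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nt <- rbind(nt, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- nv; t <- nt
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, t)
}

#' Synthetic open tube mesh with configurable ring spacing
#'
#' Stacks circular rings along z and tiles consecutive rings; graded
#' `z_values` produce a non-uniform triangulation for remeshing tests.
#'
#' @param radius Tube radius.
#' @param n_seg Vertices per ring.
#' @param z_values Ring positions along z.
#' @return A [triangle_mesh()].
#' @export
tube_mesh <- function(radius = 1, n_seg = 48L, z_values = seq(0, 3, by = 0.3)) {
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ring <- cbind(radius * cos(th), radius * sin(th))
  verts <- NULL; tris <- NULL
  for (i in seq_along(z_values)) {
    verts <- rbind(verts, cbind(ring, z_values[i]))
    if (i > 1) {
      a <- (i - 2L) * n_seg + seq_len(n_seg)
      b <- (i - 1L) * n_seg + seq_len(n_seg)
      an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
      tris <- rbind(tris, cbind(a, an, b), cbind(an, bn, b))
    }
  }
  triangle_mesh(verts, tris)
}

#' Write a mesh as ASCII PLY
#'
#' Vertices carry their role as an integer property (`role`: 1 luminal,
#' 2 basal, 3 cavity, 0 unassigned).
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           "property int role",
           sprintf("element face %d", nrow(mesh$triangles)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  writeLines(sprintf("%.8g %.8g %.8g %d",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], mesh$role), con, sep = "\n")
  if (nrow(mesh$triangles))
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L),
               con, sep = "\n")
  invisible(path)
}

#' Write a mesh as ASCII OBJ
#'
#' @inheritParams write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con, sep = "\n")
  if (nrow(mesh$triangles))
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con, sep = "\n")
  invisible(path)
}
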