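test_that("two identical squares tile into a closed quadrilateral tube", {
  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
  A <- cbind(sq, 0); B <- cbind(sq, 0.3)
  tri <- tile_adjacent_contours(A, B, d_max = 1)
  expect_equal(nrow(tri), 8L)
  mesh <- triangle_mesh(rbind(A, B), tri)
  e <- persiseg:::mesh_edges(mesh)
  # Euler characteristic of a tube (annulus) is 0
  expect_equal(nrow(mesh$vertices) - nrow(e) + nrow(tri), 0L)
})

test_that("contours farther than d_max generate no triangles", {
  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
  A <- cbind(sq, 0)
  B <- cbind(sq[, 1] + 2, sq[, 2], 0.3)   # 2 um lateral offset, d_max 1
  expect_equal(nrow(tile_adjacent_contours(A, B, d_max = 1)), 0L)
})

test_that("membrane contours split at the extreme columns toward the lumen", {
  circ <- circle3d(5, 0, n = 36, center = c(10, 10))
  # y grows downward; lumen 'up' means smaller y
  arcs <- split_basal_luminal(circ, "up")
  expect_lt(mean(arcs$luminal[, 2]), mean(arcs$basal[, 2]))
  split_x <- c(arcs$luminal[1, 1], arcs$luminal[nrow(arcs$luminal), 1])
  expect_setequal(round(split_x, 6), round(range(circ$vertices[, 1]), 6))
  # cavity contours are attached whole to the luminal side
  cav <- circ; cav$role <- "cavity"
  arcs2 <- split_basal_luminal(cav, "up")
  expect_equal(nrow(arcs2$luminal), nrow(circ$vertices))
  expect_equal(nrow(arcs2$basal), 0L)
  expect_error(split_basal_luminal(circ, NULL), "lumen_direction")
})

test_that("phantom reconstruction meets the distance and separation contracts", {
  ph <- generate_phantom_stack(small_phantom_params())
  segs <- lapply(seq_along(ph$stack), function(z)
    segment_slice(intensity_image(ph$stack[[z]]$values), slice_index = z))
  mesh <- reconstruct_mesh(segs)
  aud <- audit_mesh(mesh, 1.0)
  expect_true(aud$d_max_ok)
  expect_true(aud$welding_ok)
  expect_equal(aud$components, ph$truth$expected_components)
  # every component is pure in role class (cavity vs membrane)
  comp <- persiseg:::mesh_vertex_components(mesh)
  for (cc in unique(comp[!is.na(comp)])) {
    roles <- unique(mesh$role[which(comp == cc)])
    expect_true(all(roles == 3L) || all(roles %in% c(1L, 2L)))
  }
})

test_that("large slice gaps split the surface instead of tiling across", {
  ph <- generate_phantom_stack(small_phantom_params())
  segs <- lapply(seq_along(ph$stack), function(z)
    segment_slice(intensity_image(ph$stack[[z]]$values), slice_index = z))
  contiguous <- reconstruct_mesh(segs[c(1, 2, 3)])
  gapped <- reconstruct_mesh(segs[c(1, 2, 5, 6)])   # gap of 3 slices
  expect_equal(mesh_component_count(gapped),
               2L * mesh_component_count(contiguous))
})

test_that("a stack of identical circles tiles to a tube of the expected area", {
  zs <- seq(0, by = 0.3, length.out = 11)
  verts <- NULL; tris <- NULL
  for (i in seq_along(zs)) {
    ci <- circle3d(5, zs[i], n = 72)
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, ci$vertices)
    if (i > 1) {
      tri <- tile_adjacent_contours(circle3d(5, zs[i - 1], n = 72), ci, 1)
      tri[tri > 72] <- tri[tri > 72] - 72L + off
      tri[tri <= 72] <- tri[tri <= 72] + off - 72L
      tris <- rbind(tris, tri)
    }
  }
  mesh <- triangle_mesh(verts, tris)
  perim <- 72 * 2 * 5 * sin(pi / 72)
  expect_lt(abs(sum(triangle_areas(mesh)) - perim * (max(zs) - min(zs))) /
              (perim * (max(zs) - min(zs))), 0.05)
})

test_that("Taubin smoothing preserves volume and reduces curvature noise", {
  s <- icosphere_mesh(3)
  expect_identical(taubin_smooth(s, iters = 0L), s)
  v0 <- abs(mesh_volume(s))
  s2 <- taubin_smooth(s, 0.5, -0.53, 10L)
  expect_lt(abs(abs(mesh_volume(s2)) - v0) / v0, 0.02)
  expect_identical(s2$triangles, s$triangles)

  set.seed(6)
  noisy <- s
  jitter <- 1 + rnorm(nrow(s$vertices), sd = 0.03)
  noisy$vertices <- s$vertices * jitter
  sm <- taubin_smooth(noisy, 0.5, -0.53, 10L)
  expect_lt(var(curvature_proxy(sm)), var(curvature_proxy(noisy)))

  expect_error(taubin_smooth(s, 0.5, -0.4, 5L), "mu < -lambda")
})

test_that("uniform remeshing equalizes triangle areas and keeps topology", {
  tb <- tube_mesh(1, 48, cumsum(c(0, 0.05 * 1.15^(0:29))))
  rm <- remesh_uniform(tb, 600)
  expect_lt(abs(nrow(rm$vertices) - 600) / 600, 0.1)
  expect_lt(cv_of(triangle_areas(rm)), 0.5 * cv_of(triangle_areas(tb)))
  expect_equal(mesh_component_count(rm), mesh_component_count(tb))

  s <- icosphere_mesh(2)
  ri <- remesh_uniform(s, nrow(s$vertices))
  expect_lte(cv_of(triangle_areas(ri)), cv_of(triangle_areas(s)) + 1e-9)

  r4 <- suppressWarnings(remesh_uniform(s, 4))
  expect_equal(nrow(r4$vertices), 4L)
  expect_gte(nrow(r4$triangles), 2L)
  expect_equal(mesh_component_count(r4), 1L)

  expect_warning(big <- remesh_uniform(s, 10 * nrow(s$vertices)), "target")
  expect_identical(big, s)
  expect_error(remesh_uniform(s, 3), "at least 4")
})

test_that("mesh writers emit readable PLY and OBJ", {
  dir <- withr::local_tempdir()
  mesh <- icosphere_mesh(1)
  ply <- file.path(dir, "m.ply"); obj <- file.path(dir, "m.obj")
  write_ply(mesh, ply); write_obj(mesh, obj)
  hdr <- readLines(ply, n = 10)
  expect_equal(hdr[1], "ply")
  expect_true(any(grepl("property int role", hdr)))
  expect_true(any(grepl(sprintf("element vertex %d", nrow(mesh$vertices)), hdr)))
  objl <- readLines(obj)
  expect_equal(sum(startsWith(objl, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(objl, "f ")), nrow(mesh$triangles))
})

test_that("degenerate triangles are rejected by the mesh constructor", {
  expect_error(triangle_mesh(diag(3), rbind(c(1, 1, 2))), "degenerate")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
})
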