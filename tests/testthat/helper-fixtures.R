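# shared fixtures and small utilities for the test suite

cv_of <- function(x) stats::sd(x) / mean(x)

disk_mask <- function(H, W, ctr, r) {
  d <- sqrt(outer((seq_len(H) - ctr[1])^2, (seq_len(W) - ctr[2])^2, "+"))
  d <= r
}

# small, fast phantom used by unit tests (the default study-size phantom is
# exercised by the acceptance suite)
small_phantom_params <- function(...) {
  phantom_params(shape = c(64L, 64L, 6L), center = c(32.5, 32.5),
                 membrane_radii = c(24, 24, 30), z_center = 3.5,
                 band_thickness = 4,
                 invagination = list(width = 5, depth = 10),
                 cavities = list(
                   list(center = c(39, 23, 3.5), radii = c(5, 5, 10),
                        intensity = 0.10),
                   list(center = c(38, 42, 3.5), radii = c(4, 4, 10),
                        intensity = 0.10)),
                 ...)
}

# mean distance from contour vertices to the crack boundary of a truth mask
mean_contour_distance <- function(contour, truth_mask) {
  truth_v <- trace_region_boundary(truth_mask)
  directed_mean <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  directed_mean(contour$vertices, truth_v)
}

# discrete mean-curvature proxy: norm of the uniform-Laplacian vector
curvature_proxy <- function(mesh) {
  e <- persiseg:::mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  src <- c(e[, 1], e[, 2]); dst <- c(e[, 2], e[, 1])
  deg <- tabulate(src, n)
  nb <- rowsum(mesh$vertices[dst, , drop = FALSE], src, reorder = TRUE)
  idx <- as.integer(rownames(nb))
  lap <- nb / deg[idx] - mesh$vertices[idx, , drop = FALSE]
  sqrt(rowSums(lap^2))
}

# lifted polygon circle (smooth, analytic) for tiling tests
circle3d <- function(radius, z, n = 64L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  structure(list(vertices = cbind(center[1] + radius * cos(th),
                                  center[2] + radius * sin(th), z),
                 closed = TRUE, role = "membrane", cavity_id = NA_integer_),
            class = "contour3d")
}
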